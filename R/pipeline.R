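#' Pipeline configuration
#'
#' Resolved thresholds and run parameters for an end-to-end run. All call
#' thresholds default to the values used throughout the package
#' (half-life fold change 1.5; TE fold change 1.5 at raw p < 0.05;
#' delta-Psi 0.1 at FDR < 0.05; GLORI replicate rate 0.1; exon-to-m6A
#' window 10,000 nt; editing gates 5-99% rate, 1.5x control ratio, 2
#' mutations). Overrides are recorded in the resolved config written next
#' to the outputs.
#'
#' @param seed Mandatory seed for every stochastic stage.
#' @param cell_type Cell-type label stamped on outputs.
#' @param sim A [sim_config()] (defaults to `sim_config(seed)`), for runs
#'   on synthetic inputs.
#' @param ... Threshold overrides: `hl_fc`, `te_fc`, `te_p`, `dpsi`,
#'   `psi_fdr`, `glori_rate`, `exon_window`, `tribe_rate_min`,
#'   `tribe_rate_max`, `tribe_control_ratio`, `tribe_min_mutations`,
#'   `nfolds`, `nrounds`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, cell_type = "synthetic",
                            sim = sim_config(seed), ...) {
  stopifnot(!missing(seed))
  cfg <- list(seed = seed, cell_type = cell_type, sim = sim,
              hl_fc = 1.5, te_fc = 1.5, te_p = 0.05,
              dpsi = 0.1, psi_fdr = 0.05, glori_rate = 0.1,
              exon_window = 10000,
              tribe_rate_min = 0.05, tribe_rate_max = 0.99,
              tribe_control_ratio = 1.5, tribe_min_mutations = 2,
              nfolds = 10, nrounds = 300)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with a `seed` field and optional overrides
#'   (threshold names as in [pipeline_config()], plus a `sim` block of
#'   [sim_config()] arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must provide a seed")
  sim_args <- y$sim %||% list()
  sim_args$seed <- sim_args$seed %||% y$seed
  y$sim <- NULL
  seed <- y$seed; y$seed <- NULL
  cell_type <- y$cell_type %||% "synthetic"; y$cell_type <- NULL
  do.call(pipeline_config,
          c(list(seed = seed, cell_type = cell_type,
                 sim = do.call(sim_config, sim_args)), y))
}

write_stamped_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# readingm6a %s | cell_type=%s | seed=%d",
                     as.character(utils::packageVersion("readingm6a")),
                     cfg$cell_type, cfg$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates all inputs from the configured simulation, then executes
#' readout calling (half-life, TE, Psi), m6A site filtering, RBP-context
#' feature encoding, classifier training with cross-validation, and
#' editing-site calling, writing one TSV per stage plus a resolved config
#' copy into `out_dir`. The run is deterministic given the same config
#' and seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the per-stage results (`halflife`,
#'   `te`, `splicing`, `sites`, `features`, `cv`, `importance`,
#'   `editing`, `truth`) and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done", name))
    res
  }

  sim <- stage("simulate", {
    s <- gen_transcriptome(cfg$sim)
    truth <- gen_ground_truth(cfg$sim, s)
    list(sim = s, truth = truth)
  })

  hl <- stage("halflife", {
    cm <- ercc_normalize(gen_decay_experiment(cfg$sim, sim$truth))
    classify_halflife(fit_decay(cm, "shControl"),
                      fit_decay(cm, "shMETTL3"), fc_threshold = cfg$hl_fc)
  })
  te <- stage("te", {
    e <- gen_te_experiment(cfg$sim, sim$truth)
    te_change(e$rpf, e$rna, fc_threshold = cfg$te_fc,
              p_threshold = cfg$te_p)
  })
  sp <- stage("splice", {
    classify_splicing(gen_psi_experiment(cfg$sim, sim$truth, sim$sim),
                      dpsi_threshold = cfg$dpsi,
                      fdr_threshold = cfg$psi_fdr)
  })
  sites <- stage("sites", {
    filter_glori(sim$sim$m6a, NULL, min_rate = cfg$glori_rate)
  })
  feats <- stage("encode", {
    fx <- gen_readout_features(cfg$sim, sim$sim)
    f <- assemble_features(unique(sites$gene_id), sites, fx$tracks,
                           sim$sim$txome, genome = sim$sim$genome,
                           level = "gene", exon_window = cfg$exon_window)
    list(features = f, labels = fx$labels, reader = fx$reader)
  })
  cv <- stage("model", {
    train_cv(feats$features, feats$labels, seed = cfg$seed,
             nfolds = cfg$nfolds, nrounds = cfg$nrounds)
  })
  imp <- rbp_importance(cv)
  ed <- stage("tribe", {
    se <- gen_editing_data(cfg$sim)
    call_editing_sites(se$records, se$snp_mask,
                       rate_min = cfg$tribe_rate_min,
                       rate_max = cfg$tribe_rate_max,
                       control_ratio = cfg$tribe_control_ratio,
                       min_mutations = cfg$tribe_min_mutations)
  })

  calls <- rbind(
    data.frame(unit_id = hl$gene_id, layer = "halflife", call = hl$call),
    data.frame(unit_id = te$gene_id, layer = "te", call = te$call),
    data.frame(unit_id = sp$event_id, layer = "splicing", call = sp$call))
  write_stamped_tsv(calls, file.path(out_dir, "readout_calls.tsv"), cfg)
  write_stamped_tsv(hl, file.path(out_dir, "halflife.tsv"), cfg)
  write_stamped_tsv(te, file.path(out_dir, "te_change.tsv"), cfg)
  write_stamped_tsv(sp, file.path(out_dir, "psi_events.tsv"), cfg)
  write_stamped_tsv(as.data.frame(sites),
                    file.path(out_dir, "m6a_sites.tsv"), cfg)
  write_stamped_tsv(data.frame(unit_id = names(cv$scores),
                               score = as.numeric(cv$scores),
                               label = cv$labels, fold = cv$fold),
                    file.path(out_dir, "cv_scores.tsv"), cfg)
  write_stamped_tsv(imp$rbp_ranking,
                    file.path(out_dir, "importance.tsv"), cfg)
  write_stamped_tsv(ed$sites, file.path(out_dir, "editing_calls.tsv"), cfg)
  resolved <- unclass(cfg); resolved$sim <- unclass(resolved$sim)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))

  invisible(list(halflife = hl, te = te, splicing = sp, sites = sites,
                 features = feats, cv = cv, importance = imp, editing = ed,
                 truth = sim$truth, sim = sim$sim, out_dir = out_dir))
}
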