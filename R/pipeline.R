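# End-to-end orchestration: simulate (or read) inputs, run the LMM
# screen and variance partition, the MERF evaluation, the pathway
# contribution tables and the power calculation, and write all outputs
# plus a machine-readable summary.

# Small deterministic polynomial hash for config provenance (hex string).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Collects the analysis constants in one place: the diagnostic cut
#' points (PTSD raw score strictly greater than 31; depression t-score at
#' least 60), the false-discovery level 0.05, the ten MERF seeds, and the
#' power-analysis design (rho 0.5 at n 51).
#'
#' @param sim a [sim_config()] used when no input paths are given.
#' @param species_path,pathways_path,cohort_path,outcomes_path optional
#'   paths to on-disk inputs replacing simulation.
#' @param outcomes named character vector mapping analysis labels to
#'   panel columns.
#' @param merf_outcomes labels (subset of `names(outcomes)`) evaluated by
#'   the MERF stage.
#' @param fdr_level screen selection level.
#' @param seeds MERF evaluation seeds.
#' @param merf a [merf_control()].
#' @param n_repeats permutation-importance repeats.
#' @param ptsd_cut,dep_cut diagnostic cut points.
#' @param group_week week whose diagnosis defines contribution groups.
#' @param contrib_rank taxonomic rank for contribution tables.
#' @param power_rho,power_n,power_alpha power-analysis design.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       species_path = NULL, pathways_path = NULL,
                       cohort_path = NULL, outcomes_path = NULL,
                       outcomes = c(ptsd = "pcl5_raw",
                                    depression = "promis_t",
                                    somatic = "somatic_count"),
                       merf_outcomes = names(outcomes),
                       fdr_level = 0.05, seeds = 0:9,
                       merf = merf_control(), n_repeats = 5,
                       ptsd_cut = 31, dep_cut = 60, group_week = 12,
                       contrib_rank = "genus",
                       power_rho = 0.5, power_n = 51, power_alpha = 0.05,
                       out_dir = "results") {
  if (!all(names(outcomes) %in% c("ptsd", "depression", "somatic")) ||
      length(outcomes) == 0)
    stop("config error: outcome labels must be ptsd/depression/somatic")
  if (!all(merf_outcomes %in% names(outcomes)))
    stop("config error: merf_outcomes must name configured outcomes")
  if (fdr_level <= 0 || fdr_level >= 1)
    stop("config error: fdr_level must lie in (0, 1)")
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulation (or input loading), the per-outcome LMM screen,
#' global model and variance partition, the multi-seed MERF evaluation
#' with permutation importance, the diagnosis-stratified pathway
#' contribution tables, and the power analysis. All tabular outputs are
#' written as CSV under `config$out_dir` together with `summary.json`.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[gutapns] ", ...)
  summary <- list(
    package_version = as.character(utils::packageVersion("gutapns")),
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    seeds = config$seeds)

  data <- stage("simulate", {
    if (!is.null(config$species_path)) {
      list(species = read_species_table(config$species_path),
           pathways = read_pathway_table(config$pathways_path),
           cohort = utils::read.csv(config$cohort_path,
                                    stringsAsFactors = FALSE),
           panel = utils::read.csv(config$outcomes_path,
                                   stringsAsFactors = FALSE),
           truth = NULL)
    } else {
      log_msg("simulating synthetic study (seed ", config$sim$seed, ")")
      study <- simulate_study(config$sim)
      write_tables(list(synthetic = study$species,
                        synthetic_pw = study$pathways),
                   config$out_dir)
      utils::write.csv(study$cohort,
                       file.path(config$out_dir, "synthetic_cohort.csv"),
                       row.names = FALSE)
      utils::write.csv(study$panel,
                       file.path(config$out_dir, "synthetic_outcomes.csv"),
                       row.names = FALSE)
      study
    }
  })
  summary$n_subjects <- nrow(data$cohort)
  summary$n_species <- length(data$species$species)

  summary$screen <- list()
  partitions <- list()
  for (lbl in names(config$outcomes)) {
    oc <- config$outcomes[[lbl]]
    res <- stage(paste0("screen_", lbl), {
      log_msg("screening species for ", lbl, " (", oc, ")")
      scr <- screen_features(data$panel, data$species, data$cohort, oc,
                             fdr_level = config$fdr_level)
      utils::write.csv(scr, file.path(config$out_dir,
                                      paste0("screen_", lbl, ".csv")),
                       row.names = FALSE)
      glm <- fit_global_lmm(scr, data$panel, data$species, data$cohort, oc)
      vp <- variance_partition(glm)
      vp_out <- as.data.frame(vp)
      vp_out$residual_ratio <- rep(attr(vp, "residual_ratio"),
                                   length.out = nrow(vp_out))
      utils::write.csv(vp_out,
                       file.path(config$out_dir,
                                 paste0("variance_partition_", lbl, ".csv")),
                       row.names = FALSE)
      list(scr = scr, vp = vp)
    })
    partitions[[lbl]] <- res$vp
    summary$screen[[lbl]] <- list(
      n_selected = sum(res$scr$selected),
      microbiome_share = attr(res$vp, "microbiome_share"))
  }

  feats <- stage("features", merf_features(data$species, data$cohort))
  summary$merf <- list()
  for (lbl in config$merf_outcomes) {
    oc <- config$outcomes[[lbl]]
    res <- stage(paste0("merf_", lbl), {
      log_msg("MERF evaluation for ", lbl, " over ",
              length(config$seeds), " seeds")
      runs <- run_seeds(data$panel, feats, oc, seeds = config$seeds,
                        control = config$merf, n_repeats = config$n_repeats)
      metrics <- do.call(rbind, lapply(runs, function(r) {
        data.frame(seed = r$seed,
                   rmse_test = if (is.null(r$error)) r$rmse_test else NA,
                   corr_test = if (is.null(r$error)) r$corr_test else NA,
                   error = if (is.null(r$error)) "" else r$error)
      }))
      utils::write.csv(metrics,
                       file.path(config$out_dir,
                                 paste0("merf_metrics_", lbl, ".csv")),
                       row.names = FALSE)
      rows <- data$panel$subject_id
      imp <- aggregate_importance(runs,
                                  feature_data = feats[rows, , drop = FALSE],
                                  outcome_values = data$panel[[oc]])
      utils::write.csv(imp,
                       file.path(config$out_dir,
                                 paste0("importance_", lbl, ".csv")),
                       row.names = FALSE)
      list(metrics = metrics, imp = imp)
    })
    summary$merf[[lbl]] <- list(
      mean_rmse = mean(res$metrics$rmse_test, na.rm = TRUE),
      mean_corr = mean(res$metrics$corr_test, na.rm = TRUE),
      top_feature = if (nrow(res$imp) > 0) res$imp$feature[1] else NA)
  }

  contrib <- stage("pathway_contrib", {
    wk <- data$panel[data$panel$week == config$group_week, ]
    diag_of <- function(lbl) {
      v <- if (lbl == "ptsd") {
        ifelse(diagnose_ptsd(wk$pcl5_raw, config$ptsd_cut),
               paste0("PTSD Raw Score > ", config$ptsd_cut),
               paste0("PTSD Raw Score <= ", config$ptsd_cut))
      } else {
        ifelse(diagnose_depression(wk$promis_t, config$dep_cut),
               paste0("Depression t-score >= ", config$dep_cut),
               paste0("Depression t-score < ", config$dep_cut))
      }
      stats::setNames(v, data$cohort$sample_id[
        match(wk$subject_id, data$cohort$subject_id)])
    }
    ids <- unique(sub(":.*$", "", sub("\\|.*$", "",
      pathways_with_strata(data$pathways))))
    tabs <- list()
    for (lbl in intersect(c("ptsd", "depression"), names(config$outcomes))) {
      groups <- diag_of(lbl)
      for (id in ids) {
        fr <- taxon_fractions(data$pathways, id, rank = config$contrib_rank)
        tabs[[paste(lbl, id)]] <- group_contribution(fr, groups)
      }
    }
    tab <- do.call(rbind, tabs)
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(config$out_dir, "pathway_contributions.csv"),
                     row.names = FALSE)
    tab
  })
  summary$pathway_contrib <- list(n_pathways = length(unique(contrib$pathway_id)))

  summary$power <- stage("power", list(
    rho = config$power_rho, n = config$power_n, alpha = config$power_alpha,
    power = round(spearman_power(config$power_rho, config$power_n,
                                 config$power_alpha), 4)))

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  log_msg("wrote ", file.path(config$out_dir, "summary.json"))
  invisible(summary)
}

# pathway keys that have at least one stratified row
pathways_with_strata <- function(pw) {
  keys <- pw$row_keys
  strat <- grepl("|", keys, fixed = TRUE)
  unique(sub("\\|.*$", "", keys[strat]))
}
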