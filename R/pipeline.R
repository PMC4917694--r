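#' Study-replica run configuration
#'
#' Bundles the cohort specification with analysis toggles and output
#' location.  A run is a pure function of its configuration: identical
#' configurations (including seed) produce identical report bundles.
#'
#' @param n_normal_subjects,n_asym_kc_subjects,seed,rho passed to
#'   [cohort_spec()].
#' @param posthoc_adjust pairwise p-value adjustment (`"none"` or `"holm"`).
#' @param truncate_ci report truncated AUC CIs (the raw Wald bounds are
#'   always written alongside).
#' @param transform_nonmonotone apply the probability transform to
#'   non-monotone markers before ROC analysis.
#' @param combos named list of feature subsets for the combined models, one
#'   per pairwise comparison (the all-variable set excludes `Min_Max_ep`,
#'   which is `Min_ep - Max` by definition and therefore aliased).
#' @param outdir output directory.
#' @param write_maps also write the full long-format map CSV (large).
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(n_normal_subjects = 52L, n_asym_kc_subjects = 22L,
                       seed = 1L, rho = 0.5,
                       posthoc_adjust = "none", truncate_ci = TRUE,
                       transform_nonmonotone = TRUE,
                       combos = list(
                         keratoconic_vs_normal = c("Min_Med", "S_I", "Min_ep"),
                         keratoconic_vs_fellow = c("SD", "CCT"),
                         fellow_vs_normal = setdiff(feature_names, "Min_Max_ep")),
                       outdir = "results/study", write_maps = FALSE) {
  spec <- cohort_spec(n_normal_subjects, n_asym_kc_subjects, seed, rho)
  structure(list(spec = spec, posthoc_adjust = posthoc_adjust,
                 truncate_ci = truncate_ci,
                 transform_nonmonotone = transform_nonmonotone,
                 combos = combos, outdir = outdir, write_maps = write_maps),
            class = "run_config")
}

#' Read / write a run configuration
#'
#' Plain-text (YAML) round trip of the scalar configuration fields; the
#' calibration stays at package defaults unless overridden in code.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(
    n_normal_subjects = config$spec$n_normal_subjects,
    n_asym_kc_subjects = config$spec$n_asym_kc_subjects,
    seed = config$spec$seed, rho = config$spec$rho,
    posthoc_adjust = config$posthoc_adjust,
    truncate_ci = config$truncate_ci,
    transform_nonmonotone = config$transform_nonmonotone,
    combos = config$combos,
    outdir = config$outdir, write_maps = config$write_maps), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(y$n_normal_subjects, y$n_asym_kc_subjects, y$seed, y$rho,
             y$posthoc_adjust, y$truncate_ci, y$transform_nonmonotone,
             lapply(y$combos, unlist), y$outdir, y$write_maps)
}

study_pairs <- function() {
  list(keratoconic_vs_normal = c("keratoconic", "normal"),
       keratoconic_vs_fellow = c("keratoconic", "fellow"),
       fellow_vs_normal = c("fellow", "normal"))
}

#' Run the full study replica
#'
#' simulate -> extract -> screen -> stats -> ROC, writing the report bundle
#' under `config$outdir`: the eye roster, the 14-variable feature table,
#' per-eye screening results, the three-group summary table, the
#' hypothesis tests, one single-variable AUC table per pairwise comparison
#' (disease = first group of the pair), the combined-model table, ROC curve
#' points for the fellow-versus-normal comparison, and a run manifest.
#' Progress is logged to stderr.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory tables and output paths.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
                                     ...)
  out <- function(name) file.path(config$outdir, name)
  wcsv <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE)
    out(name)
  }

  log_stage("simulate: ", config$spec$n_normal_subjects, " healthy + ",
            config$spec$n_asym_kc_subjects, " asymmetric-KC subjects, seed ",
            config$spec$seed)
  eyes <- generate_cohort(config$spec)
  roster <- data.frame(
    patient_id = vapply(eyes, `[[`, "", "patient_id"),
    side = vapply(eyes, `[[`, "", "side"),
    group = vapply(eyes, `[[`, "", "group"),
    slit_lamp_kc = vapply(eyes, function(e) isTRUE(e$slit_lamp_kc), logical(1)))
  wcsv(roster, "cohort.csv")
  if (config$write_maps) wcsv(maps_to_long(eyes), "maps.csv")

  log_stage("extract: 14 variables for ", length(eyes), " eyes")
  feats <- extract_features(eyes)
  wcsv(feats, "features.csv")

  log_stage("screen: topographic criteria")
  screen <- screen_cohort(eyes)
  wcsv(screen, "screening.csv")

  log_stage("stats: summaries, KS, Kruskal-Wallis + post hoc")
  summ <- summarize_features(feats)
  tests <- test_features(feats, adjust = config$posthoc_adjust)
  wcsv(summ, "summary.csv")
  wcsv(tests, "tests.csv")

  log_stage("roc: per-variable cluster-adjusted AUCs")
  aucs <- list()
  for (pair_name in names(study_pairs())) {
    pair <- study_pairs()[[pair_name]]
    sub <- feats[feats$group %in% pair, ]
    tab <- auc_table(sub, labels = sub$group == pair[1],
                     cluster_ids = sub$patient_id,
                     transform_nonmonotone = config$transform_nonmonotone)
    aucs[[pair_name]] <- tab
    wcsv(tab, paste0("auc_", pair_name, ".csv"))
  }

  log_stage("roc: combined models")
  combined <- do.call(rbind, lapply(names(config$combos), function(pair_name) {
    pair <- study_pairs()[[pair_name]]
    vars <- config$combos[[pair_name]]
    sub <- feats[feats$group %in% pair, ]
    cm <- glm_combine(sub[, vars, drop = FALSE], sub$group == pair[1],
                      cluster_ids = sub$patient_id)
    data.frame(comparison = pair_name,
               variables = paste(vars, collapse = "+"),
               auc = cm$auc$auc, se = cm$auc$se,
               ci_low = cm$auc$ci95[1], ci_high = cm$auc$ci95[2],
               ci_low_raw = cm$auc$ci95_untruncated[1],
               ci_high_raw = cm$auc$ci95_untruncated[2])
  }))
  wcsv(combined, "combined_models.csv")

  sub <- feats[feats$group %in% c("fellow", "normal"), ]
  roc_fig <- do.call(rbind, lapply(c("Min", "Y_location", "CCT"), function(f) {
    cbind(variable = f, roc_points(sub[[f]], sub$group == "fellow"))
  }))
  cm_all <- glm_combine(sub[, config$combos$fellow_vs_normal, drop = FALSE],
                        sub$group == "fellow")
  roc_fig <- rbind(roc_fig, cbind(variable = "combined",
                                  roc_points(cm_all$linear_predictor,
                                             sub$group == "fellow")))
  wcsv(roc_fig, "roc_curves_fellow_vs_normal.csv")

  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(seed = config$spec$seed,
                   n_eyes = length(eyes),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   package_version = as.character(utils::packageVersion("kcmaps")),
                   config_md5 = unname(tools::md5sum(cfg_path)))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  log_stage("done: report bundle in ", config$outdir)

  invisible(list(eyes = eyes, features = feats, screening = screen,
                 summary = summ, tests = tests, aucs = aucs,
                 combined = combined, outdir = config$outdir))
}
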