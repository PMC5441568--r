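# Pipeline configuration, orchestration and reporting: ties the generator,
# preprocessing, ICA, classification and statistics stages into one
# reproducible run driven by a single config and a single seed.

#' Pipeline configuration
#'
#' Defaults equal the declared analysis parameters: 20 components,
#' 0.01-0.08 Hz band, 6 mm FWHM, 6 dropped volumes, target mean 10,000,
#' 1000 map permutations, 10,000 score permutations, alpha = 0.05,
#' Bonferroni family of 4.  A single global `seed` fans out to per-stage
#' seeds by fixed offsets.
#'
#' @param out_dir output directory for stage artifacts.
#' @param data_dir optional directory with an existing cohort (written by
#'   [write_cohort()]); when given, synthesis is skipped.
#' @param seed global seed.
#' @param synth a [cohort_config()] for the synthesis stage (its seed is
#'   overridden by the global seed).
#' @param grid_shape atlas grid for synthesis.
#' @param preprocess,ica,classifier,stats named lists overriding stage
#'   parameters (see Details in the package vignette).
#' @return list of class `icn_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("icnscore_run_"),
                            data_dir = NULL, seed = 1,
                            synth = cohort_config(),
                            grid_shape = c(16, 16, 8),
                            preprocess = list(), ica = list(),
                            classifier = list(), stats = list()) {
  cfg <- list(
    paths = list(out_dir = out_dir, data_dir = data_dir),
    seed = as.integer(seed),
    synth = synth,
    grid_shape = grid_shape,
    preprocess = modifyList(list(k_drop = 6, target_mean = 10000,
                                 band = c(0.01, 0.08), fwhm_mm = 6), preprocess),
    ica = modifyList(list(k = 20, mode = "dual_regression"), ica),
    classifier = modifyList(list(anchors = c(1L, 2L), pca_dim = 50,
                                 C = c(0.01, 0.1, 1, 10, 100),
                                 gamma_mult = c(1, 10)), classifier),
    stats = modifyList(list(n_perm_maps = 1000, n_perm_scores = 10000,
                            alpha = 0.05, family_size = 4,
                            fc_components = NULL), stats))
  class(cfg) <- "icn_config"
  cfg
}

#' Run the full pipeline
#'
#' Executes synthesis (unless `data_dir` is set) -> preprocessing -> group
#' ICA -> subject ICNs -> nested LOO ensemble -> follow-up scoring ->
#' permutation/association statistics, writing scores, metrics, ROC points,
#' selection frequencies and association tables under `out_dir` together
#' with a JSON run manifest.
#'
#' @param config an [pipeline_config()].
#' @param keep_scans keep preprocessed scans in the returned object
#'   (memory-heavy; default FALSE).
#' @return list of class `icn_run`: `ensemble`, `followup`,
#'   `score_decrease`, `association`, `fc_perm`, `match`, `manifest`, plus
#'   the `records` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), keep_scans = FALSE) {
  stopifnot(inherits(config, "icn_config"))
  t0 <- Sys.time()
  dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[icnscore] ", fmt), ...))
  stages_done <- character(0)

  # --- stage 1: data ---------------------------------------------------------
  if (is.null(config$paths$data_dir)) {
    synth <- config$synth
    synth$seed <- .child_seed(config$seed, 1L)
    atlas <- make_atlas(config$grid_shape, k = synth$k_components,
                        seed = .child_seed(config$seed, 2L))
    log_stage("simulate: %d+%d subjects, %d components, delta = %g",
              synth$n_patients, synth$n_controls, synth$k_components, synth$delta)
    cohort <- simulate_cohort(atlas, synth)
    scans <- cohort$scans; nuisance <- cohort$nuisance; records <- cohort$records
    truth <- cohort$truth
  } else {
    if (!dir.exists(config$paths$data_dir))
      stop(sprintf("path error: data_dir %s does not exist", config$paths$data_dir),
           call. = FALSE)
    log_stage("load cohort from %s", config$paths$data_dir)
    loaded <- read_cohort(config$paths$data_dir)
    scans <- loaded$scans; nuisance <- loaded$nuisance; records <- loaded$records
    atlas <- NULL; truth <- NULL
  }
  stages_done <- c(stages_done, "data")

  # --- stage 2: preprocessing ------------------------------------------------
  log_stage("preprocess: %d scans", length(scans))
  pp <- config$preprocess
  scans <- lapply(names(scans), function(key) {
    preprocess_scan(scans[[key]], nuisance[[key]],
                    params = list(k_drop = pp$k_drop, target_mean = pp$target_mean,
                                  band = pp$band, fwhm_mm = pp$fwhm_mm))
  })
  names(scans) <- paste(vapply(scans, `[[`, "", "subject_id"),
                        vapply(scans, `[[`, "", "session"), sep = "_")
  stages_done <- c(stages_done, "preprocess")

  # --- stage 3: group ICA + subject ICNs ------------------------------------
  base_keys <- names(scans)[vapply(scans, function(s) s$session == "baseline", logical(1))]
  log_stage("group ICA: k = %d on %d baseline scans", config$ica$k, length(base_keys))
  gica <- group_ica(scans[base_keys], k = config$ica$k,
                    seed = .child_seed(config$seed, 3L))
  match <- if (!is.null(atlas)) match_templates(gica, atlas) else NULL
  log_stage("subject ICNs (%s)", config$ica$mode)
  icns <- lapply(scans, subject_icns, group = gica, mode = config$ica$mode)
  stages_done <- c(stages_done, "ica")

  # --- stage 4: classification ----------------------------------------------
  rec_base <- records[records$session == "baseline", ]
  ord <- match(base_keys, paste(rec_base$subject_id, "baseline", sep = "_"))
  rec_base <- rec_base[ord, ]
  anchors <- config$classifier$anchors
  if (!is.null(match)) {
    a <- match$component[match(c("DMN", "MTL"), match$label)]
    if (!any(is.na(a))) anchors <- a
  }
  feats <- feature_set(icns[base_keys], rec_base$group, anchors = anchors,
                       component_labels = if (!is.null(match)) match$label else NULL)
  grid <- svm_grid(C = config$classifier$C, gamma_mult = config$classifier$gamma_mult)
  log_stage("nested LOO ensemble: %d subjects", length(base_keys))
  ens <- loo_ensemble(feats, grid = grid, pca_dim = config$classifier$pca_dim,
                      seed = .child_seed(config$seed, 4L))
  fu_keys <- names(scans)[vapply(scans, function(s) s$session == "followup", logical(1))]
  followup <- NULL
  if (length(fu_keys) > 0) {
    rec_fu <- records[records$session == "followup", ]
    ord_fu <- match(fu_keys, paste(rec_fu$subject_id, "followup", sep = "_"))
    fu_feats <- feature_set(icns[fu_keys], rec_fu$group[ord_fu], anchors = anchors)
    log_stage("follow-up scoring: %d scans", length(fu_keys))
    followup <- score_followup(ens, fu_feats)
  }
  stages_done <- c(stages_done, "classify")

  # --- stage 5: statistics ---------------------------------------------------
  st <- config$stats
  score_decrease <- NULL; association <- NULL; fc_perm <- NULL
  if (!is.null(followup)) {
    log_stage("statistics: score decrease + association (%d pairs)", nrow(followup))
    score_decrease <- tryCatch(
      perm_score_decrease(followup$baseline_score, followup$followup_score,
                          n_perm = st$n_perm_scores, exclude_misclassified = TRUE,
                          seed = .child_seed(config$seed, 5L)),
      error = function(e) { warning(conditionMessage(e)); NULL })
    rec_fu <- records[records$session == "followup", ]
    rec_pre <- records[records$session == "baseline", ]
    m <- match(followup$subject_id, rec_fu$subject_id)
    mb <- match(followup$subject_id, rec_pre$subject_id)
    resp <- data.frame(
      total = treatment_response(rec_pre$panss_total[mb], rec_fu$panss_total[m]),
      pos = treatment_response(rec_pre$panss_pos[mb], rec_fu$panss_pos[m]),
      neg = treatment_response(rec_pre$panss_neg[mb], rec_fu$panss_neg[m]),
      gen = treatment_response(rec_pre$panss_gen[mb], rec_fu$panss_gen[m]))
    covs <- data.frame(age = rec_pre$age[mb], sex = rec_pre$sex[mb],
                       education_years = rec_pre$education_years[mb],
                       illness_years = rec_pre$illness_years[mb])
    association <- tryCatch(
      score_response_association(followup$baseline_score, resp, covs,
                                 family_size = st$family_size),
      error = function(e) { warning(conditionMessage(e)); NULL })

    # Voxelwise paired sign-flip tests on FC maps of the most-selected
    # components, per treatment arm.
    fc_comps <- st$fc_components
    if (is.null(fc_comps)) fc_comps <- which(ens$selection_freq > 0.5)
    fc_perm <- list()
    for (arm_name in c("ECT", "MED")) {
      sids <- rec_fu$subject_id[rec_fu$arm == arm_name]
      sids <- intersect(sids, followup$subject_id)
      if (length(sids) < 3) next
      for (cc in fc_comps) {
        pre <- lapply(sids, function(s) fc_map(scans[[paste0(s, "_baseline")]],
                                               icns[[paste0(s, "_baseline")]]$timecourses[cc, ]))
        post <- lapply(sids, function(s) fc_map(scans[[paste0(s, "_followup")]],
                                                icns[[paste0(s, "_followup")]]$timecourses[cc, ]))
        fc_perm[[sprintf("%s_comp%02d", arm_name, cc)]] <-
          paired_perm_test(pre, post, n_perm = st$n_perm_maps, alpha = st$alpha,
                           seed = .child_seed(config$seed, 600L + cc))
      }
    }
  }
  stages_done <- c(stages_done, "stats")

  # --- outputs ---------------------------------------------------------------
  out <- config$paths$out_dir
  write.csv(ens$scores, file.path(out, "scores.csv"), row.names = FALSE)
  if (!is.null(followup))
    write.csv(followup, file.path(out, "followup_scores.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(ens$metrics), file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(component = names(ens$selection_freq),
                       frequency = as.numeric(ens$selection_freq)),
            file.path(out, "selection_frequency.csv"), row.names = FALSE)
  roc <- .roc_points(ens$scores$aggregated_score, ens$scores$label)
  write.csv(roc, file.path(out, "roc.csv"), row.names = FALSE)
  if (!is.null(association))
    write.csv(as.data.frame(association), file.path(out, "association.csv"),
              row.names = FALSE)
  files <- list.files(out, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("icnscore")),
    seed = config$seed,
    config = .config_snapshot(config),
    stages = stages_done,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    outputs = data.frame(path = basename(files), md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(ensemble = ens, followup = followup,
                 score_decrease = score_decrease, association = association,
                 fc_perm = fc_perm, match = match, records = records,
                 truth = truth, gica = gica,
                 scans = if (keep_scans) scans else NULL,
                 manifest = manifest, config = config),
            class = "icn_run")
}

.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$synth <- unclass(snap$synth)
  snap
}

.roc_points <- function(scores, labels) {
  thr <- sort(unique(c(-Inf, scores, Inf)))
  pos <- labels > 0
  data.frame(threshold = thr,
             tpr = vapply(thr, function(t) mean(scores[pos] > t), numeric(1)),
             fpr = vapply(thr, function(t) mean(scores[!pos] > t), numeric(1)))
}

#' @export
print.icn_run <- function(x, ...) {
  cat("<icn_run>\n")
  print(x$ensemble$metrics)
  if (!is.null(x$score_decrease))
    cat(sprintf("score decrease: mean %.3f, one-tailed permutation p = %.4g (n = %d)\n",
                x$score_decrease$observed, x$score_decrease$p, x$score_decrease$n_pairs))
  if (!is.null(x$association)) {
    cat("baseline score vs response (covariate-adjusted Spearman):\n")
    print(as.data.frame(x$association)[, c("measure", "rho", "p_raw", "p_bonferroni")])
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `run-all` (full
#' pipeline), `report` (print a previous run's metrics).  Flags:
#' `--config` (JSON overriding [pipeline_config()] fields), `--seed`,
#' `--out`, `--data` (cohort directory, skips synthesis), `--mode`
#' (`dual_regression`/`guided`).  Used by the `inst/cli/icnscore` script.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
icn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: icnscore <simulate|run-all|report> [--config F] [--seed N] [--out D] [--data D] [--mode M]\n")
    return(invisible(1L))
  }
  cmd <- args[1]; args <- args[-1]
  opt <- list(seed = 1L, out = "icnscore_out", data = NULL, config = NULL,
              mode = "dual_regression")
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "skip-synthesis") { i <- i + 1; next }
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  cfg <- pipeline_config(out_dir = opt$out, data_dir = opt$data,
                         seed = as.integer(opt$seed),
                         ica = list(mode = opt$mode))
  if (!is.null(opt$config)) {
    user <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    cfg <- modifyList(cfg, user)
    class(cfg) <- "icn_config"
  }
  if (cmd == "simulate") {
    atlas <- make_atlas(cfg$grid_shape, k = cfg$synth$k_components,
                        seed = .child_seed(cfg$seed, 2L))
    synth <- cfg$synth; synth$seed <- .child_seed(cfg$seed, 1L)
    write_cohort(simulate_cohort(atlas, synth), opt$out)
    cat(sprintf("cohort written to %s\n", opt$out))
  } else if (cmd == "run-all") {
    run <- run_pipeline(cfg)
    print(run)
  } else if (cmd == "report") {
    mf <- file.path(opt$out, "metrics.json")
    if (!file.exists(mf)) stop(sprintf("no metrics.json under %s", opt$out), call. = FALSE)
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    cat(sprintf("accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | AUC %.3f\n",
                100 * m$accuracy, 100 * m$sensitivity, 100 * m$specificity, m$auc))
  } else {
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  }
  invisible(0L)
}
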