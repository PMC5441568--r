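# Synthetic cohort generator.
#
# The generative model mirrors what the downstream analysis assumes: each
# scan is a linear mixture of K smooth spatial component maps by subject
# loadings and band-limited time courses, plus nuisance contributions and
# Gaussian noise.  Patients deviate from controls in the mean loading of a
# designated "affected" component subset; after treatment each patient's
# affected loadings move a fraction rho_i back toward the control mean, and
# symptom improvement is generated as a noisy linear function of rho_i.
# Everything planted is recorded in `truth` so recovery is testable.

#' Build a dispersed-blob component atlas
#'
#' Places `k` spherical Gaussian blobs on a jittered lattice with enough
#' spacing that all pairwise spatial correlations stay below 0.3.  Components
#' 1 and 2 are labelled `DMN` and `MTL` (the a-priori anchor networks); the
#' first `n_affected` components (anchors included) form the default
#' affected set carrying group effects.
#'
#' @param grid_shape integer length-3 voxel grid dimensions.
#' @param k number of components (>= 2).
#' @param seed RNG seed; the atlas is a deterministic function of its inputs.
#' @param sigma_vox Gaussian blob width (SD, voxels).
#' @param n_affected size of the default affected component set.
#' @return an object of class `icn_atlas`: `grid_shape`, `maps` (k x voxel,
#'   non-negative, max exactly 1 per row), `labels`, `anchors`, `affected`,
#'   `centers`, `sigma_vox`.
#' @export
make_atlas <- function(grid_shape = c(16, 16, 8), k = 20, seed = 1,
                       sigma_vox = 1.1, n_affected = 6) {
  k <- .chk_count(k, "k", min = 2L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("invalid configuration: `grid_shape` must be 3 positive integers", call. = FALSE)
  spacing <- 4
  cand_axis <- function(d) {
    if (d < 5L) return(if (d >= 3L) (d + 1) / 2 else numeric(0))
    n_pos <- floor((d - 3) / spacing) + 1            # keep ~1.5 voxel margins
    offset <- (d - 1 - (n_pos - 1) * spacing) / 2 + 1
    offset + spacing * seq(0, n_pos - 1)
  }
  cx <- cand_axis(grid_shape[1]); cy <- cand_axis(grid_shape[2]); cz <- cand_axis(grid_shape[3])
  cand <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  if (nrow(cand) < k)
    stop(sprintf("invalid configuration: grid %s too small to place %d dispersed blobs (capacity %d)",
                 paste(grid_shape, collapse = "x"), k, nrow(cand)), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  centers <- cand[sample.int(nrow(cand), k), , drop = FALSE]
  centers <- centers + matrix(runif(3L * k, -0.5, 0.5), ncol = 3L)
  maps <- blob_maps(grid_shape, centers, sigma_vox)
  n_affected <- min(n_affected, k)
  labels <- if (k > 2) c("DMN", "MTL", sprintf("IC%02d", seq(3, length.out = k - 2)))
            else c("DMN", "MTL")[seq_len(k)]
  structure(
    list(grid_shape = grid_shape, maps = maps, labels = labels,
         anchors = seq_len(min(2L, k)), affected = seq_len(n_affected),
         centers = centers, sigma_vox = sigma_vox),
    class = "icn_atlas")
}

#' @export
print.icn_atlas <- function(x, ...) {
  cat(sprintf("<icn_atlas> %d components on %s grid; anchors: %s; affected: %s\n",
              nrow(x$maps), paste(x$grid_shape, collapse = "x"),
              paste(x$labels[x$anchors], collapse = ", "),
              paste(x$labels[x$affected], collapse = ", ")))
  invisible(x)
}

# Evaluate unit-peak Gaussian blob maps at given centers (k x 3).
blob_maps <- function(grid_shape, centers, sigma_vox) {
  vx <- seq_len(grid_shape[1]); vy <- seq_len(grid_shape[2]); vz <- seq_len(grid_shape[3])
  grid <- as.matrix(expand.grid(x = vx, y = vy, z = vz))
  k <- nrow(centers)
  maps <- matrix(0, nrow = k, ncol = nrow(grid))
  for (j in seq_len(k)) {
    d2 <- (grid[, 1] - centers[j, 1])^2 + (grid[, 2] - centers[j, 2])^2 +
          (grid[, 3] - centers[j, 3])^2
    m <- exp(-d2 / (2 * sigma_vox^2))
    maps[j, ] <- m / max(m)          # unit peak on the voxel grid
  }
  maps
}

# Save/restore .Random.seed so generator calls do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate band-limited component time courses
#'
#' Rows are built in the frequency domain with power concentrated in the
#' resting-state analysis band (0.01-0.08 Hz), then centred, orthogonalised
#' (Gram-Schmidt) and scaled to unit variance.  Exact orthogonality of the
#' zero-mean rows implies pairwise correlation 0.
#'
#' @param k number of time courses.
#' @param n_volumes series length (>= 30).
#' @param tr_seconds sampling interval in seconds.
#' @param seed RNG seed.
#' @param band in-band frequency range in Hz.
#' @return a `k x n_volumes` matrix, rows zero-mean and unit-variance.
#' @export
simulate_time_courses <- function(k, n_volumes, tr_seconds = 2, seed = 1,
                                  band = c(0.01, 0.08)) {
  k <- .chk_count(k, "k")
  if (!is.numeric(n_volumes) || n_volumes < 30)
    stop("invalid configuration: `n_volumes` must be >= 30", call. = FALSE)
  n_volumes <- as.integer(n_volumes)
  if (k >= n_volumes)
    stop("invalid configuration: need k < n_volumes for orthogonal rows", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  freqs <- seq(0, floor(n_volumes / 2)) / (n_volumes * tr_seconds)
  amp <- ifelse(freqs >= band[1] & freqs <= band[2], 1, 0.05)
  amp[1] <- 0                                     # no DC
  if (n_volumes %% 2 == 0) amp[length(amp)] <- 0  # drop Nyquist bin
  tc <- matrix(0, k, n_volumes)
  for (j in seq_len(k)) {
    phase <- runif(length(freqs), 0, 2 * pi)
    half <- amp * exp(1i * phase)
    spec <- complex(length.out = n_volumes)
    spec[seq_along(freqs)] <- half
    idx <- seq(2, length(freqs) - if (n_volumes %% 2 == 0) 1 else 0)
    spec[n_volumes + 2 - idx] <- Conj(half[idx])
    tc[j, ] <- Re(fft(spec, inverse = TRUE)) / n_volumes
  }
  tc <- tc - rowMeans(tc)
  # Gram-Schmidt on centred rows: exact mutual orthogonality.
  for (j in seq_len(k)) {
    if (j > 1) {
      prev <- tc[seq_len(j - 1), , drop = FALSE]
      coef <- drop(prev %*% tc[j, ]) / rowSums(prev^2)
      tc[j, ] <- tc[j, ] - drop(crossprod(prev, coef))
    }
    tc[j, ] <- tc[j, ] - mean(tc[j, ])
  }
  tc / apply(tc, 1, sd)
}

#' Cohort design configuration
#'
#' Defaults reproduce the emulated study design: 34 patients and 34 controls
#' at baseline, 29 patients rescanned after six weeks (13 ECT, 16
#' medication-only), runs of 240 volumes at TR 2 s, 20 components of which 6
#' (anchors included) carry group effects.
#'
#' @param n_patients,n_controls baseline group sizes.
#' @param n_followup_ect,n_followup_med follow-up counts by treatment arm.
#' @param n_volumes volumes per run.
#' @param tr_seconds repetition time (s).
#' @param k_components number of atlas components.
#' @param affected indices of components carrying the group effect; `NULL`
#'   takes the atlas default.
#' @param delta group effect: absolute shift of the patient mean loading on
#'   each affected component (loading units; control loadings are
#'   N(1, 0.1)).  `delta = 0` defines the null cohort.
#' @param response_gain slope linking individual normalization fraction
#'   rho_i to relative PANSS reduction.
#' @param response_coupling rank coupling (Gaussian copula correlation) of
#'   rho_i to the patient's baseline nearness-to-normal: patients whose
#'   affected-component loadings deviate least improve most, which is what
#'   makes the baseline brain-state score predictive of response.  The
#'   Beta(2,2) marginal of rho_i is preserved; 0 decouples them.
#' @param noise_sd additive Gaussian voxel noise SD (component signal has
#'   unit-variance time courses and unit-peak maps).
#' @param map_jitter per-subject SD (voxels) of blob-centre jitter,
#'   emulating inter-subject spatial variability of networks.
#' @param seed RNG seed for everything the generator draws.
#' @return a list of class `icn_cohort_config`.
#' @export
cohort_config <- function(n_patients = 34, n_controls = 34,
                          n_followup_ect = 13, n_followup_med = 16,
                          n_volumes = 240, tr_seconds = 2,
                          k_components = 20, affected = NULL,
                          delta = 0.15, response_gain = 0.6,
                          response_coupling = 0.9,
                          noise_sd = 0.5, map_jitter = 0.25, seed = 1) {
  cfg <- list(n_patients = .chk_count(n_patients, "n_patients"),
              n_controls = .chk_count(n_controls, "n_controls"),
              n_followup_ect = .chk_count(n_followup_ect, "n_followup_ect", 0L),
              n_followup_med = .chk_count(n_followup_med, "n_followup_med", 0L),
              n_volumes = .chk_count(n_volumes, "n_volumes", 30L),
              tr_seconds = as.numeric(tr_seconds),
              k_components = .chk_count(k_components, "k_components", 2L),
              affected = affected, delta = as.numeric(delta),
              response_gain = as.numeric(response_gain),
              response_coupling = as.numeric(response_coupling),
              noise_sd = as.numeric(noise_sd),
              map_jitter = as.numeric(map_jitter),
              seed = as.integer(seed))
  if (cfg$delta < 0) stop("invalid configuration: delta must be >= 0", call. = FALSE)
  if (cfg$n_followup_ect + cfg$n_followup_med > cfg$n_patients)
    stop("invalid configuration: more follow-ups than patients", call. = FALSE)
  class(cfg) <- "icn_cohort_config"
  cfg
}

.LOADING_SD <- 0.1       # between-subject SD of component loadings
.BASELINE_OFFSET <- 100  # additive intensity offset so scans have positive mean
.PANSS_MEANS <- c(total = 80.59, pos = 26.94, neg = 16.74, gen = 37.00)
.PANSS_SD_TOTAL <- 7.25

#' Simulate a patient/control treatment cohort
#'
#' @param atlas an [make_atlas()] atlas.
#' @param config an [cohort_config()]; its `k_components` must match the atlas.
#' @return an object of class `icn_cohort`: `scans` (named list of
#'   [new_scan()] objects keyed `subject_session`), `nuisance` (named list of
#'   nuisance sets: `motion` T x 6, `wm`, `csf`), `records` (phenotype
#'   data.frame, one row per subject per session), `truth` (generative
#'   loadings, per-subject blob centres, rho_i, affected set and signs),
#'   plus the atlas and config.
#' @export
simulate_cohort <- function(atlas, config = cohort_config()) {
  stopifnot(inherits(atlas, "icn_atlas"))
  k <- nrow(atlas$maps)
  if (config$k_components != k)
    stop("invalid configuration: config$k_components does not match atlas", call. = FALSE)
  affected <- if (is.null(config$affected)) atlas$affected else as.integer(config$affected)
  if (length(affected) > 0 && (min(affected) < 1L || max(affected) > k))
    stop("invalid configuration: affected component index out of range", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  np <- config$n_patients; nc <- config$n_controls
  nfu <- config$n_followup_ect + config$n_followup_med
  pat_ids <- sprintf("PAT%02d", seq_len(np))
  ctl_ids <- sprintf("CTL%02d", seq_len(nc))
  fu_idx <- sort(sample.int(np, nfu))
  ect_idx <- sort(sample(fu_idx, config$n_followup_ect))
  arm <- rep("none", np); arm[fu_idx] <- "MED"; arm[ect_idx] <- "ECT"

  # Fixed per-component effect signs, shared by all patients.
  signs <- integer(k); signs[affected] <- sample(c(-1L, 1L), length(affected), replace = TRUE)

  # Covariates near the study's Table-1 margins.
  rtnorm <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)
  age_p <- rtnorm(np, 29.35, 8.47, 18, 45); age_c <- rtnorm(nc, 27.71, 5.11, 18, 45)
  sex_p <- ifelse(runif(np) < 10 / 34, "M", "F")
  sex_c <- ifelse(runif(nc) < 12 / 34, "M", "F")
  edu_p <- rtnorm(np, 13.12, 2.82, 6, 22); edu_c <- rtnorm(nc, 15.03, 4.06, 6, 22)
  ill_p <- rtnorm(np, 6.23, 6.23, 0.2, 30)

  # Baseline PANSS: total near printed mean, split proportionally by the
  # printed subscale means with mild multiplicative jitter.
  pre_total_raw <- rtnorm(np, .PANSS_MEANS[["total"]], .PANSS_SD_TOTAL, 30, 210)
  frac0 <- .PANSS_MEANS[c("pos", "neg", "gen")] / sum(.PANSS_MEANS[c("pos", "neg", "gen")])
  pre_sub <- t(vapply(seq_len(np), function(i) {
    w <- frac0 * exp(rnorm(3, 0, 0.05)); w <- w / sum(w)
    w * pre_total_raw[i]
  }, numeric(3)))
  pre_total <- rowSums(pre_sub)

  # Baseline loadings.  Controls: N(1, sd); patients: mean shifted by
  # sign*delta on affected components.
  lam_pat <- matrix(rnorm(np * k, 1, .LOADING_SD), np, k)
  lam_pat[, affected] <- lam_pat[, affected] +
    matrix(signs[affected] * config$delta, np, length(affected), byrow = TRUE)
  lam_ctl <- matrix(rnorm(nc * k, 1, .LOADING_SD), nc, k)

  # Individual normalization fraction rho_i: Beta(2,2) marginal, rank-coupled
  # (Gaussian copula, correlation response_coupling) to baseline
  # nearness-to-normal so that less-deviant patients respond more.
  severity <- if (length(affected) > 0) {
    drop(lam_pat[, affected, drop = FALSE] %*% signs[affected])
  } else rep(0, np)
  sev_std <- if (sd(severity) > 0) (severity - mean(severity)) / sd(severity) else rep(0, np)
  a_cpl <- min(max(config$response_coupling, 0), 1)
  z <- -a_cpl * sev_std + sqrt(1 - a_cpl^2) * rnorm(np)
  rho <- qbeta(pnorm(z), 2, 2)
  rho[setdiff(seq_len(np), fu_idx)] <- NA_real_
  reduction <- pmin(pmax(config$response_gain * rho + rnorm(np, 0, 0.05), 0), 0.9)
  sub_reduction <- pmin(pmax(reduction + matrix(rnorm(np * 3, 0, 0.03), np, 3), 0), 0.95)
  post_sub <- pre_sub * (1 - sub_reduction)
  post_total <- rowSums(post_sub)
  subjects <- data.frame(
    subject_id = c(pat_ids, ctl_ids),
    group = rep(c("patient", "control"), c(np, nc)),
    arm = c(arm, rep("none", nc)),
    age = c(age_p, age_c), sex = c(sex_p, sex_c),
    education_years = c(edu_p, edu_c),
    illness_years = c(ill_p, rep(NA_real_, nc)),
    stringsAsFactors = FALSE)

  loadings <- list(); centers <- list(); scans <- list(); nuisance <- list()
  records <- list(); truth_rows <- list()
  V <- prod(atlas$grid_shape)

  simulate_nuisance <- function(Tn) {
    rw <- function(scale) {
      x <- cumsum(rnorm(Tn)) / sqrt(Tn)
      scale * (x - mean(x))
    }
    list(motion = vapply(seq_len(6), function(i) rw(0.3), numeric(Tn)),
         wm = rw(1), csf = rw(1))
  }

  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]; grp <- subjects$group[i]
    lam0 <- if (grp == "patient") lam_pat[i, ] else lam_ctl[i - np, ]
    ctr <- atlas$centers + matrix(rnorm(3 * k, 0, config$map_jitter), ncol = 3)
    maps_i <- if (config$map_jitter > 0) blob_maps(atlas$grid_shape, ctr, atlas$sigma_vox) else atlas$maps
    centers[[sid]] <- ctr
    sessions <- "baseline"
    is_fu <- grp == "patient" && match(sid, pat_ids) %in% fu_idx
    if (is_fu) sessions <- c("baseline", "followup")
    for (ses in sessions) {
      lam <- lam0
      if (ses == "followup") {
        r <- rho[match(sid, pat_ids)]
        lam[affected] <- lam[affected] + r * (1 - lam[affected])
        lam <- lam + rnorm(k, 0, 0.02)
      }
      tc <- simulate_time_courses(k, config$n_volumes, config$tr_seconds,
                                  seed = .child_seed(config$seed, 1000L + 7L * i +
                                                       (ses == "followup")))
      nus <- simulate_nuisance(config$n_volumes)
      nuis_patterns <- matrix(rnorm(V * 8, 0, 0.2), V, 8)
      nuis_series <- cbind(nus$motion, nus$wm, nus$csf)
      Y <- crossprod(maps_i, lam * tc) +
        nuis_patterns %*% t(nuis_series) +
        matrix(rnorm(V * config$n_volumes, 0, config$noise_sd), V, config$n_volumes) +
        .BASELINE_OFFSET
      key <- paste(sid, ses, sep = "_")
      scans[[key]] <- new_scan(array(Y, dim = c(atlas$grid_shape, config$n_volumes)),
                               tr_seconds = config$tr_seconds, subject_id = sid,
                               session = ses, voxel_size_mm = c(3, 3, 3))
      nuisance[[key]] <- nus
      loadings[[key]] <- lam
      ip <- match(sid, pat_ids)
      records[[key]] <- data.frame(
        subject_id = sid, group = grp, arm = subjects$arm[i], session = ses,
        age = subjects$age[i], sex = subjects$sex[i],
        education_years = subjects$education_years[i],
        illness_years = subjects$illness_years[i],
        panss_total = if (grp == "patient") {
          if (ses == "baseline") pre_total[ip] else post_total[ip]
        } else NA_real_,
        panss_pos = if (grp == "patient") {
          if (ses == "baseline") pre_sub[ip, 1] else post_sub[ip, 1]
        } else NA_real_,
        panss_neg = if (grp == "patient") {
          if (ses == "baseline") pre_sub[ip, 2] else post_sub[ip, 2]
        } else NA_real_,
        panss_gen = if (grp == "patient") {
          if (ses == "baseline") pre_sub[ip, 3] else post_sub[ip, 3]
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }

  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  load_mat <- do.call(rbind, loadings)
  truth <- list(
    loadings = data.frame(scan_key = rep(names(loadings), each = k),
                          subject_id = rep(sub("_(baseline|followup)$", "", names(loadings)), each = k),
                          session = rep(sub("^.*_", "", names(loadings)), each = k),
                          component = rep(seq_len(k), length(loadings)),
                          loading = as.numeric(t(load_mat)),
                          stringsAsFactors = FALSE),
    rho = data.frame(subject_id = pat_ids, rho = rho, stringsAsFactors = FALSE),
    centers = centers, affected = affected, signs = signs,
    control_mean = 1, loading_sd = .LOADING_SD)

  structure(list(scans = scans, nuisance = nuisance, records = records,
                 truth = truth, atlas = atlas, config = config),
            class = "icn_cohort")
}

#' @export
print.icn_cohort <- function(x, ...) {
  nb <- sum(x$records$session == "baseline")
  nf <- sum(x$records$session == "followup")
  cat(sprintf("<icn_cohort> %d baseline + %d follow-up scans (%d patients / %d controls), %d components, delta = %g\n",
              nb, nf, x$config$n_patients, x$config$n_controls,
              x$config$k_components, x$config$delta))
  invisible(x)
}

#' Regenerate a subject's true component maps from stored truth
#'
#' @param cohort an `icn_cohort`.
#' @param subject_id subject identifier.
#' @return k x voxel matrix of that subject's generative spatial maps.
#' @export
true_subject_maps <- function(cohort, subject_id) {
  ctr <- cohort$truth$centers[[subject_id]]
  if (is.null(ctr)) stop(sprintf("unknown subject: %s", subject_id), call. = FALSE)
  blob_maps(cohort$atlas$grid_shape, ctr, cohort$atlas$sigma_vox)
}

#' Write a cohort to disk
#'
#' One NIfTI per scan, one plain-text nuisance file per scan (8 columns:
#' six motion parameters, WM, CSF), a phenotype CSV, truth CSVs, and a JSON
#' manifest listing every file with its MD5.
#'
#' @param cohort an `icn_cohort`.
#' @param directory output directory (created if absent).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "icn_cohort"))
  if (length(cohort$scans) == 0L) stop("empty cohort: nothing to write", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("I/O error: cannot create directory %s", directory), call. = FALSE)
  files <- character(0)
  for (key in names(cohort$scans)) {
    f <- file.path(directory, paste0("sub-", key, ".nii"))
    write_scan(cohort$scans[[key]], f)
    nus <- cohort$nuisance[[key]]
    nf <- file.path(directory, paste0("sub-", key, "_nuisance.txt"))
    nm <- cbind(nus$motion, nus$wm, nus$csf)
    colnames(nm) <- c(sprintf("motion%d", 1:6), "wm", "csf")
    write.table(nm, nf, row.names = FALSE, quote = FALSE, sep = "\t")
    files <- c(files, f, nf)
  }
  pf <- file.path(directory, "phenotypes.csv")
  write.csv(cohort$records, pf, row.names = FALSE)
  tf <- file.path(directory, "truth_loadings.csv")
  write.csv(cohort$truth$loadings, tf, row.names = FALSE)
  rf <- file.path(directory, "truth_subjects.csv")
  write.csv(cohort$truth$rho, rf, row.names = FALSE)
  files <- c(files, pf, tf, rf)
  manifest <- list(
    n_scans = length(cohort$scans),
    grid_shape = cohort$atlas$grid_shape,
    n_volumes = cohort$config$n_volumes,
    tr_seconds = cohort$config$tr_seconds,
    seed = cohort$config$seed,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read scans and phenotypes written by [write_cohort()]
#'
#' @param directory cohort directory containing `manifest.json`.
#' @return list with `scans`, `nuisance`, `records` (truth is not reloaded).
#' @export
read_cohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("path error: no manifest.json in %s", directory), call. = FALSE)
  records <- read_phenotypes(file.path(directory, "phenotypes.csv"))
  scans <- list(); nuisance <- list()
  for (i in seq_len(nrow(records))) {
    key <- paste(records$subject_id[i], records$session[i], sep = "_")
    scans[[key]] <- read_scan(file.path(directory, paste0("sub-", key, ".nii")),
                              subject_id = records$subject_id[i],
                              session = records$session[i])
    nm <- as.matrix(read.table(file.path(directory, paste0("sub-", key, "_nuisance.txt")),
                               header = TRUE))
    nuisance[[key]] <- list(motion = nm[, 1:6, drop = FALSE], wm = nm[, 7], csf = nm[, 8])
  }
  list(scans = scans, nuisance = nuisance, records = records)
}
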