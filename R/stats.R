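# Permutation tests on paired connectivity maps and scores, and
# covariate-adjusted rank correlation between brain-state scores and
# normalized treatment response.

#' Normalized treatment response
#'
#' `(pre - post) / pre`: the relative reduction of a symptom score from
#' baseline, 1 = full remission, 0 = no change, negative = worsening.
#'
#' @param pre,post baseline and endpoint scores; `pre` must be positive.
#' @return numeric vector of response proportions.
#' @export
treatment_response <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("invalid input: baseline scores must be positive", call. = FALSE)
  (pre - post) / pre
}

#' Paired sign-flip permutation test on voxelwise difference maps
#'
#' A "pseudo paired t-test": the statistic is the paired t on the per-voxel
#' Fisher-z differences; the null distribution is generated by randomly
#' sign-flipping each subject's whole difference map.  Two-sided add-one
#' p-values, masked at `alpha` (uncorrected).
#'
#' @param pre_maps,post_maps lists of `icn_fcmap` (or numeric voxel
#'   vectors), matched by position/subject.
#' @param n_perm number of permutations (default 1000).
#' @param alpha voxelwise significance level (default 0.05).
#' @param seed RNG seed.
#' @return list of class `icn_paired_perm`: `t` (voxel statistic), `p`
#'   (voxel p-values in [1/(n_perm+1), 1]), `mask` (p <= alpha),
#'   `n_permutations`, `alpha`.
#' @export
paired_perm_test <- function(pre_maps, post_maps, n_perm = 1000, alpha = 0.05,
                             seed = 1) {
  getz <- function(m) if (inherits(m, "icn_fcmap")) m$z_values else as.numeric(m)
  if (length(pre_maps) != length(post_maps))
    stop("invalid input: pre/post map counts differ", call. = FALSE)
  ids_pre <- vapply(pre_maps, function(m) if (inherits(m, "icn_fcmap")) m$subject_id else NA_character_, "")
  ids_post <- vapply(post_maps, function(m) if (inherits(m, "icn_fcmap")) m$subject_id else NA_character_, "")
  if (!all(is.na(ids_pre)) && !identical(ids_pre, ids_post))
    stop("invalid input: pre/post maps are not matched by subject", call. = FALSE)
  D <- t(vapply(seq_along(pre_maps),
                function(i) getz(post_maps[[i]]) - getz(pre_maps[[i]]),
                numeric(length(getz(pre_maps[[1]])))))
  n <- nrow(D)
  if (n < 3L) stop("invalid input: need at least 3 pairs", call. = FALSE)
  tstat <- function(M) {
    mu <- colMeans(M)
    s <- sqrt((colSums(M^2) - n * mu^2) / (n - 1))
    s[s == 0] <- Inf
    mu / (s / sqrt(n))
  }
  t_obs <- tstat(D)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- integer(ncol(D))
  for (b in seq_len(n_perm)) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    exceed <- exceed + (abs(tstat(D * sgn)) >= abs(t_obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  structure(list(t = t_obs, p = p, mask = p <= alpha,
                 n_permutations = n_perm, alpha = alpha),
            class = "icn_paired_perm")
}

#' One-tailed sign-flip permutation test for a score decrease
#'
#' Tests whether follow-up scores are lower than baseline scores: the
#' statistic is the mean paired difference (baseline - follow-up), with a
#' sign-flip null and a one-tailed (decrease) add-one p-value.  Optionally
#' first excludes baseline-misclassified patients (aggregated baseline
#' score <= 0).
#'
#' @param baseline_scores,followup_scores paired score vectors.
#' @param n_perm number of permutations (default 10000).
#' @param exclude_misclassified drop pairs with baseline score <= 0.
#' @param seed RNG seed.
#' @return list: `p`, `observed` (mean decrease), `n_pairs`, `n_perm`.
#' @export
perm_score_decrease <- function(baseline_scores, followup_scores,
                                n_perm = 10000, exclude_misclassified = FALSE,
                                seed = 1) {
  if (length(baseline_scores) != length(followup_scores))
    stop("invalid input: unpaired scores", call. = FALSE)
  keep <- rep(TRUE, length(baseline_scores))
  if (exclude_misclassified) keep <- baseline_scores > 0
  d <- baseline_scores[keep] - followup_scores[keep]
  n <- length(d)
  if (n < 3L) stop("invalid input: fewer than 3 pairs after filtering", call. = FALSE)
  obs <- mean(d)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sgn <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  null <- drop(sgn %*% d) / n
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  list(p = p, observed = obs, n_pairs = n, n_perm = n_perm)
}

#' Residualize a variable on covariates
#'
#' Ordinary least squares of `y` on an intercept plus the covariate
#' columns; returns residuals (orthogonal to the design at machine
#' precision).
#'
#' @param y numeric response.
#' @param covariates data.frame or matrix of covariates; character/factor
#'   columns (e.g. sex) are expanded to indicator contrasts.
#' @return numeric residual vector.
#' @export
residualize <- function(y, covariates) {
  X <- .design_matrix(covariates)
  if (nrow(X) != length(y)) stop("invalid input: length mismatch", call. = FALSE)
  if (length(y) <= ncol(X) + 1L)
    stop("invalid input: need n > number of covariates + 1", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L)
    stop("invalid input: rank-deficient covariate design", call. = FALSE)
  drop(qr.resid(qrX, y))
}

.design_matrix <- function(covariates) {
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) return(col)
    f <- as.factor(col)
    if (nlevels(droplevels(f)) < 2L) return(NULL)   # constant factor: no information
    stats::model.matrix(~ f)[, -1, drop = FALSE]
  })
  cols <- Filter(Negate(is.null), cols)
  if (length(cols) == 0L)
    stop("invalid input: rank-deficient covariate design", call. = FALSE)
  X <- do.call(cbind, cols)
  # drop constant numeric columns as well; a fully empty design is an error
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!any(keep))
    stop("invalid input: rank-deficient covariate design", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  storage.mode(X) <- "double"
  X
}

#' Regression-based outlier screen
#'
#' Fits least squares `y ~ x` and flags observations whose externally
#' studentized residual falls outside the central 95% interval of its
#' reference t distribution.
#'
#' @param x,y numeric vectors (n >= 5); `x` must have positive variance.
#' @param level central coverage of the interval (default 0.95).
#' @return integer indices of flagged observations (possibly empty).
#' @export
detect_outliers <- function(x, y, level = 0.95) {
  n <- length(x)
  if (n < 5L || length(y) != n) stop("invalid input: need matched n >= 5", call. = FALSE)
  if (sd(x) == 0) stop("invalid input: degenerate x (zero variance)", call. = FALSE)
  fit <- lm(y ~ x)
  if (suppressWarnings(summary(fit)$sigma) <= 1e-10 * (sd(y) + .Machine$double.eps))
    return(integer(0))                             # exact fit: nothing to flag
  rs <- stats::rstudent(fit)
  crit <- qt(1 - (1 - level) / 2, df = n - 3)
  as.integer(which(!is.na(rs) & abs(rs) > crit))
}

#' Covariate-adjusted association between scores and treatment response
#'
#' Residualizes both the scores and each response measure on the covariates
#' (age, sex, education, illness duration), computes the Spearman rank
#' correlation with Bonferroni correction across the response family, then
#' repeats after removing regression-flagged outliers.
#'
#' @param scores baseline (or change) classification scores, one per patient.
#' @param response data.frame of response measures (columns, e.g. the four
#'   PANSS measures) or a single numeric vector.
#' @param covariates covariate data.frame (see [residualize()]).
#' @param family_size Bonferroni family size (default: number of response
#'   columns, conventionally 4).
#' @return data.frame of class `icn_association`, one row per measure:
#'   `measure`, `rho`, `p_raw`, `p_bonferroni`, `n`, `outliers` (comma-sep
#'   indices), `rho_no_outliers`, `p_no_outliers`.
#' @export
score_response_association <- function(scores, response, covariates,
                                       family_size = NULL) {
  if (is.numeric(response)) response <- data.frame(response = response)
  if (is.null(family_size)) family_size <- ncol(response)
  n <- length(scores)
  if (n < 5L) stop("invalid input: need at least 5 patients", call. = FALSE)
  rs <- residualize(scores, covariates)
  rows <- lapply(names(response), function(ms) {
    rr <- residualize(response[[ms]], covariates)
    ct <- suppressWarnings(cor.test(rs, rr, method = "spearman"))
    out <- detect_outliers(rs, rr)
    if (length(out) > 0 && n - length(out) >= 5) {
      ct2 <- suppressWarnings(cor.test(rs[-out], rr[-out], method = "spearman"))
      rho2 <- unname(ct2$estimate); p2 <- ct2$p.value
    } else {
      rho2 <- unname(ct$estimate); p2 <- ct$p.value
    }
    data.frame(measure = ms, rho = unname(ct$estimate), p_raw = ct$p.value,
               p_bonferroni = min(1, family_size * ct$p.value), n = n,
               outliers = paste(out, collapse = ","),
               rho_no_outliers = rho2, p_no_outliers = p2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "family_size") <- family_size
  class(res) <- c("icn_association", "data.frame")
  res
}
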