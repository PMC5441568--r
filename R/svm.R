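# R-level wrapper around the compiled SMO C-SVC: kernel construction from
# (possibly multi-component) feature blocks, training with Platt sigmoid
# probability calibration, and prediction of signed probability scores.

#' Fit a C-SVC on a precomputed kernel
#'
#' @param K n x n precomputed kernel matrix.
#' @param y labels coded +1 (patient) / -1 (control).
#' @param C soft-margin cost.
#' @param calibrate fit a Platt sigmoid on the training decision values
#'   (needed to emit probability scores).
#' @return list of class `icn_svm`: `coef` (alpha_i y_i), `rho`, `platt`
#'   (A, B) and the training labels.
#' @export
svm_fit <- function(K, y, C = 1, calibrate = TRUE) {
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid input: training set contains a single class", call. = FALSE)
  if (nrow(K) != length(y)) stop("kernel/label dimension mismatch", call. = FALSE)
  fit <- .svm_fit_cpp(K, y, C)
  platt <- if (calibrate) .platt_fit(fit$decision, y) else c(A = NA_real_, B = NA_real_)
  structure(list(coef = drop(fit$coef), rho = fit$rho, platt = platt,
                 decision = drop(fit$decision), y = y, C = C,
                 iterations = fit$iterations),
            class = "icn_svm")
}

#' Decision values for new samples
#'
#' @param model an `icn_svm`.
#' @param K_cross m x n cross-kernel between the m new samples and the n
#'   training samples (same order as at fit time).
#' @return numeric decision values (positive = patient side).
#' @export
svm_decision <- function(model, K_cross) {
  if (ncol(K_cross) != length(model$coef))
    stop("invalid input: cross-kernel columns must match training size", call. = FALSE)
  drop(K_cross %*% model$coef) - model$rho
}

#' Calibrated probability of the patient (+1) class
#' @param model an `icn_svm` fitted with `calibrate = TRUE`.
#' @param K_cross cross-kernel as in [svm_decision()].
#' @export
svm_probability <- function(model, K_cross) {
  if (any(is.na(model$platt)))
    stop("model was fitted without probability calibration", call. = FALSE)
  f <- svm_decision(model, K_cross)
  .platt_prob(f, model$platt)
}

# Platt sigmoid P(y=+1 | f) = 1 / (1 + exp(A f + B)), fitted by Newton
# descent with backtracking on the regularized maximum-likelihood objective
# (Lin-Weng-style implementation).
.platt_fit <- function(f, y, max_iter = 100, min_step = 1e-10, sigma = 1e-12) {
  prior1 <- sum(y > 0); prior0 <- sum(y < 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  obj <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  Fval <- obj(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sigma + sum(f * f * d2); h22 <- sigma + sum(d2); h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= min_step) {
      newA <- A + stepsize * dA; newB <- B + stepsize * dB
      newF <- obj(newA, newB)
      if (newF < Fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; Fval <- newF
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < min_step) break
  }
  c(A = A, B = B)
}

.platt_prob <- function(f, platt) {
  fApB <- platt[["A"]] * f + platt[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

# ---- kernel construction over additive feature blocks -----------------------

# Linear Gram and squared-distance matrices for one feature block (rows =
# samples).  Both are additive across blocks, which lets the classifier
# combine any component subset without touching voxel data again.
.block_gram <- function(X) tcrossprod(X)
.block_dist2 <- function(G) {
  d <- diag(G)
  D <- outer(d, d, "+") - 2 * G
  D[D < 0] <- 0
  D
}

# Combine per-component Gram/dist blocks for a component set under a kernel
# spec: list(kernel = "linear") or list(kernel = "rbf", gamma = g).
.combine_kernel <- function(grams, dists, set, spec) {
  if (spec$kernel == "linear") {
    Reduce(`+`, grams[set])
  } else {
    exp(-spec$gamma * Reduce(`+`, dists[set]))
  }
}
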