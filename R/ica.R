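# Group spatial ICA (temporal concatenation + PCA reduction + fixed-point
# ICA with symmetric decorrelation), subject-specific back-reconstruction
# (dual regression, with an optional "guided" negentropy refinement that
# stays spatially close to the group map), template matching, and voxelwise
# Fisher-z functional connectivity maps.

# E[log cosh(Z)] for Z ~ N(0,1); baseline for the negentropy surrogate.
.EG_GAUSS <- 0.3745672

#' Group independent component analysis
#'
#' Scans are voxel-centred and temporally concatenated; the spatial
#' covariance is reduced to `k` principal components and a fixed-point ICA
#' (log-cosh contrast, symmetric decorrelation) is run on the whitened
#' spatial PCs.  Maps are z-scored over voxels, signed so skewness is
#' non-negative, and ordered by descending explained data variance.
#'
#' @param scans list of (preprocessed) `icn_scan` objects on a common grid.
#' @param k number of components (default 20).
#' @param seed RNG seed for the ICA initialisation; results are
#'   deterministic given the seed.
#' @param tol,max_iter fixed-point convergence controls; on non-convergence
#'   the ICA restarts from `seed + 1` (up to `max_restarts` times).
#' @param max_restarts maximum number of reseeded restarts.
#' @return list of class `icn_gica`: `maps` (k x voxel, z-scored),
#'   `k`, `variance_retained`, `eigenvalues`, `seed`, `converged`.
#' @export
group_ica <- function(scans, k = 20, seed = 1, tol = 1e-6, max_iter = 500,
                      max_restarts = 5) {
  if (!is.list(scans) || length(scans) < 2L)
    stop("invalid input: group ICA needs at least 2 scans", call. = FALSE)
  k <- .chk_count(k, "k", min = 2L)
  V <- prod(dim(scans[[1]]$data)[1:3])
  C <- matrix(0, V, V)
  total_T <- 0L
  for (s in scans) {
    X <- scan_matrix(s)                    # voxel x time
    if (nrow(X) != V) stop("invalid input: scans are not on a common grid", call. = FALSE)
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
    total_T <- total_T + ncol(X)
  }
  eg <- eigen(C / total_T, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  if (k > sum(lambda > 1e-10 * lambda[1]))
    stop(sprintf("invalid configuration: k = %d exceeds the rank of the concatenated data", k),
         call. = FALSE)
  variance_retained <- sum(lambda[seq_len(k)]) / sum(lambda)
  Z <- t(eg$vectors[, seq_len(k), drop = FALSE])   # k x V spatial PCs

  # Whiten rows of Z over voxels (zero mean, identity covariance).
  Z <- Z - rowMeans(Z)
  cz <- tcrossprod(Z) / V
  ez <- eigen(cz, symmetric = TRUE)
  Kw <- diag(1 / sqrt(pmax(ez$values, 1e-300))) %*% t(ez$vectors)
  Zw <- Kw %*% Z

  converged <- FALSE
  W <- NULL
  for (restart in 0:max_restarts) {
    old <- .Random.seed_save()
    set.seed(.child_seed(seed + restart, 11L))
    W <- .sym_orth(matrix(rnorm(k * k), k, k))
    .Random.seed_restore(old)
    for (it in seq_len(max_iter)) {
      S <- W %*% Zw
      gS <- tanh(S)
      W1 <- gS %*% t(Zw) / V - diag(rowMeans(1 - gS^2)) %*% W
      W1 <- .sym_orth(W1)
      delta <- max(abs(1 - abs(rowSums(W1 * W))))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  S <- W %*% Zw                                    # k x V sources

  # Explained variance per component: Z ~= M S with M = (W Kw)^{-1}.
  M <- solve(W %*% Kw)
  energy <- colSums(M^2 * lambda[seq_len(k)])
  ord <- order(energy, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  sk <- apply(S, 1, function(x) mean((x - mean(x))^3))
  S <- S * ifelse(sk < 0, -1, 1)
  S <- (S - rowMeans(S)) / apply(S, 1, sd)

  structure(list(maps = S, k = k, variance_retained = variance_retained,
                 eigenvalues = lambda, seed = seed, converged = converged),
            class = "icn_gica")
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W.
.sym_orth <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors) %*% W
}

#' @export
print.icn_gica <- function(x, ...) {
  cat(sprintf("<icn_gica> %d components, %.1f%% variance retained, %s\n",
              x$k, 100 * x$variance_retained,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Subject-specific intrinsic connectivity networks
#'
#' `dual_regression` (default): stage-1 least squares of the scan on the
#' group maps gives subject time courses; stage-2 least squares of the scan
#' on those time courses gives subject maps.  `guided`: starts from the
#' dual-regression maps and refines each by gradient ascent on a log-cosh
#' negentropy surrogate, constrained to keep spatial correlation with the
#' group map at or above `tau`.
#'
#' @param scan a preprocessed `icn_scan`.
#' @param group an [group_ica()] result on the same grid.
#' @param mode `"dual_regression"` or `"guided"`.
#' @param tau minimum spatial correlation with the group map (guided mode).
#' @param max_iter,tol refinement controls (guided mode).
#' @return list of class `icn_subject_icn`: `maps` (k x voxel),
#'   `timecourses` (k x T), `subject_id`, `session`, `mode`.
#' @export
subject_icns <- function(scan, group, mode = c("dual_regression", "guided"),
                         tau = 0.7, max_iter = 100, tol = 1e-5) {
  mode <- match.arg(mode)
  stopifnot(inherits(scan, "icn_scan"), inherits(group, "icn_gica"))
  Y <- scan_matrix(scan)
  if (nrow(Y) != ncol(group$maps))
    stop("invalid input: scan grid does not match the group maps", call. = FALSE)
  Yc <- Y - rowMeans(Y)
  S <- group$maps
  A <- solve(tcrossprod(S), S %*% Yc)              # k x T time courses
  # Stage 2 regresses on variance-normalized time courses so the subject
  # maps keep the component amplitude (the standard choice when maps feed a
  # group comparison); fc_map and the classifier are invariant to the
  # time-course scale itself.
  An <- A / apply(A, 1, sd)
  M <- solve(tcrossprod(An), An %*% t(Yc))         # k x V subject maps
  if (mode == "guided") {
    for (j in seq_len(nrow(M)))
      M[j, ] <- .guided_refine(M[j, ], S[j, ], tau, max_iter, tol)
  }
  structure(list(maps = M, timecourses = A, subject_id = scan$subject_id,
                 session = scan$session, mode = mode),
            class = "icn_subject_icn")
}

.standardize <- function(x) (x - mean(x)) / sd(x)

.negentropy <- function(x) (mean(log(cosh(x))) - .EG_GAUSS)^2

# Gradient ascent on the negentropy surrogate, re-standardizing each step
# and blending back toward the group map whenever the correlation
# constraint is violated.  Steps that would decrease negentropy are halved
# away, so the refined map is never worse than the initializer.
.guided_refine <- function(m, g, tau, max_iter, tol) {
  g <- .standardize(g)
  m <- .standardize(m)
  project <- function(x) {
    x <- .standardize(x)
    if (cor(x, g) >= tau) return(x)
    f <- function(a) cor(.standardize(a * x + (1 - a) * g), g) - tau
    a <- tryCatch(stats::uniroot(f, c(0, 1), tol = 1e-12)$root, error = function(e) 0)
    .standardize(a * x + (1 - a) * g)
  }
  m <- project(m)
  J <- .negentropy(m)
  step <- 0.5
  for (it in seq_len(max_iter)) {
    u <- mean(log(cosh(m))) - .EG_GAUSS
    grad <- 2 * u * tanh(m)
    cand <- project(m + step * .standardize(grad))
    Jc <- .negentropy(cand)
    if (Jc >= J) {
      if (Jc - J < tol) { m <- cand; J <- Jc; break }
      m <- cand; J <- Jc
    } else {
      step <- step / 2
      if (step < 1e-6) break
    }
  }
  m
}

#' Match group components to template maps
#'
#' Greedy one-to-one assignment by descending absolute spatial correlation;
#' a component whose best remaining |r| is below `min_r` is labelled
#' `"unmatched"`.
#'
#' @param group an [group_ica()] result (or any k x voxel map matrix).
#' @param templates an `icn_atlas` or a map matrix with optional rownames
#'   as labels.
#' @param min_r matching threshold on |spatial correlation| (default 0.3).
#' @return data.frame: `component`, `template` (index or NA), `label`, `r`.
#' @export
match_templates <- function(group, templates, min_r = 0.3) {
  G <- if (inherits(group, "icn_gica")) group$maps else as.matrix(group)
  if (inherits(templates, "icn_atlas")) {
    Tm <- templates$maps; labels <- templates$labels
  } else {
    Tm <- as.matrix(templates)
    labels <- rownames(Tm)
    if (is.null(labels)) labels <- sprintf("template%02d", seq_len(nrow(Tm)))
  }
  if (nrow(Tm) == 0L) stop("invalid input: empty template set", call. = FALSE)
  if (ncol(G) != ncol(Tm))
    stop("invalid input: group and template maps are on different grids", call. = FALSE)
  R <- cor(t(G), t(Tm))                            # k_g x k_t
  out <- data.frame(component = seq_len(nrow(G)), template = NA_integer_,
                    label = "unmatched", r = NA_real_, stringsAsFactors = FALSE)
  Rw <- abs(R)
  repeat {
    if (all(is.na(Rw)) || max(Rw, na.rm = TRUE) < min_r) break
    ij <- which(Rw == max(Rw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out$template[ij[1]] <- ij[2]
    out$label[ij[1]] <- labels[ij[2]]
    out$r[ij[1]] <- R[ij[1], ij[2]]
    Rw[ij[1], ] <- NA; Rw[, ij[2]] <- NA
  }
  out
}

#' Voxelwise Fisher-z functional connectivity map
#'
#' Pearson correlation of one component time course against every voxel
#' series, clipped to |r| <= 1 - 1e-7 and Fisher-z transformed.
#'
#' @param scan a preprocessed `icn_scan`.
#' @param timecourse numeric series with one value per volume.
#' @return list of class `icn_fcmap`: `z_values` (voxel vector),
#'   `subject_id`, `session`.
#' @export
fc_map <- function(scan, timecourse) {
  stopifnot(inherits(scan, "icn_scan"))
  Tn <- n_volumes(scan)
  if (length(timecourse) != Tn)
    stop("invalid input: time course length does not match volume count", call. = FALSE)
  if (sd(timecourse) == 0)
    stop("invalid input: zero-variance time course", call. = FALSE)
  Y <- scan_matrix(scan)
  r <- suppressWarnings(drop(cor(timecourse, t(Y))))
  r[is.na(r)] <- 0                                 # zero-variance voxels
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  structure(list(z_values = atanh(r), subject_id = scan$subject_id,
                 session = scan$session),
            class = "icn_fcmap")
}
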