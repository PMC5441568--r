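# Nested leave-one-out SVM ensemble.
#
# Outer LOO over subjects estimates generalization; within each outer fold,
# forward component selection (anchored on the a-priori DMN/MTL components)
# and a small C/kernel grid are tuned by inner LOO accuracy on the training
# subjects only.  The fold then yields one base classifier per inner
# leave-one-out training subset; each scores the outer test subject with a
# signed calibrated probability (s = 2p - 1, positive = patient), and the
# median of the base scores is the subject's aggregated brain-state score.
#
# Kernels are precomputed per component (linear Gram and squared-distance
# blocks are additive over components), so candidate component sets are
# evaluated without revisiting voxel data.

#' Hyperparameter grid for the SVM
#'
#' @param C soft-margin costs.
#' @param gamma_mult RBF gamma multipliers; gamma = mult / d with d the
#'   total feature dimension of the candidate component set.  The linear
#'   kernel is always included.
#' @return list with elements `C` and `kernels`.
#' @export
svm_grid <- function(C = c(0.01, 0.1, 1, 10, 100), gamma_mult = c(1, 10)) {
  kernels <- c(list(list(kernel = "linear")),
               lapply(gamma_mult, function(g) list(kernel = "rbf", gamma_mult = g)))
  list(C = C, kernels = kernels)
}

#' Assemble a feature set from subject-specific component maps
#'
#' Each subject contributes one masked, flattened spatial map per component;
#' the mask and component order are identical across subjects.  Maps are
#' kept on their native (amplitude-carrying) scale here; voxelwise
#' z-scoring across subjects happens inside each training fold (see
#' [loo_ensemble()]), so no test-subject information leaks into the
#' standardization.
#'
#' @param icns list of `icn_subject_icn` objects (one per subject/session).
#' @param groups character vector, `"patient"` or `"control"`, per entry.
#' @param anchors indices of the a-priori anchor components (default 1:2,
#'   the DMN and MTL slots of the synthetic atlas).
#' @param component_labels optional component names.
#' @param mask optional logical voxel mask (default: all voxels).
#' @return list of class `icn_features`: `blocks` (list per component of
#'   n x voxel matrices), `labels` (+1 patient / -1 control), `groups`,
#'   `subject_ids`, `sessions`, `anchors`, `component_labels`.
#' @export
feature_set <- function(icns, groups, anchors = c(1L, 2L),
                        component_labels = NULL, mask = NULL) {
  stopifnot(length(icns) == length(groups))
  k <- nrow(icns[[1]]$maps)
  V <- ncol(icns[[1]]$maps)
  if (is.null(mask)) mask <- rep(TRUE, V)
  nv <- sum(mask)
  blocks <- lapply(seq_len(k), function(cc) {
    t(vapply(icns, function(ic) ic$maps[cc, mask], numeric(nv)))
  })
  if (is.null(component_labels)) component_labels <- sprintf("C%02d", seq_len(k))
  structure(list(
    blocks = blocks,
    labels = ifelse(groups == "patient", 1L, -1L),
    groups = groups,
    subject_ids = vapply(icns, `[[`, "", "subject_id"),
    sessions = vapply(icns, `[[`, "", "session"),
    anchors = as.integer(anchors),
    component_labels = component_labels), class = "icn_features")
}

n_components <- function(features) length(features$blocks)
n_subjects <- function(features) nrow(features$blocks[[1]])

# Per-component voxelwise standardization + PCA guard, both fitted on
# training rows only and applied to all rows; returns projected blocks plus
# the fitted centring/scaling/rotation.
.pca_blocks <- function(features, train_idx, pca_dim) {
  lapply(features$blocks, function(B) {
    tr <- B[train_idx, , drop = FALSE]
    ctr <- colMeans(tr)
    scl <- apply(tr, 2, sd)
    scl[scl < 1e-12] <- 1
    Z <- sweep(sweep(B, 2, ctr), 2, scl, "/")
    r <- min(length(train_idx) - 1L, pca_dim, ncol(B))
    sv <- svd(Z[train_idx, , drop = FALSE], nu = 0, nv = r)
    list(proj = Z %*% sv$v, center = ctr, scale = scl, rotation = sv$v)
  })
}

# Gram + squared-distance blocks (additive over components) from projected
# feature blocks.
.kernel_blocks <- function(proj_blocks) {
  grams <- lapply(proj_blocks, function(pb) .block_gram(pb$proj))
  dists <- lapply(grams, .block_dist2)
  dims <- vapply(proj_blocks, function(pb) ncol(pb$proj), integer(1))
  list(grams = grams, dists = dists, dims = dims)
}

.kernel_for <- function(kb, set, kernel_spec, idx_row, idx_col) {
  if (kernel_spec$kernel == "linear") {
    K <- Reduce(`+`, kb$grams[set])
  } else {
    gamma <- kernel_spec$gamma_mult / sum(kb$dims[set])
    K <- exp(-gamma * Reduce(`+`, kb$dists[set]))
  }
  K[idx_row, idx_col, drop = FALSE]
}

# Inner-LOO accuracy of a component set on training rows, maximized over the
# C/kernel grid.  Ties on accuracy keep the earlier grid entry (fixed
# order: kernels as listed, C ascending), so the search is deterministic.
.grid_eval <- function(kb, set, y, train_idx, grid) {
  best <- list(acc = -Inf, C = NA, kernel = NULL)
  for (ks in grid$kernels) {
    K <- .kernel_for(kb, set, ks, train_idx, train_idx)
    for (C in grid$C) {
      acc <- .svm_loo_acc_cpp(K, y, C)
      if (acc > best$acc) best <- list(acc = acc, C = C, kernel = ks)
    }
  }
  best
}

#' Forward component selection with anchored start
#'
#' Starts from the anchor set and greedily adds the component that most
#' improves inner leave-one-out accuracy on the training set (grid-searching
#' C and kernel inside every evaluation); stops when no candidate strictly
#' improves.  Ties prefer the smaller component index.
#'
#' @param features an [feature_set()] restricted to training subjects, or a
#'   full one plus `train_idx`.
#' @param labels +1/-1 labels (default from `features`).
#' @param anchors anchor component indices (default from `features`).
#' @param grid an [svm_grid()].
#' @param pca_dim per-component PCA dimension cap (NULL disables the guard).
#' @param train_idx training row indices (default: all rows).
#' @return list of class `icn_base_classifier`: `selected`, `params`
#'   (C, kernel), `inner_accuracy`, `model` (fitted on the full training
#'   set, Platt-calibrated), `pca` and `train_idx` (to score new samples).
#' @export
forward_select <- function(features, labels = features$labels,
                           anchors = features$anchors, grid = svm_grid(),
                           pca_dim = 50, train_idx = seq_len(n_subjects(features))) {
  y <- as.integer(labels[train_idx])
  if (length(y) < 4L) stop("invalid input: need at least 4 training subjects", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid input: training set contains a single class", call. = FALSE)
  pb <- .pca_blocks(features, train_idx, if (is.null(pca_dim)) .Machine$integer.max else pca_dim)
  kb <- .kernel_blocks(pb)
  sel <- .forward_search(kb, y, anchors, grid, train_idx)
  K <- .kernel_for(kb, sel$selected, sel$kernel, train_idx, train_idx)
  model <- svm_fit(K, y, C = sel$C, calibrate = TRUE)
  structure(list(selected = sel$selected, params = list(C = sel$C, kernel = sel$kernel),
                 inner_accuracy = sel$acc, model = model, pca = pb,
                 kernel_blocks = kb, train_idx = train_idx,
                 labels = y, features_n = n_subjects(features)),
            class = "icn_base_classifier")
}

.forward_search <- function(kb, y, anchors, grid, train_idx) {
  k <- length(kb$grams)
  selected <- sort(unique(as.integer(anchors)))
  best <- .grid_eval(kb, selected, y, train_idx, grid)
  repeat {
    if (best$acc >= 1) break
    candidates <- setdiff(seq_len(k), selected)
    if (length(candidates) == 0L) break
    round_best <- list(acc = best$acc, comp = NA_integer_)
    for (cc in candidates) {                       # ascending index = tie-break
      ev <- .grid_eval(kb, c(selected, cc), y, train_idx, grid)
      if (ev$acc > round_best$acc) round_best <- list(acc = ev$acc, comp = cc, ev = ev)
    }
    if (is.na(round_best$comp)) break              # no strict improvement
    selected <- sort(c(selected, round_best$comp))
    best <- round_best$ev
  }
  list(selected = selected, C = best$C, kernel = best$kernel, acc = best$acc)
}

#' Signed probability score of samples under a fitted classifier
#'
#' Projects the samples' component maps through the classifier's per-fold
#' PCA, builds the kernel against the training subjects and returns
#' s = 2 p - 1, where p is the Platt-calibrated probability of the patient
#' class: s in [-1, 1], s > 0 iff predicted patient.
#'
#' @param classifier an `icn_base_classifier` from [forward_select()].
#' @param features an [feature_set()] with the same components/mask; all its
#'   rows are scored.
#' @return numeric vector of signed scores.
#' @export
classification_score <- function(classifier, features) {
  if (n_components(features) != length(classifier$pca))
    stop("invalid input: feature component count does not match classifier", call. = FALSE)
  proj <- lapply(seq_along(features$blocks), function(cc) {
    p <- classifier$pca[[cc]]
    if (ncol(features$blocks[[cc]]) != length(p$center))
      stop("invalid input: feature dimension does not match classifier", call. = FALSE)
    sweep(sweep(features$blocks[[cc]], 2, p$center), 2, p$scale, "/") %*% p$rotation
  })
  train_proj <- lapply(classifier$pca[classifier$selected],
                       function(p) p$proj[classifier$train_idx, , drop = FALSE])
  test_proj <- proj[classifier$selected]
  Kc <- .cross_kernel(test_proj, train_proj, classifier$params$kernel)
  p <- svm_probability(classifier$model, Kc)
  2 * p - 1
}

.cross_kernel <- function(test_blocks, train_blocks, kernel_spec) {
  G <- Reduce(`+`, Map(function(a, b) a %*% t(b), test_blocks, train_blocks))
  if (kernel_spec$kernel == "linear") return(G)
  d_total <- sum(vapply(train_blocks, ncol, integer(1)))
  gamma <- kernel_spec$gamma_mult / d_total
  na <- Reduce(`+`, lapply(test_blocks, function(a) rowSums(a^2)))
  nb <- Reduce(`+`, lapply(train_blocks, function(b) rowSums(b^2)))
  D <- outer(na, nb, "+") - 2 * G
  D[D < 0] <- 0
  exp(-gamma * D)
}

# Base scores of one outer fold for an arbitrary test sample.
# fold: list(train_idx, selected, params); kb: kernel blocks over the n
# baseline rows plus (optionally) extra rows appended for the test sample.
.fold_base_scores <- function(kb, y_train, fold, test_row) {
  m <- length(fold$train_idx)
  scores <- numeric(m)
  for (u in seq_len(m)) {
    sub <- fold$train_idx[-u]
    K <- .kernel_for(kb, fold$selected, fold$params$kernel, sub, sub)
    fit <- svm_fit(K, y_train[-u], C = fold$params$C, calibrate = TRUE)
    Kc <- .kernel_for(kb, fold$selected, fold$params$kernel, test_row, sub)
    scores[u] <- 2 * svm_probability(fit, Kc) - 1
  }
  scores
}

#' Nested leave-one-out SVM ensemble
#'
#' @param features an [feature_set()] of baseline subjects.
#' @param labels +1/-1 labels (default from `features`).
#' @param anchors anchor components always kept in the selected set.
#' @param grid an [svm_grid()].
#' @param pca_dim per-component PCA cap (default 50).
#' @param seed kept for interface symmetry; the procedure is deterministic.
#' @param progress print per-fold progress.
#' @return list of class `icn_ensemble`: `scores` (data.frame per subject:
#'   `subject_id`, `label`, `aggregated_score`, `predicted_label`,
#'   `n_base`), `folds` (per-fold selected set, params, train indices and
#'   base scores), `metrics` (see [evaluate()]), `selection_freq` per
#'   component, and the `features` (kept for follow-up scoring).
#' @export
loo_ensemble <- function(features, labels = features$labels,
                         anchors = features$anchors, grid = svm_grid(),
                         pca_dim = 50, seed = 1, progress = FALSE) {
  n <- n_subjects(features)
  if (n < 6L) stop("invalid input: need at least 6 subjects", call. = FALSE)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("invalid input: both classes must be present", call. = FALSE)
  folds <- vector("list", n)
  agg <- numeric(n); nbase <- integer(n)
  base_scores <- vector("list", n)
  skipped <- logical(n)
  for (t in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), t)
    if (length(unique(y[train_idx])) < 2L) {
      warning(sprintf("fold %d skipped: training set single-class", t))
      skipped[t] <- TRUE
      next
    }
    pb <- .pca_blocks(features, train_idx, pca_dim)
    kb <- .kernel_blocks(pb)
    sel <- .forward_search(kb, y[train_idx], anchors, grid, train_idx)
    fold <- list(test_idx = t, train_idx = train_idx, selected = sel$selected,
                 params = list(C = sel$C, kernel = sel$kernel),
                 inner_accuracy = sel$acc)
    bs <- .fold_base_scores(kb, y[train_idx], fold, t)
    folds[[t]] <- fold
    base_scores[[t]] <- bs
    agg[t] <- median(bs)
    nbase[t] <- length(bs)
    if (progress)
      message(sprintf("fold %d/%d: selected {%s}, inner acc %.3f", t, n,
                      paste(features$component_labels[sel$selected], collapse = ","),
                      sel$acc))
  }
  keep <- !skipped
  pred <- ifelse(agg > 0, 1L, -1L)                 # aggregated score 0 -> control
  scores <- data.frame(subject_id = features$subject_ids,
                       session = features$sessions,
                       label = y, aggregated_score = agg,
                       predicted_label = pred, n_base = nbase,
                       stringsAsFactors = FALSE)[keep, ]
  metrics <- evaluate(pred[keep], y[keep], agg[keep])
  k <- n_components(features)
  selfreq <- vapply(seq_len(k), function(cc)
    mean(vapply(folds[keep], function(f) cc %in% f$selected, logical(1))), numeric(1))
  names(selfreq) <- features$component_labels
  structure(list(scores = scores, folds = folds, base_scores = base_scores,
                 metrics = metrics, selection_freq = selfreq,
                 features = features, grid = grid, pca_dim = pca_dim),
            class = "icn_ensemble")
}

#' @export
print.icn_ensemble <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<icn_ensemble> %d subjects | accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f\n",
              nrow(x$scores), 100 * m$accuracy, 100 * m$sensitivity,
              100 * m$specificity, m$auc))
  top <- sort(x$selection_freq, decreasing = TRUE)
  cat("  selection freq:", paste(sprintf("%s=%.2f", names(top)[seq_len(min(8, length(top)))],
                                         top[seq_len(min(8, length(top)))]), collapse = " "), "\n")
  invisible(x)
}

#' Classification metrics
#'
#' @param predictions +1/-1 predicted labels.
#' @param labels +1/-1 true labels (+1 = patient).
#' @param scores optional continuous scores for the AUC (rank statistic).
#' @return list of class `icn_metrics`: `accuracy`, `sensitivity` (patient
#'   recall), `specificity` (control recall), `auc`, `confusion` (tp, fn,
#'   tn, fp).
#' @export
evaluate <- function(predictions, labels, scores = NULL) {
  if (length(predictions) == 0L) stop("invalid input: empty predictions", call. = FALSE)
  if (length(predictions) != length(labels)) stop("length mismatch", call. = FALSE)
  pos <- labels > 0; neg <- !pos
  if (!any(pos) || !any(neg))
    stop("undefined metric: both classes must be present", call. = FALSE)
  tp <- sum(predictions > 0 & pos); fn <- sum(predictions <= 0 & pos)
  tn <- sum(predictions <= 0 & neg); fp <- sum(predictions > 0 & neg)
  auc <- if (is.null(scores)) NA_real_ else {
    r <- rank(scores)
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(neg))
  }
  structure(list(accuracy = (tp + tn) / length(labels),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = auc,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "icn_metrics")
}

#' @export
print.icn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | sensitivity %.2f%% | specificity %.2f%% | AUC %s\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' Score follow-up scans with the baseline fold classifiers
#'
#' Each follow-up scan is scored by the base classifiers of that subject's
#' own outer fold (which excluded the subject at training time), aggregated
#' by the median — so scoring the baseline features themselves returns the
#' baseline aggregated score exactly.
#'
#' @param ensemble an [loo_ensemble()] result on baseline features.
#' @param followup_features an [feature_set()] of follow-up scans; every
#'   subject must appear in the baseline ensemble.
#' @return data.frame: `subject_id`, `baseline_score`, `followup_score`,
#'   `n_base`.
#' @export
score_followup <- function(ensemble, followup_features) {
  base_feat <- ensemble$features
  out <- vector("list", n_subjects(followup_features))
  for (i in seq_len(n_subjects(followup_features))) {
    sid <- followup_features$subject_ids[i]
    t <- match(sid, base_feat$subject_ids)
    if (is.na(t) || is.null(ensemble$folds[[t]]))
      stop(sprintf("invalid input: subject %s not in the baseline ensemble", sid),
           call. = FALSE)
    fold <- ensemble$folds[[t]]
    # Rebuild the fold's PCA and kernel blocks with the follow-up sample
    # appended as row n+1, then rerun the fold's base classifiers on it.
    pb <- .pca_blocks(base_feat, fold$train_idx, ensemble$pca_dim)
    pb_aug <- lapply(seq_along(pb), function(cc) {
      p <- pb[[cc]]
      extra <- sweep(sweep(followup_features$blocks[[cc]][i, , drop = FALSE],
                           2, p$center), 2, p$scale, "/") %*% p$rotation
      p$proj <- rbind(p$proj, extra)
      p
    })
    kb <- .kernel_blocks(pb_aug)
    nrow_aug <- nrow(pb_aug[[1]]$proj)
    y_train <- base_feat$labels[fold$train_idx]
    bs <- .fold_base_scores(kb, y_train, fold, nrow_aug)
    out[[i]] <- data.frame(subject_id = sid,
                           baseline_score = ensemble$scores$aggregated_score[
                             match(sid, ensemble$scores$subject_id)],
                           followup_score = median(bs),
                           n_base = length(bs), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
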