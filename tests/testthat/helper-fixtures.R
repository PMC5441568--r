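# Shared fixture builders.  Everything is generated in code at test time;
# sizes are desk-scale so the whole suite stays inside the runtime budget.

# A small deterministic scan: k blobs mixed with band-limited time courses.
tiny_scan <- function(grid = c(10, 10, 4), n_volumes = 60, tr = 2, seed = 1,
                      noise_sd = 0.2, offset = 100) {
  set.seed(seed)
  a <- make_atlas(grid, k = 4, seed = seed, n_affected = 2)
  tc <- simulate_time_courses(4, n_volumes, tr, seed = seed)
  Y <- crossprod(a$maps, tc) + matrix(rnorm(prod(grid) * n_volumes, 0, noise_sd),
                                      prod(grid), n_volumes) + offset
  new_scan(array(Y, dim = c(grid, n_volumes)), tr_seconds = tr,
           subject_id = sprintf("T%03d", seed))
}

tiny_nuisance <- function(n_volumes, seed = 1) {
  set.seed(seed)
  rw <- function() { x <- cumsum(rnorm(n_volumes)); x - mean(x) }
  list(motion = vapply(1:6, function(i) rw(), numeric(n_volumes)),
       wm = rw(), csf = rw())
}

# Small full cohort reused by several test files (built once per file load).
small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      a <- make_atlas(c(12, 12, 6), k = 8, seed = 2, n_affected = 4)
      cfg <- cohort_config(n_patients = 8, n_controls = 8, n_followup_ect = 3,
                           n_followup_med = 3, n_volumes = 80, k_components = 8,
                           delta = 0.4, seed = 3)
      memo <<- simulate_cohort(a, cfg)
    }
    memo
  }
})

# Gaussian feature sets with a planted mean shift on selected components:
# lets classifier tests run without any imaging stages.
synthetic_features <- function(n_per_class = 10, k = 8, v = 30,
                               signal = integer(0), shift = 1.5, seed = 1,
                               anchors = c(1L, 2L)) {
  set.seed(seed)
  n <- 2 * n_per_class
  groups <- rep(c("patient", "control"), each = n_per_class)
  blocks <- lapply(seq_len(k), function(cc) {
    B <- matrix(rnorm(n * v), n, v)
    if (cc %in% signal) {
      dir <- rnorm(v); dir <- dir / sqrt(sum(dir^2))
      B[seq_len(n_per_class), ] <- B[seq_len(n_per_class), ] +
        shift * matrix(dir, n_per_class, v, byrow = TRUE)
    }
    B
  })
  structure(list(blocks = blocks,
                 labels = ifelse(groups == "patient", 1L, -1L),
                 groups = groups,
                 subject_ids = sprintf("S%02d", seq_len(n)),
                 sessions = rep("baseline", n),
                 anchors = anchors,
                 component_labels = sprintf("C%02d", seq_len(k))),
            class = "icn_features")
}

# Independent periodogram band-power fraction (oracle for generator and
# band-pass contracts): power in [lo, hi] over total non-DC power.
band_fraction <- function(x, tr, lo = 0.01, hi = 0.08) {
  n <- length(x)
  s <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / (n * tr)
  f[f > 1 / (2 * tr)] <- 1 / tr - f[f > 1 / (2 * tr)]
  inb <- f >= lo & f <= hi
  sum(s[inb]) / sum(s[-1])
}

expect_scan_equal <- function(a, b, tol = 1e-8) {
  expect_equal(dim(a$data), dim(b$data))
  expect_lt(max(abs(a$data - b$data)), tol)
}
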