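# Shared fixtures and independent oracles for the test suite. Fixtures are
# built in code (no stored data); oracles deliberately use different code
# paths than the implementation they check.

# --- fixtures ---------------------------------------------------------------

tiny_atlas <- function(n_rois = 2L, n_voxels = 20L) {
  roi_atlas(roi_names = paste0("R", seq_len(n_rois)),
            n_voxels = rep(n_voxels, n_rois))
}

tiny_schedules <- function(n_runs = 4L, seed = 1L, n_candidates = 5L) {
  seeds <- seed + seq_len(2L * n_runs)
  lapply(seq_len(n_runs), function(r) {
    ord <- optimize_order(run_composition(), n_candidates = n_candidates,
                          seed = seeds[2L * r - 1L])
    build_schedule(ord, seed = seeds[2L * r])
  })
}

tiny_dataset <- function(n_runs = 4L, seed = 1L, atlas = tiny_atlas(),
                         scenario = "paper_like", amp = 1.2,
                         noise_sd = 1, ...) {
  axes <- if (scenario == "custom") {
    amps <- matrix(amp, nrow(atlas), 3,
                   dimnames = list(atlas$roi, c("VIS", "CFS", "CFF")))
    sample_coding_axes(atlas, scenario = "custom", seed = seed,
                       amplitudes = amps,
                       rho = setNames(rep(0.9, nrow(atlas)), atlas$roi))
  } else {
    sample_coding_axes(atlas, scenario = scenario, seed = seed)
  }
  simulate_subject(tiny_schedules(n_runs, seed = seed + 100L), axes,
                   noise_sd = noise_sd, seed = seed + 200L, ...)
}

# --- oracles ----------------------------------------------------------------

# Transition-deviation score by explicit loop counting (independent of the
# vectorized implementation).
score_order_oracle <- function(categories) {
  n <- length(categories)
  dev <- function(k) {
    reps <- 0L
    for (i in seq_len(n - k)) {
      if (categories[i] == categories[i + k]) reps <- reps + 1L
    }
    abs(reps / (n - k) - 0.5)
  }
  list(lag1_dev = dev(1L), lag2_dev = dev(2L),
       total = dev(1L) + dev(2L))
}

# Exact rational upper binomial tail for p = 1/2: sum(choose(n, k:n)) / 2^n.
binomial_tail_half_oracle <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# High-precision standard-normal quantile via root finding on pnorm (does
# not call qnorm).
qnorm_oracle <- function(p) {
  vapply(p, function(pp) {
    uniroot(function(z) pnorm(z) - pp, c(-10, 10), tol = 1e-12)$root
  }, numeric(1))
}

# Student upper-tail probability through the incomplete-beta representation
# (does not call pt).
student_p_oracle <- function(t, df) {
  x <- df / (df + t^2)
  half <- pbeta(x, df / 2, 0.5) / 2
  ifelse(t >= 0, half, 1 - half)
}

# Brute-force Benjamini-Hochberg step-up straight from the definition.
fdr_bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(m)) {
    if (p[o[i]] <= i * q / m) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}
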