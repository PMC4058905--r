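test_that("default atlas has 12 uniquely named ROIs sized 30-200 voxels", {
  atlas <- roi_atlas()
  expect_equal(nrow(atlas), 12L)
  expect_false(anyDuplicated(atlas$roi) > 0)
  expect_true(all(atlas$n_voxels >= 30 & atlas$n_voxels <= 200))
  expect_error(roi_atlas(roi_names = c("A", "A")), "unique")
  expect_error(roi_atlas(roi_names = "A", n_voxels = 1L), "at least 2")
})

test_that("coding-axes scenarios plant the intended amplitude map", {
  null_axes <- sample_coding_axes(scenario = "null", seed = 1)
  expect_true(all(null_axes$amplitudes == 0))

  pl <- sample_coding_axes(scenario = "paper_like", seed = 1)
  expect_equal(pl$amplitudes["FG", "CFS"], 0)
  expect_gt(pl$amplitudes["FG", "CFF"], 0)
  expect_true(all(pl$amplitudes[, "VIS"] > 0))
  expect_setequal(rownames(pl$amplitudes)[pl$amplitudes[, "CFS"] > 0],
                  c("MOG", "LG", "MLOS"))
  expect_setequal(rownames(pl$amplitudes)[pl$amplitudes[, "CFF"] > 0],
                  c("LG", "FG", "SPCS"))

  ft <- sample_coding_axes(scenario = "full_transfer", seed = 1)
  expect_true(all(ft$rho == 1))
  expect_error(sample_coding_axes(scenario = "nonsense"), "arg")
})

test_that("axes are unit norm with overlap rho^2 and rho=1 identity", {
  atlas <- tiny_atlas(n_rois = 3, n_voxels = 400)
  amps <- matrix(1, 3, 3, dimnames = list(atlas$roi, c("VIS", "CFS", "CFF")))
  for (r in c(0, 0.5, 1)) {
    ax <- sample_coding_axes(atlas, scenario = "custom", seed = 2,
                             amplitudes = amps,
                             rho = setNames(rep(r, 3), atlas$roi))
    for (roi in atlas$roi) {
      w <- ax$axes[[roi]]$w
      expect_equal(unname(sqrt(colSums(w^2))), rep(1, 3), tolerance = 1e-10)
      overlap <- sum(w[, "CFS"] * w[, "CFF"])
      if (r == 1) {
        expect_identical(w[, "CFS"], w[, "CFF"])
      } else {
        # Unique parts are orthogonal to w_shared but only orthogonal to each
        # other in expectation; 400 voxels keeps the cross term ~ 1/sqrt(400).
        expect_equal(overlap, r^2, tolerance = 0.2)
      }
      # Color nuisance is exactly orthogonal to every category axis.
      expect_equal(max(abs(crossprod(ax$axes[[roi]]$color_dir, w))), 0,
                   tolerance = 1e-10)
    }
  }
})

test_that("trial patterns are deterministic, aligned, and separable when noiseless", {
  atlas <- tiny_atlas()
  ds1 <- tiny_dataset(n_runs = 2, seed = 3, atlas = atlas)
  ds2 <- tiny_dataset(n_runs = 2, seed = 3, atlas = atlas)
  expect_identical(ds1$patterns, ds2$patterns)
  expect_equal(nrow(ds1$events), 2 * 48)
  expect_equal(nrow(ds1$patterns[[1]]), nrow(ds1$events))

  # Near-noiseless with planted amplitude: projections on the coding axis
  # separate faces from tools perfectly in every planted (ROI, method).
  axes <- sample_coding_axes(atlas, scenario = "custom", seed = 4,
                             amplitudes = matrix(
                               1, 2, 3,
                               dimnames = list(atlas$roi,
                                               c("VIS", "CFS", "CFF"))),
                             rho = setNames(c(1, 1), atlas$roi))
  ds <- simulate_subject(tiny_schedules(2, seed = 8), axes,
                         noise_sd = 1e-6, exemplar_sd = 0, color_sd = 0,
                         seed = 9)
  for (roi in atlas$roi) {
    proj <- ds$patterns[[roi]] %*% axes$axes[[roi]]$w[, "VIS"]
    expect_true(all(proj[ds$events$category == "face"] > 0))
    expect_true(all(proj[ds$events$category == "tool"] < 0))
  }
})

test_that("null amplitudes give chance-level accuracy over many simulations", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 15)
  axes <- sample_coding_axes(atlas, scenario = "null", seed = 1)
  schedules <- tiny_schedules(2, seed = 20)
  accs <- vapply(1:200, function(i) {
    ds <- simulate_subject(schedules, axes, seed = 1000 + i)
    res <- decode_subject(ds, regimes = "within:VIS")
    res$accuracy[1]
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 1e-12)
})

test_that("double-gamma HRF and timeseries mode peak 4-6 s after onset", {
  # Kernel: numeric evaluation of the double-gamma difference.
  grid <- seq(0, 30, by = 0.01)
  h <- hrf_double_gamma(grid)
  expect_equal(grid[which.max(h)], 5, tolerance = 0.05)
  expect_equal(max(h), 1)
  expect_true(all(hrf_double_gamma(c(-1, -5)) == 0))

  # A single trial at onset 10 s: series peak within 4-6 s of onset.
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 4)
  axes <- sample_coding_axes(atlas, scenario = "custom", seed = 2,
                             amplitudes = matrix(
                               5, 1, 3,
                               dimnames = list(atlas$roi,
                                               c("VIS", "CFS", "CFF"))),
                             rho = setNames(1, atlas$roi))
  ord <- run_composition()[1, , drop = FALSE]
  sch <- build_schedule(ord, seed = 1, n_volumes = 30,
                        lead_in_seconds = 10)
  ds <- simulate_subject(list(sch), axes, noise_sd = 1e-6, mode = "timeseries",
                        exemplar_sd = 0, color_sd = 0, seed = 3)
  v <- ds$series[[1]][[1]][, which.max(abs(axes$axes[[1]]$w[, "VIS"]))]
  peak_time <- (which.max(abs(v)) - 1) * 2
  expect_gte(peak_time - 10, 4)
  expect_lte(peak_time - 10, 6)
})

test_that("simulated behavior honors its rates", {
  # 10,000 invisible trials: accuracy within 3 binomial SE of chance.
  ev <- data.frame(method = "CFS", category = rep(c("face", "tool"), 5000))
  beh <- simulate_behavior(ev, seed = 5)
  se <- sqrt(0.25 / nrow(ev))
  expect_lt(abs(mean(beh$guess == ev$category) - 0.5), 3 * se)
  expect_lt(abs(mean(beh$breakthrough) - 0.031), 3 * sqrt(0.031 * 0.969 / nrow(ev)))
  expect_true(all(is.na(beh$seen)))

  # Zero breakthrough rate leaves no flags.
  rates <- default_behavior_rates()
  rates$breakthrough[] <- 0
  beh0 <- simulate_behavior(ev, rates = rates, seed = 6)
  expect_false(any(beh0$breakthrough))

  # Visible trials are near ceiling and use the defaults verbatim.
  evv <- data.frame(method = "VIS", category = rep(c("face", "tool"), 5000))
  behv <- simulate_behavior(evv, seed = 7)
  expect_lt(abs(mean(behv$guess_correct) - 0.994),
            3 * sqrt(0.994 * 0.006 / nrow(evv)))
  expect_false(any(behv$breakthrough))
  expect_false(any(is.na(behv$seen)))

  bad <- default_behavior_rates()
  bad$visible_accuracy <- 1.2
  expect_error(simulate_behavior(ev, rates = bad), "0, 1")
})

test_that("cross-method decodability increases with rho", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 40)
  amps <- matrix(1.5, 1, 3, dimnames = list(atlas$roi,
                                            c("VIS", "CFS", "CFF")))
  rho_grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_dp <- vapply(rho_grid, function(r) {
    dps <- vapply(1:6, function(i) {
      ax <- sample_coding_axes(atlas, scenario = "custom", seed = 100 + i,
                               amplitudes = amps,
                               rho = setNames(r, atlas$roi))
      ds <- simulate_subject(tiny_schedules(4, seed = 200 + i), ax,
                             seed = 300 + i)
      res <- decode_subject(ds, regimes = "cross:CFS-CFF")
      res$dprime[1]
    }, numeric(1))
    mean(dps)
  }, numeric(1))
  expect_gt(cor(rho_grid, mean_dp, method = "spearman"), 0)
})
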