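test_that("extract_trial_pattern averages the 4 s and 6 s volumes", {
  series <- matrix(0, nrow = 12, ncol = 2)
  series[8, ] <- 2   # volume index 7 (0-based), t = 14 s
  series[9, ] <- 4   # t = 16 s
  expect_equal(extract_trial_pattern(series, onset = 10), c(3, 3))

  const <- matrix(7, nrow = 10, ncol = 3)
  expect_equal(extract_trial_pattern(const, onset = 4), c(7, 7, 7))

  # Too close to the run end: flagged as NA for the caller to drop.
  expect_true(all(is.na(extract_trial_pattern(series, onset = 20))))
})

test_that("extracted pattern of a noiseless trial follows the HRF kernel", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 3)
  amps <- matrix(2, 1, 3, dimnames = list(atlas$roi, c("VIS", "CFS", "CFF")))
  axes <- sample_coding_axes(atlas, scenario = "custom", seed = 1,
                             amplitudes = amps, rho = setNames(1, atlas$roi))
  ord <- run_composition()[run_composition()$category == "face", ][1, ]
  sch <- build_schedule(ord, seed = 1, n_volumes = 25, lead_in_seconds = 10)
  ds <- simulate_subject(list(sch), axes, noise_sd = 1e-9,
                         mode = "timeseries", exemplar_sd = 0, color_sd = 0,
                         seed = 2, ar1 = 0)
  got <- extract_trial_pattern(ds$series[[1]][[1]], onset = 10)
  # Oracle: amplitude * axis * mean of the boxcar-convolved kernel at 4, 6 s.
  kern <- function(t) {
    sum(hrf_double_gamma(t - seq(0, 1.9, by = 0.1))) * 0.1
  }
  want <- 2 * axes$axes[[1]]$w[, "VIS"] * mean(c(kern(4), kern(6)))
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("average_patterns is an unweighted cell mean", {
  p <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(unname(average_patterns(p[1, , drop = FALSE], "a")),
               p[1, , drop = FALSE])
  same <- average_patterns(rbind(c(1, 2), c(1, 2)), c("a", "a"))
  expect_equal(unname(same), rbind(c(1, 2)))
  zero <- average_patterns(rbind(c(1, -1), c(-1, 1)), c("a", "a"))
  expect_equal(unname(zero), rbind(c(0, 0)))
  expect_error(average_patterns(p[0, , drop = FALSE], character(0)),
               "empty cell")
})

test_that("within-method fold plans enumerate runs x directions", {
  plan8 <- make_folds_within(1:8, "VIS")
  expect_equal(nrow(plan8), 16L)
  plan2 <- make_folds_within(1:2, "CFS")
  expect_equal(nrow(plan2), 4L)
  # Dropped run: 14 folds and the run never appears.
  plan7 <- make_folds_within(setdiff(1:8, 5), "CFF")
  expect_equal(nrow(plan7), 14L)
  expect_false(5 %in% plan7$test_run)
  expect_false(5 %in% attr(plan7, "train_runs"))
  expect_warning(make_folds_within(3L, "CFF"), "fewer than 2")
})

test_that("cross-method fold plans respect their preconditions", {
  plan <- make_folds_cross("CFS", "CFF", 1:8, 1:8)
  expect_equal(nrow(plan), 16L)
  expect_true(all(plan$train_method == "CFS"))
  expect_true(all(plan$test_method == "CFF"))
  expect_error(make_folds_cross("CFS", "CFS", 1:8, 1:8), "distinct")
  # Swapped train/test is a distinct regime.
  swap <- make_folds_cross("CFF", "CFS", 1:8, 1:8)
  expect_false(identical(plan$regime[1], swap$regime[1]))
  # Without the cross-exemplar constraint: one fold per run.
  loose <- make_folds_cross("CFS", "CFF", 1:8, 1:8, cross_exemplar = FALSE)
  expect_equal(nrow(loose), 8L)
})

test_that("no exemplar id or run appears on both sides of a fold", {
  ds <- tiny_dataset(n_runs = 4, seed = 21)
  split <- default_exemplar_split()
  mask <- apply_qc(ds, split = split)
  cells <- invisidec:::cell_index(ds$events, mask$trial_usable, split)
  for (rg in all_regimes()) {
    spec <- invisidec:::parse_regime(rg)
    plan <- if (spec$type == "within") {
      make_folds_within(invisidec:::retained_runs_for(mask, spec$train),
                        spec$train, split)
    } else {
      make_folds_cross(spec$train, spec$test,
                       invisidec:::retained_runs_for(mask, spec$train),
                       invisidec:::retained_runs_for(mask, spec$test), split)
    }
    idx <- invisidec:::fold_rows(cells, plan)
    for (f in seq_along(idx)) {
      tr <- idx[[f]]$train
      te <- idx[[f]]$test
      tr_ex <- unlist(lapply(cells$trials[tr],
                             function(r) ds$events$exemplar[r]))
      te_ex <- unlist(lapply(cells$trials[te],
                             function(r) ds$events$exemplar[r]))
      expect_length(intersect(tr_ex, te_ex), 0L)
      expect_length(intersect(cells$run[tr], cells$run[te]), 0L)
    }
  }
})

test_that("the linear classifier behaves on canonical cases", {
  u <- c(1, 0.5, -1)
  x <- rbind(u, -u)
  fit <- train_linear_classifier(x, c("face", "tool"))
  expect_equal(predict(fit, u), "face")
  expect_equal(predict(fit, -u), "tool")

  # A training pattern of separable data keeps its own label.
  set.seed(31)
  x2 <- rbind(matrix(rnorm(20, mean = 2), 5), matrix(rnorm(20, mean = -2), 5))
  lab <- rep(c("face", "tool"), each = 5)
  fit2 <- train_linear_classifier(x2, lab)
  expect_equal(unname(predict(fit2, x2)), lab)

  expect_error(train_linear_classifier(x, c("face", "face")), "both classes")

  # Determinism for fixed input order.
  f1 <- train_linear_classifier(x2, lab)
  f2 <- train_linear_classifier(x2, lab)
  expect_identical(f1, f2)
})

test_that("noiseless planted data decodes perfectly; evaluation pools counts", {
  atlas <- tiny_atlas(n_rois = 1)
  ds <- tiny_dataset(n_runs = 4, seed = 23, atlas = atlas,
                     scenario = "custom", amp = 1, noise_sd = 1e-6,
                     exemplar_sd = 1e-7, color_sd = 0)
  res <- decode_subject(ds, regimes = "within:VIS")
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$H + res$M, 8L)   # 4 runs x 2 directions, 1 face cell each
  expect_equal(res$FA + res$CR, 8L)
  expect_equal(res$dprime, qnorm(8.5 / 9) - qnorm(0.5 / 9))
  # Count arithmetic: accuracy = (H + CR) / total.
  expect_equal(res$accuracy, (res$H + res$CR) / 16)
})

test_that("d-prime matches the quantile oracle and its symmetries", {
  expect_equal(dprime(5, 5, 5, 5), 0)
  expect_equal(dprime(12, 4, 4, 12, correction = "none"), 2 * qnorm(0.75))
  expect_equal(dprime(12, 4, 4, 12, correction = "none"), 1.349, tolerance = 1e-3)
  expect_equal(dprime(8, 0, 0, 8), qnorm(8.5 / 9) - qnorm(0.5 / 9))
  expect_equal(dprime(8, 0, 0, 8), 3.19, tolerance = 1e-2)
  expect_error(dprime(0, 0, 3, 5), "at least one")

  # Independent inverse-normal oracle on a rate grid, 1e-9 agreement.
  for (H in c(1, 4, 7)) {
    for (FA in c(1, 4, 7)) {
      got <- dprime(H, 8 - H, FA, 8 - FA)
      want <- qnorm_oracle((H + 0.5) / 9) - qnorm_oracle((FA + 0.5) / 9)
      expect_equal(got, want, tolerance = 1e-9)
      # Antisymmetry under swapping the signal class: with tool as signal
      # but "face" kept as the signal response, hits become FA and false
      # alarms become H.
      expect_equal(dprime(FA, 8 - FA, H, 8 - H), -got, tolerance = 1e-12)
    }
  }
})

test_that("label permutation drives accuracy to chance", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 15)
  axes <- sample_coding_axes(atlas, seed = 40, scenario = "custom",
                             amplitudes = matrix(
                               1.5, 1, 3,
                               dimnames = list(atlas$roi,
                                               c("VIS", "CFS", "CFF"))),
                             rho = setNames(0.9, atlas$roi))
  schedules <- tiny_schedules(2, seed = 41)
  set.seed(42)
  accs <- vapply(1:60, function(i) {
    ds <- simulate_subject(schedules, axes, seed = 500 + i)
    # Permute pattern rows within each (run, method) stratum: severs the
    # pattern-label link while keeping every design cell balanced.
    for (r in unique(ds$events$run)) {
      for (m in c("VIS", "CFS", "CFF")) {
        rows <- which(ds$events$run == r & ds$events$method == m)
        perm <- sample(rows)
        ds$patterns <- lapply(ds$patterns, function(p) {
          p[rows, ] <- p[perm, , drop = FALSE]
          p
        })
      }
    }
    decode_subject(ds, regimes = "within:VIS")$accuracy
  }, numeric(1))
  accs <- accs[!is.na(accs)]
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("zero amplitude yields mean d-prime within 3 SE of 0", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 12)
  axes <- sample_coding_axes(atlas, scenario = "null", seed = 50)
  schedules <- tiny_schedules(2, seed = 51)
  dps <- vapply(1:200, function(i) {
    ds <- simulate_subject(schedules, axes, seed = 600 + i)
    suppressWarnings(decode_subject(ds, regimes = "within:CFS")$dprime)
  }, numeric(1))
  dps <- dps[!is.na(dps)]  # rare chance-level guessing run exclusions
  se <- sd(dps) / sqrt(length(dps))
  expect_lt(abs(mean(dps)), 3 * se)
})

test_that("within-method d-prime increases with planted amplitude", {
  atlas <- tiny_atlas(n_rois = 1, n_voxels = 30)
  grid <- c(0, 0.5, 1.5, 3)
  mean_dp <- vapply(grid, function(a) {
    dps <- vapply(1:8, function(i) {
      ax <- sample_coding_axes(atlas, scenario = "custom", seed = 700 + i,
                               amplitudes = matrix(
                                 a, 1, 3,
                                 dimnames = list(atlas$roi,
                                                 c("VIS", "CFS", "CFF"))),
                               rho = setNames(0.5, atlas$roi))
      ds <- simulate_subject(tiny_schedules(3, seed = 800 + i), ax,
                             seed = 900 + i)
      decode_subject(ds, regimes = "within:VIS")$dprime
    }, numeric(1))
    mean(dps)
  }, numeric(1))
  expect_true(all(diff(mean_dp) > 0))
})

test_that("subjects with too few retained runs give NA results, not errors", {
  ds <- tiny_dataset(n_runs = 2, seed = 60)
  ev <- ds$events
  # Exclude both runs for CFS via perfect guessing.
  sel <- ev$method == "CFS"
  ev$guess[sel] <- ev$category[sel]
  ds$events <- ev
  mask <- apply_qc(ds)
  expect_warning(res <- decode_subject(ds, mask,
                                       regimes = c("within:CFS",
                                                   "within:VIS")),
                 "fewer than 2")
  cfs <- res[res$regime == "within:CFS", ]
  expect_true(all(is.na(cfs$dprime)))
  expect_true(all(!is.na(res$dprime[res$regime == "within:VIS"])))
})
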