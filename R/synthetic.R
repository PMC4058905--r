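#' Default region-of-interest atlas specification
#'
#' The 12 bilateral anatomical ROIs used throughout the package's worked
#' examples and simulations, with surface sizes typical of an anatomical
#' parcellation and voxel counts proportional to size (about 30-200 voxels).
#'
#' @param roi_names character vector of ROI abbreviations.
#' @param full_names matching full anatomical names.
#' @param size_cm2 matching surface sizes (cm^2); voxel counts are derived
#'   from these unless `n_voxels` is given.
#' @param n_voxels optional explicit voxel counts (>= 2 each).
#' @return a `data.frame` of class `roi_atlas` with columns `roi`,
#'   `full_name`, `size_cm2`, `n_voxels`.
#' @export
#' @examples
#' roi_atlas()
roi_atlas <- function(roi_names = NULL, full_names = NULL, size_cm2 = NULL,
                      n_voxels = NULL) {
  if (is.null(roi_names)) {
    roi_names <- c("IOGS", "MFG", "MOG", "FG", "LG", "OP",
                   "CTPS", "IPS", "MLOS", "AOS", "LOTS", "SPCS")
    full_names <- c(
      "Inferior occipital gyrus and sulcus", "Middle frontal gyrus",
      "Middle occipital gyrus", "Fusiform gyrus", "Lingual gyrus",
      "Occipital pole", "Posterior transverse collateral sulcus",
      "Intraparietal sulcus", "Middle occipital and lunate sulci",
      "Anterior occipital sulcus", "Lateral occipitotemporal sulcus",
      "Precentral sulcus, superior part")
    size_cm2 <- c(23.96, 64.96, 33.69, 27.08, 42.04, 38.05,
                  8.36, 55.58, 17.84, 13.24, 17.66, 24.32)
  }
  if (anyDuplicated(roi_names)) {
    stop("ROI names must be unique", call. = FALSE)
  }
  if (is.null(full_names)) full_names <- roi_names
  if (is.null(size_cm2)) size_cm2 <- rep(NA_real_, length(roi_names))
  if (is.null(n_voxels)) {
    # ~3 voxels per cm^2, floored at 30, gives the 30-200 voxel range.
    n_voxels <- pmax(30L, as.integer(round(size_cm2 * 3)))
  }
  if (any(n_voxels < 2L)) {
    stop("every ROI needs at least 2 voxels", call. = FALSE)
  }
  out <- data.frame(roi = roi_names, full_name = full_names,
                    size_cm2 = size_cm2, n_voxels = as.integer(n_voxels),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_atlas", "data.frame")
  out
}

unit <- function(v) v / sqrt(sum(v^2))

orthogonalize <- function(v, basis) {
  # Project out the span of `basis` exactly (columns need not be mutually
  # orthogonal), via an orthonormal QR basis.
  qb <- qr.Q(qr(basis))
  drop(v - qb %*% crossprod(qb, v))
}

#' Sample per-ROI, per-method category coding axes
#'
#' Draws, for every ROI, one unit coding axis per presentation method along
#' which face and tool patterns separate, together with an amplitude
#' `a >= 0` per (ROI, method) and an overlap parameter `rho` per ROI that
#' controls how much of the axis is shared across methods:
#' `w_m = rho * w_shared + sqrt(1 - rho^2) * w_unique_m`, with the unique
#' parts orthogonal to the shared axis. `rho = 1` makes the axes identical
#' across methods (full cross-method transfer); `rho = 0` makes them
#' orthogonal in expectation.
#'
#' Scenarios:
#' \describe{
#'   \item{`paper_like`}{visible information planted in every ROI; CFS
#'     information only in the lateral/medial occipital subset (MOG, LG,
#'     MLOS); CFF information only in LG, FG and SPCS; `rho` high only in
#'     posterior-occipital ROIs.}
#'   \item{`null`}{all amplitudes 0 (no category information anywhere).}
#'   \item{`full_transfer`}{`paper_like` amplitudes with `rho = 1`
#'     everywhere.}
#'   \item{`custom`}{amplitudes and rho supplied by the caller.}
#' }
#'
#' @param atlas an [roi_atlas()].
#' @param scenario one of `"paper_like"`, `"null"`, `"full_transfer"`,
#'   `"custom"`.
#' @param seed integer seed or `NULL`.
#' @param amp_visible planted visible amplitude (default 1.5).
#' @param amp_invisible planted invisible amplitude (default 1.2).
#' @param rho_high,rho_low overlap used in high- and low-overlap ROIs
#'   (defaults 0.9 and 0.1).
#' @param cfs_rois,cff_rois,high_rho_rois planted ROI subsets for the
#'   `paper_like` scenario.
#' @param amplitudes for `scenario = "custom"`: numeric matrix
#'   (ROI x method, dimnames required).
#' @param rho for `scenario = "custom"`: named numeric vector per ROI.
#' @return object of class `coding_axes`: list with per-ROI axes (`$axes`),
#'   the amplitude matrix (`$amplitudes`), `$rho`, `$scenario`, `$atlas`.
#' @export
sample_coding_axes <- function(atlas = roi_atlas(),
                               scenario = c("paper_like", "null",
                                            "full_transfer", "custom"),
                               seed = NULL,
                               amp_visible = 1.5,
                               amp_invisible = 1.2,
                               rho_high = 0.9,
                               rho_low = 0.1,
                               cfs_rois = c("MOG", "LG", "MLOS"),
                               cff_rois = c("LG", "FG", "SPCS"),
                               high_rho_rois = c("IOGS", "MOG", "LG", "OP",
                                                 "MLOS", "CTPS"),
                               amplitudes = NULL,
                               rho = NULL) {
  scenario <- match.arg(scenario)
  rois <- atlas$roi
  n_roi <- length(rois)
  amp <- matrix(0, n_roi, 3, dimnames = list(rois, .methods))
  rho_vec <- setNames(rep(rho_low, n_roi), rois)
  if (scenario %in% c("paper_like", "full_transfer")) {
    amp[, "VIS"] <- amp_visible
    amp[intersect(cfs_rois, rois), "CFS"] <- amp_invisible
    amp[intersect(cff_rois, rois), "CFF"] <- amp_invisible
    rho_vec[intersect(high_rho_rois, rois)] <- rho_high
    if (scenario == "full_transfer") rho_vec[] <- 1
  } else if (scenario == "null") {
    rho_vec[] <- 0.5
  } else {
    if (is.null(amplitudes) || is.null(rho)) {
      stop("scenario 'custom' requires `amplitudes` and `rho`", call. = FALSE)
    }
    amp[rownames(amplitudes), colnames(amplitudes)] <- amplitudes
    rho_vec[names(rho)] <- rho
  }
  if (any(amp < 0) || any(rho_vec < 0 | rho_vec > 1)) {
    stop("amplitudes must be >= 0 and rho in [0, 1]", call. = FALSE)
  }
  axes <- with_rng(seed, {
    lapply(seq_len(n_roi), function(i) {
      d <- atlas$n_voxels[i]
      r <- rho_vec[i]
      w_shared <- unit(rnorm(d))
      w <- matrix(0, d, 3, dimnames = list(NULL, .methods))
      uniq <- matrix(0, d, 3, dimnames = list(NULL, .methods))
      for (m in .methods) {
        u <- unit(orthogonalize(rnorm(d), cbind(w_shared)))
        uniq[, m] <- u
        w[, m] <- if (r == 1) w_shared else r * w_shared + sqrt(1 - r^2) * u
      }
      # Color nuisance direction, orthogonal to every category axis.
      cdir <- unit(orthogonalize(rnorm(d), cbind(w_shared, uniq)))
      list(w = w, w_shared = w_shared, color_dir = cdir)
    })
  })
  names(axes) <- rois
  structure(
    list(axes = axes, amplitudes = amp, rho = rho_vec,
         scenario = scenario, atlas = atlas),
    class = "coding_axes"
  )
}

#' @export
print.coding_axes <- function(x, ...) {
  cat(sprintf("coding axes (%s): %d ROIs\n", x$scenario, nrow(x$atlas)))
  planted <- colSums(x$amplitudes > 0)
  cat("  planted ROIs per method:",
      paste(sprintf("%s=%d", names(planted), planted), collapse = ", "), "\n")
  invisible(x)
}

#' Default behavioral response rates
#'
#' Group-mean rates used by [simulate_behavior()]: chance category guessing
#' on invisible trials, rare breakthrough (3.1% CFS, 4.3% CFF), near-ceiling
#' visible accuracy (99.4%) and visible seen reports (96.2%).
#'
#' @return named list of rates.
#' @export
default_behavior_rates <- function() {
  list(invisible_accuracy = 0.5,
       breakthrough = c(CFS = 0.031, CFF = 0.043),
       visible_accuracy = 0.994,
       visible_seen = 0.962)
}

#' Simulate per-trial behavioral records
#'
#' Draws one independent Bernoulli outcome per trial per rate: the category
#' guess (chance-accurate on invisible trials, near-ceiling on visible
#' trials), the breakthrough report on invisible trials, and the "clearly
#' visible" report on visible trials.
#'
#' @param events events table with `method` and `category` columns (one row
#'   per trial).
#' @param rates list as from [default_behavior_rates()].
#' @param seed integer seed or `NULL`.
#' @return `data.frame` with one row per trial: `guess`, `guess_correct`,
#'   `breakthrough` (invisible trials; `FALSE` on visible trials) and `seen`
#'   (visible trials; `NA` otherwise).
#' @export
simulate_behavior <- function(events, rates = default_behavior_rates(),
                              seed = NULL) {
  stopifnot(all(c("method", "category") %in% names(events)))
  allr <- c(rates$invisible_accuracy, rates$breakthrough,
            rates$visible_accuracy, rates$visible_seen)
  if (any(allr < 0 | allr > 1)) {
    stop("behavioral rates must lie in [0, 1]", call. = FALSE)
  }
  method <- match_method(events$method)
  category <- match_category(events$category)
  n <- length(method)
  with_rng(seed, {
    vis <- method == "VIS"
    acc <- ifelse(vis, rates$visible_accuracy, rates$invisible_accuracy)
    correct <- runif(n) < acc
    other <- ifelse(category == "face", "tool", "face")
    guess <- ifelse(correct, category, other)
    bt_rate <- rep(0, n)
    for (m in .invisible_methods) {
      bt_rate[method == m] <- rates$breakthrough[[m]]
    }
    breakthrough <- runif(n) < bt_rate
    seen <- rep(NA, n)
    seen[vis] <- runif(sum(vis)) < rates$visible_seen
    data.frame(guess = guess, guess_correct = correct,
               breakthrough = breakthrough, seen = seen,
               stringsAsFactors = FALSE)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the response peak at `peak`
#' seconds and the undershoot trough near `undershoot` seconds, scaled to a
#' peak height of 1.
#'
#' @param t time in seconds (vector).
#' @param peak response peak time (default 5 s).
#' @param undershoot undershoot peak time (default 15 s).
#' @param undershoot_ratio relative undershoot amplitude (default 1/6).
#' @return numeric vector of HRF values; 0 for `t < 0`.
#' @export
hrf_double_gamma <- function(t, peak = 5, undershoot = 15,
                             undershoot_ratio = 1 / 6) {
  raw <- function(x) {
    v <- dgamma(x, shape = peak + 1, rate = 1) -
      undershoot_ratio * dgamma(x, shape = undershoot + 1, rate = 1)
    v[x < 0] <- 0
    v
  }
  grid <- seq(0, undershoot * 3, by = 0.01)
  raw(t) / max(raw(grid))
}

# BOLD response of one 2-s stimulus, evaluated at times `t` (seconds) after
# run start: a boxcar of `duration` seconds convolved with the HRF.
hrf_regressor <- function(t, onset, duration = 2, dt = 0.1, ...) {
  steps <- seq(0, duration - dt, by = dt)
  resp <- rowSums(vapply(steps,
                         function(s) hrf_double_gamma(t - onset - s, ...),
                         numeric(length(t)))) * dt
  resp
}

ar1_noise <- function(n_time, n_vox, noise_sd, ar1) {
  innov_sd <- noise_sd * sqrt(1 - ar1^2)
  e <- matrix(rnorm(n_time * n_vox, sd = innov_sd), n_time, n_vox)
  if (ar1 != 0) {
    e <- apply(e, 2, function(col) {
      as.numeric(stats::filter(col, ar1, method = "recursive"))
    })
  }
  e
}

#' Simulate one subject's multivoxel dataset
#'
#' Generates trial-level voxel patterns (or TR-resolved time series) for
#' every ROI of an atlas, with category information planted along the coding
#' axes. The trial-mean pattern of a trial with category sign `s` (face +1,
#' tool -1) under method `m` in ROI `r` is
#' `s * a[r, m] * w[r, m] + exemplar offset + color nuisance`; trial mode
#' adds i.i.d. Gaussian noise per trial, whereas timeseries mode convolves
#' the trial means with a double-gamma HRF sampled at the TR and adds AR(1)
#' Gaussian noise. Exemplar offsets are drawn once per subject and reused
#' across runs, so cross-exemplar splits genuinely test generalization
#' beyond exemplar identity. The color nuisance lies along a direction
#' orthogonal to every category axis and vanishes for CFF trials, whose two
#' color slots are physically the same flickering compound.
#'
#' @param schedules list of `trial_schedule` objects, one per run.
#' @param axes a `coding_axes` object.
#' @param noise_sd trial-level noise standard deviation (> 0, default 1).
#' @param mode `"trial"` (patterns) or `"timeseries"` (TR-resolved series).
#' @param seed integer seed or `NULL`.
#' @param exemplar_sd standard deviation of the per-exemplar pattern offsets
#'   (default 0.3).
#' @param color_sd amplitude of the color nuisance component (default 0.3).
#' @param ar1 AR(1) coefficient of the timeseries noise (default 0.3).
#' @param behavior_rates rates passed to [simulate_behavior()].
#' @param subject subject identifier stored in the dataset.
#' @return an object of class `roi_dataset`: list with `events` (one row per
#'   trial across runs, including behavioral columns), `patterns` (trial
#'   mode: named list of trials x voxels matrices per ROI), `series`
#'   (timeseries mode: `series[[roi]][[run]]`, volumes x voxels), `atlas`,
#'   `mode`, `tr_seconds`, `n_volumes`, `subject`.
#' @export
simulate_subject <- function(schedules, axes, noise_sd = 1,
                             mode = c("trial", "timeseries"),
                             seed = NULL, exemplar_sd = 0.3, color_sd = 0.3,
                             ar1 = 0.3,
                             behavior_rates = default_behavior_rates(),
                             subject = 1L) {
  mode <- match.arg(mode)
  stopifnot(noise_sd > 0, length(schedules) >= 1L)
  atlas <- axes$atlas
  if (!identical(names(axes$axes), atlas$roi)) {
    stop("coding axes do not match their atlas", call. = FALSE)
  }
  events <- do.call(rbind, lapply(seq_along(schedules), function(r) {
    ev <- as_events(schedules[[r]])
    cbind(run = r, trial = seq_len(nrow(ev)), ev)
  }))
  rownames(events) <- NULL
  n_trials <- nrow(events)
  s_cat <- ifelse(events$category == "face", 1, -1)
  col_sign <- ifelse(events$method == "CFF", 0,
                     ifelse(events$color == "red", 1, -1))
  method_idx <- match(events$method, .methods)

  with_rng(seed, {
    behavior <- simulate_behavior(events, rates = behavior_rates)
    patterns <- NULL
    series <- NULL
    # Trial-mean pattern matrix for one ROI (n_trials x voxels), noiseless.
    roi_means <- function(i) {
      d <- atlas$n_voxels[i]
      ax <- axes$axes[[i]]
      a <- axes$amplitudes[i, ]
      # Per-exemplar offsets, drawn once per subject, reused across runs.
      ex_off <- array(rnorm(2L * 4L * d, sd = exemplar_sd),
                      dim = c(2L, 4L, d))
      mu <- t(ax$w[, method_idx, drop = FALSE]) * (s_cat * a[method_idx])
      for (ci in 1:2) {
        for (ei in 1:4) {
          rows <- which(events$category == .categories[ci] &
                          events$exemplar == ei)
          if (length(rows)) {
            mu[rows, ] <- mu[rows, ] +
              rep(ex_off[ci, ei, ], each = length(rows))
          }
        }
      }
      mu + (col_sign * color_sd) %o% ax$color_dir
    }
    if (mode == "trial") {
      patterns <- lapply(seq_len(nrow(atlas)), function(i) {
        d <- atlas$n_voxels[i]
        roi_means(i) + matrix(rnorm(n_trials * d, sd = noise_sd),
                              n_trials, d)
      })
      names(patterns) <- atlas$roi
    } else {
      tr <- schedules[[1L]]$tr_seconds
      nv <- schedules[[1L]]$n_volumes
      times <- (seq_len(nv) - 1L) * tr
      H <- lapply(schedules, function(sch) {
        vapply(sch$trials$onset,
               function(on) hrf_regressor(times, on,
                                          duration = sch$trials$duration[1L]),
               numeric(nv))
      })
      series <- lapply(seq_len(nrow(atlas)), function(i) {
        mu <- roi_means(i)
        lapply(seq_along(schedules), function(r) {
          rows <- events$run == r
          H[[r]] %*% mu[rows, , drop = FALSE] +
            ar1_noise(nv, atlas$n_voxels[i], noise_sd, ar1)
        })
      })
      names(series) <- atlas$roi
    }
    structure(
      list(events = cbind(events, behavior), patterns = patterns,
           series = series, atlas = atlas, mode = mode,
           tr_seconds = schedules[[1L]]$tr_seconds,
           n_volumes = schedules[[1L]]$n_volumes,
           subject = subject),
      class = "roi_dataset"
    )
  })
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("roi dataset: subject %s, %d trials over %d runs, %d ROIs (%s mode)\n",
              x$subject, nrow(x$events), length(unique(x$events$run)),
              nrow(x$atlas), x$mode))
  invisible(x)
}

#' Simulate a full cohort
#'
#' Applies [simulate_subject()] to every subject of a [design_cohort()],
#' each with its own derived random stream.
#'
#' @param design a `cohort_design`.
#' @param axes a `coding_axes` object (shared structure; draws differ per
#'   subject only through the noise, exemplar offsets and behavior).
#' @param seed master seed or `NULL`.
#' @param ... further arguments to [simulate_subject()].
#' @return object of class `cohort_dataset`: list with `subjects` (list of
#'   `roi_dataset`), `atlas`, `axes`, `design`.
#' @export
simulate_cohort <- function(design, axes, seed = NULL, ...) {
  stopifnot(inherits(design, "cohort_design"))
  seeds <- derive_seeds(seed, design$n_subjects)
  subjects <- lapply(seq_len(design$n_subjects), function(s) {
    simulate_subject(design$schedules[[s]], axes,
                     seed = seed_or_null(seeds[s]), subject = s, ...)
  })
  structure(
    list(subjects = subjects, atlas = axes$atlas, axes = axes,
         design = design),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort dataset: %d subjects, %d ROIs, scenario %s\n",
              length(x$subjects), nrow(x$atlas), x$axes$scenario))
  invisible(x)
}
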