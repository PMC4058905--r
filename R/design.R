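#' Trial composition of one experimental run
#'
#' Builds the fixed 48-trial composition of a run: 8 stimuli (4 face and 4
#' tool exemplars) x 2 color slots x 3 presentation methods. For the visible
#' and CFS methods the two slots are the red- and green-outline versions of
#' each stimulus; during CFF both scheduled presentations are the flickering
#' red/green compound but are tracked as distinct color slots for
#' bookkeeping, so every (method, category, exemplar, color) cell occurs
#' exactly once.
#'
#' @return a `data.frame` with 48 rows and columns `method`, `category`,
#'   `exemplar` (1..4 within category) and `color`.
#' @export
#' @examples
#' comp <- run_composition()
#' nrow(comp) # 48
run_composition <- function() {
  comp <- expand.grid(
    color = .colors,
    exemplar = 1:4,
    category = .categories,
    method = .methods,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  comp <- comp[, c("method", "category", "exemplar", "color")]
  rownames(comp) <- NULL
  comp
}

#' Score a category sequence for transition predictability
#'
#' Measures how far the lag-1 and lag-2 category-repetition probabilities of
#' a trial sequence deviate from 0.5. A perfectly counterbalanced order makes
#' a face equally likely to follow a face or a tool (lag 1), and equally
#' likely to recur two trials later (lag 2), so both deviations are 0.
#'
#' @param categories character vector of category labels, length >= 3, in
#'   presentation order.
#' @return an object of class `order_score`: a list with `lag1_dev`,
#'   `lag2_dev`, `total` (their sum) and `degenerate` (`TRUE` when only one
#'   category is present, in which case both deviations are 0.5).
#' @export
#' @examples
#' score_order(c("face", "tool", "tool", "face"))$lag1_dev # |1/3 - 0.5|
score_order <- function(categories) {
  categories <- as.character(categories)
  n <- length(categories)
  if (n < 3L) {
    stop("`categories` must contain at least 3 trials", call. = FALSE)
  }
  degenerate <- length(unique(categories)) < 2L
  lag_dev <- function(k) {
    abs(mean(categories[seq_len(n - k)] == categories[seq_len(n - k) + k]) - 0.5)
  }
  out <- list(
    lag1_dev = lag_dev(1L),
    lag2_dev = lag_dev(2L),
    degenerate = degenerate
  )
  out$total <- out$lag1_dev + out$lag2_dev
  class(out) <- "order_score"
  out
}

#' @export
print.order_score <- function(x, ...) {
  cat(sprintf("order score: lag1 dev %.4f + lag2 dev %.4f = %.4f%s\n",
              x$lag1_dev, x$lag2_dev, x$total,
              if (x$degenerate) " (degenerate: single category)" else ""))
  invisible(x)
}

#' Select a transition-minimizing run order
#'
#' Draws `n_candidates` uniform random shuffles of the run's category
#' sequence, scores each with [score_order()] and keeps the first candidate
#' attaining the minimum total deviation. The optimization operates at the
#' category level only; exemplar, color and method assignments are then
#' filled in by an independent uniform shuffle of the face trials into the
#' face slots and of the tool trials into the tool slots.
#'
#' @param composition run composition as from [run_composition()].
#' @param n_candidates number of candidate shuffles to evaluate (>= 1).
#'   Candidates are generated sequentially, so for a fixed seed the best
#'   score is non-increasing in `n_candidates`.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return the reordered composition `data.frame`, with the winning
#'   `order_score` attached as attribute `"score"`.
#' @export
optimize_order <- function(composition = run_composition(),
                           n_candidates = 10000L,
                           seed = NULL) {
  stopifnot(is.data.frame(composition),
            all(c("method", "category", "exemplar", "color") %in%
                  names(composition)))
  if (n_candidates < 1L) {
    stop("`n_candidates` must be >= 1", call. = FALSE)
  }
  cats <- composition$category
  if (length(cats) < 3L) {
    stop("run composition must contain at least 3 trials", call. = FALSE)
  }
  with_rng(seed, {
    best <- NULL
    best_score <- Inf
    for (i in seq_len(n_candidates)) {
      cand <- sample(cats)
      sc <- score_order(cand)
      if (sc$total < best_score) {
        best <- cand
        best_score <- sc$total
        best_sc <- sc
      }
    }
    # Slot the concrete trials into the winning category sequence.
    order_idx <- integer(length(cats))
    for (k in unique(cats)) {
      order_idx[best == k] <- sample(which(composition$category == k))
    }
    out <- composition[order_idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "score") <- best_sc
    out
  })
}

#' Lay out trial timing for one run
#'
#' Assigns onsets to an ordered trial list using the slow event-related
#' timing of the experiment: every trial lasts 2 s and is followed by a blank
#' inter-stimulus interval drawn independently and with equal probability
#' from {6, 8} s. The run is padded with rest to a fixed number of volumes.
#'
#' @param order ordered trial composition (48 rows by default).
#' @param seed integer seed for the ISI draws, or `NULL`.
#' @param tr_seconds repetition time in seconds (default 2).
#' @param n_volumes number of volumes per run (default 242, i.e. 484 s).
#' @param lead_in_seconds rest before the first trial onset (default 4 s;
#'   trailing rest fills the remainder of the run).
#' @param trial_seconds stimulus duration (default 2 s).
#' @param isi_choices candidate ISIs in seconds (default `c(6, 8)`).
#' @return an object of class `trial_schedule`: a list with `trials` (the
#'   composition plus `onset`, `duration`, `isi` columns), `tr_seconds`,
#'   `n_volumes` and `duration_seconds`.
#' @export
build_schedule <- function(order,
                           seed = NULL,
                           tr_seconds = 2,
                           n_volumes = 242L,
                           lead_in_seconds = 4,
                           trial_seconds = 2,
                           isi_choices = c(6, 8)) {
  stopifnot(is.data.frame(order), nrow(order) >= 1L)
  n <- nrow(order)
  # length(isi_choices) == 1 must not trigger sample()'s 1:n behavior
  isis <- with_rng(seed, isi_choices[sample.int(length(isi_choices), n,
                                                replace = TRUE)])
  onsets <- lead_in_seconds + c(0, cumsum(trial_seconds + isis[-n]))
  duration <- n_volumes * tr_seconds
  if (onsets[n] + trial_seconds > duration) {
    stop("trials do not fit in ", n_volumes, " volumes of ", tr_seconds,
         " s", call. = FALSE)
  }
  trials <- order
  trials$onset <- onsets
  trials$duration <- rep(trial_seconds, n)
  trials$isi <- isis
  rownames(trials) <- NULL
  structure(
    list(trials = trials, tr_seconds = tr_seconds,
         n_volumes = as.integer(n_volumes),
         duration_seconds = duration),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("trial schedule: %d trials, %d volumes x %g s TR = %g s\n",
              nrow(x$trials), x$n_volumes, x$tr_seconds, x$duration_seconds))
  invisible(x)
}

#' Events table of a schedule
#'
#' Flattens a `trial_schedule` into a BIDS-events-like table.
#'
#' @param schedule a `trial_schedule`.
#' @return `data.frame` with columns `onset`, `duration`, `method`,
#'   `category`, `exemplar`, `color`.
#' @export
as_events <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  schedule$trials[, c("onset", "duration", "method", "category",
                      "exemplar", "color")]
}

#' Generate the experimental design for a full cohort
#'
#' Produces one transition-minimized, timed run order per (subject, run),
#' each from its own derived random stream, mirroring per-subject order
#' generation.
#'
#' @param n_subjects number of subjects (default 17).
#' @param n_runs runs per subject (default 8).
#' @param n_candidates candidate shuffles per run order (default 10000; the
#'   desk-scale stand-in for an exhaustive search).
#' @param seed master seed; every run order and ISI draw derives from it.
#' @param ... further arguments passed to [build_schedule()].
#' @return an object of class `cohort_design`: list with `schedules`
#'   (`schedules[[subject]][[run]]`), `manifest` (`data.frame` of subject and
#'   run ids) and the generating parameters.
#' @export
design_cohort <- function(n_subjects = 17L, n_runs = 8L,
                          n_candidates = 10000L, seed = NULL, ...) {
  stopifnot(n_subjects >= 1L, n_runs >= 1L)
  seeds <- derive_seeds(seed, n_subjects * n_runs * 2L)
  comp <- run_composition()
  schedules <- vector("list", n_subjects)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    schedules[[s]] <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      ord <- optimize_order(comp, n_candidates = n_candidates,
                            seed = seed_or_null(seeds[k + 1L]))
      schedules[[s]][[r]] <- build_schedule(ord,
                                            seed = seed_or_null(seeds[k + 2L]),
                                            ...)
      k <- k + 2L
    }
  }
  manifest <- expand.grid(run = seq_len(n_runs), subject = seq_len(n_subjects),
                          KEEP.OUT.ATTRS = FALSE)[, c("subject", "run")]
  rownames(manifest) <- NULL
  structure(
    list(schedules = schedules, manifest = manifest,
         n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         n_candidates = n_candidates, seed = seed),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort design: %d subjects x %d runs = %d runs\n",
              x$n_subjects, x$n_runs, nrow(x$manifest)))
  invisible(x)
}
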