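#' Flag breakthrough trials as unusable
#'
#' Any CFS or CFF trial on which the subject reported breakthrough (i.e.
#' saw anything other than the suppressing pattern or the fused field) is
#' eliminated from further analysis. Visible trials are unaffected: there the
#' second button box records the required "clearly visible" report, not a
#' failure of suppression.
#'
#' @param events events table with `method` and `breakthrough` columns.
#' @return logical vector, `TRUE` where the trial remains usable.
#' @export
flag_breakthrough <- function(events) {
  stopifnot(all(c("method", "breakthrough") %in% names(events)))
  method <- match_method(events$method)
  !(method %in% .invisible_methods & events$breakthrough %in% TRUE)
}

#' Exact upper-tail binomial probability
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`, computed by summing the
#' probability mass function.
#'
#' @param k_successes observed success count (0 <= k <= n).
#' @param n_trials number of trials.
#' @param p0 null success probability in (0, 1) (default 0.5).
#' @return the one-sided upper-tail probability.
#' @export
#' @examples
#' binomial_tail(12, 16) # 2517/65536
binomial_tail <- function(k_successes, n_trials, p0 = 0.5) {
  if (n_trials < 1 || k_successes < 0 || k_successes > n_trials) {
    stop("need 0 <= k_successes <= n_trials with n_trials >= 1",
         call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) {
    stop("`p0` must lie strictly between 0 and 1", call. = FALSE)
  }
  i <- seq(from = k_successes, to = n_trials)
  sum(choose(n_trials, i) * p0^i * (1 - p0)^(n_trials - i))
}

#' Exclude runs with above-chance guessing of invisible categories
#'
#' A (run, method) block of invisible trials is dropped when the subject
#' guessed stimulus category with accuracy strictly greater than the
#' threshold (75%, chosen so that the exact cumulative binomial tail over a
#' full block of 16 trials falls below 0.05). The binomial tail probability
#' is computed and reported alongside, but the accuracy threshold is the
#' operative rule. Exclusion is per method ("for that trial type"); visible
#' blocks are always retained, regardless of subject response.
#'
#' @param events events table with `run`, `method`, `category` and `guess`
#'   columns (one row per trial).
#' @param threshold accuracy cutoff (default 0.75; strict inequality).
#' @param pool_invisible pool CFS and CFF guesses within a run before
#'   testing (default `FALSE`: each invisible method is tested separately).
#' @return `data.frame` with one row per (run, method): `n`, `k` (correct
#'   guesses), `accuracy`, `binom_p`, `retained`, `reason`.
#' @export
binomial_run_exclusion <- function(events, threshold = 0.75,
                                   pool_invisible = FALSE) {
  stopifnot(all(c("run", "method", "category", "guess") %in% names(events)))
  method <- match_method(events$method)
  correct <- match_category(events$guess) == match_category(events$category)
  out <- expand.grid(run = sort(unique(events$run)), method = .methods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$k <- NA_integer_
  out$accuracy <- NA_real_; out$binom_p <- NA_real_
  out$retained <- TRUE
  out$reason <- "ok"
  for (i in seq_len(nrow(out))) {
    m <- out$method[i]
    sel <- if (pool_invisible && m %in% .invisible_methods) {
      events$run == out$run[i] & method %in% .invisible_methods
    } else {
      events$run == out$run[i] & method == m
    }
    out$n[i] <- sum(sel)
    out$k[i] <- sum(correct[sel])
    if (out$n[i] > 0L) {
      out$accuracy[i] <- out$k[i] / out$n[i]
      out$binom_p[i] <- binomial_tail(out$k[i], out$n[i])
    }
    if (m %in% .invisible_methods && isTRUE(out$accuracy[i] > threshold)) {
      out$retained[i] <- FALSE
      out$reason[i] <- "binomial_excluded"
    }
  }
  out
}

#' Minimum-exemplar retention rule
#'
#' After trial-level exclusions, a run is thrown out for a presentation
#' method when it no longer has at least two usable exemplars per category;
#' operationally, when any category x exemplar-set cell of that (run,
#' method) block is empty, so the averaged cell pattern that the
#' cross-exemplar classification needs cannot be formed.
#'
#' @param events events table with `run`, `method`, `category`, `exemplar`.
#' @param usable logical vector of per-trial usability (e.g. from
#'   [flag_breakthrough()]).
#' @param split an exemplar split as from [default_exemplar_split()].
#' @return `data.frame` with one row per (run, method): `retained`,
#'   `reason`.
#' @export
min_exemplar_rule <- function(events, usable,
                              split = default_exemplar_split()) {
  stopifnot(length(usable) == nrow(events))
  out <- expand.grid(run = sort(unique(events$run)), method = .methods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$retained <- TRUE
  out$reason <- "ok"
  for (i in seq_len(nrow(out))) {
    sel <- events$run == out$run[i] & events$method == out$method[i]
    for (cat in .categories) {
      for (set in split) {
        cell <- sel & usable & events$category == cat &
          events$exemplar %in% set
        if (!any(cell)) {
          out$retained[i] <- FALSE
          out$reason[i] <- "insufficient_exemplars"
        }
      }
    }
  }
  out
}

#' Apply all behavioral exclusion rules to a dataset
#'
#' Runs, in order: breakthrough trial removal, the above-chance guessing run
#' exclusion, and the minimum-exemplar rule. A trial in a dropped (run,
#' method) block is unusable.
#'
#' @param dataset an `roi_dataset` (or any list with an `events` table).
#' @param split exemplar split used by the minimum-exemplar rule.
#' @param threshold guessing accuracy cutoff (default 0.75).
#' @param pool_invisible see [binomial_run_exclusion()].
#' @return object of class `usability_mask`: list with `trial_usable`
#'   (logical per trial) and `retention` (per (run, method): `retained`,
#'   `reason`, guessing diagnostics).
#' @export
apply_qc <- function(dataset, split = default_exemplar_split(),
                     threshold = 0.75, pool_invisible = FALSE) {
  events <- dataset$events
  usable <- flag_breakthrough(events)
  guess <- binomial_run_exclusion(events, threshold = threshold,
                                  pool_invisible = pool_invisible)
  # Trials of guessing-excluded blocks become unusable before the
  # minimum-exemplar check.
  key <- paste(events$run, events$method)
  dropped <- paste(guess$run, guess$method)[!guess$retained]
  usable_after_guess <- usable & !(key %in% dropped)
  exem <- min_exemplar_rule(events, usable_after_guess, split = split)
  retention <- guess
  both <- !exem$retained & retention$retained
  retention$retained <- retention$retained & exem$retained
  retention$reason[both] <- exem$reason[both]
  trial_usable <- usable_after_guess &
    !(key %in% paste(retention$run, retention$method)[!retention$retained])
  structure(list(trial_usable = trial_usable, retention = retention),
            class = "usability_mask")
}

#' @export
print.usability_mask <- function(x, ...) {
  cat(sprintf("usability mask: %d/%d trials usable; %d/%d (run, method) blocks retained\n",
              sum(x$trial_usable), length(x$trial_usable),
              sum(x$retention$retained), nrow(x$retention)))
  invisible(x)
}
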