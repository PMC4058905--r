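#' One-sample one-sided t-test against chance
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with the upper-tail Student
#' probability on `n - 1` degrees of freedom.
#'
#' @param values numeric vector (NAs dropped).
#' @param mu0 null mean (default 0, chance-level d-prime).
#' @return list with `n`, `mean`, `df`, `t`, `p` (`t` and `p` are `NA`, with
#'   a warning, for n < 2 or zero variance).
#' @export
#' @examples
#' one_sample_t_onesided(c(1, 2, 3)) # t = sqrt(12), p ~ 0.0371
one_sample_t_onesided <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    warning("fewer than 2 observations; t undefined", call. = FALSE)
    return(list(n = n, mean = if (n) mean(values) else NA_real_,
                df = NA_integer_, t = NA_real_, p = NA_real_))
  }
  s <- sd(values)
  if (s == 0) {
    warning("zero variance; t undefined", call. = FALSE)
    return(list(n = n, mean = mean(values), df = n - 1L, t = NA_real_,
                p = NA_real_))
  }
  t <- (mean(values) - mu0) / (s / sqrt(n))
  list(n = n, mean = mean(values), df = n - 1L, t = t,
       p = pt(t, df = n - 1L, lower.tail = FALSE))
}

#' Paired one-sided t-test
#'
#' One-sample one-sided t-test on the paired differences `a - b`. With
#' `direction = "auto"` (the default) the test is one-sided in the direction
#' of the observed mean difference.
#'
#' @param a,b paired numeric vectors of equal length (pairs with any NA are
#'   dropped).
#' @param direction `"auto"`, `"greater"` (a > b) or `"less"` (a < b).
#' @return list with `n`, `mean_diff`, `df`, `t`, `p`, `direction`.
#' @export
paired_t_onesided <- function(a, b, direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) {
    warning("fewer than 2 complete pairs; t undefined", call. = FALSE)
    return(list(n = n, mean_diff = if (n) mean(d) else NA_real_,
                df = NA_integer_, t = NA_real_, p = NA_real_,
                direction = direction))
  }
  if (sd(d) == 0) {
    warning("zero variance of paired differences; t undefined",
            call. = FALSE)
    return(list(n = n, mean_diff = mean(d), df = n - 1L, t = NA_real_,
                p = NA_real_, direction = direction))
  }
  if (direction == "auto") {
    direction <- if (mean(d) >= 0) "greater" else "less"
  }
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- if (direction == "greater") {
    pt(t, df = n - 1L, lower.tail = FALSE)
  } else {
    pt(t, df = n - 1L, lower.tail = TRUE)
  }
  list(n = n, mean_diff = mean(d), df = n - 1L, t = t, p = p,
       direction = direction)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject all hypotheses up to the largest `i` with
#' `p_(i) <= i * q / m`. Adjusted p-values are
#' `min_{j >= i} m * p_(j) / j`, capped at 1. NAs are excluded from `m` and
#' propagate.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical) and `p_adj`.
#' @export
#' @examples
#' fdr_bh(c(0.004, 0.03, 0.04))$reject # all TRUE
fdr_bh <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n_all <- length(pvalues)
  reject <- rep(NA, n_all)
  p_adj <- rep(NA_real_, n_all)
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m > 0L) {
    p <- pvalues[ok]
    o <- order(p)
    ranked <- p[o]
    adj_ranked <- rev(cummin(rev(m * ranked / seq_len(m))))
    adj_ranked <- pmin(adj_ranked, 1)
    passes <- ranked <= seq_len(m) * q / m
    k <- if (any(passes)) max(which(passes)) else 0L
    rej_ranked <- seq_len(m) <= k
    p_adj[ok[o]] <- adj_ranked
    reject[ok[o]] <- rej_ranked
  }
  list(reject = reject, p_adj = p_adj)
}

#' Group-level table for one decoding regime
#'
#' Aggregates subject-level d-prime values per ROI: one-sided t against
#' chance (0), then Benjamini-Hochberg FDR across the ROIs of this analysis
#' family.
#'
#' @param results decoding results as from [decode_cohort()].
#' @param regime regime label to summarize.
#' @param rois ROI family (default: all ROIs present for the regime).
#' @param q FDR level (default 0.05).
#' @return `data.frame` with one row per ROI: `roi`, `regime`, `n`,
#'   `mean_dprime`, `t`, `p`, `p_adj`, `significant`.
#' @export
group_table <- function(results, regime, rois = NULL, q = 0.05) {
  sub <- results[results$regime == regime, , drop = FALSE]
  if (is.null(rois)) rois <- unique(sub$roi)
  rows <- lapply(rois, function(r) {
    tt <- suppressWarnings(
      one_sample_t_onesided(sub$dprime[sub$roi == r])
    )
    data.frame(roi = r, regime = regime, n = tt$n,
               mean_dprime = tt$mean, t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q = q)
  out$p_adj <- fdr$p_adj
  out$significant <- fdr$reject %in% TRUE
  rownames(out) <- NULL
  out
}

#' Gate downstream analyses on visible decoding
#'
#' Returns the ROIs whose visible within-method decoding survived FDR
#' correction; all invisible and cross-method analyses are then restricted
#' to this subset (and each re-corrected within its own family).
#'
#' @param visible_table a [group_table()] for the `within:VIS` regime over
#'   the full ROI set.
#' @return character vector of gated ROI names (possibly empty, with a
#'   warning).
#' @export
gate_rois <- function(visible_table) {
  gate <- visible_table$roi[visible_table$significant %in% TRUE]
  if (length(gate) == 0L) {
    warning("no ROI survived visible-decoding FDR correction; ",
            "downstream analyses will be skipped", call. = FALSE)
  }
  gate
}

#' Paired regime contrasts per ROI
#'
#' One-sided paired t-tests between two regimes' subject-level d-prime
#' values, run in the ROIs where significant classification occurred for at
#' least one of the two regimes; both raw and BH-adjusted p-values are
#' reported.
#'
#' @param results decoding results.
#' @param regime_a,regime_b contrasted regimes.
#' @param rois ROI family for the contrast.
#' @param q FDR level for the adjusted p-values.
#' @param direction passed to [paired_t_onesided()] (default `"auto"`: the
#'   direction of the observed mean difference).
#' @return `data.frame` per ROI: `roi`, `contrast`, `n`, `mean_diff`,
#'   `direction`, `t`, `p`, `p_adj`, `significant`.
#' @export
paired_contrasts <- function(results, regime_a, regime_b, rois, q = 0.05,
                             direction = "auto") {
  rows <- lapply(rois, function(r) {
    a <- results[results$regime == regime_a & results$roi == r, ]
    b <- results[results$regime == regime_b & results$roi == r, ]
    ab <- merge(a[, c("subject", "dprime")], b[, c("subject", "dprime")],
                by = "subject", suffixes = c("_a", "_b"))
    tt <- suppressWarnings(
      paired_t_onesided(ab$dprime_a, ab$dprime_b, direction = direction)
    )
    data.frame(roi = r, contrast = paste(regime_a, "vs", regime_b),
               n = tt$n, mean_diff = tt$mean_diff,
               direction = tt$direction, t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(out)
  }
  fdr <- fdr_bh(out$p, q = q)
  out$p_adj <- fdr$p_adj
  out$significant <- fdr$reject %in% TRUE
  rownames(out) <- NULL
  out
}

#' Run the full simulated decoding analysis
#'
#' End-to-end orchestration on synthetic data: cohort design, coding-axes
#' sampling, multivoxel simulation, behavioral QC, visible within-method
#' decoding over all ROIs, FDR gating, invisible within-method and
#' cross-method decoding restricted to the gate, and group tables with
#' paired method contrasts. Deterministic given `seed`.
#'
#' @param n_subjects,n_runs cohort size (defaults 17 and 8).
#' @param scenario coding-axes scenario (see [sample_coding_axes()]).
#' @param seed master seed.
#' @param atlas ROI atlas.
#' @param n_candidates candidate run orders per run (default 200 here:
#'   order quality does not affect decoding of trial-mode data, so the
#'   pipeline default trades search depth for speed; use
#'   [optimize_order()]'s own default for design work).
#' @param noise_sd,mode,... forwarded to [simulate_subject()] via
#'   [simulate_cohort()].
#' @param split exemplar split.
#' @param q FDR level (default 0.05).
#' @param axes optionally a pre-built `coding_axes` (overrides `scenario`).
#' @param regimes regimes to analyze (default [all_regimes()]).
#' @param correction,cost,cross_exemplar decoding options.
#' @return object of class `invisidec_analysis`: list with `gate`, `within`
#'   (named list of group tables), `cross` (named list), `contrasts`,
#'   `results` (subject-level decoding rows), `qc` (per-subject retention
#'   tables), `config`.
#' @export
run_full_analysis <- function(n_subjects = 17L, n_runs = 8L,
                              scenario = "paper_like", seed = NULL,
                              atlas = roi_atlas(), n_candidates = 200L,
                              noise_sd = 1, mode = "trial",
                              split = default_exemplar_split(),
                              q = 0.05, axes = NULL,
                              regimes = all_regimes(),
                              correction = "loglinear", cost = 1,
                              cross_exemplar = TRUE, ...) {
  seeds <- derive_seeds(seed, 3L)
  design <- design_cohort(n_subjects, n_runs, n_candidates = n_candidates,
                          seed = seed_or_null(seeds[1L]))
  if (is.null(axes)) {
    axes <- sample_coding_axes(atlas, scenario = scenario,
                               seed = seed_or_null(seeds[2L]))
  }
  cohort <- simulate_cohort(design, axes, seed = seed_or_null(seeds[3L]),
                            noise_sd = noise_sd, mode = mode, ...)
  masks <- lapply(cohort$subjects, apply_qc, split = split)

  vis_results <- decode_cohort(cohort, masks = masks,
                               regimes = "within:VIS", split = split,
                               correction = correction, cost = cost)
  table_vis <- group_table(vis_results, "within:VIS", rois = atlas$roi,
                           q = q)
  gate <- gate_rois(table_vis)

  results <- vis_results
  within <- list("within:VIS" = table_vis)
  cross <- list()
  contrasts <- NULL
  if (length(gate) > 0L) {
    other <- setdiff(regimes, "within:VIS")
    if (length(other) > 0L) {
      gated <- decode_cohort(cohort, masks = masks, regimes = other,
                             rois = gate, split = split,
                             correction = correction, cost = cost,
                             cross_exemplar = cross_exemplar)
      results <- rbind(results, gated)
    }
    for (rg in setdiff(regimes, "within:VIS")) {
      tab <- group_table(results, rg, rois = gate, q = q)
      if (grepl("^within:", rg)) within[[rg]] <- tab else cross[[rg]] <- tab
    }
    # Paired within-method contrasts where significant classification
    # occurred for at least one of the two regimes.
    pairs <- list(c("within:VIS", "within:CFF"),
                  c("within:VIS", "within:CFS"),
                  c("within:CFF", "within:CFS"))
    contrasts <- do.call(rbind, lapply(pairs, function(pr) {
      tabs <- lapply(pr, function(rg) {
        if (rg %in% names(within)) within[[rg]] else NULL
      })
      sig_rois <- unique(unlist(lapply(tabs, function(tb) {
        if (is.null(tb)) character() else tb$roi[tb$significant]
      })))
      if (length(sig_rois) == 0L) {
        return(NULL)
      }
      paired_contrasts(results, pr[1L], pr[2L], rois = sig_rois, q = q)
    }))
  }
  qc_tables <- lapply(masks, function(m) m$retention)
  structure(
    list(gate = gate, within = within, cross = cross,
         contrasts = contrasts, results = results, qc = qc_tables,
         axes = axes,
         config = list(n_subjects = n_subjects, n_runs = n_runs,
                       scenario = axes$scenario, seed = seed,
                       noise_sd = noise_sd, mode = mode, q = q,
                       correction = correction, cost = cost,
                       cross_exemplar = cross_exemplar,
                       n_candidates = n_candidates)),
    class = "invisidec_analysis"
  )
}

#' @export
print.invisidec_analysis <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf("invisidec analysis: %d subjects, %d runs, scenario %s\n",
              cfg$n_subjects, cfg$n_runs, cfg$scenario))
  cat(sprintf("visible gate: %d ROI(s): %s\n", length(x$gate),
              paste(x$gate, collapse = ", ")))
  for (nm in names(x$within)) {
    tb <- x$within[[nm]]
    sig <- tb$roi[tb$significant]
    cat(sprintf("%s significant: %s\n", nm,
                if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
  }
  for (nm in names(x$cross)) {
    tb <- x$cross[[nm]]
    sig <- tb$roi[tb$significant]
    cat(sprintf("%s significant: %s\n", nm,
                if (length(sig)) paste(sig, collapse = ", ") else "(none)"))
  }
  invisible(x)
}
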