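#' Exemplar split for cross-exemplar classification
#'
#' Partitions the four exemplar ids of each category into two disjoint sets,
#' so that classifier training and testing never share an individual
#' exemplar. The default is the deterministic split {1, 2} vs {3, 4}
#' (applied within each category, hence 2 faces + 2 tools per set); pass a
#' seed for a random split.
#'
#' @param seed `NULL` for the deterministic default, or an integer seed to
#'   draw a random balanced split.
#' @return list with integer vectors `set_A` and `set_B`.
#' @export
default_exemplar_split <- function(seed = NULL) {
  if (is.null(seed)) {
    return(list(set_A = c(1L, 2L), set_B = c(3L, 4L)))
  }
  with_rng(seed, {
    a <- sort(sample(1:4, 2L))
    list(set_A = a, set_B = setdiff(1:4, a))
  })
}

#' Extract the trial response pattern from a voxel time series
#'
#' Averages the volumes acquired 4 s and 6 s after stimulus onset (the
#' second and third TR following onset at TR = 2 s), element-wise per voxel.
#'
#' @param series volumes x voxels matrix for one run.
#' @param onset trial onset in seconds from the first volume.
#' @param tr repetition time in seconds (default 2).
#' @param offsets TR offsets after onset to average (default `c(2, 3)`).
#' @return voxel vector, or a vector of `NA` when the trial lies too close
#'   to the run end for the required volumes to exist (callers flag such
#'   trials unusable).
#' @export
extract_trial_pattern <- function(series, onset, tr = 2, offsets = c(2, 3)) {
  series <- as.matrix(series)
  idx <- floor((onset + offsets * tr) / tr) + 1L  # volumes are 0-based
  if (any(idx < 1L) || any(idx > nrow(series))) {
    return(rep(NA_real_, ncol(series)))
  }
  colMeans(series[idx, , drop = FALSE])
}

#' Average trial patterns within cells
#'
#' Unweighted mean of the rows of a trial-pattern matrix within each level
#' of a grouping vector.
#'
#' @param patterns trials x voxels matrix.
#' @param group grouping vector of length `nrow(patterns)`.
#' @return matrix with one row per group level (rownames = levels).
#' @export
average_patterns <- function(patterns, group) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) == 0L) {
    stop("cannot average an empty cell of trial patterns", call. = FALSE)
  }
  group <- as.character(group)
  sums <- rowsum(patterns, group)
  counts <- as.vector(table(group)[rownames(sums)])
  sums / counts
}

# Trial-level pattern matrices per ROI, extracting from the time series
# when necessary. Returns list(patterns = list per ROI, usable = logical
# per-trial extraction validity).
trial_patterns <- function(dataset) {
  if (dataset$mode == "trial") {
    ok <- rep(TRUE, nrow(dataset$events))
    return(list(patterns = dataset$patterns, usable = ok))
  }
  ev <- dataset$events
  pats <- lapply(dataset$series, function(runs) {
    t(vapply(seq_len(nrow(ev)), function(i) {
      extract_trial_pattern(runs[[ev$run[i]]], ev$onset[i],
                            tr = dataset$tr_seconds)
    }, numeric(ncol(runs[[1L]]))))
  })
  usable <- !is.na(pats[[1L]][, 1L])
  list(patterns = pats, usable = usable)
}

# Cell index (run x method x category x exemplar-set) over usable trials.
# Returns a data.frame keyed by cell with a list-column of trial rows.
cell_index <- function(events, usable, split) {
  cells <- expand.grid(run = sort(unique(events$run)), method = .methods,
                       category = .categories,
                       set = names(split),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    which(usable &
            events$run == cells$run[i] &
            events$method == cells$method[i] &
            events$category == cells$category[i] &
            events$exemplar %in% split[[cells$set[i]]])
  })
  keep <- lengths(rows) > 0L
  cells <- cells[keep, , drop = FALSE]
  cells$trials <- rows[keep]
  rownames(cells) <- NULL
  cells
}

# Averaged cell patterns for one ROI: matrix with one row per cell_index row.
cell_patterns_roi <- function(pattern_mat, cells) {
  t(vapply(cells$trials, function(rows) {
    colMeans(pattern_mat[rows, , drop = FALSE])
  }, numeric(ncol(pattern_mat))))
}

parse_regime <- function(regime) {
  if (grepl("^within:", regime)) {
    m <- match_method(sub("^within:", "", regime))
    list(type = "within", train = m, test = m, label = paste0("within:", m))
  } else if (grepl("^cross:", regime)) {
    mm <- strsplit(sub("^cross:", "", regime), "-", fixed = TRUE)[[1L]]
    if (length(mm) != 2L) {
      stop("cross regime must be 'cross:TRAIN-TEST'", call. = FALSE)
    }
    mm <- match_method(mm)
    if (mm[1L] == mm[2L]) {
      stop("cross-method regime requires two distinct methods",
           call. = FALSE)
    }
    list(type = "cross", train = mm[1L], test = mm[2L],
         label = paste0("cross:", mm[1L], "-", mm[2L]))
  } else {
    stop("unknown regime '", regime,
         "' (expected 'within:M' or 'cross:M1-M2')", call. = FALSE)
  }
}

#' All decoding regimes
#'
#' The three within-method regimes plus all six ordered cross-method
#' train/test pairs.
#'
#' @return character vector of regime labels.
#' @export
all_regimes <- function() {
  cross <- expand.grid(train = .methods, test = .methods,
                       stringsAsFactors = FALSE)
  cross <- cross[cross$train != cross$test, ]
  c(paste0("within:", .methods),
    paste0("cross:", cross$train, "-", cross$test))
}

#' Build the leave-one-run-out cross-exemplar fold plan within one method
#'
#' For each retained run `r` and each of the two exemplar-set directions
#' (train set A / test set B, and the swap), the classifier trains on the
#' training set's cell patterns from all retained runs except `r` and tests
#' on the other set's cells from run `r`: `2 * n_runs` folds. No exemplar id
#' and no run ever appears on both sides of a fold.
#'
#' @param retained_runs integer vector of runs retained for the method.
#' @param method presentation method.
#' @param split exemplar split (names give the two set labels).
#' @return a `fold_plan` data.frame (columns `test_run`, `train_set`,
#'   `test_set`, `train_method`, `test_method`, `regime`) with the retained
#'   training runs as attribute `train_runs`; empty (0 rows, with a warning)
#'   when fewer than 2 runs are retained.
#' @export
make_folds_within <- function(retained_runs, method,
                              split = default_exemplar_split()) {
  method <- match_method(method)
  sets <- names(split)
  if (length(retained_runs) < 2L) {
    warning("fewer than 2 retained runs for method ", method,
            "; subject excluded for this regime", call. = FALSE)
    plan <- data.frame(test_run = integer(), train_set = character(),
                       test_set = character(), train_method = character(),
                       test_method = character(), regime = character(),
                       stringsAsFactors = FALSE)
  } else {
    plan <- expand.grid(test_run = retained_runs, dir = 1:2,
                        KEEP.OUT.ATTRS = FALSE)
    plan <- data.frame(
      test_run = plan$test_run,
      train_set = sets[plan$dir],
      test_set = sets[3L - plan$dir],
      train_method = method,
      test_method = method,
      regime = paste0("within:", method),
      stringsAsFactors = FALSE
    )
  }
  attr(plan, "train_runs") <- retained_runs
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Build a cross-method fold plan
#'
#' Trains on method `m1` and tests on a held-out run containing only trials
#' from method `m2`. For each run retained for `m2`, training uses the `m1`
#' cells of all `m1`-retained runs except the held-out run. By default the
#' cross-exemplar constraint also applies (the same two set directions as
#' within-method, giving `2 * n_runs` folds); disable it with
#' `cross_exemplar = FALSE` to train and test on all exemplars.
#'
#' @param m1,m2 training and testing methods (must differ).
#' @param retained_runs_train,retained_runs_test runs retained for `m1` and
#'   `m2` respectively.
#' @param split exemplar split.
#' @param cross_exemplar keep the disjoint-exemplar constraint (default
#'   `TRUE`).
#' @return a `fold_plan` as in [make_folds_within()].
#' @export
make_folds_cross <- function(m1, m2, retained_runs_train,
                             retained_runs_test,
                             split = default_exemplar_split(),
                             cross_exemplar = TRUE) {
  m1 <- match_method(m1)
  m2 <- match_method(m2)
  if (m1 == m2) {
    stop("cross-method folds require two distinct methods", call. = FALSE)
  }
  sets <- names(split)
  ok <- length(retained_runs_test) >= 1L &&
    any(vapply(retained_runs_test,
               function(r) length(setdiff(retained_runs_train, r)) >= 1L,
               logical(1L)))
  if (!ok) {
    warning("no usable cross-method folds for ", m1, "->", m2,
            "; subject excluded for this regime", call. = FALSE)
    runs <- integer()
  } else {
    runs <- retained_runs_test[vapply(retained_runs_test, function(r) {
      length(setdiff(retained_runs_train, r)) >= 1L
    }, logical(1L))]
  }
  if (cross_exemplar) {
    grid <- expand.grid(test_run = runs, dir = 1:2, KEEP.OUT.ATTRS = FALSE)
    plan <- data.frame(
      test_run = grid$test_run,
      train_set = sets[grid$dir],
      test_set = sets[3L - grid$dir],
      stringsAsFactors = FALSE
    )
  } else {
    plan <- data.frame(test_run = runs, train_set = "all", test_set = "all",
                       stringsAsFactors = FALSE)
  }
  if (nrow(plan)) {
    plan$train_method <- m1
    plan$test_method <- m2
    plan$regime <- paste0("cross:", m1, "-", m2)
  } else {
    plan$train_method <- character()
    plan$test_method <- character()
    plan$regime <- character()
  }
  attr(plan, "train_runs") <- retained_runs_train
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Train a linear two-class classifier
#'
#' Maximum-margin linear decision rule with hinge loss and a fixed
#' regularization constant (a linear support vector machine with default
#' cost `C = 1`), fit by deterministic dual coordinate descent. Faces are
#' coded +1 and tools -1; prediction is the sign of the decision value.
#'
#' @param x training patterns (rows) x features matrix.
#' @param labels character vector of `"face"` / `"tool"` labels.
#' @param cost regularization constant (default 1).
#' @return object of class `linear_svm`: list with `w`, `b`, `cost`.
#' @export
train_linear_classifier <- function(x, labels, cost = 1) {
  x <- as.matrix(x)
  labels <- match_category(labels)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  y <- ifelse(labels == "face", 1, -1)
  wb <- svm_dcd(x, y, C = cost)
  d <- ncol(x)
  structure(list(w = wb[seq_len(d)], b = wb[d + 1L], cost = cost),
            class = "linear_svm")
}

#' @rdname train_linear_classifier
#' @param object a fitted `linear_svm`.
#' @param newdata patterns to classify (matrix or vector).
#' @param ... unused.
#' @return for `predict`: character vector of predicted labels.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
  else as.matrix(newdata)
  score <- drop(newdata %*% object$w) + object$b
  ifelse(score > 0, "face", "tool")
}

#' Signal-detection sensitivity of a confusion table
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with face as the signal class.
#' The default log-linear correction adds 0.5 to each count (so perfect
#' classification yields a finite value); `correction = "none"` uses the raw
#' rates.
#'
#' @param H,M,FA,CR hits, misses, false alarms, correct rejections.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return the d-prime value.
#' @export
#' @examples
#' dprime(12, 4, 4, 12, correction = "none") # 2 * qnorm(0.75)
dprime <- function(H, M, FA, CR, correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (H + M <= 0 || FA + CR <= 0) {
    stop("d-prime needs at least one signal and one noise test pattern",
         call. = FALSE)
  }
  if (correction == "loglinear") {
    hr <- (H + 0.5) / (H + M + 1)
    far <- (FA + 0.5) / (FA + CR + 1)
  } else {
    hr <- H / (H + M)
    far <- FA / (FA + CR)
  }
  qnorm(hr) - qnorm(far)
}

# Per-voxel standardization on training statistics only (no test leakage).
scale_train_test <- function(train, test) {
  n <- nrow(train)
  mu <- colMeans(train)
  sig <- sqrt(pmax(colSums(train^2) / n - mu^2, 0) * n / max(n - 1, 1))
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sig, "/"),
       test = sweep(sweep(test, 2, mu), 2, sig, "/"))
}

# Resolve each fold of a plan to integer row indices into the cell index.
# Computed once per plan and reused across ROIs (the indices do not depend
# on the voxel data).
fold_rows <- function(cells, plan) {
  train_runs <- attr(plan, "train_runs")
  lapply(seq_len(nrow(plan)), function(i) {
    tr_set <- plan$train_set[i]
    te_set <- plan$test_set[i]
    tr <- which(cells$method == plan$train_method[i] &
                  cells$run %in% setdiff(train_runs, plan$test_run[i]) &
                  (tr_set == "all" | cells$set == tr_set))
    te <- which(cells$method == plan$test_method[i] &
                  cells$run == plan$test_run[i] &
                  (te_set == "all" | cells$set == te_set))
    list(train = tr, test = te)
  })
}

#' Evaluate a fold plan on one ROI's cell patterns
#'
#' Runs every fold of the plan (train a linear SVM on the training cells,
#' classify the test cells), pools the confusion counts over folds, and
#' computes accuracy and a single d-prime per plan. Features are z-scored
#' per voxel using training statistics only.
#'
#' @param cells cell index from the internal grouping (run x method x
#'   category x exemplar-set).
#' @param mat matching matrix of averaged cell patterns (rows align with
#'   `cells`).
#' @param plan a `fold_plan`.
#' @param correction d-prime correction (see [dprime()]).
#' @param cost SVM regularization constant.
#' @param scale z-score features on training statistics (default `TRUE`).
#' @param pool `"counts"` (default: pool confusion counts, one d-prime) or
#'   `"folds"` (average per-fold d-primes).
#' @param fold_idx optional precomputed fold row indices (internal speed-up
#'   when evaluating the same plan across many ROIs).
#' @return list with `H`, `M`, `FA`, `CR`, `n_folds`, `accuracy`, `dprime`;
#'   all `NA` for an empty plan.
#' @export
evaluate_folds <- function(cells, mat, plan,
                           correction = c("loglinear", "none"),
                           cost = 1, scale = TRUE,
                           pool = c("counts", "folds"),
                           fold_idx = NULL) {
  correction <- match.arg(correction)
  pool <- match.arg(pool)
  empty <- list(H = NA_integer_, M = NA_integer_, FA = NA_integer_,
                CR = NA_integer_, n_folds = 0L, accuracy = NA_real_,
                dprime = NA_real_)
  if (nrow(plan) == 0L) {
    return(empty)
  }
  if (is.null(fold_idx)) fold_idx <- fold_rows(cells, plan)
  H <- M <- FA <- CR <- 0L
  fold_dp <- numeric(0)
  n_run_folds <- 0L
  for (i in seq_len(nrow(plan))) {
    tr_rows <- fold_idx[[i]]$train
    te_rows <- fold_idx[[i]]$test
    if (length(te_rows) == 0L ||
        length(unique(cells$category[tr_rows])) < 2L) {
      next
    }
    xtr <- mat[tr_rows, , drop = FALSE]
    xte <- mat[te_rows, , drop = FALSE]
    if (scale) {
      sc <- scale_train_test(xtr, xte)
      xtr <- sc$train
      xte <- sc$test
    }
    # Inlined train_linear_classifier()/predict() fast path (identical
    # semantics; avoids per-fold validation overhead in tight loops).
    y <- ifelse(cells$category[tr_rows] == "face", 1, -1)
    wb <- svm_dcd(xtr, y, C = cost)
    d <- ncol(xtr)
    score <- drop(xte %*% wb[seq_len(d)]) + wb[d + 1L]
    pred <- ifelse(score > 0, "face", "tool")
    truth <- cells$category[te_rows]
    h <- sum(pred == "face" & truth == "face")
    m <- sum(pred == "tool" & truth == "face")
    fa <- sum(pred == "face" & truth == "tool")
    cr <- sum(pred == "tool" & truth == "tool")
    H <- H + h; M <- M + m; FA <- FA + fa; CR <- CR + cr
    n_run_folds <- n_run_folds + 1L
    if (pool == "folds" && (h + m) > 0 && (fa + cr) > 0) {
      fold_dp <- c(fold_dp, dprime(h, m, fa, cr, correction = correction))
    }
  }
  if (n_run_folds == 0L || (H + M) == 0L || (FA + CR) == 0L) {
    return(empty)
  }
  dp <- if (pool == "counts") {
    dprime(H, M, FA, CR, correction = correction)
  } else {
    mean(fold_dp)
  }
  list(H = H, M = M, FA = FA, CR = CR, n_folds = n_run_folds,
       accuracy = (H + CR) / (H + M + FA + CR), dprime = dp)
}

retained_runs_for <- function(mask, method) {
  r <- mask$retention
  r$run[r$method == method & r$retained]
}

#' Decode one subject across ROIs and regimes
#'
#' Applies the full per-subject decoding chain: trial-pattern extraction,
#' QC-masked cell averaging, fold-plan construction per regime and linear
#' SVM evaluation pooled to one confusion table and d-prime per (ROI,
#' regime).
#'
#' @param dataset an `roi_dataset`.
#' @param mask a `usability_mask` from [apply_qc()] (computed on the fly
#'   when `NULL`).
#' @param regimes regime labels (see [all_regimes()]).
#' @param rois ROI subset (default: all atlas ROIs).
#' @param split exemplar split.
#' @param cross_exemplar apply the disjoint-exemplar constraint to
#'   cross-method folds (default `TRUE`).
#' @param ... passed to [evaluate_folds()] (`correction`, `cost`, `scale`,
#'   `pool`).
#' @return `data.frame` with one row per (ROI, regime): `subject`, `roi`,
#'   `regime`, `H`, `M`, `FA`, `CR`, `n_folds`, `accuracy`, `dprime`.
#' @export
decode_subject <- function(dataset, mask = NULL,
                           regimes = paste0("within:", .methods),
                           rois = NULL,
                           split = default_exemplar_split(),
                           cross_exemplar = TRUE, ...) {
  if (is.null(mask)) mask <- apply_qc(dataset, split = split)
  if (is.null(rois)) rois <- dataset$atlas$roi
  tp <- trial_patterns(dataset)
  usable <- mask$trial_usable & tp$usable
  cells <- cell_index(dataset$events, usable, split)
  plans <- lapply(regimes, function(rg) {
    spec <- parse_regime(rg)
    if (spec$type == "within") {
      make_folds_within(retained_runs_for(mask, spec$train), spec$train,
                        split = split)
    } else {
      make_folds_cross(spec$train, spec$test,
                       retained_runs_for(mask, spec$train),
                       retained_runs_for(mask, spec$test),
                       split = split, cross_exemplar = cross_exemplar)
    }
  })
  fold_idx <- lapply(plans, function(pl) fold_rows(cells, pl))
  out <- vector("list", length(rois) * length(regimes))
  k <- 0L
  for (roi in rois) {
    mat <- cell_patterns_roi(tp$patterns[[roi]], cells)
    for (j in seq_along(regimes)) {
      res <- evaluate_folds(cells, mat, plans[[j]], fold_idx = fold_idx[[j]],
                            ...)
      k <- k + 1L
      out[[k]] <- data.frame(subject = dataset$subject, roi = roi,
                             regime = parse_regime(regimes[j])$label,
                             H = res$H, M = res$M, FA = res$FA, CR = res$CR,
                             n_folds = res$n_folds,
                             accuracy = res$accuracy, dprime = res$dprime,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Decode every subject of a cohort
#'
#' @param cohort a `cohort_dataset`.
#' @param masks optional list of `usability_mask` per subject (computed via
#'   [apply_qc()] when `NULL`).
#' @inheritParams decode_subject
#' @return row-bound `data.frame` of [decode_subject()] results.
#' @export
decode_cohort <- function(cohort, masks = NULL,
                          regimes = paste0("within:", .methods),
                          rois = NULL, split = default_exemplar_split(),
                          ...) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(masks)) {
    masks <- lapply(cohort$subjects, apply_qc, split = split)
  }
  do.call(rbind, lapply(seq_along(cohort$subjects), function(s) {
    decode_subject(cohort$subjects[[s]], mask = masks[[s]],
                   regimes = regimes, rois = rois, split = split, ...)
  }))
}
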