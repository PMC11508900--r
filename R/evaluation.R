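#' Area under the ROC curve
#'
#' Computed as the tie-aware Mann-Whitney rank statistic: the probability
#' that a randomly chosen presence outscores a randomly chosen absence,
#' with ties counted one half. This equals the trapezoidal integral of the
#' ROC curve and is invariant to monotone transforms of the scores.
#'
#' @param scores numeric suitability scores.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC needs both presences and absences.", class = "ensdm_metric_error")
  }
  if (anyNA(scores)) abort("AUC scores must not contain NA.", class = "ensdm_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' Predicted presence iff `score >= threshold`.
#' @inheritParams auc
#' @param threshold binarisation threshold.
#' @return list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' Cohen's kappa from confusion counts
#'
#' `(Po - Pe) / (1 - Pe)` with observed agreement `Po = (TP + TN) / n` and
#' chance agreement `Pe = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)] / n^2`.
#'
#' @param counts list/row with `TP`, `FP`, `TN`, `FN` (see
#'   [confusion_counts]).
#' @return kappa in `[-1, 1]`.
#' @export
kappa_stat <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  n <- tp + fp + tn + fn
  if (n == 0) abort("empty confusion table.", class = "ensdm_metric_error")
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) {
    abort("kappa undefined: chance agreement equals 1.", class = "ensdm_metric_error")
  }
  (po - pe) / (1 - pe)
}

#' True skill statistic from confusion counts
#'
#' Sensitivity + specificity - 1; prevalence-insensitive skill.
#' @inheritParams kappa_stat
#' @return TSS in `[-1, 1]`.
#' @export
tss_stat <- function(counts) {
  np <- counts$TP + counts$FN
  na_ <- counts$TN + counts$FP
  if (np == 0 || na_ == 0) {
    abort("TSS needs both presences and absences.", class = "ensdm_metric_error")
  }
  counts$TP / np + counts$TN / na_ - 1
}

#' Max-TSS binarisation threshold
#'
#' Evaluates TSS at every midpoint between adjacent distinct sorted scores,
#' plus the endpoints 0 and 1, and returns the maximising threshold (ties
#' broken towards the smallest threshold).
#'
#' @inheritParams auc
#' @return list with `threshold` and `tss`.
#' @export
best_threshold_by_tss <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("TSS needs both presences and absences.", class = "ensdm_metric_error")
  }
  s <- sort(unique(scores))
  cand <- sort(unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1)))
  # vectorised TSS over candidate thresholds
  tss_at <- vapply(cand, function(th) {
    tp <- sum(scores >= th & labels == 1)
    tn <- sum(scores < th & labels == 0)
    tp / n1 + tn / n0 - 1
  }, numeric(1))
  best <- which.max(tss_at)  # which.max returns the first (smallest) maximiser
  list(threshold = cand[best], tss = tss_at[best])
}

#' Evaluate the model committee on repeated splits
#'
#' For every model x repeat: fit on the calibration rows, score the
#' evaluation rows, and record AUC plus KAPPA and TSS at the max-TSS
#' threshold of that repeat's evaluation scores. Failed fits are retained
#' as records flagged `failed` (mirroring how a non-converging committee
#' member is excluded rather than aborting the analysis).
#'
#' @param specs list of [sdm_spec] (or character names, given default
#'   specs seeded from `seed`).
#' @param occ occurrence tibble with `label` and `split_*` columns (see
#'   [make_splits]).
#' @param covariates covariate tibble, one row per `occ` row (e.g. from
#'   [extract_values]), containing only the modelling variables.
#' @param seed root seed for per-model fit seeds when `specs` are names.
#' @return tibble of class `sdm_evaluation`: one row per model x repeat
#'   (`model`, `repeat_index`, `auc`, `kappa`, `tss`, `best_threshold`,
#'   `failed`, `message`), with the per-point evaluation scores retained in
#'   `attr(, "predictions")` for pooled thresholding.
#' @export
evaluate_models <- function(specs, occ, covariates, seed = 1) {
  if (is.character(specs)) {
    specs <- lapply(specs, function(nm) {
      sdm_spec(nm, seed = derive_seed(seed, paste0("fit_", nm)))
    })
  }
  split_cols <- split_columns(occ)
  if (length(split_cols) == 0) {
    abort("`occ` has no split_* columns; call make_splits() first.",
          class = "ensdm_split_error")
  }
  X <- as_tibble(covariates)
  records <- list(); preds <- list()
  for (spec in specs) {
    for (r in seq_along(split_cols)) {
      cal <- occ[[split_cols[r]]] == "calibration"
      res <- tryCatch({
        fit <- fit_sdm(spec, X[cal, , drop = FALSE], occ$label[cal])
        sc <- predict(fit, X[!cal, , drop = FALSE])
        if (anyNA(sc)) abort("NA predictions on evaluation rows.",
                             class = "ensdm_fit_error")
        lb <- occ$label[!cal]
        bt <- best_threshold_by_tss(sc, lb)
        cc <- confusion_counts(sc, lb, bt$threshold)
        list(rec = tibble(model = spec$name, repeat_index = r,
                          auc = auc(sc, lb), kappa = kappa_stat(cc),
                          tss = bt$tss, best_threshold = bt$threshold,
                          failed = FALSE, message = ""),
             pr = tibble(model = spec$name, repeat_index = r,
                         point = which(!cal), label = lb, score = sc))
      }, error = function(e) {
        list(rec = tibble(model = spec$name, repeat_index = r,
                          auc = NA_real_, kappa = NA_real_, tss = NA_real_,
                          best_threshold = NA_real_, failed = TRUE,
                          message = conditionMessage(e)),
             pr = NULL)
      })
      records[[length(records) + 1]] <- res$rec
      if (!is.null(res$pr)) preds[[length(preds) + 1]] <- res$pr
    }
  }
  out <- dplyr::bind_rows(records)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  class(out) <- c("sdm_evaluation", class(out))
  out
}

#' Permutation importance of covariates
#'
#' For each variable, its column is shuffled `n_shuffles` times and the
#' importance is the mean of `1 - cor(pred_original, pred_shuffled)`
#' (Pearson), clamped to `[0, 1]`. A model whose predictions do not change
#' scores 0 for that variable; constant predictions give importance 0
#' everywhere (no dependence is measurable).
#'
#' @param object anything with a `predict(object, newdata)` method
#'   returning numeric suitabilities (an `sdm_fit` or `sdm_ensemble`).
#' @param covariates covariate tibble (rows = points).
#' @param n_shuffles shuffles per variable (default 3).
#' @param seed integer seed.
#' @return tibble: `variable`, `importance`, sorted by decreasing
#'   importance.
#' @export
permutation_importance <- function(object, covariates, n_shuffles = 3, seed = 1) {
  X <- as_tibble(covariates)
  if (nrow(X) < 2) abort("need at least 2 rows.", class = "ensdm_data_error")
  p0 <- predict(object, X)
  const0 <- stats::sd(p0, na.rm = TRUE) == 0 || all(is.na(p0))
  imp <- with_seed(seed, {
    vapply(names(X), function(v) {
      if (const0) return(0)
      vals <- vapply(seq_len(n_shuffles), function(s) {
        Xs <- X
        Xs[[v]] <- sample(Xs[[v]])
        ps <- predict(object, Xs)
        if (isTRUE(all.equal(ps, p0))) return(0)
        r <- suppressWarnings(stats::cor(p0, ps, use = "complete.obs"))
        if (is.na(r)) r <- 0
        1 - r
      }, numeric(1))
      mean(vals)
    }, numeric(1))
  })
  tibble(variable = names(X), importance = clamp01(unname(imp))) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Response curve of a fitted model or ensemble
#'
#' Evaluation-strip method: each requested variable is swept over
#' `n_steps` equal steps spanning its unmasked range while every other
#' variable is held at its unmasked mean. Reports the sampled curve, the
#' favourable range(s) — maximal sweep intervals where suitability exceeds
#' `favorable_cutoff` — and the optimum (sweep argmax; ties towards the
#' smallest value).
#'
#' @param object an `sdm_fit` or `sdm_ensemble`.
#' @param stack the [align_stack] stack the model applies to.
#' @param variables variables to sweep (default: all model variables).
#' @param n_steps sweep resolution (default 100).
#' @param favorable_cutoff suitability defining a favourable value
#'   (default 0.5).
#' @return object of class `response_curves`: list with `curves` (tibble
#'   `variable`, `value`, `suitability`), `favorable` (tibble `variable`,
#'   `lower`, `upper`) and `optima` (tibble `variable`, `optimum`,
#'   `suitability`).
#' @export
response_curve <- function(object, stack, variables = NULL, n_steps = 100,
                           favorable_cutoff = 0.5) {
  model_vars <- if (inherits(object, "sdm_ensemble")) {
    object$members[[1]]$variables
  } else {
    object$variables
  }
  variables <- variables %||% model_vars
  bad <- setdiff(variables, stack$layer_names)
  if (length(bad) > 0) {
    abort(sprintf("variable(s) not in stack: %s", paste(bad, collapse = ", ")),
          class = "ensdm_schema_error")
  }
  keep <- !as.vector(stack$shared_mask)
  ref_vals <- vapply(model_vars, function(v) {
    mean(as.vector(stack$layers[[v]]$values)[keep])
  }, numeric(1))
  curves <- list(); fav <- list(); opt <- list()
  for (v in variables) {
    x <- as.vector(stack$layers[[v]]$values)[keep]
    rng <- range(x)
    if (diff(rng) == 0) {
      abort(sprintf("variable '%s' is constant over the unmasked area.", v),
            class = "ensdm_degenerate_error")
    }
    sweep <- seq(rng[1], rng[2], length.out = n_steps)
    nd <- as_tibble(as.list(ref_vals))[rep(1, n_steps), ]
    nd[[v]] <- sweep
    s <- predict(object, nd)
    curves[[v]] <- tibble(variable = v, value = sweep, suitability = s)
    above <- s > favorable_cutoff
    if (any(above)) {
      runs <- rle(above)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      ok <- runs$values
      fav[[v]] <- tibble(variable = v, lower = sweep[starts[ok]],
                         upper = sweep[ends[ok]])
    }
    best <- which.max(s)
    opt[[v]] <- tibble(variable = v, optimum = sweep[best], suitability = s[best])
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 favorable = dplyr::bind_rows(fav),
                 optima = dplyr::bind_rows(opt),
                 cutoff = favorable_cutoff),
            class = "response_curves")
}

#' @export
print.response_curves <- function(x, ...) {
  cat(sprintf("<response_curves> %d variable(s), cutoff %.3g\n",
              length(unique(x$curves$variable)), x$cutoff))
  print(x$optima)
  invisible(x)
}
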