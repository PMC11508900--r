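#' Pairwise Pearson correlation of candidate covariates
#'
#' @param values data frame / tibble of numeric covariate columns (rows =
#'   calibration points or cells).
#' @param use passed to [stats::cor]; the default requires complete data.
#'   Use `"pairwise.complete.obs"` after setting sentinel values (e.g. flat
#'   aspect, -1) to `NA`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(values, use = "everything") {
  m <- as.matrix(values)
  if (!is.numeric(m)) abort("covariates must be numeric.", class = "ensdm_data_error")
  if (nrow(m) < 3) {
    abort("need at least 3 points for a correlation matrix.", class = "ensdm_data_error")
  }
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    abort(sprintf("zero-variance variable(s): %s",
                  paste(colnames(m)[degenerate], collapse = ", ")),
          class = "ensdm_degenerate_error")
  }
  r <- stats::cor(m, use = use)
  diag(r) <- 1
  r
}

#' Screen covariates by correlation and contribution
#'
#' Greedy collinearity elimination: repeatedly locate the variable pair
#' with the largest `|r|` above `threshold` and drop the member with the
#' lower contribution score (tie: drop the lexicographically later name),
#' until no pair among the kept variables exceeds the threshold. The
#' contribution scores are used only relationally (which member of a pair
#' survives), never as an absolute cutoff.
#'
#' @param corr correlation matrix from [pearson_matrix].
#' @param contribution named numeric vector of importance scores, one per
#'   variable (typically permutation importance of a preliminary ensemble
#'   fitted on all candidates; see [permutation_importance]).
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return an object of class `screening_report`: list with
#'   `correlation`, `contribution`, `kept` (character), and `dropped`
#'   (tibble: `variable`, `reason`, `partner`).
#' @export
screen_variables <- function(corr, contribution, threshold = 0.8) {
  vars <- colnames(corr)
  if (is.null(vars) || !setequal(vars, rownames(corr))) {
    abort("`corr` must have matching row/column names.", class = "ensdm_data_error")
  }
  miss <- setdiff(vars, names(contribution))
  if (length(miss) > 0) {
    abort(sprintf("contribution missing for: %s", paste(miss, collapse = ", ")),
          class = "ensdm_data_error")
  }
  kept <- vars
  dropped <- tibble(variable = character(), reason = character(), partner = character())
  repeat {
    sub <- abs(corr[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (length(kept) < 2 || max(sub) <= threshold) break
    # all pairs attaining the worst |r|; when several tie, eliminate the
    # globally weakest candidate among their lower-contribution members
    ties <- which(sub == max(sub), arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    cand <- apply(ties, 1, function(ij) {
      a <- kept[ij[1]]; b <- kept[ij[2]]
      ca <- contribution[[a]]; cb <- contribution[[b]]
      if (ca < cb) a else if (cb < ca) b else max(a, b)
    })
    cand <- unname(cand)
    ord <- order(unname(contribution[cand]), -xtfrm(cand))
    pick <- ord[1]
    drop_var <- cand[pick]
    a <- kept[ties[pick, 1]]; b <- kept[ties[pick, 2]]
    partner <- setdiff(c(a, b), drop_var)
    kept <- setdiff(kept, drop_var)
    dropped <- dplyr::bind_rows(dropped, tibble(
      variable = drop_var,
      reason = sprintf("high_correlation_with %s", partner),
      partner = partner
    ))
  }
  structure(
    list(correlation = corr, contribution = contribution[vars],
         kept = kept, dropped = dropped, threshold = threshold),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> |r| threshold %.3g\n", x$threshold))
  cat(sprintf("  kept (%d): %s\n", length(x$kept), paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped) > 0) {
    cat(sprintf("  dropped (%d):\n", nrow(x$dropped)))
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("    %s (%s)\n", x$dropped$variable[i], x$dropped$reason[i]))
    }
  } else {
    cat("  dropped: none\n")
  }
  invisible(x)
}

#' Write a screening report to disk
#'
#' Exports the correlation matrix as CSV and the keep/drop decisions as
#' JSON next to it.
#' @param report a [screen_variables] result.
#' @param csv_path,json_path output files.
#' @return invisibly, the report.
#' @export
write_screening_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$correlation, csv_path)
  jsonlite::write_json(
    list(threshold = report$threshold, kept = report$kept,
         dropped = report$dropped,
         contribution = as.list(report$contribution)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
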