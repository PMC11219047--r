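#' Enumerate component combinations
#'
#' All non-empty subsets of the component list in a deterministic canonical
#' order: by subset size, then lexicographically in the order the components
#' are listed. Optional constraints filter the enumeration.
#'
#' @param components character vector of 1-10 component names.
#' @param must_include components every subset must contain.
#' @return List of character vectors (subsets).
#' @examples
#' length(enumerate_combinations(letters[1:6]))  # 63
#' @export
enumerate_combinations <- function(components, must_include = character(0)) {
  n <- length(components)
  if (n < 1L || n > 10L) stop("need between 1 and 10 components")
  if (anyDuplicated(components)) stop("component names must be unique")
  if (!all(must_include %in% components)) {
    stop("must_include components not in the component list")
  }
  subsets <- list()
  for (size in seq_len(n)) {
    idx <- utils::combn(n, size, simplify = FALSE)  # lexicographic by index
    subsets <- c(subsets, lapply(idx, function(i) components[i]))
  }
  if (length(must_include)) {
    keep <- vapply(subsets, function(s) all(must_include %in% s), logical(1))
    subsets <- subsets[keep]
  }
  subsets
}

subset_label <- function(subset) paste(subset, collapse = "+")

#' Score-correlation matrix over component combinations
#'
#' For every candidate component subset, computes the Pearson correlation of
#' its composite score (valid animals only) with each reference metric over
#' complete pairs, then ranks the subsets within each metric by descending
#' absolute correlation (midranks for ties; `statistic = "signed_r"` ranks
#' by signed r after multiplying by per-metric expected signs). The overall
#' rank of a subset is the arithmetic mean of its per-metric ranks, where
#' lower means better overall correlation; subsets with fewer than
#' `min_metrics` computable cells get no overall rank.
#'
#' @param cohort cohort data frame (scored groups pooled by default).
#' @param rubric a `cavalus_rubric`.
#' @param subsets list of component subsets, e.g. from
#'   [enumerate_combinations()].
#' @param metrics reference-metric column names (default: all present).
#' @param calibration IVC calibration; derived from the control group when
#'   needed and not supplied.
#' @param min_pairs minimum complete pairs for a cell to be computable.
#' @param min_metrics minimum computable cells for an overall rank.
#' @param statistic rank by absolute (`"abs_r"`, default) or sign-corrected
#'   (`"signed_r"`) correlation.
#' @param expected_signs named +-1 vector per metric, required for
#'   `"signed_r"`.
#' @param groups correlate over both groups pooled (default) or HF animals
#'   only.
#' @return Object of class `cavalus_corr_matrix`: list with `subsets`,
#'   `labels`, `metrics`, matrices `r`, `n`, `ranks` (subsets x metrics),
#'   `overall_rank`, `n_metrics_used`, and `excluded` (labels of subsets
#'   with no computable cell, e.g. all-invalid composites).
#' @export
score_correlation_matrix <- function(cohort, rubric, subsets,
                                     metrics = reference_metrics(cohort),
                                     calibration = NULL,
                                     min_pairs = 6L, min_metrics = 3L,
                                     statistic = c("abs_r", "signed_r"),
                                     expected_signs = NULL,
                                     groups = c("pooled", "hf")) {
  statistic <- match.arg(statistic)
  groups <- match.arg(groups)
  stopifnot(length(subsets) >= 1L, length(metrics) >= 1L)
  if (statistic == "signed_r" &&
      (is.null(expected_signs) || !all(metrics %in% names(expected_signs)))) {
    stop("signed_r ranking needs expected_signs for every metric")
  }
  if ("ivc" %in% unlist(subsets) && is.null(calibration) &&
      rubric$components$ivc$rule$mode == "calibrated") {
    calibration <- ivc_calibration(cohort)
  }
  dat <- if (groups == "hf") cohort[cohort$group == "hf", , drop = FALSE] else cohort

  labels <- vapply(subsets, subset_label, character(1))
  nr <- length(subsets); nc <- length(metrics)
  r_mat <- matrix(NA_real_, nr, nc, dimnames = list(labels, metrics))
  n_mat <- matrix(0L, nr, nc, dimnames = list(labels, metrics))
  excluded <- character(0)

  for (i in seq_len(nr)) {
    sc <- composite_scores(dat, rubric, subsets[[i]], calibration = calibration)
    if (!any(sc$valid)) {
      excluded <- c(excluded, labels[i])
      next
    }
    for (j in seq_len(nc)) {
      res <- pearson_cor(sc$total_points, dat[[metrics[j]]])
      n_mat[i, j] <- res$n
      if (res$computable && res$n >= min_pairs) r_mat[i, j] <- res$r
    }
  }
  if (length(excluded)) {
    message("excluded (no valid composite scores): ",
            paste(excluded, collapse = ", "))
  }

  key <- if (statistic == "abs_r") {
    abs(r_mat)
  } else {
    sweep(r_mat, 2, expected_signs[metrics], `*`)
  }
  ranks <- apply(key, 2, function(col) {
    out <- rep(NA_real_, length(col))
    ok <- !is.na(col)
    out[ok] <- rank(-col[ok], ties.method = "average")
    out
  })
  ranks <- matrix(ranks, nr, nc, dimnames = dimnames(r_mat))
  n_used <- rowSums(!is.na(ranks))
  overall <- ifelse(n_used >= min_metrics, rowMeans(ranks, na.rm = TRUE),
                    NA_real_)
  overall[labels %in% excluded] <- NA_real_

  structure(list(subsets = subsets, labels = labels, metrics = metrics,
                 r = r_mat, n = n_mat, ranks = ranks,
                 overall_rank = stats::setNames(overall, labels),
                 n_metrics_used = stats::setNames(as.integer(n_used), labels),
                 excluded = excluded, statistic = statistic),
            class = "cavalus_corr_matrix")
}

#' Shortlist the best-ranked combinations
#'
#' Returns the `k` subsets with the smallest overall rank. Ties at the
#' boundary are broken by fewer components, then canonical enumeration
#' order, making the selection deterministic.
#'
#' @param matrix a `cavalus_corr_matrix`.
#' @param k shortlist size.
#' @return List of subsets (character vectors) with the chosen overall ranks
#'   attached as attribute `"overall_rank"`.
#' @export
select_top_k <- function(matrix, k = 7L) {
  stopifnot(inherits(matrix, "cavalus_corr_matrix"), k >= 1L)
  ok <- which(!is.na(matrix$overall_rank))
  if (length(ok) < k) {
    warning(sprintf("only %d subsets have a computable overall rank (k = %d); returning all",
                    length(ok), k))
    k <- length(ok)
  }
  sizes <- vapply(matrix$subsets, length, integer(1))
  ord <- ok[order(matrix$overall_rank[ok], sizes[ok], ok)]
  pick <- ord[seq_len(k)]
  out <- matrix$subsets[pick]
  attr(out, "overall_rank") <- matrix$overall_rank[pick]
  out
}

#' Select the winning combination by maximal Youden's J
#'
#' Runs an ROC analysis (positive class = HF group) for every shortlisted
#' subset and picks the one whose Youden-optimal operating point has the
#' largest J; ties are broken by higher specificity at the optimum, then by
#' fewer components, then canonical order. Subsets with no valid composite
#' scores or with only one group among the valid animals are skipped with a
#' message.
#'
#' @param cohort cohort data frame with a `group` column.
#' @param rubric a `cavalus_rubric`.
#' @param shortlist list of subsets, e.g. from [select_top_k()].
#' @param calibration IVC calibration (auto-derived when needed).
#' @return Object of class `cavalus_selection`: list with `shortlist`,
#'   `roc` (per-subset `cavalus_roc`s), `winner` (character vector of
#'   components), `winner_label`, `winner_cutoff`, `winner_j`, `winner_se`,
#'   `winner_sp`.
#' @export
select_winner <- function(cohort, rubric, shortlist, calibration = NULL) {
  stopifnot(length(shortlist) >= 1L)
  if ("ivc" %in% unlist(shortlist) && is.null(calibration) &&
      rubric$components$ivc$rule$mode == "calibrated") {
    calibration <- ivc_calibration(cohort)
  }
  labels <- vapply(shortlist, subset_label, character(1))
  rocs <- vector("list", length(shortlist))
  names(rocs) <- labels
  for (i in seq_along(shortlist)) {
    sc <- composite_scores(cohort, rubric, shortlist[[i]], calibration = calibration)
    keep <- sc$valid
    if (!any(keep) || length(unique(sc$group[keep])) < 2L) {
      message("skipping ", labels[i], ": no valid scores in both groups")
      next
    }
    rocs[[i]] <- roc_curve(sc$total_points[keep],
                           as.integer(sc$group[keep] == "hf"))
  }
  usable <- which(!vapply(rocs, is.null, logical(1)))
  if (!length(usable)) stop("no shortlisted subset produced a usable ROC curve")
  j <- vapply(rocs[usable], function(r) r$j_at_optimal, numeric(1))
  sp <- vapply(rocs[usable], function(r) r$sp_at_optimal, numeric(1))
  sizes <- vapply(shortlist[usable], length, integer(1))
  ord <- order(-j, -sp, sizes, usable)
  win <- usable[ord[1L]]
  wroc <- rocs[[win]]
  structure(list(shortlist = shortlist, roc = rocs,
                 winner = shortlist[[win]], winner_label = labels[win],
                 winner_cutoff = wroc$optimal_cutoff,
                 winner_j = wroc$j_at_optimal,
                 winner_se = wroc$se_at_optimal,
                 winner_sp = wroc$sp_at_optimal),
            class = "cavalus_selection")
}

#' @export
print.cavalus_corr_matrix <- function(x, ...) {
  cat(sprintf("Score-correlation matrix: %d combinations x %d reference metrics (%s ranking)\n",
              length(x$subsets), length(x$metrics), x$statistic))
  best <- order(x$overall_rank)[seq_len(min(5L, sum(!is.na(x$overall_rank))))]
  cat("  best overall ranks:\n")
  for (i in best) {
    cat(sprintf("    %5.1f  %s\n", x$overall_rank[i], x$labels[i]))
  }
  invisible(x)
}

#' @export
print.cavalus_selection <- function(x, ...) {
  cat(sprintf("Winning combination: %s\n", x$winner_label))
  cat(sprintf("  cutoff %s points; J = %.2f (Se %.0f%%, Sp %.0f%%)\n",
              format(x$winner_cutoff), x$winner_j,
              100 * x$winner_se, 100 * x$winner_sp))
  invisible(x)
}
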