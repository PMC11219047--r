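#' Observer-pair agreement on composite scores
#'
#' Compares two (observer, pass) score series on the animals both members
#' scored with a valid composite: Pearson's correlation of the paired totals
#' plus Bland-Altman bias and 95% limits of agreement. Same observer across
#' different passes measures intra-observer agreement; different observers
#' on the same pass measure inter-observer agreement.
#'
#' @param totals composite totals from [observer_totals()].
#' @param pair_a,pair_b length-2 vectors `c(observer_id, pass)`.
#' @return List of class `cavalus_pair_agreement` with `pair_label`, `r`,
#'   `p_value`, `bias`, `loa_low`, `loa_high`, `n`, `computable`.
#' @export
pairwise_agreement <- function(totals, pair_a, pair_b) {
  stopifnot(length(pair_a) == 2L, length(pair_b) == 2L)
  pick <- function(pair) {
    sel <- totals$observer_id == pair[1] & totals$pass == pair[2] & totals$valid
    stats::setNames(totals$total_points[sel], totals$animal_id[sel])
  }
  a <- pick(pair_a); b <- pick(pair_b)
  shared <- intersect(names(a), names(b))
  label <- sprintf("obs%d/pass%d vs obs%d/pass%d",
                   pair_a[1], pair_a[2], pair_b[1], pair_b[2])
  if (length(shared) < 3L) {
    return(structure(list(pair_label = label, r = NA_real_, p_value = NA_real_,
                          bias = NA_real_, loa_low = NA_real_,
                          loa_high = NA_real_, n = length(shared),
                          computable = FALSE),
                     class = "cavalus_pair_agreement"))
  }
  av <- a[shared]; bv <- b[shared]
  cor_res <- pearson_cor(av, bv)
  ba <- bland_altman(av, bv, pair_label = label)
  # a perfectly reproduced (or constant-offset) rescoring has zero variance
  # in the differences but is still perfect agreement: report r = 1
  r <- if (cor_res$computable) cor_res$r else if (all(av - bv == (av - bv)[1])) 1 else NA_real_
  structure(list(pair_label = label, r = r, p_value = cor_res$p_value,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 n = length(shared), computable = TRUE),
            class = "cavalus_pair_agreement")
}

#' Full observer-agreement report
#'
#' One row per comparable pair: every unordered pair of distinct observers
#' on their first pass (inter-observer), plus each observer's repeated
#' passes against each other (intra-observer). Rows are deterministically
#' ordered (intra first, then inter by observer ids); pairs with
#' insufficient overlap are kept and flagged as not computable.
#'
#' @param totals composite totals from [observer_totals()].
#' @return Data frame with columns `pair`, `type`, `r`, `p_value`, `bias`,
#'   `loa_low`, `loa_high`, `n`, `computable`.
#' @export
agreement_report <- function(totals) {
  series <- unique(totals[, c("observer_id", "pass")])
  series <- series[order(series$observer_id, series$pass), ]
  if (nrow(series) < 2L) stop("need at least two observer/pass series")
  pairs <- list()
  # intra-observer: successive passes of the same observer
  for (obs in unique(series$observer_id)) {
    p <- sort(series$pass[series$observer_id == obs])
    if (length(p) >= 2L) {
      for (i in seq_len(length(p) - 1L)) {
        pairs[[length(pairs) + 1L]] <- list(a = c(obs, p[i]), b = c(obs, p[i + 1L]),
                                            type = "intra")
      }
    }
  }
  # inter-observer: distinct observers, first pass each
  obs_ids <- sort(unique(series$observer_id))
  if (length(obs_ids) >= 2L) {
    cmb <- utils::combn(obs_ids, 2L)
    for (i in seq_len(ncol(cmb))) {
      pairs[[length(pairs) + 1L]] <- list(a = c(cmb[1, i], 1L), b = c(cmb[2, i], 1L),
                                          type = "inter")
    }
  }
  rows <- lapply(pairs, function(p) {
    res <- pairwise_agreement(totals, p$a, p$b)
    data.frame(pair = res$pair_label, type = p$type, r = res$r,
               p_value = res$p_value, bias = res$bias,
               loa_low = res$loa_low, loa_high = res$loa_high,
               n = res$n, computable = res$computable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cavalus_pair_agreement <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("%s: r = %.3f, bias = %.2f pts, 95%% LOA [%.2f, %.2f], n = %d\n",
                x$pair_label, x$r, x$bias, x$loa_low, x$loa_high, x$n))
  } else {
    cat(sprintf("%s: not computable (only %d shared valid scores)\n",
                x$pair_label, x$n))
  }
  invisible(x)
}
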