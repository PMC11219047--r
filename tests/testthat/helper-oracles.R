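# Independent brute-force oracles used across the suite. Deliberately naive
# (explicit loops, direct formulas) and sharing no code with the package.

# pairwise concordance statistic: (concordant + half tied) / (n1 * n0)
oracle_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# two-sided exact Mann-Whitney p via the null distribution of U
# (stats::dwilcox; independent of the package's enumeration path)
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  u_all <- 0:(n1 * n2)
  d <- stats::dwilcox(u_all, n1, n2)
  sum(d[abs(u_all - mu) >= abs(U - mu) - 1e-9])
}

# naive score-correlation matrix + midrank aggregation over explicit loops
oracle_corr_ranks <- function(score_list, metric_df, min_pairs = 6) {
  n_sub <- length(score_list)
  metrics <- names(metric_df)
  r <- matrix(NA_real_, n_sub, length(metrics))
  for (i in seq_len(n_sub)) {
    for (j in seq_along(metrics)) {
      s <- score_list[[i]]; m <- metric_df[[j]]
      ok <- is.finite(s) & is.finite(m)
      if (sum(ok) < min_pairs) next
      s <- s[ok]; m <- m[ok]
      if (stats::sd(s) == 0 || stats::sd(m) == 0) next
      num <- sum((s - mean(s)) * (m - mean(m)))
      r[i, j] <- num / sqrt(sum((s - mean(s))^2) * sum((m - mean(m))^2))
    }
  }
  ranks <- r
  for (j in seq_along(metrics)) {
    col <- abs(r[, j])
    ok <- !is.na(col)
    ranks[ok, j] <- rank(-col[ok], ties.method = "average")
    ranks[!ok, j] <- NA
  }
  overall <- rowMeans(ranks, na.rm = TRUE)
  list(r = r, ranks = ranks, overall = overall)
}

# small hand-rolled cohort for scoring tests: one row per animal with the
# finding columns the rubric needs
tiny_cohort <- function(ivc = 2.0, b = 0L, eff = 0L, def = 0L, thick = 0L,
                        sliding = "present", group = "hf",
                        id = sprintf("a%02d", seq_along(ivc))) {
  data.frame(animal_id = id, species = "rat", sex = "male", group = group,
             ivc_diameter_max = ivc, ivc_diameter_min = ivc * 0.5,
             b_line_profile = as.integer(b), pleural_effusion = as.integer(eff),
             pleural_defects = as.integer(def),
             pleural_thickening = as.integer(thick),
             lung_sliding = sliding, stringsAsFactors = FALSE)
}

fixed_calibration <- list(mean = 2.0, sd = 0.5, n = 20)  # threshold 3.0 at k = 2
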