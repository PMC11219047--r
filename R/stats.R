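#' Pearson product-moment correlation
#'
#' Computes Pearson's r between two paired vectors together with a two-sided
#' p-value from the t transform with n - 2 degrees of freedom. Pairs with a
#' missing value in either member are dropped. Fewer than three complete
#' pairs, or zero variance in either vector, yield a "not computable" result
#' (`computable = FALSE`, `r` and `p_value` set to `NA`) rather than an error,
#' so callers iterating over many score/metric cells can handle degenerate
#' cells uniformly.
#'
#' @param x,y numeric vectors of equal length.
#' @return A list of class `cavalus_correlation` with elements `r`, `p_value`,
#'   `n` (complete pairs) and `computable`.
#' @examples
#' pearson_cor(1:10, (1:10)^2)
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- structure(list(r = NA_real_, p_value = NA_real_, n = n,
                        computable = FALSE),
                   class = "cavalus_correlation")
  if (n < 3L) return(out)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx <= 0 || syy <= 0) return(out)
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- clamp(r, -1, 1)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out$r <- r; out$p_value <- p; out$computable <- TRUE
  out
}

#' Shapiro-Wilk test of normality
#'
#' W statistic and approximate p-value following Royston's AS R94 algorithm:
#' expected normal order statistics m_i = qnorm((i - 3/8)/(n + 1/4)), weights
#' from the normalized m with polynomial corrections to the one (n = 4, 5) or
#' two (n > 5) extreme coefficients, and a normalizing transformation of
#' 1 - W to an approximate standard normal deviate (log-based for n >= 12,
#' shifted-log for 4 <= n <= 11, exact arcsine form for n = 3).
#'
#' @param x numeric vector, 3 <= length <= 5000 after dropping missing values.
#' @return List with `W`, `p_value`, `n`, `computable`. A constant sample is
#'   reported as not computable.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  out <- list(W = NA_real_, p_value = NA_real_, n = n, computable = FALSE)
  if (n < 3L || n > 5000L) return(out)
  x <- sort(x)
  ssq <- sum((x - mean(x))^2)
  if (ssq <= 0) return(out)

  m <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  ssumm2 <- sum(m^2)
  a <- m / sqrt(ssumm2)
  if (n > 3L) {
    u <- 1 / sqrt(n)
    # polynomial corrections to the extreme weights (Royston 1995)
    a_n <- a[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
      4.434685 * u^4 - 2.706056 * u^5
    if (n > 5L) {
      a_n1 <- a[n - 1L] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
        5.682633 * u^4 - 3.582633 * u^5
      phi <- (ssumm2 - 2 * m[n]^2 - 2 * m[n - 1L]^2) /
        (1 - 2 * a_n^2 - 2 * a_n1^2)
      a <- m / sqrt(phi)
      a[n] <- a_n; a[n - 1L] <- a_n1
      a[1L] <- -a_n; a[2L] <- -a_n1
    } else {
      phi <- (ssumm2 - 2 * m[n]^2) / (1 - 2 * a_n^2)
      a <- m / sqrt(phi)
      a[n] <- a_n; a[1L] <- -a_n
    }
  }
  W <- sum(a * x)^2 / ssq
  W <- min(W, 1)

  if (n == 3L) {
    # exact small-sample distribution
    p <- 1.90985931710274 * (asin(sqrt(W)) - 1.04719755119660)
    p <- clamp(p, 0, 1)
  } else if (n <= 11L) {
    gamma <- -2.273 + 0.459 * n
    w1 <- 1 - W
    if (gamma - log(w1) <= 0) {
      p <- 0
    } else {
      y <- -log(gamma - log(w1))
      mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
      sigma <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
      p <- stats::pnorm((y - mu) / sigma, lower.tail = FALSE)
    }
  } else {
    ln <- log(n)
    y <- log(1 - W)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sigma <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    p <- stats::pnorm((y - mu) / sigma, lower.tail = FALSE)
  }
  list(W = W, p_value = p, n = n, computable = TRUE)
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling. The two-sided p-value is exact (by
#' complete enumeration of rank assignments) when both group sizes are at most
#' `exact_max_n` and there are no ties; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' U counts pairs (x_i, y_j) with x_i > y_j, ties counting one half, so
#' U = 0 when every x lies below every y.
#'
#' @param x,y numeric vectors (the two groups).
#' @param exact_max_n enumeration limit per group for the exact path.
#' @return List with `U`, `p_value`, `method` ("exact" or "normal_approx"),
#'   `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 10L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  nn <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- n1 * n2 / 2

  if (!ties && max(n1, n2) <= exact_max_n) {
    # complete enumeration of which ranks the first group occupies
    combs <- utils::combn(nn, n1)
    uvals <- colSums(matrix(seq_len(nn)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(uvals - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact", n1 = n1, n2 = n2))
  }

  tab <- table(c(x, y))
  tie_term <- sum(tab^3 - tab) / (nn * (nn - 1))
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations identical
    return(list(U = U, p_value = 1, method = "normal_approx",
                n1 = n1, n2 = n2))
  }
  d <- U - mu
  cc <- if (d > 0) -0.5 else if (d < 0) 0.5 else 0
  z <- (d + cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal_approx", n1 = n1, n2 = n2)
}

#' Unpaired two-sample t test
#'
#' Student's pooled-variance two-sample t test by default; Welch's unequal
#' variance form via `welch = TRUE`.
#'
#' @param x,y numeric vectors.
#' @param welch use the Welch-Satterthwaite form.
#' @return List with `statistic`, `df`, `p_value`, `n1`, `n2`.
#' @export
t_test_unpaired <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df = df), n1 = n1, n2 = n2)
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk test to each group; if both groups are compatible
#' with normality at level `alpha` the groups are compared by an unpaired
#' Student t test, otherwise by the Mann-Whitney test. The route taken is
#' recorded, so downstream tables can report which test produced each p-value.
#'
#' @param x,y numeric vectors, each with at least 3 finite values.
#' @param alpha significance level for the normality gate.
#' @param welch use Welch's t test on the parametric route.
#' @return A list of class `cavalus_group_comparison` with `test_used`
#'   (`"t_test"` or `"mann_whitney"`), `statistic`, `p_value`, `n1`, `n2`
#'   and `normality_p` (length-2 vector of Shapiro-Wilk p-values).
#' @export
compare_groups <- function(x, y, alpha = 0.05, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L) {
    stop("need at least 3 finite observations per group")
  }
  swx <- shapiro_wilk(x); swy <- shapiro_wilk(y)
  # a constant group can never pass the gate (normality is untestable and a
  # t test would divide by zero variance) -> nonparametric route
  px <- if (swx$computable) swx$p_value else 0
  py <- if (swy$computable) swy$p_value else 0
  if (px >= alpha && py >= alpha) {
    tt <- t_test_unpaired(x, y, welch = welch)
    res <- list(test_used = "t_test", statistic = tt$statistic,
                p_value = tt$p_value, n1 = tt$n1, n2 = tt$n2,
                normality_p = c(px, py))
  } else {
    mw <- mann_whitney(x, y)
    res <- list(test_used = "mann_whitney", statistic = mw$U,
                p_value = mw$p_value, n1 = mw$n1, n2 = mw$n2,
                normality_p = c(px, py))
  }
  structure(res, class = "cavalus_group_comparison")
}

#' Bland-Altman agreement statistics
#'
#' Paired-difference agreement: bias is the mean of d = a - b and the 95%
#' limits of agreement are bias +/- 1.96 times the sample standard deviation
#' of d (n - 1 denominator). Pairs with missing values are dropped.
#'
#' @param a,b paired numeric vectors (e.g. two observers' scores).
#' @param pair_label optional label carried into the result.
#' @return A list of class `cavalus_agreement` with `pair_label`, `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `n`, `computable`.
#' @export
bland_altman <- function(a, b, pair_label = "a vs b") {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 3L) {
    return(structure(list(pair_label = pair_label, bias = NA_real_,
                          loa_low = NA_real_, loa_high = NA_real_,
                          sd_diff = NA_real_, n = n, computable = FALSE),
                     class = "cavalus_agreement"))
  }
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(pair_label = pair_label, bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 sd_diff = s, n = n, computable = TRUE),
            class = "cavalus_agreement")
}

#' @export
print.cavalus_group_comparison <- function(x, ...) {
  cat(sprintf("Two-group comparison (%s): statistic = %.4g, p = %.4g (n = %d/%d)\n",
              x$test_used, x$statistic, x$p_value, x$n1, x$n2))
  cat(sprintf("  Shapiro-Wilk gate p-values: %.4g, %.4g\n",
              x$normality_p[1], x$normality_p[2]))
  invisible(x)
}

#' @export
print.cavalus_agreement <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("%s: bias = %.3f, 95%% LOA [%.3f, %.3f], n = %d\n",
                x$pair_label, x$bias, x$loa_low, x$loa_high, x$n))
  } else {
    cat(sprintf("%s: not computable (n = %d complete pairs)\n",
                x$pair_label, x$n))
  }
  invisible(x)
}
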