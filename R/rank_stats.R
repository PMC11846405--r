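#' @title Rank-based statistics
#' @description
#' The statistical layer used to compare regulatory groups: median and
#' interquartile-range (P25-P75) summaries, a Mann-Whitney U test with
#' midranks, tie-corrected variance, continuity correction and an exact
#' small-sample mode, and a Shapiro-Wilk normality gate. All tests are
#' two-tailed; the conventional significance level is 5%.
#' @name rank-stats
NULL

#' Median and interquartile range of a sample
#'
#' @param values Numeric vector, `n >= 1`.
#' @param type Quantile convention for P25/P75, passed to
#'   [stats::quantile()] (default 7, linear interpolation between order
#'   statistics). The median is always the standard order-statistic median.
#'
#' @return An object of class `cbd_summary`: list with `n`, `median`,
#'   `p25`, `p75` and `quantile_type` (the convention is recorded so
#'   reports are self-describing).
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 10))
median_iqr <- function(values, type = 7) {
  if (length(values) == 0 || !is.numeric(values) || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.75), type = type,
                       names = FALSE)
  structure(list(n = length(values),
                 median = stats::median(values),
                 p25 = q[1], p75 = q[2],
                 quantile_type = type),
            class = "cbd_summary")
}

#' @export
print.cbd_summary <- function(x, ...) {
  cat(sprintf("<cbd_summary> n=%d median %.1f (IQR: %.2f-%.2f) [quantile type %d]\n",
              x$n, x$median, x$p25, x$p75, x$quantile_type))
  invisible(x)
}

#' @export
format.cbd_summary <- function(x, ...) {
  sprintf("%.1f (IQR: %.2f-%.2f), n=%d", x$median, x$p25, x$p75, x$n)
}

# Exact null distribution of U for tie-free samples, by count recursion:
# c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u). Counts are exact in doubles
# for every size this package uses (max count C(n1+n2, n1) < 2^53 up to
# n1 = n2 = 26).
u_null_counts <- function(n1, n2) {
  C <- vector("list", n1 + 1)
  for (m in 0:n1) C[[m + 1]] <- vector("list", n2 + 1)
  for (n in 0:n2) C[[1]][[n + 1]] <- 1
  if (n1 >= 1) {
    for (m in 1:n1) {
      C[[m + 1]][[1]] <- 1
      if (n2 >= 1) {
        for (n in 1:n2) {
          a <- C[[m]][[n + 1]]     # c(m-1, n, .): shift by n
          b <- C[[m + 1]][[n]]     # c(m, n-1, .)
          len <- m * n + 1
          av <- numeric(len)
          av[(n + 1):len] <- a
          bv <- numeric(len)
          bv[seq_along(b)] <- b
          C[[m + 1]][[n + 1]] <- av + bv
        }
      }
    }
  }
  C[[n1 + 1]][[n2 + 1]]
}

# Exact null of midrank U under ties: enumerate all choose(N, n1)
# assignments of the combined midranks to group 1. Feasible only for
# small N (gated at N <= 12 by the caller).
u_exact_p_ties <- function(r, n1, u_obs) {
  n <- length(r)
  idx <- utils::combn(n, n1)
  offset <- n1 * (n1 + 1) / 2
  us <- colSums(matrix(r[idx], nrow = n1)) - offset
  eps <- 1e-9
  lower <- mean(us <= u_obs + eps)
  upper <- mean(us >= u_obs - eps)
  min(1, 2 * min(lower, upper))
}

#' Mann-Whitney U test for two independent samples
#'
#' U is computed from midranks (tied observations share the average rank);
#' `u_statistic` is the U of the first sample, so
#' `u(x, y) + u(y, x) = n1 * n2`. The two-sided p-value is
#' `2 * min(lower tail, upper tail)` capped at 1.
#'
#' Modes:
#' \itemize{
#'   \item `exact` enumerates the permutation null -- by a count-based
#'     recursion over the tie-free U distribution, or, when ties are
#'     present, by direct enumeration of all group assignments (available
#'     only for `n1 + n2 <= 12`);
#'   \item `normal_approx` uses the tie-corrected variance
#'     `n1 n2 / 12 * ((N + 1) - sum(t^3 - t) / (N (N - 1)))` with a 0.5
#'     continuity correction;
#'   \item `auto` (default) selects `exact` when `n1 * n2 <= 400` and the
#'     combined sample has no ties, else `normal_approx`.
#' }
#' Degenerate input (every observation in both samples identical) returns
#' `p = 1` with the `degenerate` flag set.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#'
#' @return An object of class `cbd_ranktest`: list with `u_statistic`,
#'   `method`, `p_two_sided`, `n1`, `n2`, `tie_correction_applied`,
#'   `degenerate`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_two_sided # 1/3 by exact enumeration
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx"),
                           continuity = TRUE) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stop("samples must be numeric without NA", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  combined <- c(x, y)
  n <- n1 + n2
  r <- rank(combined)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_tab <- table(combined)
  has_ties <- any(tie_tab > 1)
  degenerate <- length(tie_tab) == 1
  if (mode == "auto") {
    mode <- if (!has_ties && n1 * n2 <= 400) "exact" else "normal_approx"
  }
  if (degenerate) {
    return(structure(list(u_statistic = u, method = mode, p_two_sided = 1,
                          n1 = n1, n2 = n2,
                          tie_correction_applied = has_ties,
                          degenerate = TRUE),
                     class = "cbd_ranktest"))
  }
  if (mode == "exact") {
    if (has_ties) {
      if (n > 12) {
        stop("exact mode with ties is available only for n1 + n2 <= 12 ",
             "(got ", n, "); use mode = \"normal_approx\"", call. = FALSE)
      }
      p <- u_exact_p_ties(r, n1, u)
    } else {
      counts <- u_null_counts(n1, n2)
      total <- sum(counts)
      k <- round(u) # tie-free U is integral
      lower <- sum(counts[seq_len(k + 1)]) / total
      upper <- sum(counts[(k + 1):length(counts)]) / total
      p <- min(1, 2 * min(lower, upper))
    }
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    cc <- if (continuity) 0.5 else 0
    z <- max(0, abs(u - mu) - cc) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  structure(list(u_statistic = u, method = mode,
                 p_two_sided = p, n1 = n1, n2 = n2,
                 tie_correction_applied = has_ties,
                 degenerate = FALSE),
            class = "cbd_ranktest")
}

#' @export
print.cbd_ranktest <- function(x, ...) {
  cat(sprintf("<cbd_ranktest> Mann-Whitney U = %g (n1=%d, n2=%d), %s, two-sided p = %.4g%s%s\n",
              x$u_statistic, x$n1, x$n2, x$method, x$p_two_sided,
              if (x$tie_correction_applied) ", tie-corrected" else "",
              if (x$degenerate) " [degenerate: all observations tied]" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' A thin contract-checked front end to the standard Shapiro-Wilk
#' implementation (Royston's coefficient and p-value approximations,
#' valid for 3 <= n <= 5000). Constant samples and out-of-range sizes are
#' rejected with an explanatory error rather than a cryptic failure.
#'
#' @param x Numeric sample.
#'
#' @return An object of class `cbd_normality`: list with `w_statistic`,
#'   `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  if (!is.numeric(x) || anyNA(x)) {
    stop("`x` must be numeric without NA", call. = FALSE)
  }
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("the Shapiro-Wilk approximation is defined for 3 <= n <= 5000 ",
         "(got n = ", n, ")", call. = FALSE)
  }
  if (length(unique(x)) == 1) {
    stop("the Shapiro-Wilk statistic is undefined for a constant sample ",
         "(zero variance)", call. = FALSE)
  }
  res <- stats::shapiro.test(x)
  structure(list(w_statistic = unname(res$statistic),
                 p_value = res$p.value, n = n),
            class = "cbd_normality")
}

#' @export
print.cbd_normality <- function(x, ...) {
  cat(sprintf("<cbd_normality> Shapiro-Wilk W = %.5f, p = %.4g (n=%d)\n",
              x$w_statistic, x$p_value, x$n))
  invisible(x)
}
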