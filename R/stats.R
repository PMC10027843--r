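.test_result <- function(test, statistic, df, p, n, adjusted = FALSE,
                         adjust_method = NA_character_, note = NA_character_) {
  tibble::tibble(test = test, statistic = statistic, df = df, p = p, n = n,
                 adjusted = adjusted, adjust_method = adjust_method,
                 note = note)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalizing transformations of the sample skewness
#' (D'Agostino) and kurtosis (Anscombe-Glynn) into the omnibus statistic
#' `K^2 = Z_skew^2 + Z_kurt^2`, referred to a chi-squared distribution with
#' 2 df. The approximation requires n >= 8; below that the test is
#' reported as inapplicable (`statistic` and `p` are `NA`) rather than as
#' a number.
#'
#' @param x Numeric sample.
#' @return A one-row tibble (see internals: `test`, `statistic`, `df`,
#'   `p`, `n`, ...), with `note = "inapplicable"` when n < 8.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) {
    return(.test_result("dagostino_pearson", NA_real_, NA_real_, NA_real_, n,
                        note = "inapplicable: n < 8"))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness: D'Agostino's Z
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe-Glynn's Z
  b2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  v_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(v_b2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
               ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- z_skew^2 + z_kurt^2
  .test_result("dagostino_pearson", k2, 2,
               stats::pchisq(k2, 2, lower.tail = FALSE), n)
}

#' Paired Student's t-test
#'
#' Classical paired t on the within-pair differences. Two-tailed by
#' default; the one-tailed p (for the observed direction) is carried in
#' `note` so directional reports can be cross-checked.
#'
#' @param x,y Matched numeric samples of equal length (pairs with a
#'   missing member are dropped).
#' @return A one-row test-result tibble.
#' @export
paired_t <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  if (stats::sd(x - y) <= .Machine$double.eps^0.5) {
    if (abs(mean(x - y)) <= .Machine$double.eps^0.5) {
      # identical samples: no difference at all, not a degenerate one
      return(.test_result("paired_t", 0, length(x) - 1, 1, length(x),
                          note = "one_tailed_p=0.5"))
    }
    stop("zero-variance differences: paired t undefined", call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .test_result("paired_t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, length(x),
               note = sprintf("one_tailed_p=%.6g", tt$p.value / 2))
}

#' Unpaired (two-group) Student's t-test
#'
#' Classical equal-variance two-sample t, two-tailed; used for the
#' between-channel pulse-amplitude and pulse-rate comparisons.
#'
#' @param x,y Numeric samples.
#' @return A one-row test-result tibble. If either group has zero variance
#'   and the groups are identical, the comparison is reported as
#'   inapplicable (`p = NA`) -- the all-zero post-euthanasia pulse-rate
#'   comparison is the canonical case.
#' @export
group_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (stats::sd(c(x, y)) <= .Machine$double.eps^0.5) {
    return(.test_result("group_t", NA_real_, NA_real_, NA_real_,
                        length(x) + length(y),
                        note = "inapplicable: zero variance in both groups"))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  .test_result("group_t", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, length(x) + length(y))
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak correction: the i-th smallest of m p-values becomes
#' `1 - (1 - p_(i))^(m - i + 1)`, enforced monotone non-decreasing.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way repeated-measures ANOVA with adjusted post-hoc comparisons
#'
#' Omnibus F from the standard subject-stratified ANOVA
#' (`value ~ condition + Error(subject)`), followed by all pairwise paired
#' t-tests with Holm-Sidak-adjusted p-values (the adjustment method is
#' recorded in the result, since "adjusted" alone is ambiguous).
#'
#' @param values Numeric matrix, subjects x conditions, complete (the
#'   design this battery serves is complete; missing cells are rejected).
#' @return A list with `omnibus` (one-row test-result tibble) and
#'   `posthoc` (tibble: `condition_a`, `condition_b`, `t`, `df`, `p_raw`,
#'   `p_adj`, `adjust_method`).
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    stop("missing cells: repeated-measures design must be complete",
         call. = FALSE)
  }
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  }
  conds <- colnames(values) %||% paste0("c", seq_len(ncol(values)))
  long <- data.frame(
    value = as.vector(values),
    condition = factor(rep(conds, each = nrow(values)), levels = conds),
    subject = factor(rep(seq_len(nrow(values)), times = ncol(values)))
  )
  fit <- stats::aov(value ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  f <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  # degenerate 0/0 case (identical conditions): both sums of squares vanish
  # up to round-off and the F ratio is numerical junk
  tot <- sum((values - mean(values))^2)
  if (!is.finite(f) ||
      tab["condition", "Sum Sq"] <= 1e-12 * max(tot, 1)) {
    f <- 0
  }
  omnibus <- .test_result("rm_anova_F", f, df1,
                          stats::pf(f, df1, df2, lower.tail = FALSE),
                          nrow(values),
                          note = sprintf("df2=%d", df2))
  pairs <- utils::combn(seq_along(conds), 2, simplify = FALSE)
  raw <- purrr::map_dfr(pairs, function(ij) {
    d <- values[, ij[1]] - values[, ij[2]]
    if (stats::sd(d) <= .Machine$double.eps^0.5) {
      return(tibble::tibble(condition_a = conds[ij[1]],
                            condition_b = conds[ij[2]],
                            t = 0, df = nrow(values) - 1, p_raw = 1))
    }
    tt <- stats::t.test(values[, ij[1]], values[, ij[2]], paired = TRUE)
    tibble::tibble(condition_a = conds[ij[1]], condition_b = conds[ij[2]],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value)
  })
  raw$p_adj <- holm_sidak(raw$p_raw)
  raw$adjust_method <- "holm-sidak"
  list(omnibus = omnibus, posthoc = raw)
}
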