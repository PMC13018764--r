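#' McNemar's chi-square test on discordant pair counts
#'
#' \eqn{\chi^2 = (|b - c| - k)^2 / (b + c)} with \eqn{k = 1} under the
#' continuity correction and 0 otherwise; the p value is the upper tail of
#' the chi-square distribution with 1 degree of freedom. `b` and `c` are
#' the two discordant counts (here: participants scoring `Parent more` and
#' `Doctor more`); concordant (`Equal`) cases do not enter the test.
#'
#' @param b,c_ Non-negative discordant counts.
#' @param continuity Apply the continuity correction (default TRUE).
#' @return List with `statistic` and `p.value`.
#' @export
mcnemar_test <- function(b, c_, continuity = TRUE) {
  if (b < 0 || c_ < 0) {
    stop2("phenopair_validation_error", "discordant counts must be >= 0")
  }
  if (b + c_ == 0) {
    stop2("phenopair_undefined_test",
          "McNemar test undefined: no discordant pairs")
  }
  k <- if (continuity) 1 else 0
  # R clamps the corrected difference at zero so b ~ c cannot yield a
  # positive statistic; we follow that convention
  stat <- (max(abs(b - c_) - k, 0))^2 / (b + c_)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure: sort p ascending, compute `p * m / i`, then
#' enforce monotonicity by a cumulative minimum from the largest rank down;
#' results are returned in the input order and capped at 1.
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(p) {
  check_p(p)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  i <- m:1L
  q <- pmin(1, cummin(p[o] * m / i))
  q[order(o)]
}

#' Holm step-down family-wise-error adjustment
#'
#' @inheritParams bh_adjust
#' @return Adjusted p values, same order as input.
#' @export
holm_adjust <- function(p) {
  check_p(p)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1L)))
  q[order(o)]
}

check_p <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop2("phenopair_validation_error", "p values must lie in [0, 1]")
  }
}

check_groups <- function(groups) {
  if (length(groups) < 2L) {
    stop2("phenopair_validation_error", "need at least 2 groups")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (nm in names(groups)) {
    x <- groups[[nm]]
    if (length(x) < 2L || stats::var(x) <= 0) {
      stop2("phenopair_degenerate_group",
            "group '", nm, "' needs >= 2 observations and positive variance")
    }
  }
  groups
}

#' Welch one-way analysis of variance
#'
#' Heteroscedasticity-robust one-way ANOVA (Welch's F) with the
#' Satterthwaite-style denominator degrees of freedom; equivalent to
#' `stats::oneway.test(..., var.equal = FALSE)`.
#'
#' @param groups Named list of numeric vectors, each with at least two
#'   observations and positive variance.
#' @return List with `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
welch_anova <- function(groups) {
  groups <- check_groups(groups)
  n <- vapply(groups, length, numeric(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  w <- n / v
  W <- sum(w)
  k <- length(groups)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  f <- A / B
  df2 <- (k^2 - 1) / (3 * lam)
  list(statistic = f, df1 = k - 1, df2 = df2,
       p.value = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

#' Welch two-sample t test (two-sided)
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (t), `df`, `p.value`.
#' @export
welch_t <- function(x, y) {
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                 (stats::var(y) / length(y))^2 / (length(y) - 1))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' All pairwise Welch t tests with Holm adjustment
#'
#' Tests every unordered pair of groups with Welch's t and applies Holm's
#' sequential adjustment across the pair family.
#'
#' @inheritParams welch_anova
#' @param family Family label recorded on each result row.
#' @return Data.frame of test results (`family`, `scope` = "a vs b",
#'   `statistic`, `p_raw`, `p_adjusted`, `method`, `n`).
#' @export
pairwise_welch_holm <- function(groups, family = "pairwise") {
  groups <- check_groups(groups)
  nms <- names(groups)
  pairs <- utils::combn(nms, 2L, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    tst <- welch_t(groups[[pr[1]]], groups[[pr[2]]])
    data.frame(family = family, scope = paste(pr[1], "vs", pr[2]),
               statistic = tst$statistic, p_raw = tst$p.value,
               p_adjusted = NA_real_, method = "welch_t+holm",
               n = length(groups[[pr[1]]]) + length(groups[[pr[2]]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- holm_adjust(out$p_raw)
  out
}
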