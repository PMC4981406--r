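# --- null-distribution engines ---------------------------------------------
# Both tests use average ranks; doubling the ranks makes every attainable
# statistic an integer, so the exact null distributions are built by integer
# polynomial convolution (equivalent to full enumeration over sign
# assignments / group assignments, but O(n * max rank sum)).

# distribution of 2*W+ over all 2^n sign assignments; returns counts indexed
# by value 0..sum(r2)
signed_rank_null <- function(r2) {
  v <- 1
  for (r in r2) {
    nv <- c(v, numeric(r))
    nv[(r + 1):(r + length(v))] <- nv[(r + 1):(r + length(v))] + v
    v <- nv
  }
  v
}

# counts of size-m subsets of r2 by 2*(rank sum); matrix row = subset size
rank_sum_null <- function(r2, m) {
  total <- sum(r2)
  dp <- matrix(0, nrow = m + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (r in r2) {
    dp_new <- dp
    dp_new[2:(m + 1), (r + 1):(total + 1)] <-
      dp_new[2:(m + 1), (r + 1):(total + 1)] + dp[1:m, 1:(total + 1 - r)]
    dp <- dp_new
  }
  dp[m + 1, ]
}

tail_probs <- function(counts, w2, total_outcomes) {
  vals <- seq_along(counts) - 1 # attainable 2*W values
  pg <- sum(counts[vals >= w2 - 1e-9]) / total_outcomes
  pl <- sum(counts[vals <= w2 + 1e-9]) / total_outcomes
  c(greater = pg, less = pl)
}

pick_p <- function(pg, pl, alternative) {
  switch(alternative,
         greater = pg,
         less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

signed_rank_engine <- function(x, y, alternative, exact_max = 15) {
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_used = 0L, n_zero = n_zero,
                exact = TRUE, degenerate = TRUE))
  }
  rk <- rank(abs(d))
  w <- sum(rk[d > 0])
  if (n <= exact_max) {
    counts <- signed_rank_null(round(2 * rk))
    tp <- tail_probs(counts, 2 * w, 2^n)
    p <- pick_p(tp["greater"], tp["less"], alternative)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    pg <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    pl <- stats::pnorm((w - mu + 0.5) / sigma)
    p <- pick_p(pg, pl, alternative)
    exact <- FALSE
  }
  list(statistic = w, p_value = unname(p), n_used = n, n_zero = n_zero,
       exact = exact, degenerate = FALSE)
}

rank_sum_engine <- function(a, b, alternative, exact_max = 12) {
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) abort("both groups must be nonempty")
  pooled <- c(a, b)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(m)])
  if (m + n <= exact_max) {
    counts <- rank_sum_null(round(2 * rk), m)
    tp <- tail_probs(counts, 2 * w, choose(m + n, m))
    p <- pick_p(tp["greater"], tp["less"], alternative)
    exact <- TRUE
  } else {
    mu <- m * (m + n + 1) / 2
    ties <- table(rk)
    sigma2 <- m * n * (m + n + 1) / 12 -
      m * n * sum(ties^3 - ties) / (12 * (m + n) * (m + n - 1))
    sigma <- sqrt(sigma2)
    pg <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    pl <- stats::pnorm((w - mu + 0.5) / sigma)
    p <- pick_p(pg, pl, alternative)
    exact <- FALSE
  }
  list(statistic = w, p_value = unname(p), n_a = m, n_b = n,
       exact = exact)
}

# --- user-facing comparisons -----------------------------------------------

#' Paired Wilcoxon signed-rank comparison
#'
#' Compares two matched per-cell columns (e.g. the LFP amplitude MI and the
#' PSP amplitude MI of the same cells).  Zero differences are dropped and
#' reported.  For `n <= exact_max` non-zero pairs the p-value comes from the
#' exact null distribution over all sign assignments of the observed
#' (average) ranks; larger samples use the normal approximation with tie
#' correction and continuity correction.  `alternative = "greater"` tests
#' whether `x` tends to exceed `y`.
#'
#' @param data data frame with one row per pair.
#' @param x,y column names (tidy-eval) of the paired values.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param exact_max largest `n` for which the exact distribution is used
#'   (default 15).
#' @return A one-row tibble: `test`, `alternative`, `n_pairs`, `n_used`,
#'   `n_zero`, `statistic` (rank sum of positive differences), `p_value`,
#'   `exact`, `degenerate`, `mean_x`, `mean_y`, `sem_x`, `sem_y`.
#' @export
#' @examples
#' d <- tibble::tibble(lfp = c(.2, .3, .25, .4, .15), psp = c(.1, .2, .2, .1, .1))
#' paired_signed_rank(d, lfp, psp, alternative = "greater") # p = 1/32
paired_signed_rank <- function(data, x, y, alternative = c("greater", "less", "two.sided"),
                               exact_max = 15) {
  alternative <- match.arg(alternative)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) != length(yv)) abort("x and y must be paired (equal length)")
  res <- signed_rank_engine(xv, yv, alternative, exact_max)
  if (res$degenerate) warn("all differences are zero; p = 1 (degenerate)")
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  tibble(
    test = "signed_rank",
    alternative = alternative,
    n_pairs = length(xv),
    n_used = res$n_used,
    n_zero = res$n_zero,
    statistic = res$statistic,
    p_value = res$p_value,
    exact = res$exact,
    degenerate = res$degenerate,
    mean_x = mean(xv), mean_y = mean(yv),
    sem_x = sem(xv), sem_y = sem(yv)
  )
}

#' Unpaired Wilcoxon rank-sum comparison
#'
#' Compares the values of two independent groups (e.g. cells recorded under
#' different anesthetics).  For `m + n <= exact_max` the p-value comes from
#' the exact null distribution over all assignments of the pooled (average)
#' ranks to groups; larger samples use the normal approximation with tie
#' correction and continuity correction.  `alternative = "greater"` tests
#' whether the first group tends to exceed the second.
#'
#' @param data data frame with one row per observation.
#' @param value value column (tidy-eval).
#' @param group grouping column with exactly two levels; the first level
#'   (factor order, or sorted order) is "group a".
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (default).
#' @param exact_max largest `m + n` for which the exact distribution is
#'   used (default 12).
#' @return A one-row tibble: `test`, `alternative`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic` (rank sum of group a), `p_value`, `exact`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`.
#' @export
#' @examples
#' d <- tibble::tibble(v = 1:6, g = rep(c("a", "b"), each = 3))
#' unpaired_rank_sum(d, v, g, alternative = "less") # p = 1/20
unpaired_rank_sum <- function(data, value, group,
                              alternative = c("two.sided", "greater", "less"),
                              exact_max = 12) {
  alternative <- match.arg(alternative)
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  g <- if (is.factor(g)) droplevels(g) else factor(g)
  if (nlevels(g) != 2) abort("group must have exactly two levels")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  res <- rank_sum_engine(a, b, alternative, exact_max)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  tibble(
    test = "rank_sum",
    alternative = alternative,
    group_a = levels(g)[1], group_b = levels(g)[2],
    n_a = res$n_a, n_b = res$n_b,
    statistic = res$statistic,
    p_value = res$p_value,
    exact = res$exact,
    mean_a = mean(a), mean_b = mean(b),
    sem_a = sem(a), sem_b = sem(b)
  )
}

#' Group means with standard errors
#'
#' Mean, SEM (`sd / sqrt(n)`) and count of `value_bits` (or another value
#' column) within each combination of the grouping columns.  A group of a
#' single observation gets SEM 0 with `sem_defined = FALSE`.
#'
#' @param data data frame (typically an MI table from
#'   [estimate_mi_features()]).
#' @param ... grouping columns (tidy-eval), e.g. `signal_type, feature`.
#' @param value value column (default `value_bits`).
#' @return A tibble with one row per group: groups, `mean`, `sem`, `n`,
#'   `sem_defined`.
#' @export
#' @examples
#' mi_summary(tibble::tibble(g = c("a", "a", "a"), value_bits = c(.1, .2, .3)), g)
mi_summary <- function(data, ..., value = "value_bits") {
  if (nrow(data) == 0) abort("empty selection")
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      sem_defined = dplyr::n() > 1,
      .groups = "drop"
    )
}
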