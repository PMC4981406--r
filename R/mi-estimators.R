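#' @title MI estimate objects
#' @description Constructor for the result object shared by all estimators.
#' @keywords internal
new_mi_estimate <- function(value_bits, estimator, params, n_samples,
                            clamped = FALSE, diagnostics = NULL) {
  structure(
    list(
      value_bits = value_bits,
      estimator = estimator,
      params = params,
      n_samples = n_samples,
      clamped = clamped,
      diagnostics = diagnostics
    ),
    class = "mi_estimate"
  )
}

#' @export
print.mi_estimate <- function(x, ...) {
  par_str <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat(sprintf("<mi_estimate> %s (%s), n = %d\n", x$estimator, par_str, x$n_samples))
  cat(sprintf("  I = %.4f bits%s\n", x$value_bits,
              if (isTRUE(x$clamped)) " (clamped at 0)" else ""))
  skipped <- x$diagnostics$skipped_points
  if (!is.null(skipped) && skipped > 0) {
    cat(sprintf("  %d point(s) skipped (no same-label neighbour)\n", skipped))
  }
  invisible(x)
}

#' @export
tidy.mi_estimate <- function(x, ...) {
  tibble(
    estimator = x$estimator,
    !!!x$params,
    n_samples = x$n_samples,
    value_bits = x$value_bits,
    clamped = x$clamped
  )
}

#' @export
glance.mi_estimate <- function(x, ...) {
  skipped <- x$diagnostics$skipped_points
  tibble(
    estimator = x$estimator,
    n_samples = x$n_samples,
    value_bits = x$value_bits,
    clamped = x$clamped,
    skipped_points = if (is.null(skipped)) 0L else skipped
  )
}

check_samples <- function(data, stimulus, response) {
  s <- data[[stimulus]]
  r <- data[[response]]
  if (is.null(s) || is.null(r)) {
    abort(sprintf("data must have columns '%s' and '%s'", stimulus, response))
  }
  if (any(!is.finite(r))) abort("non-finite response values")
  list(s = factor(s), r = as.numeric(r))
}

#' k-nearest-neighbour mutual information between a discrete stimulus and a
#' continuous response
#'
#' Ross-type estimator for discrete-continuous pairs.  For each point `i`
#' with same-label count \eqn{N_{S_i} \ge 2}: the distance \eqn{d_i} to its
#' \eqn{k_i}-th nearest same-label neighbour (\eqn{k_i = \min(k, N_{S_i}-1)},
#' absolute difference on the response axis, `i` excluded) is found, then
#' \eqn{m_i} counts points of any label with \eqn{|r_j - r_i| \le d_i}
#' (closed ball, `i` excluded) and
#' \deqn{I_i = \psi(N) - \psi(N_{S_i}) + \psi(k_i) - \psi(m_i)}
#' in nats.  The estimate is the mean of \eqn{I_i} over retained points,
#' converted to bits.  Points whose label occurs only once have no same-label
#' neighbour; they are excluded from the average and counted in
#' `skipped_points` (with a warning).  Exact response ties inflate \eqn{m_i};
#' the estimator is intended for continuous features.
#'
#' The estimator is exactly invariant under affine maps of the response and
#' can return small negative values on weakly informative data; see
#' [clamp_mi()].
#'
#' @param data data frame of labelled samples.
#' @param k number of same-label neighbours (default 3).
#' @param stimulus,response names of the label and response columns.
#' @return An object of class `mi_estimate` (`estimator = "knn"`) with
#'   per-point diagnostics (`N_Si`, `k_i`, `d_i`, `m_i`, `I_i` in nats,
#'   `skipped_points`).
#' @export
#' @examples
#' d <- sample_mixture(gaussian_pair_spec(), n = 400, seed = 42)
#' mi_knn(d, k = 3)
mi_knn <- function(data, k = 3, stimulus = "stimulus", response = "response") {
  if (k < 1) abort("k must be >= 1")
  sr <- check_samples(data, stimulus, response)
  s <- sr$s; r <- sr$r
  n <- length(r)
  if (n < 2) abort("no estimable points")
  counts <- table(s)
  n_si <- as.vector(counts[s])
  if (all(counts < 2)) abort("no estimable points")
  retained <- which(n_si >= 2)
  skipped <- n - length(retained)
  if (skipped > 0) {
    warn(sprintf("%d point(s) skipped: label occurs only once", skipped))
  }
  idx_by_class <- split(seq_len(n), s, drop = TRUE)
  k_i <- pmin(k, n_si - 1L)
  d_i <- rep(NA_real_, n)
  m_i <- rep(NA_integer_, n)
  for (idx in idx_by_class) {
    if (length(idx) < 2) next
    rv <- r[idx]
    for (a in seq_along(idx)) {
      i <- idx[a]
      dd <- abs(rv[-a] - rv[a])
      ki <- k_i[i]
      d <- sort(dd, partial = ki)[ki]
      d_i[i] <- d
      m_i[i] <- sum(abs(r - r[i]) <= d) - 1L
    }
  }
  ii <- digamma(n) - digamma(n_si[retained]) +
    digamma(k_i[retained]) - digamma(m_i[retained])
  diag <- list(
    per_point = tibble(
      index = retained,
      N_Si = n_si[retained],
      k_i = k_i[retained],
      d_i = d_i[retained],
      m_i = m_i[retained],
      I_i = ii
    ),
    skipped_points = skipped
  )
  new_mi_estimate(
    value_bits = mean(ii) / log(2),
    estimator = "knn",
    params = list(k = k),
    n_samples = n,
    diagnostics = diag
  )
}

# bin assignment + contingency counts shared by the binned estimators
binned_joint <- function(s, r, n_bins) {
  rng <- range(r)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(r))
    edges <- c(rng[1], rng[2])
  } else {
    width <- (rng[2] - rng[1]) / n_bins
    bin <- pmin(floor((r - rng[1]) / width) + 1L, n_bins)
    edges <- rng[1] + width * (0:n_bins)
  }
  m <- nlevels(s)
  counts <- matrix(
    tabulate((as.integer(s) - 1L) * n_bins + bin, nbins = m * n_bins),
    nrow = m, ncol = n_bins, byrow = TRUE
  )
  list(edges = edges, counts = counts)
}

plugin_mi_bits <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  ps <- rowSums(p)
  pb <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(ps, pb)[pos]))
}

#' Binned (plug-in) mutual information
#'
#' Groups the continuous response into `n_bins` equal-width bins spanning
#' the observed range (the maximum falls in the last bin), forms the
#' stimulus-by-bin contingency table, and plugs the relative frequencies
#' into the discrete MI formula with base-2 logs (`0 log 0 = 0`).  This
#' plug-in ("naive") estimator is positively biased at small sample sizes,
#' increasingly so as `n_bins` grows; see [mi_qe()] for the standard
#' extrapolation correction.
#'
#' @inheritParams mi_knn
#' @param n_bins number of equal-width response bins (`>= 1`).
#' @return An `mi_estimate` (`estimator = "binned_naive"`) whose diagnostics
#'   hold the bin edges and the contingency table.
#' @export
#' @examples
#' d <- tibble::tibble(stimulus = c(1, 1, 2, 2), response = c(0, 0, 1, 1))
#' mi_binned(d, n_bins = 2) # 1 bit
mi_binned <- function(data, n_bins, stimulus = "stimulus", response = "response") {
  if (n_bins < 1) abort("n_bins must be >= 1")
  n_bins <- as.integer(n_bins)
  sr <- check_samples(data, stimulus, response)
  if (length(sr$r) < 1) abort("empty sample set")
  bj <- binned_joint(sr$s, sr$r, n_bins)
  new_mi_estimate(
    value_bits = plugin_mi_bits(bj$counts),
    estimator = "binned_naive",
    params = list(n_bins = n_bins),
    n_samples = length(sr$r),
    diagnostics = list(bin_edges = bj$edges, counts = bj$counts)
  )
}

#' Fit the quadratic-extrapolation bias model through three naive estimates
#'
#' Solves the exactly determined system
#' \deqn{I_{naive}(N_j) = I_{true} + a/N_j + b/N_j^2, \quad j = 1, 2, 3}
#' for `(I_true, a, b)`.  Exposed separately so the extrapolation can be
#' exercised on stubbed bias curves.
#'
#' @param i_naive naive MI estimates (bits) at the three sample sizes.
#' @param n_sizes the three distinct sample sizes (typically `N`, `N/2`,
#'   `N/4`).
#' @return A list with `i_true`, `a`, `b` and the input points.
#' @export
#' @examples
#' qe_fit(c(2, 3, 5), c(400, 200, 100)) # i_true = 1, a = 400, b = 0
qe_fit <- function(i_naive, n_sizes) {
  if (length(i_naive) != 3 || length(n_sizes) != 3) {
    abort("qe_fit needs exactly three (estimate, size) pairs")
  }
  if (anyDuplicated(n_sizes)) abort("sample sizes must be distinct (singular system)")
  a_mat <- cbind(1, 1 / n_sizes, 1 / n_sizes^2)
  coef <- solve(a_mat, i_naive)
  list(
    i_true = coef[[1]], a = coef[[2]], b = coef[[3]],
    inputs = tibble(n = as.numeric(n_sizes), i_naive = as.numeric(i_naive))
  )
}

#' Quadratic-extrapolation (QE) corrected binned mutual information
#'
#' The limited-sampling bias of the plug-in estimator is approximately
#' \eqn{a/N + b/N^2}.  The data are randomly partitioned (seeded) into 2
#' halves and, independently, 4 quarters; the naive estimate is computed on
#' the full set, averaged over the halves, and averaged over the quarters,
#' and the bias model is extrapolated to \eqn{N \to \infty} via [qe_fit()].
#'
#' @inheritParams mi_binned
#' @param seed integer seed for the random partitions.
#' @return An `mi_estimate` (`estimator = "binned_qe"`) whose `value_bits`
#'   is the extrapolated `I_true`; diagnostics hold the [qe_fit()] result.
#' @export
mi_qe <- function(data, n_bins, seed, stimulus = "stimulus", response = "response") {
  if (n_bins < 1) abort("n_bins must be >= 1")
  sr <- check_samples(data, stimulus, response)
  n <- length(sr$r)
  if (n < 8) abort("too-small partitions: need at least 2 samples per quarter")
  parts <- withr::with_seed(seed, {
    list(half = sample(rep_len(1:2, n)), quarter = sample(rep_len(1:4, n)))
  })
  naive <- function(keep) {
    plugin_mi_bits(binned_joint(sr$s[keep], sr$r[keep], as.integer(n_bins))$counts)
  }
  i_full <- naive(rep(TRUE, n))
  i_half <- mean(vapply(1:2, function(g) naive(parts$half == g), numeric(1)))
  i_quarter <- mean(vapply(1:4, function(g) naive(parts$quarter == g), numeric(1)))
  fit <- qe_fit(c(i_full, i_half, i_quarter), c(n, n / 2, n / 4))
  new_mi_estimate(
    value_bits = fit$i_true,
    estimator = "binned_qe",
    params = list(n_bins = as.integer(n_bins)),
    n_samples = n,
    diagnostics = list(qe = fit, seed = seed)
  )
}

#' Clamp a negative MI estimate at zero
#'
#' Nearest-neighbour MI estimates can come out slightly negative on weakly
#' informative data (a known small-sample artifact); such values are set to
#' zero.  Clamping is applied per cell and feature, before any averaging
#' across cells.
#'
#' @param estimate an `mi_estimate`.
#' @return The estimate with `value_bits = max(value_bits, 0)` and the
#'   `clamped` flag set.
#' @export
clamp_mi <- function(estimate) {
  stopifnot(inherits(estimate, "mi_estimate"))
  estimate$value_bits <- max(estimate$value_bits, 0)
  estimate$clamped <- TRUE
  estimate
}

#' Read / write labelled sample sets
#'
#' CSV interchange format with header `stimulus,response`.
#' @param path file path.
#' @return `read_samples()`: a tibble with `stimulus` (factor) and
#'   `response` (double).
#' @export
read_samples <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    stimulus = readr::col_character(),
    response = readr::col_double()
  ))
  d$stimulus <- factor(d$stimulus)
  d
}

#' @rdname read_samples
#' @param data tibble with columns `stimulus` and `response`.
#' @export
write_samples <- function(data, path) {
  readr::write_csv(data[, c("stimulus", "response")], path)
  invisible(path)
}

#' Serialize an MI estimate as a JSON record
#'
#' @param estimate an `mi_estimate`.
#' @param path output path.
#' @export
write_mi_estimate <- function(estimate, path) {
  skipped <- estimate$diagnostics$skipped_points
  rec <- list(
    estimator = estimate$estimator,
    params = estimate$params,
    n_samples = estimate$n_samples,
    value_bits = estimate$value_bits,
    clamped = estimate$clamped,
    skipped_points = if (is.null(skipped)) 0L else skipped
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
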