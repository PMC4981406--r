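# Independent oracles, written as plainly as possible: full O(N^2) scans and
# explicit enumeration, sharing no code with the package internals.

# Ross-type discrete-continuous MI by brute force (bits)
brute_knn_mi <- function(s, r, k) {
  s <- as.character(s)
  n <- length(r)
  ii <- c()
  for (i in seq_len(n)) {
    same <- setdiff(which(s == s[i]), i)
    n_si <- length(same) + 1
    if (n_si < 2) next
    ki <- min(k, n_si - 1)
    d <- sort(abs(r[same] - r[i]))[ki]
    m_i <- 0
    for (j in seq_len(n)) {
      if (j != i && abs(r[j] - r[i]) <= d) m_i <- m_i + 1
    }
    ii <- c(ii, digamma(n) - digamma(n_si) + digamma(ki) - digamma(m_i))
  }
  mean(ii) / log(2)
}

# exact signed-rank p by enumerating every sign assignment
brute_signed_rank_p <- function(x, y, alternative) {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^n - 1), function(code) {
    signs <- as.integer(intToBits(code))[1:n] == 1
    sum(rk[signs])
  }, numeric(1))
  pg <- mean(ws >= w_obs - 1e-9)
  pl <- mean(ws <= w_obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl, two.sided = min(1, 2 * min(pg, pl)))
}

# exact rank-sum p by enumerating every assignment of ranks to group a
brute_rank_sum_p <- function(a, b, alternative) {
  m <- length(a)
  rk <- rank(c(a, b))
  w_obs <- sum(rk[seq_len(m)])
  ws <- apply(combn(length(rk), m), 2, function(idx) sum(rk[idx]))
  pg <- mean(ws >= w_obs - 1e-9)
  pl <- mean(ws <= w_obs + 1e-9)
  switch(alternative,
         greater = pg, less = pl, two.sided = min(1, 2 * min(pg, pl)))
}

# Monte Carlo MI for a two-column mixture spec (independent of quadrature):
# average of log2 f_s(r) / fbar(r) over simulated draws
mc_mixture_mi <- function(spec, n, seed) {
  withr::with_seed(seed, {
    cls <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$prior)
    dens <- function(j, r) {
      if (spec$family[j] == "gaussian") {
        dnorm(r, spec$location[j], spec$scale[j])
      } else {
        dunif(r, spec$location[j] - spec$scale[j] / 2,
              spec$location[j] + spec$scale[j] / 2)
      }
    }
    r <- vapply(cls, function(j) {
      if (spec$family[j] == "gaussian") {
        rnorm(1, spec$location[j], spec$scale[j])
      } else {
        runif(1, spec$location[j] - spec$scale[j] / 2,
              spec$location[j] + spec$scale[j] / 2)
      }
    }, numeric(1))
    fs <- vapply(seq_along(r), function(i) dens(cls[i], r[i]), numeric(1))
    fbar <- rowSums(vapply(seq_len(nrow(spec)),
                           function(j) spec$prior[j] * dens(j, r),
                           numeric(length(r))))
    mean(log2(fs / fbar))
  })
}

# one-row sweep table from a bare trace
make_sweep <- function(values, signal_type = "PSP", fs = 4000, onset_s = 0.015,
                       cell_id = "cell1", trial_id = 1L, freq = 8000) {
  tibble::tibble(
    cell_id = cell_id, trial_id = trial_id, signal_type = signal_type,
    stimulus_freq_hz = freq, sampling_rate = fs, onset_s = onset_s,
    values = list(as.numeric(values))
  )
}
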