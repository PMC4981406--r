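test_that("a single stimulus class carries exactly zero information", {
  d <- tibble::tibble(stimulus = factor(rep("a", 8)),
                      response = c(0, 1, 2.5, 4.1, 7, 11, 16, 22.3))
  est <- mi_knn(d, k = 3)
  expect_identical(est$value_bits, 0)
  expect_equal(est$diagnostics$skipped_points, 0)
})

test_that("the two-cluster hand example evaluates to psi(6) - psi(3) per point", {
  d <- tibble::tibble(
    stimulus = factor(c(1, 1, 1, 2, 2, 2)),
    response = c(0, 0.1, 0.25, 10, 10.1, 10.25)
  )
  est <- mi_knn(d, k = 1)
  expect_equal(est$diagnostics$per_point$I_i, rep(47 / 60, 6), tolerance = 1e-12)
  expect_equal(est$value_bits, (47 / 60) / log(2), tolerance = 1e-12)
  expect_false(est$clamped)
  expect_equal(est$diagnostics$per_point$m_i, rep(1L, 6))
})

test_that("knn estimates match the brute-force oracle on random small instances", {
  withr::with_seed(42, {
    for (rep in 1:60) {
      n <- sample(6:50, 1)
      n_classes <- sample(2:4, 1)
      s <- sample(letters[1:n_classes], n, replace = TRUE)
      # guarantee at least one usable class
      s[1:2] <- "a"
      r <- rnorm(n) * 10
      k <- sample(1:4, 1)
      d <- tibble::tibble(stimulus = factor(s), response = r)
      got <- suppressWarnings(mi_knn(d, k = k))$value_bits
      expect_equal(got, brute_knn_mi(s, r, k), tolerance = 1e-12)
    }
  })
})

test_that("knn MI is invariant under affine response maps", {
  d <- sample_mixture(gaussian_pair_spec(), 150, seed = 5)
  base <- mi_knn(d, k = 3)$value_bits
  exact <- mi_knn(dplyr::mutate(d, response = 2 * response), k = 3)$value_bits
  expect_identical(exact, base)
  generic <- mi_knn(dplyr::mutate(d, response = -0.37 * response + 11.2),
                    k = 3)$value_bits
  expect_equal(generic, base, tolerance = 1e-9)
})

test_that("shuffled labels give a raw mean estimate near zero", {
  d <- sample_mixture(gaussian_pair_spec(), 200, seed = 1)
  ests <- withr::with_seed(123, {
    vapply(1:50, function(i) {
      mi_knn(dplyr::mutate(d, stimulus = sample(stimulus)), k = 3)$value_bits
    }, numeric(1))
  })
  expect_lt(abs(mean(ests)), 0.02)
})

test_that("per-point k reduction and skipping handle unbalanced designs", {
  d <- tibble::tibble(
    stimulus = factor(c("a", "a", "a", "b")),
    response = c(0, 1, 2, 50)
  )
  expect_warning(est <- mi_knn(d, k = 3), "skipped")
  expect_equal(est$diagnostics$skipped_points, 1)
  # class a has 3 members, so k_i = min(3, 2) = 2 for its points
  expect_equal(est$diagnostics$per_point$k_i, rep(2L, 3))
})

test_that("degenerate inputs error as declared", {
  expect_error(
    mi_knn(tibble::tibble(stimulus = factor(c("a", "b")), response = c(1, 2))),
    "no estimable points"
  )
  expect_error(
    mi_knn(tibble::tibble(stimulus = factor(c("a", "a")), response = c(1, Inf))),
    "non-finite"
  )
  expect_error(mi_knn(sample_mixture(gaussian_pair_spec(), 10, 1), k = 0), "k must be")
})

test_that("clamping floors the estimate at zero before averaging", {
  est <- new_mi_estimate(-0.013, "knn", list(k = 3), 100)
  clamped <- clamp_mi(est)
  expect_identical(clamped$value_bits, 0)
  expect_true(clamped$clamped)
  at_zero <- clamp_mi(new_mi_estimate(0, "knn", list(k = 3), 100))
  expect_identical(at_zero$value_bits, 0)
  positive <- clamp_mi(new_mi_estimate(0.16, "knn", list(k = 3), 100))
  expect_identical(positive$value_bits, 0.16)
  expect_true(positive$clamped)
})

test_that("estimate objects tidy, glance and serialize", {
  d <- sample_mixture(gaussian_pair_spec(), 50, seed = 2)
  est <- mi_knn(d, k = 3)
  td <- tidy(est)
  expect_equal(td$value_bits, est$value_bits)
  expect_equal(td$k, 3)
  gl <- glance(est)
  expect_equal(gl$skipped_points, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_mi_estimate(est, path)
  rec <- jsonlite::read_json(path)
  expect_equal(rec$estimator, "knn")
  expect_equal(rec$value_bits, est$value_bits, tolerance = 1e-12)
})

test_that("sample sets round-trip through CSV", {
  d <- sample_mixture(uniform_pair_spec(), 25, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(d, path)
  back <- read_samples(path)
  expect_equal(back$response, d$response, tolerance = 1e-12)
  expect_equal(as.character(back$stimulus), as.character(d$stimulus))
})
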