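test_that("signed-rank hand cases match enumeration", {
  # all five differences positive: the observed W is the unique extreme
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(0, 1, 2, 3, 4))
  res <- paired_signed_rank(d, x, y, "greater")
  expect_equal(res$p_value, 1 / 32)
  expect_true(res$exact)
  expect_equal(res$n_zero, 0)

  # identical columns: degenerate, p = 1
  expect_warning(
    deg <- paired_signed_rank(tibble::tibble(x = 1:4, y = 1:4), x, y, "greater"),
    "degenerate"
  )
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  expect_equal(deg$n_zero, 4)

  # antisymmetric differences: p sits at the centre of the null
  anti <- tibble::tibble(x = c(1, 1, 2, 2), y = c(0, 2, 1, 3))
  res2 <- paired_signed_rank(anti, x, y, "greater")
  expect_equal(res2$p_value,
               brute_signed_rank_p(anti$x, anti$y, "greater"))
  expect_equal(res2$p_value, 0.6875) # P(W >= 3) over the 16 sign patterns
})

test_that("rank-sum hand cases match enumeration", {
  d <- tibble::tibble(v = 1:6, g = rep(c("a", "b"), each = 3))
  expect_equal(unpaired_rank_sum(d, v, g, alternative = "less")$p_value, 1 / 20)
  d2 <- tibble::tibble(v = 1:4, g = rep(c("a", "b"), each = 2))
  expect_equal(unpaired_rank_sum(d2, v, g, alternative = "less")$p_value, 1 / 6)
  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(unpaired_rank_sum(same, v, g)$p_value, 1)
})

test_that("exact p-values equal the brute-force enumeration oracles", {
  withr::with_seed(31, {
    for (rep in 1:30) {
      n <- sample(2:10, 1)
      x <- round(rnorm(n), 1) # rounding forces occasional ties and zeros
      y <- round(rnorm(n), 1)
      for (alt in c("greater", "less", "two.sided")) {
        got <- suppressWarnings(
          paired_signed_rank(tibble::tibble(x = x, y = y), x, y, alt)$p_value
        )
        expect_equal(got, brute_signed_rank_p(x, y, alt), tolerance = 1e-12)
      }
      m <- sample(2:5, 1); nb <- sample(2:5, 1)
      a <- round(rnorm(m), 1); b <- round(rnorm(nb), 1)
      dd <- tibble::tibble(v = c(a, b),
                           g = rep(c("g1", "g2"), c(m, nb)))
      for (alt in c("greater", "less", "two.sided")) {
        expect_equal(unpaired_rank_sum(dd, v, g, alternative = alt)$p_value,
                     brute_rank_sum_p(a, b, alt), tolerance = 1e-12)
      }
    }
  })
})

test_that("exact untied p-values also agree with wilcox.test", {
  withr::with_seed(8, {
    x <- rnorm(9); y <- rnorm(9)
    ref <- wilcox.test(x, y, paired = TRUE, alternative = "greater")$p.value
    got <- paired_signed_rank(tibble::tibble(x = x, y = y), x, y, "greater")$p_value
    expect_equal(got, ref, tolerance = 1e-12)

    a <- rnorm(5); b <- rnorm(6)
    ref2 <- wilcox.test(a, b, alternative = "two.sided")$p.value
    dd <- tibble::tibble(v = c(a, b), g = rep(c("a", "b"), c(5, 6)))
    expect_equal(unpaired_rank_sum(dd, v, g)$p_value, ref2, tolerance = 1e-12)
  })
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(12, {
    x <- rnorm(33, mean = 0.3); y <- rnorm(33)
    res <- paired_signed_rank(tibble::tibble(x = x, y = y), x, y, "greater")
    expect_false(res$exact)
    ref <- wilcox.test(x, y, paired = TRUE, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
    expect_equal(res$p_value, ref, tolerance = 1e-9)

    a <- rnorm(16); b <- rnorm(17, mean = 0.5)
    dd <- tibble::tibble(v = c(a, b), g = rep(c("p", "u"), c(16, 17)))
    res2 <- unpaired_rank_sum(dd, v, g, alternative = "less")
    expect_false(res2$exact)
    ref2 <- wilcox.test(a, b, alternative = "less",
                        exact = FALSE, correct = TRUE)$p.value
    expect_equal(res2$p_value, ref2, tolerance = 1e-9)
  })
})

test_that("opposite one-tailed exact p-values sum to at least one", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      n <- sample(3:10, 1)
      x <- rnorm(n); y <- rnorm(n)
      d <- tibble::tibble(x = x, y = y)
      pg <- paired_signed_rank(d, x, y, "greater")$p_value
      pl <- paired_signed_rank(d, x, y, "less")$p_value
      expect_gte(pg + pl, 1)
    }
  })
})

test_that("group summaries compute mean, SEM and the n = 1 edge", {
  d <- tibble::tibble(g = c("a", "a", "a", "b"),
                      value_bits = c(0.1, 0.2, 0.3, 0.4))
  s <- mi_summary(d, g)
  expect_equal(s$mean, c(0.2, 0.4))
  expect_equal(s$sem[1], 0.1 / sqrt(3), tolerance = 1e-9)
  expect_equal(s$sem[1], 0.0577, tolerance = 1e-3)
  expect_equal(s$sem[2], 0)
  expect_false(s$sem_defined[2])
  zeros <- mi_summary(tibble::tibble(g = "a", value_bits = c(0, 0, 0)), g)
  expect_equal(zeros$mean, 0)
  expect_equal(zeros$sem, 0)
  expect_error(mi_summary(tibble::tibble(value_bits = numeric(0))), "empty")
})

test_that("group comparisons validate their inputs", {
  expect_error(
    unpaired_rank_sum(tibble::tibble(v = 1:3, g = c("a", "b", "c")), v, g),
    "two levels"
  )
})
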