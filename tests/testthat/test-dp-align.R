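p0 <- align_params()

test_that("match chi-square is the squared deviation over the variance", {
  expect_equal(match_chi2(10000, 10000, 250000), 0)
  expect_equal(match_chi2(11000, 10000, 250000), 4)
  expect_equal(match_chi2(12000, 10000, 250000), 16) # doubles -> x4
  expect_error(match_chi2(1, 1, 0), "> 0")
})

test_that("small-fragment gap rule follows the halving gate", {
  f <- c(10000, 500, 10000)
  s <- c(500, 300, 500)
  # skipping the 500 bp fragment takes the chi-square to zero: allowed
  expect_true(allow_gap(20000, f, s, 1, 3, 2, p0))
  # inclusive feasible; gap allowed only when chi2 at most halves
  o1 <- 20500 + 900 # inclusive chi2 large, exclusive smaller
  chi_inc <- match_chi2(o1, 20500, sum(s^2))
  chi_exc <- match_chi2(o1, 20000, s[1]^2 + s[3]^2)
  expect_equal(allow_gap(o1, f, s, 1, 3, 2, p0), chi_exc <= 0.5 * chi_inc)
  # fragments above the detection limit are never dropped
  f2 <- c(10000, 3000, 10000)
  expect_false(allow_gap(23000, f2, s, 1, 3, 2, p0))
})

test_that("a perfect sub-map extends to a zero-error, zero-chi2 alignment", {
  refs <- synth_reference(60, 17300, seed = 13)
  f <- refs$fragments[[1]]
  s <- refs$sigmas[[1]]
  o <- f[20:27]
  hit <- list(q_pos = 3L, r_pos = 22L, variant = "plain", q_variant = "plain")
  res <- extend_seed(o, f, s, hit, p0)
  expect_equal(res$cut_errors, 0L)
  expect_equal(res$chi2, 0)
  expect_equal(res$score, 0)
  expect_equal(res$n_matches, 8L)
  expect_equal(res$r_start, 20L)
  expect_equal(res$r_end, 27L)
  expect_true(all(res$matches[, "q_end"] - res$matches[, "q_start"] == 0))
})

test_that("a missing cut is absorbed by a merged match", {
  f <- c(10000, 7000, 8000, 20000)
  s <- pmax(300, 0.05 * f)
  o <- c(10000, 15000, 20000)
  # the plain 2-mer fails on the second element, so anchor via merge23
  hit2 <- list(q_pos = 1L, r_pos = 1L, variant = "merge23",
               q_variant = "plain")
  res <- extend_seed(o, f, s, hit2, p0)
  expect_equal(res$cut_errors, 1L)
  expect_equal(res$missing_cuts, 1L)
  expect_equal(res$false_cuts, 0L)
  ora <- oracle_extend(o, f, s, seed_matches(hit2), p0)
  expect_equal(res$cut_errors, ora$ce)
  expect_equal(res$chi2, ora$chi2, tolerance = 1e-9)
})

test_that("extension is abandoned when no feasible match exists", {
  f <- c(10000, 12000, 9000, 11000, 10500, 9500, 10000, 11500)
  s <- pmax(300, 0.05 * f)
  o <- c(10000, 12000, 50000, 50000, 50000, 50000) # right side unalignable
  hit <- list(q_pos = 1L, r_pos = 1L, variant = "plain", q_variant = "plain")
  expect_null(extend_seed(o, f, s, hit, p0))
})

test_that("truncated end matches use the one-sided bound", {
  refs <- synth_reference(40, 17300, seed = 17)
  f <- refs$fragments[[1]]
  s <- refs$sigmas[[1]]
  o <- f[10:15]
  o[6] <- o[6] * 0.4 # last fragment cut short well past 3 sigma
  hit <- list(q_pos = 2L, r_pos = 11L, variant = "plain", q_variant = "plain")
  res <- extend_seed(o, f, s, hit, p0)
  expect_false(is.null(res))
  expect_equal(unname(res$matches[nrow(res$matches), "truncated"]), 1L)
  expect_equal(res$cut_errors, 0L)
})

test_that("seed matches translate hit variants correctly", {
  h <- list(q_pos = 4L, r_pos = 7L, variant = "merge12", q_variant = "merged")
  sm <- seed_matches(h)
  expect_equal(sm[1, ], c(q_start = 4, q_end = 5, r_start = 7, r_end = 8))
  expect_equal(sm[2, ], c(q_start = 6, q_end = 6, r_start = 9, r_end = 9))
})
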