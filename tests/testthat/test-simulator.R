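test_that("scenario presets carry the benchmark error rates", {
  a <- scenario("A")
  b <- scenario("B")
  expect_equal(a$d, 0.78)
  expect_equal(a$f100, 0.97)
  expect_equal(a$missing_fragment_probs$threshold_bp, c(350, 600, 1200))
  expect_equal(b$d, 0.61)
  expect_equal(b$f100, 1.38)
  expect_equal(b$missing_fragment_probs$threshold_bp, c(350, 800, 2000))
  expect_equal(a$min_map_bp, 150000)
  expect_equal(a$min_map_fragments, 10)
  expect_error(scenario_params(d = 0, f100 = 1))
})

test_that("the identity scenario reproduces the extracted sub-map exactly", {
  sc <- scenario_params(
    d = 1, f100 = 0,
    missing_fragment_probs = data.frame(threshold_bp = 1, prob = 0),
    sizing_sd = data.frame(threshold_bp = Inf, sd = 0))
  refs <- synth_reference(2000, 17300, seed = 51)
  sim <- simulate_maps(refs, 20, sc, seed = 52)
  f <- refs$fragments[[1]]
  pf <- c(0, cumsum(f))
  for (i in 1:20) {
    tr <- sim$truth[i, ]
    o <- sim$maps$fragments[[i]]
    if (tr$orientation == "reverse") o <- rev(o)
    cuts <- pf[pf > tr$start_bp & pf < tr$end_bp]
    expected <- diff(c(tr$start_bp, cuts, tr$end_bp))
    expect_equal(o, expected, tolerance = 1e-9)
    expect_equal(tr$n_retained_cuts, tr$n_true_cuts)
    expect_equal(tr$n_false_cuts, 0L)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  refs <- synth_reference(500, 17300, seed = 53)
  s1 <- simulate_maps(refs, 10, scenario("B"), seed = 54)
  s2 <- simulate_maps(refs, 10, scenario("B"), seed = 54)
  expect_identical(s1$maps, s2$maps)
  expect_identical(s1$truth, s2$truth)
  expect_identical(synth_reference(50, 17300, seed = 1),
                   synth_reference(50, 17300, seed = 1))
})

test_that("no emitted map violates the size filter", {
  refs <- synth_reference(800, 10800, seed = 55)
  sim <- simulate_maps(refs, 200, scenario("B"), seed = 56)
  expect_true(all(sim$maps$total_bp >= 150000))
  expect_true(all(sim$maps$n_fragments >= 10))
})

test_that("synthetic reference fragment sizes hit the requested mean", {
  refs <- synth_reference(13920, 17300, seed = 57)
  expect_equal(mean(refs$fragments[[1]]), 17300, tolerance = 0.02)
  expect_equal(synth_reference(1, 17300, seed = 58)$n_fragments, 1L)
})

test_that("truth logs recover the configured error rates", {
  refs <- synth_reference(3000, 17300, seed = 59)
  sim <- simulate_maps(refs, 400, scenario("A"), seed = 60)
  est <- estimate_scenario(sim$truth)
  expect_lt(abs(est$d_hat - 0.78), 3 * est$d_se)
  expect_lt(abs(est$f100_hat - 0.97), 3 * est$f100_se)
})

test_that("simulated assemblies honor the N50 target and fragment filter", {
  refs <- synth_reference(20000, 17300, seed = 61)
  asm <- simulate_assembly(refs, n50_bp = 2e6, seed = 62)
  expect_true(all(asm$scaffolds$n_fragments - 2 >= 4))
  sz <- sort(asm$scaffolds$total_bp, decreasing = TRUE)
  n50 <- sz[which(cumsum(sz) >= sum(sz) / 2)[1]]
  expect_lt(abs(n50 - 2e6) / 2e6, 0.2)
  # kept pieces are disjoint intervals of the source whose spans match
  tr <- asm$truth
  expect_equal(asm$scaffolds$total_bp, tr$end_bp - tr$start_bp,
               tolerance = 1e-9)
  expect_true(all(tr$start_bp[-1] >= tr$end_bp[-nrow(tr)] - 1e-9))
})
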