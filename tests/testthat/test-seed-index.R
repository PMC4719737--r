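test_that("index enumerates the composite-seed tuples of each position", {
  refs <- reference_maps("r", list(c(10000, 20000, 30000)))
  idx <- build_seed_index(refs)
  e <- idx$entries
  keys <- paste(round(e$key1), round(e$key2), e$variant)
  expect_setequal(keys, c("10000 20000 1", "20000 30000 1",
                          "30000 30000 2", "10000 50000 3"))
  expect_equal(e$r_pos[e$variant == 2], 1L)

  two <- build_seed_index(reference_maps("r2", list(c(5000, 6000))))
  expect_equal(length(two$entries$key1), 1L)
  expect_equal(two$entries$variant, 1L)

  expect_error(build_seed_index(refs, align_params(c = 3)))
})

test_that("entry count scales as roughly 3 per fragment", {
  refs <- synth_reference(500, 17300, seed = 3)
  idx <- build_seed_index(refs)
  expect_equal(length(idx$entries$key1), (500 - 1) + 2 * (500 - 2))
})

test_that("lookup equals a brute-force scan over all entries", {
  set.seed(21)
  refs <- synth_reference(120, 15000)
  idx <- build_seed_index(refs)
  e <- idx$entries
  p <- align_params()
  for (rep in 1:10) {
    o <- pmax(400, stats::rexp(6, 1 / 15000))
    hits <- query_seeds(o, idx, p)
    # brute force: every entry against every query tuple
    brute <- 0L
    tuples <- rbind(cbind(o[1:5], o[2:6]),
                    cbind(o[1:4] + o[2:5], o[3:6]))
    for (k in seq_len(nrow(tuples))) {
      ok <- abs(tuples[k, 1] - e$key1) <= p$C_sigma_seed * e$sd1 &
        abs(tuples[k, 2] - e$key2) <= p$C_sigma_seed * e$sd2
      brute <- brute + sum(ok)
    }
    expect_identical(nrow(hits), brute)
  }
})

test_that("error-free queries anchor at their true position", {
  refs <- synth_reference(200, 17300, seed = 5)
  idx <- build_seed_index(refs)
  f <- refs$fragments[[1]]
  o <- f[50:60]
  hits <- query_seeds(o, idx)
  plain <- hits[hits$variant == "plain" & hits$q_variant == "plain", ]
  for (i in 1:10) {
    expect_true(any(plain$q_pos == i & plain$r_pos == 49 + i))
  }
  # a first element far outside the bound yields no hit at that position
  o2 <- c(f[50] + 3 * 0.05 * f[50] + 3000, f[51])
  h2 <- query_seeds(c(o2, f[52]), idx)
  expect_false(any(h2$r_pos == 50 & h2$q_pos == 1 & h2$variant == "plain" &
                     h2$q_variant == "plain"))
})

test_that("one missing cut is recovered through a merged variant", {
  f <- c(30000, 12000, 9000, 25000, 18000)
  refs <- reference_maps("toy", list(f))
  idx <- build_seed_index(refs)
  o <- c(30000, 12000 + 9000, 25000, 18000) # cut between r2 and r3 missed
  hits <- query_seeds(o, idx)
  expect_true(any(hits$variant == "merge23" & hits$r_pos == 1))
  expect_true(any(hits$variant == "merge12" & hits$r_pos == 2))
})

test_that("composite seeding finds at least as many anchors as plain 2-mers", {
  refs <- synth_reference(400, 17300, seed = 8)
  idx <- build_seed_index(refs)
  sim <- simulate_maps(refs, 30, scenario("A"), seed = 9)
  comp <- seed_sensitivity(sim$maps, sim$truth, idx, composite = TRUE)
  plain <- seed_sensitivity(sim$maps, sim$truth, idx, composite = FALSE)
  expect_gte(comp$n_with_correct_seed, plain$n_with_correct_seed)
})
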