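test_that("an error-free sub-map aligns significant and unique at its true locus", {
  refs <- synth_reference(200, 17300, seed = 31)
  f <- refs$fragments[[1]]
  loci <- 6 * (1:30)
  maps <- experimental_maps(paste0("perfect_", 1:30),
                            lapply(loci, function(a) f[a:(a + 14)]))
  res <- align_maps(maps, refs)
  rep <- tidy(res)
  # maps whose candidate population is large enough for the normal
  # approximation are all called; every map is placed exactly
  expect_true(all(rep$status[!rep$low_population] == "significant_unique"))
  expect_gte(mean(rep$status == "significant_unique"), 0.9)
  expect_equal(rep$r_start, loci)
  expect_equal(rep$r_end, loci + 14)
  expect_true(all(rep$orientation == "forward"))
  expect_true(all(rep$chi2 < 1e-9))
})

test_that("maps unrelated to the reference are not confidently placed", {
  refs <- synth_reference(200, 17300, seed = 32)
  set.seed(33)
  junk <- experimental_maps(paste0("rand_", 1:20),
                            replicate(20, pmax(400, stats::rexp(15, 1 / 17300)),
                                      simplify = FALSE))
  res <- align_maps(junk, refs)
  rep <- tidy(res)
  # at most an occasional borderline call is tolerated at this sample size;
  # the population-level false-discovery proportion is checked elsewhere
  expect_lte(sum(rep$status == "significant_unique"), 2)
})

test_that("a tandem-duplicated region is reported non-unique", {
  set.seed(34)
  block <- pmax(400, stats::rexp(30, 1 / 17300))
  flank1 <- pmax(400, stats::rexp(60, 1 / 17300))
  flank2 <- pmax(400, stats::rexp(60, 1 / 17300))
  refs <- reference_maps("dup", list(c(flank1, block, block, flank2)))
  o <- block[5:20]
  res <- align_maps(experimental_maps("m", list(o)), refs)
  rep <- tidy(res)
  # both copies place the map equally well: the ratio of best to next-best
  # p-values is ~1, so the placement can never be called unique
  expect_true(rep$uniqueness < align_params()$uniqueness_ratio)
  expect_true(rep$status %in% c("non_unique", "non_significant"))
})

test_that("short maps are rejected with an explicit reason", {
  refs <- synth_reference(50, 17300, seed = 35)
  maps <- experimental_maps("tiny", list(c(10000, 20000)))
  res <- align_maps(maps, refs)
  expect_equal(tidy(res)$status, "rejected_too_few_fragments")
})

test_that("report writer emits the canonical column order", {
  refs <- synth_reference(100, 17300, seed = 36)
  f <- refs$fragments[[1]]
  maps <- experimental_maps(c("a", "b"),
                            list(f[10:20], f[40:52]))
  res <- align_maps(maps, refs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, path, extra = "config_hash=deadbeef")
  lines <- readLines(path)
  expect_equal(lines[1], "# config_hash=deadbeef")
  expect_equal(strsplit(lines[2], "\t")[[1]],
               c("map_id", "ref_id", "orientation", "r_start", "r_end",
                 "n_matches", "missing_cuts", "false_cuts",
                 "missing_fragments", "chi2", "wht", "vartheta", "p_value",
                 "q_value", "n_candidates", "status"))
  expect_equal(length(lines), 4)
})

test_that("tidy and glance summarize an alignment run", {
  refs <- synth_reference(150, 17300, seed = 37)
  sim <- simulate_maps(refs, 10, scenario("A"), seed = 38)
  res <- align_maps(sim$maps, refs)
  g <- glance(res)
  expect_equal(g$n_maps, 10L)
  expect_equal(
    g$n_significant_unique + g$n_non_unique + g$n_non_significant +
      g$n_no_alignment,
    10L)
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("loosening significance or uniqueness thresholds never reports fewer maps", {
  refs <- synth_reference(250, 17300, seed = 39)
  sim <- simulate_maps(refs, 25, scenario("B"), seed = 40)
  idx <- build_seed_index(refs)
  n_su <- function(q, u) {
    res <- align_maps(sim$maps, index = idx,
                      params = align_params(q_threshold = q,
                                            uniqueness_ratio = u))
    sum(tidy(res)$status == "significant_unique")
  }
  base <- n_su(0.01, 5)
  expect_gte(n_su(0.05, 5), base)
  expect_gte(n_su(0.01, 2), base)
})
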