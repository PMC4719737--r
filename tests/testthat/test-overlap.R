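p0 <- align_params()

test_that("conflict detection follows the sub-map and same-reference rules", {
  sol <- function(ws, we, ref, or, rs_bp, re_bp, off) {
    tibble::tibble(window_start = ws, window_end = we, ref_id = ref,
                   orientation = or, r_start_bp = rs_bp, r_end_bp = re_bp,
                   offset_bp = off)
  }
  a <- sol(1, 12, "refA", "forward", 100000, 300000, 0)
  b <- sol(5, 16, "refB", "forward", 900000, 1100000, 60000)
  expect_true(conflicts(a, b, p0)) # overlapping windows
  # same locus continuation: window 13..24 starts 200 kbp into the map and
  # the reference interval is shifted by the same amount
  cont <- sol(13, 24, "refA", "forward", 300000, 500000, 200000)
  expect_false(conflicts(a, cont, p0))
  # same reference, different location
  far <- sol(13, 24, "refA", "forward", 900000, 1100000, 200000)
  expect_true(conflicts(a, far, p0))
  # same reference, same spot, other strand
  flip <- sol(13, 24, "refA", "reverse", 300000, 500000, 200000)
  expect_true(conflicts(a, flip, p0))
  # different references never conflict through clause (b)
  other <- sol(13, 24, "refB", "forward", 0, 200000, 200000)
  expect_false(conflicts(a, other, p0))
})

make_junction_case <- function(seed = 71, map_range = 280:320, split_at = 300) {
  genome <- synth_reference(600, 17300, ref_id = "gen", seed = seed)
  f <- genome$fragments[[1]]
  pf <- c(0, cumsum(f))
  scaffolds <- reference_maps(c("scfA", "scfB"),
                              list(f[1:split_at], f[(split_at + 1):600]))
  scf_truth <- tibble::tibble(
    scaffold_id = c("scfA", "scfB"), ref_id = "gen",
    start_bp = c(0, pf[split_at + 1]),
    end_bp = c(pf[split_at + 1], pf[601]))
  o <- f[map_range]
  maps <- experimental_maps("jmap", list(o))
  truth <- tibble::tibble(
    map_id = "jmap", ref_id = "gen", orientation = "forward",
    start_bp = pf[min(map_range)], end_bp = pf[max(map_range) + 1])
  list(genome = genome, scaffolds = scaffolds, scf_truth = scf_truth,
       maps = maps, truth = truth)
}

test_that("a map straddling two scaffolds yields a split overlap with extensions", {
  cs <- make_junction_case()
  res <- overlap_align_maps(cs$maps, cs$scaffolds, p0)
  rep <- tidy(res)
  expect_equal(sort(unique(rep$ref_id)), c("scfA", "scfB"))
  expect_true(all(rep$overlap_type == "split-part"))
  onA <- rep[rep$ref_id == "scfA", ]
  onB <- rep[rep$ref_id == "scfB", ]
  expect_true(all(onA$extension_right >= 1)) # protrudes past scfA's right end
  expect_true(all(onB$extension_left >= 1))
  sc <- score_overlap(rep, cs$truth, cs$scf_truth)
  expect_equal(sc$n_correct_extensions, nrow(rep))
  expect_equal(sc$precision, 1)
})

test_that("every reported overlap reaches an end of one of the maps on both sides", {
  cs <- make_junction_case(seed = 72)
  res <- overlap_align_maps(cs$maps, cs$scaffolds, p0)
  rep <- tidy(res)
  expect_gt(nrow(rep), 0)
  n_scf <- cs$scaffolds$n_fragments[match(rep$ref_id, cs$scaffolds$ref_id)]
  m <- cs$maps$n_fragments[1]
  fwd <- rep$orientation == "forward"
  left_ok <- rep$q_aligned_start == 1 |
    ifelse(fwd, rep$r_start == 1, rep$r_end == n_scf)
  right_ok <- rep$q_aligned_end == m |
    ifelse(fwd, rep$r_end == n_scf, rep$r_start == 1)
  expect_true(all(left_ok & right_ok))
})

test_that("a map contained in one scaffold degenerates to a glocal alignment", {
  genome <- synth_reference(200, 17300, ref_id = "gen", seed = 73)
  f <- genome$fragments[[1]]
  maps <- experimental_maps("inside", list(f[50:69]))
  res <- overlap_align_maps(maps, genome, p0)
  rep <- tidy(res)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$overlap_type, "contained")
  expect_equal(rep$q_aligned_start, 1L)
  expect_equal(rep$q_aligned_end, 20L)
  expect_equal(rep$r_start, 50L)
  expect_equal(rep$r_end, 69L)
})

test_that("maps shorter than the window are rejected and reports stay conflict-free", {
  genome <- synth_reference(200, 17300, ref_id = "gen", seed = 74)
  short <- experimental_maps("short", list(genome$fragments[[1]][1:5]))
  res <- overlap_align_maps(short, genome, p0)
  expect_equal(nrow(res$report), 0)

  cs <- make_junction_case(seed = 75)
  res2 <- overlap_align_maps(cs$maps, cs$scaffolds, p0)
  rep <- tidy(res2)
  if (nrow(rep) >= 2) {
    for (i in seq_len(nrow(rep) - 1)) {
      for (j in (i + 1):nrow(rep)) {
        expect_false(rep$ref_id[i] == rep$ref_id[j] &&
                       rep$orientation[i] != rep$orientation[j])
      }
    }
  }
})
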