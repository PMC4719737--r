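test_that("om-tsv round trip preserves maps and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".om")
  writeLines(c("# comment", "m1\t2\t10000,20000", "m2\t3\t1500.5,800,9000"),
             path)
  maps <- read_maps(path)
  expect_equal(maps$map_id, c("m1", "m2"))
  expect_equal(maps$fragments[[1]], c(10000, 20000))
  expect_equal(maps$fragments[[2]], c(1500.5, 800, 9000))

  out <- withr::local_tempfile(fileext = ".om")
  write_maps(maps, out)
  expect_equal(read_maps(out)$fragments, maps$fragments)

  empty <- withr::local_tempfile(fileext = ".om")
  writeLines(character(0), empty)
  expect_equal(nrow(read_maps(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".om")
  writeLines("m1\t2\t10000,0", bad)
  expect_error(read_maps(bad), "must be > 0")
  writeLines("m1\t10000,0", bad)
  expect_error(read_maps(bad), "line 1")
})

test_that("range_stats matches hand sums and naive summation", {
  expect_equal(range_stats(c(5000, 7000), c(500, 700), 1, 2),
               c(sum = 12000, var = 740000))
  expect_equal(range_stats(c(5000, 7000), c(500, 700), 1, 1),
               c(sum = 5000, var = 250000))
  expect_equal(range_stats(c(5000, 7000), c(500, 700), 1, 2, gaps = 2),
               c(sum = 5000, var = 250000))
  expect_error(range_stats(c(1, 2), c(1, 1), 0, 2), "out of bounds")

  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    f <- stats::runif(n, 100, 30000)
    s <- stats::runif(n, 10, 2000)
    l <- sample(seq_len(n), 1)
    t <- if (l == n) n else sample(l:n, 1)
    gaps <- if (t > l) sample(l:t, sample(0:(t - l), 1)) else integer(0)
    keep <- setdiff(l:t, gaps)
    expect_equal(range_stats(f, s, l, t, gaps),
                 c(sum = sum(f[keep]), var = sum(s[keep]^2)))
  }
})

test_that("feasibility bound behaves per mode and is monotone in C", {
  expect_true(feasible(10000, 10000, 1, 3))
  expect_false(feasible(12000, 10000, 250000, 3)) # 4 sd off
  expect_true(feasible(8000, 10000, 250000, 3, mode = "upper"))
  expect_false(feasible(8000, 10000, 250000, 3, mode = "lower")) # 4 sd deficit
  expect_error(feasible(1, 1, 0, 3), "degenerate")

  set.seed(7)
  for (rep in 1:50) {
    o <- stats::runif(1, 1000, 50000)
    r <- stats::runif(1, 1000, 50000)
    v <- stats::runif(1, 1e4, 1e7)
    C <- stats::runif(1, 0.5, 4)
    two <- feasible(o, r, v, C)
    if (two) {
      expect_true(feasible(o, r, v, C, mode = "upper"))
      expect_true(feasible(o, r, v, C, mode = "lower"))
      expect_true(feasible(o, r, v, C + stats::runif(1, 0, 2)))
    }
  }
})

test_that("reversing maps is an involution and flips orientation labels", {
  maps <- experimental_maps("m", list(c(1, 2, 3)))
  expect_equal(reverse_maps(maps)$fragments[[1]], c(3, 2, 1))
  expect_equal(reverse_maps(reverse_maps(maps)), maps)
  one <- experimental_maps("s", list(5))
  expect_equal(reverse_maps(one)$fragments[[1]], 5)

  refs <- reference_maps("r", list(c(5000, 900)))
  rr <- reverse_maps(refs)
  expect_equal(rr$orientation, "reverse")
  expect_equal(rr$sigmas[[1]], rev(refs$sigmas[[1]]))
})

test_that("constructors enforce invariants", {
  expect_error(experimental_maps("m", list(c(1, -2))), "> 0")
  expect_error(reference_maps("r", list(c(1, 2)), sigmas = list(c(1, -1))),
               "non-negative")
  expect_error(align_params(C_sigma = 2, C_sigma_seed = 3), "C_sigma_seed")
  expect_error(align_params(c = 3), "c = 2")
})
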