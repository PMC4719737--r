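#' Error-model parameters for simulated experimental maps
#'
#' Describes the error process of a mapping run: the digestion rate `d`
#' (probability that a true cut is observed), the false-cut rate `f100`
#' (Poisson rate per 100 kbp), the size-dependent probability that a small
#' fragment goes undetected, and a size-range-dependent relative sizing
#' error. Two presets reproduce benchmark conditions at the two ends of the
#' observed quality spectrum, see [scenario()].
#'
#' @param d Digestion rate in (0, 1].
#' @param f100 False cuts per 100 kbp, >= 0.
#' @param missing_fragment_probs Data frame with increasing `threshold_bp`
#'   and `prob`: a fragment smaller than the first threshold it falls under
#'   is removed with that probability.
#' @param sizing_sd Data frame with increasing `threshold_bp` and `sd`
#'   (relative); a fragment's observed size is its true size times
#'   `1 + e`, `e ~ Normal(0, sd)` truncated at three standard deviations.
#' @param false_cut_min_bp False cuts are rejected if they would create a
#'   fragment smaller than this (default 1.2 kbp).
#' @param mean_fragments Mean fragment count of a simulated map (before
#'   filtering); counts are drawn as `shift + NegBin` fitted to this mean.
#' @param min_map_bp,min_map_fragments Maps smaller than 150 kbp or with
#'   fewer than ten fragments are discarded, mimicking instrument
#'   pre-processing.
#' @return A list of class `"om_scenario"`.
#' @export
scenario_params <- function(d, f100,
                            missing_fragment_probs = data.frame(
                              threshold_bp = c(350, 600, 1200),
                              prob = c(1, 0.75, 0.5)),
                            sizing_sd = data.frame(
                              threshold_bp = c(2000, 10000, Inf),
                              sd = c(0.15, 0.08, 0.05)),
                            false_cut_min_bp = 1200,
                            mean_fragments = 17,
                            min_map_bp = 150000,
                            min_map_fragments = 10) {
  stopifnot(d > 0, d <= 1, f100 >= 0,
            all(diff(missing_fragment_probs$threshold_bp) > 0),
            all(missing_fragment_probs$prob >= 0),
            all(missing_fragment_probs$prob <= 1),
            all(diff(sizing_sd$threshold_bp) > 0), all(sizing_sd$sd >= 0))
  structure(list(d = d, f100 = f100,
                 missing_fragment_probs = missing_fragment_probs,
                 sizing_sd = sizing_sd, false_cut_min_bp = false_cut_min_bp,
                 mean_fragments = mean_fragments, min_map_bp = min_map_bp,
                 min_map_fragments = min_map_fragments),
            class = "om_scenario")
}

#' @rdname scenario_params
#' @param name `"A"` (easier: d = 0.78, f100 = 0.97, missing-fragment
#'   probabilities 0.5 below 1.2 kbp, 0.75 below 600 bp, 1 below 350 bp) or
#'   `"B"` (harder: d = 0.61, f100 = 1.38, 0.5 below 2 kbp, 0.75 below
#'   800 bp, 1 below 350 bp).
#' @export
scenario <- function(name = c("A", "B")) {
  name <- match.arg(name)
  if (name == "A") {
    scenario_params(d = 0.78, f100 = 0.97,
                    missing_fragment_probs = data.frame(
                      threshold_bp = c(350, 600, 1200), prob = c(1, 0.75, 0.5)))
  } else {
    scenario_params(d = 0.61, f100 = 1.38,
                    missing_fragment_probs = data.frame(
                      threshold_bp = c(350, 800, 2000), prob = c(1, 0.75, 0.5)))
  }
}

#' Synthetic reference map
#'
#' Generates a stand-in for a genome-wide in-silico digest: independent
#' fragment sizes from an exponential distribution with the given mean,
#' floored at 100 bp.
#'
#' @param n_fragments Number of fragments.
#' @param mean_bp Mean fragment size (bp).
#' @param ref_id Identifier.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the map is reproducible.
#' @param sigma A [sigma_model()].
#' @return A one-row [reference_maps()] tibble.
#' @export
synth_reference <- function(n_fragments, mean_bp = 17300, ref_id = "synth",
                            seed = NULL, sigma = sigma_model()) {
  stopifnot(n_fragments >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- pmax(100, stats::rexp(n_fragments, rate = 1 / mean_bp))
  reference_maps(ref_id, list(f), sigma = sigma)
}

lookup_step <- function(x, thresholds, values, default = 0) {
  idx <- findInterval(x, thresholds) + 1L
  out <- rep(default, length(x))
  ok <- idx <= length(values)
  out[ok] <- values[idx[ok]]
  out
}

rnorm_trunc <- function(n, sd, limit = 3) {
  if (sd == 0) return(rep(0, n))
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > limit)) z[bad] <- stats::rnorm(sum(bad))
  z * sd
}

# One attempt at simulating a map; NULL when the result fails the size
# filter.  `pf` is the reference prefix-sum vector.
simulate_one <- function(ref_id, f, pf, sc) {
  L <- pf[length(pf)]
  cnt <- 4 + stats::rnbinom(1, size = 6, mu = sc$mean_fragments - 4)
  # convert the target fragment count to a bp extent using the *experimental*
  # average fragment size, i.e. the in-silico AFS inflated by missing cuts
  afs <- L / length(f)
  target <- min(cnt * afs / sc$d, L)
  start <- stats::runif(1, 0, L - target)
  end <- start + target

  # interior true cuts inside the window
  jall <- which(pf > start & pf < end) - 1L # ref cut index j at pf[j + 1]
  n_true <- length(jall)
  keep <- stats::runif(n_true) <= sc$d
  cut_pos <- pf[jall[keep] + 1L] - start
  cut_ref <- jall[keep]

  # false cuts: Poisson over the map extent, rejecting placements that would
  # create fragments below the detection limit
  n_false <- stats::rpois(1, sc$f100 * target / 1e5)
  placed <- 0L
  for (dummy in seq_len(n_false)) {
    for (try in 1:100) {
      p <- stats::runif(1, 0, target)
      if (min(abs(c(cut_pos, 0, target) - p)) >= sc$false_cut_min_bp) {
        cut_pos <- c(cut_pos, p)
        cut_ref <- c(cut_ref, NA_integer_)
        placed <- placed + 1L
        break
      }
    }
  }
  ord <- order(cut_pos)
  cut_pos <- cut_pos[ord]
  cut_ref <- cut_ref[ord]

  r_first <- sum(pf <= start)
  sizes <- diff(c(0, cut_pos, target))
  left_ref <- c(r_first - 1L, cut_ref)      # ref cut left of each fragment
  right_ref <- c(cut_ref, NA_integer_)      # ref cut right of each fragment
  left_true <- c(FALSE, !is.na(cut_ref))
  right_true <- c(!is.na(cut_ref), FALSE)
  frag_ref <- ifelse(is.na(left_ref), NA_integer_, left_ref + 1L)
  clean <- left_true & right_true & !is.na(left_ref) & !is.na(right_ref) &
    (right_ref - left_ref == 1L)

  # missing fragments: the fragment disappears and its flanking cuts
  # collapse to one; neighbours keep their own sizes
  p_rm <- lookup_step(sizes, sc$missing_fragment_probs$threshold_bp,
                      sc$missing_fragment_probs$prob, default = 0)
  rm_idx <- which(stats::runif(length(sizes)) <= p_rm & p_rm > 0)
  dropped_bp <- sizes[rm_idx]
  if (length(rm_idx)) {
    # a collapsed boundary breaks the 1:1 property of both neighbours' shared
    # cuts only on the removed side; neighbour clean flags stay valid because
    # they reference their own original boundary cuts, which still exist,
    # but pairs spanning the removal are no longer reference-consecutive.
    sizes <- sizes[-rm_idx]
    frag_ref <- frag_ref[-rm_idx]
    clean <- clean[-rm_idx]
  }
  if (length(sizes) == 0) return(NULL)

  # size-range-dependent sizing error
  sdv <- lookup_step(sizes, sc$sizing_sd$threshold_bp, sc$sizing_sd$sd,
                     default = sc$sizing_sd$sd[nrow(sc$sizing_sd)])
  err <- vapply(sdv, function(s) rnorm_trunc(1, s), numeric(1))
  sizes <- sizes * (1 + err)

  orientation <- if (stats::runif(1) < 0.5) "reverse" else "forward"
  if (orientation == "reverse") {
    sizes <- rev(sizes)
    frag_ref <- rev(frag_ref)
    clean <- rev(clean)
  }
  if (sum(sizes) < sc$min_map_bp || length(sizes) < sc$min_map_fragments) {
    return(NULL)
  }
  list(fragments = sizes, truth = tibble::tibble(
    ref_id = ref_id, orientation = orientation,
    start_bp = start, end_bp = end,
    r_first = r_first, r_last = sum(pf < end),
    n_true_cuts = n_true, n_retained_cuts = sum(keep),
    n_false_cuts = placed, n_dropped_fragments = length(dropped_bp),
    dropped_bp = list(dropped_bp), frag_ref = list(frag_ref),
    frag_clean = list(clean)))
}

#' Simulate experimental maps with truth logs
#'
#' Draws maps from reference maps under the configured error process, in
#' this order: sample a map extent and a uniform start (possibly truncating
#' end fragments), remove each interior true cut with probability `1 - d`
#' (Binomial), insert false cuts as a Poisson process with rate `f100` per
#' 100 kbp (rejecting placements that would create fragments below 1.2
#' kbp), remove small fragments with the size-dependent probabilities, and
#' apply size-range-dependent sizing errors. Maps smaller than 150 kbp or
#' with fewer than ten fragments are discarded and redrawn, so exactly `n`
#' maps are returned. Each map is reported on a uniformly random strand.
#'
#' @param refs A [reference_maps()] tibble (forward orientation); maps are
#'   drawn from references proportionally to their length.
#' @param n Number of maps to return.
#' @param sc A [scenario_params()] or [scenario()] object.
#' @param map_prefix Identifier prefix.
#' @param seed Optional integer seed.
#' @param max_attempts Attempt budget, a multiple of `n`.
#' @return A list with `maps` (experimental maps tibble) and `truth` (one
#'   row per map: source interval, strand, cut provenance counts and the
#'   per-fragment reference-fragment index and 1:1 cleanliness flags).
#' @export
simulate_maps <- function(refs, n, sc = scenario("A"), map_prefix = "sim",
                          seed = NULL, max_attempts = 50 * n) {
  if (!is.null(seed)) set.seed(seed)
  pfs <- lapply(refs$fragments, function(f) c(0, cumsum(f)))
  wt <- refs$total_bp / sum(refs$total_bp)
  maps <- vector("list", n)
  truths <- vector("list", n)
  got <- 0L
  for (att in seq_len(max_attempts)) {
    ri <- if (nrow(refs) == 1) 1L else sample.int(nrow(refs), 1, prob = wt)
    res <- simulate_one(refs$ref_id[ri], refs$fragments[[ri]], pfs[[ri]], sc)
    if (is.null(res)) next
    got <- got + 1L
    maps[[got]] <- res$fragments
    truths[[got]] <- res$truth
    if (got == n) break
  }
  if (got < n) stop("simulation attempt budget exhausted; check scenario")
  ids <- sprintf("%s_%04d", map_prefix, seq_len(n))
  truth <- dplyr::bind_rows(truths)
  truth$map_id <- ids
  truth <- truth[, c("map_id", setdiff(names(truth), "map_id"))]
  list(maps = experimental_maps(ids, maps), truth = truth)
}

#' Simulate an assembly: fragment references into scaffold-sized pieces
#'
#' Partitions each reference map into pieces whose sizes follow a
#' log-normal distribution calibrated so the length-weighted median (N50)
#' matches `n50_bp`. Pieces with fewer than `min_non_end_fragments`
#' non-end fragments are dropped, since such maps cannot be confidently
#' aligned.
#'
#' @param refs A [reference_maps()] tibble.
#' @param n50_bp Target scaffold N50 in bp.
#' @param sdlog Log-scale standard deviation of piece sizes.
#' @param min_non_end_fragments Minimum interior fragments per kept piece.
#' @param seed Optional integer seed.
#' @param sigma A [sigma_model()] for the scaffold maps.
#' @return A list with `scaffolds` (a [reference_maps()] tibble) and
#'   `truth` (scaffold_id, source ref_id, start_bp, end_bp).
#' @export
simulate_assembly <- function(refs, n50_bp, sdlog = 0.7,
                              min_non_end_fragments = 4, seed = NULL,
                              sigma = sigma_model()) {
  if (!is.null(seed)) set.seed(seed)
  meanlog <- log(n50_bp) - sdlog^2
  out <- list()
  tr <- list()
  for (ri in seq_len(nrow(refs))) {
    f <- refs$fragments[[ri]]
    pf <- c(0, cumsum(f))
    L <- pf[length(pf)]
    sizes <- numeric(0)
    while (sum(sizes) < L) {
      sizes <- c(sizes, stats::rlnorm(16, meanlog, sdlog))
    }
    bnd <- pmin(cumsum(sizes), L)
    bnd <- c(0, bnd[seq_len(which(bnd >= L)[1])])
    for (k in seq_len(length(bnd) - 1)) {
      a <- bnd[k]; b <- bnd[k + 1]
      cuts <- pf[pf > a & pf < b]
      frag <- diff(c(a, cuts, b))
      frag <- frag[frag > 0]
      if (length(frag) - 2 < min_non_end_fragments) next
      sid <- sprintf("%s_scf%04d", refs$ref_id[ri], k)
      out[[length(out) + 1L]] <- reference_maps(sid, list(frag), sigma = sigma)
      tr[[length(tr) + 1L]] <- tibble::tibble(
        scaffold_id = sid, ref_id = refs$ref_id[ri], start_bp = a, end_bp = b)
    }
  }
  if (!length(out)) stop("no scaffolds survived the non-end fragment filter")
  list(scaffolds = dplyr::bind_rows(out), truth = dplyr::bind_rows(tr))
}

#' Estimate error-process parameters from a truth log
#'
#' Recovers the realized digestion rate (retained true cuts over all true
#' cuts) and false-cut rate per 100 kbp from a [simulate_maps()] truth log,
#' with binomial / Poisson standard errors.
#'
#' @param truth A truth tibble from [simulate_maps()].
#' @return A one-row tibble: `d_hat`, `d_se`, `f100_hat`, `f100_se`,
#'   `n_maps`.
#' @export
estimate_scenario <- function(truth) {
  n_true <- sum(truth$n_true_cuts)
  n_kept <- sum(truth$n_retained_cuts)
  span <- sum(truth$end_bp - truth$start_bp)
  d_hat <- n_kept / n_true
  f100_hat <- sum(truth$n_false_cuts) / (span / 1e5)
  tibble::tibble(
    d_hat = d_hat,
    d_se = sqrt(d_hat * (1 - d_hat) / n_true),
    f100_hat = f100_hat,
    f100_se = sqrt(sum(truth$n_false_cuts)) / (span / 1e5),
    n_maps = nrow(truth))
}
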