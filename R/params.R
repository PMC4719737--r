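#' Alignment parameters
#'
#' Bundles every tunable of the seed-and-extend aligner. Defaults are the
#' recommended operating point for optical-map data: sizing deviations of a
#' feasible match are bounded by `C_sigma` reference standard deviations
#' (3 if sizing errors are roughly normal), seeds use the stricter
#' `C_sigma_seed` because seed fragments are expected to be higher quality,
#' and the dynamic programming band allows at most `max_false_cuts`
#' consecutive false cuts and `max_missing_cuts` consecutive missing cuts
#' within a single match.
#'
#' @param C_sigma Feasibility bound, in reference standard deviations, for a
#'   match (two-sided).
#' @param C_sigma_seed Stricter per-element bound used when looking up seeds;
#'   must not exceed `C_sigma`.
#' @param c Seed order (number of elements per indexed tuple). Only `c = 2`
#'   is supported.
#' @param max_missing_cuts Maximum missing cuts within one match (reference
#'   fragments merged into a single match, minus one).
#' @param max_false_cuts Maximum false cuts within one match (experimental
#'   fragments merged into a single match, minus one).
#' @param f_min_feasible Early-stop count: a seed extension is abandoned when
#'   no feasible match has been found after analyzing at least this many
#'   experimental fragments on a side.
#' @param small_fragment_bp Reference fragments at or below this size (bp) may
#'   be treated as missing (below the experimental detection limit).
#' @param gap_max_run At most this many consecutive reference fragments may be
#'   skipped as missing within one match.
#' @param q_threshold FDR level at which an alignment is called significant.
#' @param uniqueness_ratio Minimum ratio between the next-best and the best
#'   candidate p-value for the best alignment to be called unique. A stringent
#'   value of 30 is recommended for noisy real data.
#' @param window_l Sliding-window length (fragments) for overlap alignment.
#' @param conflict_tol_bp Tolerance (bp) when deciding whether two window
#'   placements of the same map imply the same reference location.
#' @param include_truncated_chi2 Whether the sizing term of a one-sided
#'   (truncated) end match contributes to the chi-square score. Default
#'   `FALSE`: a truncated fragment has no meaningful sizing deviation.
#'
#' @return A list of class `"om_params"`.
#' @examples
#' p <- align_params(uniqueness_ratio = 30)
#' p$C_sigma
#' @export
align_params <- function(C_sigma = 3,
                         C_sigma_seed = 2,
                         c = 2,
                         max_missing_cuts = 8,
                         max_false_cuts = 5,
                         f_min_feasible = 5,
                         small_fragment_bp = 2000,
                         gap_max_run = 3,
                         q_threshold = 0.01,
                         uniqueness_ratio = 5,
                         window_l = 12,
                         conflict_tol_bp = 50000,
                         include_truncated_chi2 = FALSE) {
  p <- list(
    C_sigma = C_sigma, C_sigma_seed = C_sigma_seed, c = c,
    max_missing_cuts = max_missing_cuts, max_false_cuts = max_false_cuts,
    f_min_feasible = f_min_feasible, small_fragment_bp = small_fragment_bp,
    gap_max_run = gap_max_run, q_threshold = q_threshold,
    uniqueness_ratio = uniqueness_ratio, window_l = window_l,
    conflict_tol_bp = conflict_tol_bp,
    include_truncated_chi2 = include_truncated_chi2
  )
  num <- vapply(p[setdiff(names(p), "include_truncated_chi2")], is.numeric, logical(1))
  if (!all(num)) stop("all alignment parameters except flags must be numeric")
  if (any(unlist(p[names(num)[num]]) <= 0)) {
    stop("alignment parameters must be positive")
  }
  if (C_sigma_seed > C_sigma) stop("C_sigma_seed must not exceed C_sigma")
  if (c != 2) stop("only seed order c = 2 is supported")
  structure(p, class = "om_params")
}

#' Standard-deviation model for in-silico fragments
#'
#' Sizing error of an experimental fragment, relative to its in-silico
#' counterpart, grows with fragment size but has an absolute floor. The
#' per-fragment standard deviation assigned to a reference fragment of size
#' `r` is `max(sigma_min, rho * r)`. Both knobs are technology-dependent and
#' fully configurable.
#'
#' @param rho Relative standard deviation (default 0.05, i.e. 5 %).
#' @param sigma_min Floor on the standard deviation in bp (default 300).
#' @return A function mapping a numeric vector of fragment sizes (bp) to
#'   standard deviations (bp), carrying `rho` and `sigma_min` as attributes.
#' @examples
#' sm <- sigma_model()
#' sm(c(1000, 50000))
#' @export
sigma_model <- function(rho = 0.05, sigma_min = 300) {
  stopifnot(rho > 0, sigma_min > 0)
  f <- function(sizes) pmax(sigma_min, rho * sizes)
  attr(f, "rho") <- rho
  attr(f, "sigma_min") <- sigma_min
  f
}
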