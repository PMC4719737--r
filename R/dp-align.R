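#' Chi-square contribution of a match
#'
#' The sizing-error penalty of matching experimental fragments summing to
#' `o_sum` against reference fragments summing to `r_sum` with sizing
#' variance `r_var`: `(o_sum - r_sum)^2 / r_var`.
#'
#' @param o_sum,r_sum Sums in bp.
#' @param r_var Variance in bp^2, > 0.
#' @return Numeric chi-square contribution.
#' @examples
#' match_chi2(11000, 10000, 250000) # (1000/500)^2 = 4
#' @export
match_chi2 <- function(o_sum, r_sum, r_var) {
  if (any(r_var <= 0)) stop("r_var must be > 0")
  (o_sum - r_sum)^2 / r_var
}

#' Decide whether a small reference fragment may be treated as missing
#'
#' Fragment `j` inside the match of experimental sum `o_sum` against
#' reference fragments `l..t` may be skipped (together with up to
#' `gap_max_run - 1` further consecutive small fragments, here tested for
#' `j` alone) when the resulting match is feasible and its chi-square is at
#' most half of the best feasible alternative that keeps `j`, or when
#' keeping `j` admits no feasible match at all.
#'
#' @param o_sum Experimental fragment sum in bp.
#' @param fragments,sigmas Reference fragment sizes and standard deviations.
#' @param l,t Reference fragment range of the match.
#' @param j Index of the candidate missing fragment, `l < j < t`.
#' @param params An [align_params()].
#' @return Logical.
#' @export
allow_gap <- function(o_sum, fragments, sigmas, l, t, j,
                      params = align_params()) {
  if (fragments[j] > params$small_fragment_bp) return(FALSE)
  if (j <= l || j >= t) return(FALSE)
  inc <- range_stats(fragments, sigmas, l, t)
  exc <- range_stats(fragments, sigmas, l, t, gaps = j)
  if (exc[["var"]] <= 0) return(FALSE)
  exc_feas <- feasible(o_sum, exc[["sum"]], exc[["var"]], params$C_sigma)
  if (!exc_feas) return(FALSE)
  inc_feas <- feasible(o_sum, inc[["sum"]], inc[["var"]], params$C_sigma)
  if (!inc_feas) return(TRUE)
  chi_inc <- match_chi2(o_sum, inc[["sum"]], inc[["var"]])
  chi_exc <- match_chi2(o_sum, exc[["sum"]], exc[["var"]])
  chi_exc <= 0.5 * chi_inc
}

# Translate a seed hit into its two anchor matches, as a matrix of rows
# (q_start, q_end, r_start, r_end), 1-based inclusive.
seed_matches <- function(hit) {
  i <- hit$q_pos
  j <- hit$r_pos
  qm <- hit$q_variant == "merged"
  q1 <- if (qm) c(i, i + 1L) else c(i, i)
  q2 <- if (qm) c(i + 2L, i + 2L) else c(i + 1L, i + 1L)
  r1 <- switch(hit$variant,
    plain   = c(j, j),
    merge12 = c(j, j + 1L),
    merge23 = c(j, j)
  )
  r2 <- switch(hit$variant,
    plain   = c(j + 1L, j + 1L),
    merge12 = c(j + 2L, j + 2L),
    merge23 = c(j + 1L, j + 2L)
  )
  matrix(c(q1[1], q2[1], q1[2], q2[2], r1[1], r2[1], r1[2], r2[2]),
         nrow = 2, ncol = 4,
         dimnames = list(NULL, c("q_start", "q_end", "r_start", "r_end")))
}

#' Extend a seed into an optimal alignment
#'
#' Runs banded dynamic programming on both sides of the seed, minimizing the
#' total number of cut errors (missing cuts + false cuts + missing
#' fragments) with ties broken by the total sizing chi-square. In glocal
#' mode the whole experimental map must be covered (end matches may be
#' truncated under a one-sided bound); in overlap mode each side instead
#' stops at the first end of either map it reaches, preferring longer
#' alignments.
#'
#' @param o Numeric vector of experimental fragment sizes.
#' @param fragments,sigmas Reference fragment sizes and standard deviations.
#' @param hit One seed hit (a one-row tibble or list with `q_pos`, `r_pos`,
#'   `variant`, `q_variant`).
#' @param params An [align_params()].
#' @param mode `"glocal"` or `"overlap"`.
#' @return A list describing the alignment (`matches`, error counts, `chi2`,
#'   `score`, aligned ranges) or `NULL` when no feasible extension exists.
#' @export
extend_seed <- function(o, fragments, sigmas, hit, params = align_params(),
                        mode = c("glocal", "overlap")) {
  mode <- match.arg(mode)
  sm <- seed_matches(hit)
  m <- length(o)
  n <- length(fragments)
  if (sm[2, "q_end"] > m || sm[2, "r_end"] > n || sm[1, "q_start"] < 1 ||
      sm[1, "r_start"] < 1) {
    stop("seed hit is inconsistent with the given maps")
  }
  res <- dp_extend_cpp(o, fragments, sigmas^2, sm,
                       params$C_sigma, params$max_false_cuts,
                       params$max_missing_cuts, params$f_min_feasible,
                       params$small_fragment_bp, params$gap_max_run,
                       mode == "overlap", params$include_truncated_chi2)
  if (!isTRUE(res$found)) return(NULL)
  res$found <- NULL
  res$mode <- mode
  res
}
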