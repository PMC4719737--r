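#' Wilson-Hilferty transform of a chi-square score
#'
#' Maps a chi-square statistic with `n_matches` degrees of freedom (one per
#' match of the alignment) to an approximately standard-normal score via the
#' cube-root transform. Converges quickly, which is what makes the sizing
#' error comparable across candidate alignments of different structure.
#'
#' @param chi2 Non-negative chi-square value.
#' @param n_matches Number of matches, >= 1.
#' @return Numeric score.
#' @examples
#' wht(2, 2) # 1/3
#' @export
wht <- function(chi2, n_matches) {
  if (any(n_matches < 1)) stop("n_matches must be >= 1")
  a <- 2 / (9 * n_matches)
  ((chi2 / n_matches)^(1 / 3) - (1 - a)) / sqrt(a)
}

# population Z-transform; a zero-spread feature carries no information and
# standardizes to 0
zpop <- function(x) {
  mu <- mean(x)
  sdv <- sqrt(mean((x - mu)^2))
  if (sdv == 0) return(rep(0, length(x)))
  (x - mu) / sdv
}

#' Per-feature Z-scores over a candidate population
#'
#' Standardizes each alignment feature (number of matches, cut errors,
#' Wilson-Hilferty transformed chi-square) against the mean and population
#' standard deviation of all candidate solutions found for the same
#' experimental map. A feature with zero spread yields Z = 0 for every
#' candidate.
#'
#' @param features A data frame with columns `n_matches`, `cut_errors`,
#'   `wht`.
#' @return A tibble of the same rows with columns `z_matches`,
#'   `z_cut_errors`, `z_wht`.
#' @export
feature_zscores <- function(features) {
  if (nrow(features) < 2) stop("insufficient candidates: need at least 2")
  tibble::tibble(
    z_matches = zpop(features$n_matches),
    z_cut_errors = zpop(features$cut_errors),
    z_wht = zpop(features$wht)
  )
}

#' Combined candidate score and p-value
#'
#' Sums the per-feature Z-scores with signs reflecting whether lower values
#' are preferable (-1 for the number of matches, where more matches mean a
#' more reliable alignment; +1 for cut errors and the transformed sizing
#' error), re-standardizes the sum over the population, and converts the
#' resulting score to a p-value under the standard normal.
#'
#' @param z A data frame from [feature_zscores()].
#' @return A tibble with columns `vartheta` and `p_value`.
#' @export
combine_zscores <- function(z) {
  inner <- -z$z_matches + z$z_cut_errors + z$z_wht
  v <- zpop(inner)
  tibble::tibble(vartheta = v, p_value = stats::pnorm(v))
}

# Fragment-count strata for the FDR analysis: bins of width 2 fragments,
# merged left-to-right until each stratum holds at least `min_n` maps.
fdr_strata <- function(m, min_n = 50) {
  bin <- floor(m / 2)
  ub <- sort(unique(bin))
  counts <- vapply(ub, function(b) sum(bin == b), integer(1))
  stratum_of <- integer(length(ub))
  cur <- 1L
  acc <- 0L
  for (i in seq_along(ub)) {
    stratum_of[i] <- cur
    acc <- acc + counts[i]
    if (acc >= min_n && i < length(ub)) {
      cur <- cur + 1L
      acc <- 0L
    }
  }
  # a trailing underfull stratum is merged into its predecessor
  if (acc < min_n && cur > 1L) {
    stratum_of[stratum_of == cur] <- cur - 1L
  }
  stratum_of[match(bin, ub)]
}

#' Significance and uniqueness assessment of best alignments
#'
#' Computes FDR q-values (Benjamini-Hochberg) over the candidate-solution
#' p-values of comparable experimental maps - those in the same
#' fragment-count stratum - and combines them with the uniqueness ratio
#' between the next-best and best p-value of each map to call a status:
#' `significant_unique`, `non_unique`, `non_significant`, or the map's
#' pre-existing failure reason.
#'
#' When `candidates` is supplied, the null population for the FDR
#' adjustment is the pooled set of *all* candidate p-values of the
#' stratum's maps; since sub-optimal candidates are approximately uniform
#' on (0, 1), this anchors the adjustment to the noise population and
#' keeps the false-discovery proportion controlled even when many maps
#' carry a weak spurious optimum. Without `candidates` the adjustment
#' falls back to the best p-values alone.
#'
#' @param best A data frame with one row per experimental map and columns
#'   `map_id`, `n_fragments`, `p_value`, `p_next` (NA when no competing
#'   placement exists) and `n_candidates`.
#' @param params An [align_params()].
#' @param stratum_min_maps Minimum maps per fragment-count stratum before
#'   bins (width 2) are merged.
#' @param candidates Optional data frame of all candidate solutions with
#'   columns `map_id` and `p_value`.
#' @return `best` with added columns `q_value`, `uniqueness`, `status`.
#' @export
assess_alignments <- function(best, params = align_params(),
                              stratum_min_maps = 50, candidates = NULL) {
  out <- tibble::as_tibble(best)
  out$q_value <- NA_real_
  scorable <- !is.na(out$p_value) & out$n_candidates >= 2
  if (any(scorable)) {
    strat <- fdr_strata(out$n_fragments[scorable], min_n = stratum_min_maps)
    q <- rep(NA_real_, sum(scorable))
    sc_ids <- if ("map_id" %in% names(out)) out$map_id[scorable]
    for (sid in unique(strat)) {
      sel <- strat == sid
      p_best <- out$p_value[scorable][sel]
      pool <- p_best
      if (!is.null(candidates)) {
        cp <- candidates$p_value[candidates$map_id %in% sc_ids[sel]]
        cp <- cp[!is.na(cp)]
        if (length(cp)) pool <- cp
      }
      sp <- sort(pool)
      sq <- stats::p.adjust(sp, method = "BH")
      # BH-adjusted values are nondecreasing in p, so each best p reads off
      # the adjusted value at its position in the pooled sorted vector
      q[sel] <- sq[pmax(1L, findInterval(p_best, sp))]
    }
    out$q_value[scorable] <- q
  }
  out$uniqueness <- ifelse(is.na(out$p_next), Inf, out$p_next / out$p_value)
  out$status <- dplyr::case_when(
    is.na(out$p_value) & out$n_candidates == 0 ~ "no_feasible_alignment",
    out$n_candidates < 2 ~ "non_significant",
    out$q_value > params$q_threshold ~ "non_significant",
    out$uniqueness < params$uniqueness_ratio ~ "non_unique",
    TRUE ~ "significant_unique"
  )
  out$low_population <- !is.na(out$n_candidates) & out$n_candidates > 0 &
    out$n_candidates < 60
  out
}
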