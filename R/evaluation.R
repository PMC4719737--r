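reciprocal_overlap <- function(a1, a2, b1, b2, frac = 0.5) {
  ov <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
  ov >= frac * (a2 - a1) & ov >= frac * (b2 - b1)
}

#' Score a glocal alignment report against a truth log
#'
#' An alignment is counted correct when it names the true reference map and
#' strand and its reported reference interval overlaps the true source
#' interval by at least 50 % reciprocally (insensitive to truncated ends).
#' Sensitivity is correct significant-unique alignments over all simulated
#' maps; precision is correct over reported significant-unique alignments.
#'
#' @param report A [tidy()] report from [align_maps()].
#' @param truth A truth tibble from [simulate_maps()].
#' @return A one-row tibble: `n_maps`, `n_reported`, `n_correct`,
#'   `sensitivity`, `precision`.
#' @export
score_glocal <- function(report, truth) {
  if (!all(report$map_id %in% truth$map_id)) {
    stop("report contains map_ids missing from the truth log")
  }
  j <- dplyr::inner_join(report, truth, by = "map_id",
                         suffix = c("", ".truth"))
  rep_sel <- j$status == "significant_unique" & !is.na(j$ref_id)
  correct <- rep_sel & j$ref_id == j$ref_id.truth &
    j$orientation == j$orientation.truth &
    reciprocal_overlap(j$r_start_bp, j$r_end_bp, j$start_bp, j$end_bp)
  n_rep <- sum(rep_sel)
  tibble::tibble(
    n_maps = nrow(truth), n_reported = n_rep, n_correct = sum(correct),
    sensitivity = sum(correct) / nrow(truth),
    precision = if (n_rep > 0) sum(correct) / n_rep else NA_real_)
}

# Are any of a map's seed hits consistent with its true placement?  A hit is
# correct when it is on the true reference and strand and its reference
# position matches the truth-logged reference fragment of its first query
# constituent to within one fragment.
correct_seed_any <- function(o, truth_row, index, params, composite = TRUE) {
  m <- length(o)
  fr <- truth_row$frag_ref[[1]]
  for (qrev in c(FALSE, TRUE)) {
    h <- query_seeds(if (qrev) rev(o) else o, index, params,
                     composite = composite)
    if (!nrow(h)) next
    ref_fwd <- h$orientation == "forward"
    align_or <- ifelse(ref_fwd != qrev, "forward", "reverse")
    sel <- h$ref_id == truth_row$ref_id & align_or == truth_row$orientation
    if (!any(sel)) next
    i_st <- if (qrev) m + 1L - h$q_pos[sel] else h$q_pos[sel]
    expected <- fr[i_st]
    if (any(!is.na(expected) & abs(h$r_pos[sel] - expected) <= 1)) return(TRUE)
  }
  FALSE
}

#' Fraction of maps with at least one correct seed
#'
#' The sensitivity of the seeding stage alone: for each simulated map (with
#' at least `min_fragments` fragments), does the index lookup return any
#' seed at the map's true location and strand?
#'
#' @param maps,truth Output of [simulate_maps()].
#' @param index A [build_seed_index()] over the source references.
#' @param params An [align_params()].
#' @param min_fragments Only maps with at least this many fragments count.
#' @param composite Use composite seeds (`TRUE`) or plain 2-mers only.
#' @return A one-row tibble: `n_maps`, `n_with_correct_seed`, `pct`.
#' @export
seed_sensitivity <- function(maps, truth, index, params = align_params(),
                             min_fragments = 10, composite = TRUE) {
  keep <- maps$n_fragments >= min_fragments
  maps <- maps[keep, ]
  truth <- truth[match(maps$map_id, truth$map_id), ]
  hitv <- vapply(seq_len(nrow(maps)), function(i) {
    correct_seed_any(maps$fragments[[i]], truth[i, ], index, params,
                     composite = composite)
  }, logical(1))
  tibble::tibble(n_maps = nrow(maps), n_with_correct_seed = sum(hitv),
                 pct = 100 * mean(hitv))
}

#' Score an overlap alignment report against truth logs
#'
#' A reported overlap alignment is correct when it places the map on the
#' scaffold that covers its true source interval, on the true strand, with
#' the aligned interval (lifted to source-genome coordinates) overlapping
#' the true interval by at least 50 % of its aligned extent. A correct
#' alignment counts as an extension when at least one experimental fragment
#' protrudes past a scaffold end.
#'
#' @param report An overlap report from [overlap_align_maps()] ([tidy()]).
#' @param truth Map truth from [simulate_maps()] (source-genome intervals).
#' @param scaffold_truth Scaffold truth from [simulate_assembly()].
#' @return A one-row tibble: `n_reported`, `n_correct`, `precision`,
#'   `n_correct_extensions`.
#' @export
score_overlap <- function(report, truth, scaffold_truth) {
  if (!nrow(report)) {
    return(tibble::tibble(n_reported = 0L, n_correct = 0L,
                          precision = NA_real_, n_correct_extensions = 0L))
  }
  j <- dplyr::inner_join(report, truth, by = "map_id", suffix = c("", ".truth"))
  j <- dplyr::left_join(j, scaffold_truth,
                        by = c("ref_id" = "scaffold_id"), suffix = c("", ".scf"))
  g_start <- j$start_bp.scf + j$r_start_bp
  g_end <- j$start_bp.scf + j$r_end_bp
  ov <- pmax(0, pmin(g_end, j$end_bp) - pmax(g_start, j$start_bp))
  correct <- !is.na(j$ref_id.scf) & j$ref_id.scf == j$ref_id.truth &
    j$orientation == j$orientation.truth & ov >= 0.5 * (g_end - g_start)
  ext <- (j$extension_left + j$extension_right) >= 1
  tibble::tibble(
    n_reported = nrow(j), n_correct = sum(correct),
    precision = sum(correct) / nrow(j),
    n_correct_extensions = sum(correct & ext))
}
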