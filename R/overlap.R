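# implied placement of the whole map on the reference, in bp, from a window
# (or sub-map) solution; used to decide whether two placements agree
implied_start <- function(orientation, r_start_bp, r_end_bp, offset_bp) {
  ifelse(orientation == "forward", r_start_bp - offset_bp,
         r_end_bp + offset_bp)
}

#' Conflict test between two sub-map alignments
#'
#' Two window solutions of the same experimental map conflict when their
#' windows overlap, or when they align to the same reference map but at a
#' different location or strand. "Same location" means the two placements
#' imply the same position of the whole map on the reference to within
#' `params$conflict_tol_bp` (sizing errors shift implied positions by a few
#' kbp over a window).
#'
#' @param s1,s2 One-row window-solution tibbles with columns `window_start`,
#'   `window_end`, `ref_id`, `orientation`, `r_start_bp`, `r_end_bp`,
#'   `offset_bp`.
#' @param params An [align_params()].
#' @return Logical.
#' @export
conflicts <- function(s1, s2, params = align_params()) {
  if (s1$window_start <= s2$window_end && s2$window_start <= s1$window_end) {
    return(TRUE)
  }
  if (s1$ref_id != s2$ref_id) return(FALSE)
  if (s1$orientation != s2$orientation) return(TRUE)
  i1 <- implied_start(s1$orientation, s1$r_start_bp, s1$r_end_bp, s1$offset_bp)
  i2 <- implied_start(s2$orientation, s2$r_start_bp, s2$r_end_bp, s2$offset_bp)
  abs(i1 - i2) > params$conflict_tol_bp
}

# glocal sub-alignments of every sliding window of one map, with per-window
# best candidate and uniqueness
window_solutions <- function(o, map_id, index, params) {
  l <- params$window_l
  m <- length(o)
  pf <- c(0, cumsum(o))
  rows <- list()
  for (w in seq_len(m - l + 1)) {
    sub <- o[w:(w + l - 1)]
    cands <- glocal_candidates(sub, index, params)
    if (!nrow(cands)) {
      rows[[w]] <- tibble::tibble(
        map_id = map_id, window_start = w, window_end = w + l - 1L,
        offset_bp = pf[w], n_candidates = 0L, p_value = NA_real_,
        p_next = NA_real_, ref = NA_integer_, ref_id = NA_character_,
        orientation = NA_character_, r_start = NA_integer_,
        r_end = NA_integer_, r_start_bp = NA_real_, r_end_bp = NA_real_,
        best = list(NULL))
      next
    }
    if (nrow(cands) >= 2) {
      cands <- score_candidates(cands)
      bb <- pick_best(cands)
      best <- bb$best
      p_next <- bb$p_next
      cand_p <- cands$p_value
    } else {
      best <- cands[1, ]
      best$p_value <- NA_real_
      p_next <- NA_real_
      cand_p <- numeric(0)
    }
    rows[[w]] <- tibble::tibble(
      map_id = map_id, window_start = w, window_end = w + l - 1L,
      offset_bp = pf[w], n_candidates = nrow(cands), p_value = best$p_value,
      p_next = p_next, ref = best$ref, ref_id = best$ref_id,
      orientation = best$orientation, r_start = best$r_start,
      r_end = best$r_end, r_start_bp = best$r_start_bp,
      r_end_bp = best$r_end_bp, best = list(best), cand_p = list(cand_p))
  }
  dplyr::bind_rows(rows)
}

# Extend a window's best sub-alignment to an overlap alignment over the full
# map: seed the overlap-mode DP with the sub-alignment's non-truncated
# matches, shifted to full-map coordinates.
extend_window <- function(o, win, index, params) {
  best <- win$best[[1]]
  mt <- best$matches[[1]]
  mt <- mt[mt[, "truncated"] == 0, , drop = FALSE]
  if (!nrow(mt)) return(NULL)
  m <- length(o)
  w <- win$window_start
  qs <- mt[, "q_start"] + w - 1L
  qe <- mt[, "q_end"] + w - 1L
  rs <- mt[, "r_start"]
  re <- mt[, "r_end"]
  rev_q <- best$orientation == "reverse"
  if (rev_q) {
    o_use <- rev(o)
    qs2 <- m + 1L - qe
    qe2 <- m + 1L - qs
    ord <- order(qs2)
    seed <- cbind(qs2, qe2, rs, re)[ord, , drop = FALSE]
  } else {
    o_use <- o
    seed <- cbind(qs, qe, rs, re)
  }
  f <- index$refs$fragments[[best$ref]]
  s <- index$refs$sigmas[[best$ref]]
  res <- dp_extend_cpp(o_use, f, s^2, seed, params$C_sigma,
                       params$max_false_cuts, params$max_missing_cuts,
                       params$f_min_feasible, params$small_fragment_bp,
                       params$gap_max_run, TRUE, params$include_truncated_chi2)
  if (!isTRUE(res$found)) return(NULL)
  qa <- c(res$q_aligned_start, res$q_aligned_end)
  if (rev_q) qa <- c(m + 1L - qa[2], m + 1L - qa[1])
  pf <- c(0, cumsum(f))
  ext_left <- qa[1] - 1L
  ext_right <- m - qa[2]
  tibble::tibble(
    map_id = win$map_id, window_start = win$window_start,
    ref_id = best$ref_id, orientation = best$orientation,
    r_start = res$r_start, r_end = res$r_end,
    r_start_bp = pf[res$r_start], r_end_bp = pf[res$r_end + 1],
    q_aligned_start = qa[1], q_aligned_end = qa[2],
    extension_left = ext_left, extension_right = ext_right,
    n_matches = res$n_matches, missing_cuts = res$missing_cuts,
    false_cuts = res$false_cuts, missing_fragments = res$missing_fragments,
    chi2 = res$chi2, score = res$score)
}

#' Overlap alignment of experimental maps by sliding windows
#'
#' Divides each experimental map into sub-maps of `params$window_l`
#' fragments with a step-1 sliding window, glocally aligns and statistically
#' evaluates every window, then iterates the ranked window solutions
#' best-first: stopping at the first non-significant or non-unique solution,
#' skipping duplicates, solutions conflicting with better-ranked picks, and
#' solutions non-unique against worse-ranked conflicting ones, and extending
#' each survivor with overlap-mode dynamic programming until it reaches an
#' end of either map on both sides. Multiple non-conflicting overlaps per
#' map (split alignments) are reported.
#'
#' @inheritParams align_maps
#' @return An object of class `"om_overlaps"`; [tidy()] gives the report
#'   (one row per reported overlap, with `overlap_type` and extension
#'   fragment counts), `$windows` the per-window solutions.
#' @export
overlap_align_maps <- function(maps, refs = NULL, params = align_params(),
                               index = NULL) {
  if (is.null(index)) index <- build_seed_index(refs, params)
  wins <- list()
  for (i in seq_len(nrow(maps))) {
    o <- maps$fragments[[i]]
    if (length(o) < params$window_l) next
    wins[[length(wins) + 1L]] <-
      window_solutions(o, maps$map_id[i], index, params)
  }
  wins <- dplyr::bind_rows(wins)
  if (!nrow(wins)) {
    return(structure(list(report = tibble::tibble(), windows = wins,
                          params = params),
                     class = "om_overlaps"))
  }
  # pooled q-value analysis over all candidate solutions found for the
  # sliding windows of the run (windows share length: one stratum)
  wins$q_value <- NA_real_
  has_p <- !is.na(wins$p_value)
  pool <- sort(unlist(wins$cand_p))
  if (length(pool)) {
    padj <- stats::p.adjust(pool, method = "BH")
    wins$q_value[has_p] <-
      padj[pmax(1L, findInterval(wins$p_value[has_p], pool))]
  }
  wins$uniqueness <- ifelse(is.na(wins$p_next), Inf, wins$p_next / wins$p_value)
  wins$label <- dplyr::case_when(
    wins$n_candidates == 0 ~ "no_feasible_alignment",
    wins$n_candidates < 2 ~ "non_significant",
    wins$q_value > params$q_threshold ~ "non_significant",
    wins$uniqueness < params$uniqueness_ratio ~ "non_unique",
    TRUE ~ "significant_unique"
  )

  reports <- list()
  for (id in unique(wins$map_id)) {
    mw <- wins[wins$map_id == id, ]
    sols <- mw[!is.na(mw$p_value), ]
    if (!nrow(sols)) next
    sols <- sols[order(sols$p_value, sols$window_start), ]
    o <- maps$fragments[[match(id, maps$map_id)]]
    picked <- list()
    picked_ext <- list()
    for (k in seq_len(nrow(sols))) {
      cur <- sols[k, ]
      if (cur$label != "significant_unique") break
      if (any(vapply(picked, function(p) conflicts(p, cur, params),
                     logical(1)))) next
      later <- sols[-seq_len(k), , drop = FALSE]
      if (nrow(later)) {
        conf_later <- vapply(seq_len(nrow(later)), function(jj)
          conflicts(cur, later[jj, ], params), logical(1))
        if (any(conf_later &
                later$p_value / cur$p_value < params$uniqueness_ratio)) next
      }
      ext <- extend_window(o, cur, index, params)
      if (is.null(ext)) next
      dup <- any(vapply(picked_ext, function(e)
        e$ref_id == ext$ref_id && e$orientation == ext$orientation &&
          e$r_start == ext$r_start && e$r_end == ext$r_end, logical(1)))
      if (dup) next
      ext$p_value <- cur$p_value
      ext$q_value <- cur$q_value
      ext$uniqueness <- cur$uniqueness
      picked[[length(picked) + 1L]] <- cur
      picked_ext[[length(picked_ext) + 1L]] <- ext
    }
    if (!length(picked_ext)) next
    rep <- dplyr::bind_rows(picked_ext)
    rep$overlap_type <- dplyr::case_when(
      nrow(rep) > 1 ~ "split-part",
      rep$extension_left == 0 & rep$extension_right == 0 ~ "contained",
      rep$extension_left > 0 & rep$extension_right > 0 ~ "both",
      rep$extension_left > 0 ~ "left",
      TRUE ~ "right"
    )
    reports[[length(reports) + 1L]] <- rep
  }
  structure(list(report = dplyr::bind_rows(reports), windows = wins,
                 params = params, refs = index$refs),
            class = "om_overlaps")
}

#' @export
print.om_overlaps <- function(x, ...) {
  cat(sprintf("<om_overlaps> %d reported overlap(s) from %d window solution(s)\n",
              nrow(x$report), nrow(x$windows)))
  invisible(x)
}

#' @describeIn overlap_align_maps Overlap report as a tibble.
#' @param x An `om_overlaps` object.
#' @param ... Unused.
#' @export
tidy.om_overlaps <- function(x, ...) x$report

#' @describeIn overlap_align_maps One-row summary of an overlap run.
#' @export
glance.om_overlaps <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_maps = length(unique(x$windows$map_id)),
    n_overlaps = nrow(r),
    n_extending = if (nrow(r)) {
      sum(r$extension_left + r$extension_right >= 1)
    } else 0L,
    n_split = if (nrow(r)) sum(r$overlap_type == "split-part") else 0L)
}
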