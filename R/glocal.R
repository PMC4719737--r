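#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

candidate_cols <- function() {
  tibble::tibble(
    map_id = character(0), ref = integer(0), ref_id = character(0),
    orientation = character(0), r_start = integer(0), r_end = integer(0),
    r_start_bp = numeric(0), r_end_bp = numeric(0),
    q_aligned_start = integer(0), q_aligned_end = integer(0),
    n_matches = integer(0), missing_cuts = integer(0),
    false_cuts = integer(0), missing_fragments = integer(0),
    cut_errors = integer(0), chi2 = numeric(0), score = numeric(0),
    wht = numeric(0), matches = list()
  )
}

# All deduplicated feasible extensions of every seed of one experimental map.
# The reverse strand is searched by reversing the query, not the index.
glocal_candidates <- function(o, index, params, mode = "glocal",
                              composite = TRUE) {
  m <- length(o)
  refs <- index$refs
  runs <- list(list(o = o, rev = FALSE), list(o = rev(o), rev = TRUE))
  hits <- dplyr::bind_rows(lapply(runs, function(rn) {
    h <- query_seeds(rn$o, index, params, composite = composite)
    if (nrow(h)) h$query_rev <- rn$rev else h$query_rev <- logical(0)
    h
  }))
  if (!nrow(hits)) return(candidate_cols())
  ref_fwd <- hits$orientation == "forward"
  hits$align_orientation <- ifelse(ref_fwd != hits$query_rev, "forward", "reverse")
  hits <- hits[order(hits$seed_errors), ]
  hits <- hits[!duplicated(hits[, c("ref", "align_orientation", "r_pos",
                                    "q_pos", "query_rev")]), ]
  # batch the DP extensions per (reference, query strand) group
  grp <- paste(hits$ref, hits$query_rev)
  ext <- vector("list", nrow(hits))
  for (g in unique(grp)) {
    sel <- which(grp == g)
    ri <- hits$ref[sel[1]]
    qrev <- hits$query_rev[sel[1]]
    hm <- cbind(hits$q_pos[sel], hits$r_pos[sel],
                match(hits$variant[sel], c("plain", "merge12", "merge23")),
                as.integer(hits$q_variant[sel] == "merged"))
    res <- dp_extend_batch_cpp(
      if (qrev) rev(o) else o, refs$fragments[[ri]], refs$sigmas[[ri]]^2, hm,
      params$C_sigma, params$max_false_cuts, params$max_missing_cuts,
      params$f_min_feasible, params$small_fragment_bp, params$gap_max_run,
      mode == "overlap", params$include_truncated_chi2)
    for (k in seq_along(sel)) ext[[sel[k]]] <- res[[k]]
  }
  pf_cache <- vector("list", max(hits$ref))
  for (ri in unique(hits$ref)) {
    pf_cache[[ri]] <- c(0, cumsum(refs$fragments[[ri]]))
  }
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cand <- ext[[i]]
    if (is.null(cand) || !isTRUE(cand$found)) next
    h <- list(ref = hits$ref[i], ref_id = hits$ref_id[i],
              align_orientation = hits$align_orientation[i],
              query_rev = hits$query_rev[i])
    mt <- cand$matches
    if (h$query_rev) {
      qs <- m + 1L - mt[, "q_end"]
      qe <- m + 1L - mt[, "q_start"]
      mt[, "q_start"] <- rev(qs)
      mt[, "q_end"] <- rev(qe)
      mt[, "r_start"] <- rev(mt[, "r_start"])
      mt[, "r_end"] <- rev(mt[, "r_end"])
      mt[, c("n_gaps", "truncated", "part")] <-
        mt[rev(seq_len(nrow(mt))), c("n_gaps", "truncated", "part")]
      qa <- c(m + 1L - cand$q_aligned_end, m + 1L - cand$q_aligned_start)
    } else {
      qa <- c(cand$q_aligned_start, cand$q_aligned_end)
    }
    pf <- pf_cache[[h$ref]]
    out[[i]] <- list(
      ref = h$ref, ref_id = h$ref_id, orientation = h$align_orientation,
      r_start = cand$r_start, r_end = cand$r_end,
      r_start_bp = pf[cand$r_start], r_end_bp = pf[cand$r_end + 1],
      q_aligned_start = qa[1], q_aligned_end = qa[2],
      n_matches = cand$n_matches, missing_cuts = cand$missing_cuts,
      false_cuts = cand$false_cuts, missing_fragments = cand$missing_fragments,
      cut_errors = cand$cut_errors, chi2 = cand$chi2, score = cand$score,
      wht = wht(cand$chi2, cand$n_matches), matches = mt
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(candidate_cols())
  fld <- function(nm, mode) vapply(out, function(x) x[[nm]], vector(mode, 1))
  cands <- tibble::tibble(
    ref = fld("ref", "integer"), ref_id = fld("ref_id", "character"),
    orientation = fld("orientation", "character"),
    r_start = fld("r_start", "integer"), r_end = fld("r_end", "integer"),
    r_start_bp = fld("r_start_bp", "double"),
    r_end_bp = fld("r_end_bp", "double"),
    q_aligned_start = fld("q_aligned_start", "integer"),
    q_aligned_end = fld("q_aligned_end", "integer"),
    n_matches = fld("n_matches", "integer"),
    missing_cuts = fld("missing_cuts", "integer"),
    false_cuts = fld("false_cuts", "integer"),
    missing_fragments = fld("missing_fragments", "integer"),
    cut_errors = fld("cut_errors", "integer"), chi2 = fld("chi2", "double"),
    score = fld("score", "double"), wht = fld("wht", "double"),
    matches = lapply(out, `[[`, "matches"))
  key <- paste(cands$ref, cands$r_start, cands$r_end,
               vapply(cands$matches, function(mm)
                 paste(mm[, 1:4], collapse = ","), character(1)))
  ord <- order(cands$cut_errors, cands$chi2)
  cands <- cands[ord, ]
  cands[!duplicated(key[ord]), ]
}

# attach vartheta / p_value to a candidate population (>= 2 members)
score_candidates <- function(cands) {
  z <- feature_zscores(cands)
  cbind(cands, combine_zscores(z))
}

# best candidate and the best p among non-overlapping competing placements
pick_best <- function(cands) {
  ord <- order(cands$p_value, cands$cut_errors, cands$chi2, cands$ref,
               cands$r_start)
  cands <- cands[ord, ]
  best <- cands[1, ]
  competing <- cands$ref != best$ref |
    cands$r_start > best$r_end | cands$r_end < best$r_start
  p_next <- if (any(competing)) min(cands$p_value[competing]) else NA_real_
  list(best = best, p_next = p_next)
}

#' Glocal alignment of experimental maps to reference maps
#'
#' The end-to-end aligner: for every experimental map, composite seeds are
#' looked up on both strands, each seed is extended by banded dynamic
#' programming into a feasible glocal alignment, the deduplicated candidate
#' population is scored statistically, and the best candidate is assessed
#' for significance (stratified FDR) and uniqueness.
#'
#' @param maps An experimental maps tibble ([read_maps()],
#'   [experimental_maps()], [simulate_maps()]).
#' @param refs A [reference_maps()] tibble (forward orientation; the reverse
#'   strand is searched automatically), or `NULL` when `index` is given.
#' @param params An [align_params()].
#' @param index Optional prebuilt [build_seed_index()] over `refs`.
#' @return An object of class `"om_alignments"`: use [tidy()] for the
#'   per-map report, [glance()] for a one-row summary, `$candidates` for the
#'   full candidate populations.
#' @export
align_maps <- function(maps, refs = NULL, params = align_params(),
                       index = NULL) {
  if (is.null(index)) index <- build_seed_index(refs, params)
  n <- nrow(maps)
  if (n == 0) {
    rep0 <- tibble::tibble(
      map_id = character(0), n_fragments = integer(0),
      ref_id = character(0), orientation = character(0),
      r_start = integer(0), r_end = integer(0), r_start_bp = numeric(0),
      r_end_bp = numeric(0), n_matches = integer(0),
      missing_cuts = integer(0), false_cuts = integer(0),
      missing_fragments = integer(0), chi2 = numeric(0), wht = numeric(0),
      vartheta = numeric(0), p_value = numeric(0), q_value = numeric(0),
      uniqueness = numeric(0), n_candidates = integer(0),
      status = character(0), low_population = logical(0))
    return(structure(list(report = rep0, candidates = candidate_cols(),
                          params = params, refs = index$refs),
                     class = "om_alignments"))
  }
  best_rows <- vector("list", n)
  cand_rows <- vector("list", n)
  for (i in seq_len(n)) {
    o <- maps$fragments[[i]]
    id <- maps$map_id[i]
    if (length(o) < params$c + 1) {
      best_rows[[i]] <- tibble::tibble(
        map_id = id, n_fragments = length(o), n_candidates = 0L,
        p_value = NA_real_, p_next = NA_real_,
        status_override = "rejected_too_few_fragments")
      next
    }
    cands <- glocal_candidates(o, index, params)
    if (!nrow(cands)) {
      best_rows[[i]] <- tibble::tibble(
        map_id = id, n_fragments = length(o), n_candidates = 0L,
        p_value = NA_real_, p_next = NA_real_, status_override = NA_character_)
      next
    }
    if (nrow(cands) == 1) {
      cands$vartheta <- NA_real_
      cands$p_value <- NA_real_
      bb <- list(best = cands[1, ], p_next = NA_real_)
    } else {
      cands <- score_candidates(cands)
      bb <- pick_best(cands)
    }
    cands$map_id <- id
    cand_rows[[i]] <- cands
    best_rows[[i]] <- tibble::tibble(
      map_id = id, n_fragments = length(o), n_candidates = nrow(cands),
      p_value = bb$best$p_value, p_next = bb$p_next,
      status_override = NA_character_, placement = list(bb$best))
  }
  best <- dplyr::bind_rows(best_rows)
  all_cands <- dplyr::bind_rows(cand_rows)
  best <- assess_alignments(best, params, candidates = all_cands)
  ov <- !is.na(best$status_override)
  best$status[ov] <- best$status_override[ov]
  report <- dplyr::bind_cols(
    best[, c("map_id", "n_fragments")],
    dplyr::bind_rows(lapply(seq_len(nrow(best)), function(i) {
      pl <- if ("placement" %in% names(best) && !is.null(best$placement[[i]])) {
        best$placement[[i]]
      } else NULL
      if (is.null(pl)) {
        tibble::tibble(ref_id = NA_character_, orientation = NA_character_,
                       r_start = NA_integer_, r_end = NA_integer_,
                       r_start_bp = NA_real_, r_end_bp = NA_real_,
                       n_matches = NA_integer_, missing_cuts = NA_integer_,
                       false_cuts = NA_integer_,
                       missing_fragments = NA_integer_, chi2 = NA_real_,
                       wht = NA_real_, vartheta = NA_real_)
      } else {
        pl[, c("ref_id", "orientation", "r_start", "r_end", "r_start_bp",
               "r_end_bp", "n_matches", "missing_cuts", "false_cuts",
               "missing_fragments", "chi2", "wht", "vartheta")]
      }
    })),
    best[, c("p_value", "q_value", "uniqueness", "n_candidates", "status",
             "low_population")]
  )
  structure(list(report = tibble::as_tibble(report),
                 candidates = all_cands,
                 params = params, refs = index$refs),
            class = "om_alignments")
}

#' @export
print.om_alignments <- function(x, ...) {
  n <- nrow(x$report)
  su <- sum(x$report$status == "significant_unique", na.rm = TRUE)
  cat(sprintf("<om_alignments> %d map(s), %d significant and unique (q <= %g, ratio >= %g)\n",
              n, su, x$params$q_threshold, x$params$uniqueness_ratio))
  invisible(x)
}

#' @describeIn align_maps Per-map alignment report as a tibble.
#' @param x An `om_alignments` object.
#' @param ... Unused.
#' @export
tidy.om_alignments <- function(x, ...) x$report

#' @describeIn align_maps One-row summary of an alignment run.
#' @export
glance.om_alignments <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_maps = nrow(r),
    n_significant_unique = sum(r$status == "significant_unique", na.rm = TRUE),
    n_non_unique = sum(r$status == "non_unique", na.rm = TRUE),
    n_non_significant = sum(r$status == "non_significant", na.rm = TRUE),
    n_no_alignment = sum(r$status == "no_feasible_alignment", na.rm = TRUE),
    median_candidates = stats::median(r$n_candidates, na.rm = TRUE)
  )
}

#' Write an alignment report as TSV
#'
#' Emits the canonical column order used by downstream tooling:
#' map_id, ref_id, orientation, r_start, r_end, n_matches, missing_cuts,
#' false_cuts, missing_fragments, chi2, wht, vartheta, p_value, q_value,
#' n_candidates, status.
#'
#' @param x An `om_alignments` object or its [tidy()] report.
#' @param path Output path.
#' @param extra Comment lines (without the leading `#`) written above the
#'   header, e.g. a configuration hash.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, extra = character(0)) {
  rep <- if (inherits(x, "om_alignments")) x$report else x
  cols <- c("map_id", "ref_id", "orientation", "r_start", "r_end",
            "n_matches", "missing_cuts", "false_cuts", "missing_fragments",
            "chi2", "wht", "vartheta", "p_value", "q_value", "n_candidates",
            "status")
  cols <- intersect(cols, names(rep))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(extra)) writeLines(paste0("# ", extra), con)
  utils::write.table(rep[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
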