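#' Build a sorted index of continuous-valued composite seeds
#'
#' For every position `j` of every reference map the index holds the 2-tuples
#' `(r_j, r_{j+1})` (plain), `(r_j + r_{j+1}, r_{j+2})` (merge12) and
#' `(r_j, r_{j+1} + r_{j+2})` (merge23). The two merged variants pre-absorb
#' one missing cut in the experimental map (equivalently a false cut in the
#' in-silico map), which is what lets short error-prone maps still anchor.
#' Entries are sorted by their first element so lookups can binary-search an
#' interval and then verify each candidate against its own standard
#' deviation.
#'
#' The search interval is made safe by two monotone envelopes precomputed at
#' build time: the running maximum of `key + C * sd` and the suffix minimum
#' of `key - C * sd`. Any entry outside the bracketing interval provably
#' fails its own per-element test, so no true candidate is skipped regardless
#' of how heteroskedastic the sigma model is.
#'
#' @param refs A [reference_maps()] tibble (typically forward orientation
#'   only; the aligner searches the reverse strand by reversing the query).
#' @param params An [align_params()]; `c` must be 2.
#' @return An object of class `"om_seed_index"`.
#' @export
build_seed_index <- function(refs, params = align_params()) {
  if (params$c != 2) stop("unsupported seed order: only c = 2 is implemented")
  if (!nrow(refs)) stop("no reference maps to index")
  per_ref <- lapply(seq_len(nrow(refs)), function(ri) {
    f <- refs$fragments[[ri]]
    s <- refs$sigmas[[ri]]
    v <- s^2
    n <- length(f)
    out <- list()
    if (n >= 2) {
      j <- seq_len(n - 1)
      out$plain <- list(key1 = f[j], var1 = v[j],
                        key2 = f[j + 1], var2 = v[j + 1],
                        r_pos = j, variant = rep(1L, n - 1))
    }
    if (n >= 3) {
      j <- seq_len(n - 2)
      out$m12 <- list(key1 = f[j] + f[j + 1], var1 = v[j] + v[j + 1],
                      key2 = f[j + 2], var2 = v[j + 2],
                      r_pos = j, variant = rep(2L, n - 2))
      out$m23 <- list(key1 = f[j], var1 = v[j],
                      key2 = f[j + 1] + f[j + 2], var2 = v[j + 1] + v[j + 2],
                      r_pos = j, variant = rep(3L, n - 2))
    }
    if (!length(out)) return(NULL)
    cmb <- lapply(names(out[[1]]), function(nm)
      unlist(lapply(out, `[[`, nm), use.names = FALSE))
    names(cmb) <- names(out[[1]])
    cmb$ref <- rep.int(ri, length(cmb$key1))
    cmb
  })
  per_ref <- per_ref[!vapply(per_ref, is.null, logical(1))]
  if (!length(per_ref)) stop("reference maps are too short to index (need >= 2 fragments)")
  nm <- names(per_ref[[1]])
  idx <- lapply(nm, function(x) unlist(lapply(per_ref, `[[`, x), use.names = FALSE))
  names(idx) <- nm
  ord <- order(idx$key1, idx$key2)
  idx <- lapply(idx, `[`, ord)
  idx$sd1 <- sqrt(idx$var1)
  idx$sd2 <- sqrt(idx$var2)
  idx$var1 <- idx$var2 <- NULL
  C <- params$C_sigma_seed
  idx$env_hi <- cummax(idx$key1 + C * idx$sd1)
  idx$env_lo <- rev(cummin(rev(idx$key1 - C * idx$sd1)))
  structure(list(entries = idx, refs = refs, C_env = C, params = params),
            class = "om_seed_index")
}

#' @export
print.om_seed_index <- function(x, ...) {
  cat(sprintf("<om_seed_index> %d entries over %d reference map(s), C_seed = %g\n",
              length(x$entries$key1), nrow(x$refs), x$C_env))
  invisible(x)
}

seed_window <- function(index, q, C) {
  e <- index$entries
  # smallest entry whose (key + C sd) running max reaches q; largest whose
  # suffix min of (key - C sd) is still <= q
  lo <- findInterval(q, e$env_hi, left.open = TRUE) + 1L
  hi <- findInterval(q, e$env_lo)
  c(lo, hi)
}

#' Look up candidate seeds for an experimental map
#'
#' Query tuples are formed from consecutive experimental fragments:
#' `(o_i, o_{i+1})` and, to absorb one false cut on the experimental side,
#' `(o_i + o_{i+1}, o_{i+2})`. Every index entry whose elements all agree
#' with the query tuple within `C_sigma_seed` reference standard deviations
#' is returned.
#'
#' @param o Numeric vector of experimental fragment sizes (bp), or a one-row
#'   experimental maps tibble.
#' @param index An [build_seed_index()] object.
#' @param params An [align_params()].
#' @param composite If `FALSE`, restrict to plain 2-mers on both sides
#'   (no merged variants); used to quantify what composite seeding buys.
#' @return A tibble of seed hits: `ref` (row in the indexed reference table),
#'   `ref_id`, `orientation` (of the indexed map), `r_pos`, `variant`,
#'   `q_pos`, `q_variant`, `seed_errors`.
#' @export
query_seeds <- function(o, index, params = index$params, composite = TRUE) {
  if (is.data.frame(o)) o <- o$fragments[[1]]
  m <- length(o)
  if (m < params$c + 1) {
    return(tibble::tibble(ref = integer(0), ref_id = character(0),
                          orientation = character(0), r_pos = integer(0),
                          variant = character(0), q_pos = integer(0),
                          q_variant = character(0), seed_errors = integer(0)))
  }
  C <- params$C_sigma_seed
  if (!isTRUE(all.equal(C, index$C_env))) {
    # envelopes were built for a different bound; rebuild them for this one
    e <- index$entries
    index$entries$env_hi <- cummax(e$key1 + C * e$sd1)
    index$entries$env_lo <- rev(cummin(rev(e$key1 - C * e$sd1)))
    index$C_env <- C
  }
  e <- index$entries
  tuples <- list()
  i <- seq_len(m - 1)
  tuples$plain <- list(q1 = o[i], q2 = o[i + 1], q_pos = i,
                       q_variant = rep("plain", m - 1))
  if (composite && m >= 3) {
    i <- seq_len(m - 2)
    tuples$merged <- list(q1 = o[i] + o[i + 1], q2 = o[i + 2], q_pos = i,
                          q_variant = rep("merged", m - 2))
  }
  acc_ref <- list(); acc_rpos <- list(); acc_var <- list()
  acc_qpos <- list(); acc_qvar <- list()
  nres <- 0L
  for (tp in tuples) {
    for (k in seq_along(tp$q_pos)) {
      w <- seed_window(index, tp$q1[k], C)
      if (w[1] > w[2]) next
      sel <- w[1]:w[2]
      ok <- abs(tp$q1[k] - e$key1[sel]) <= C * e$sd1[sel] &
            abs(tp$q2[k] - e$key2[sel]) <= C * e$sd2[sel]
      if (!composite) ok <- ok & e$variant[sel] == 1L
      if (!any(ok)) next
      sel <- sel[ok]
      nres <- nres + 1L
      acc_ref[[nres]] <- e$ref[sel]
      acc_rpos[[nres]] <- e$r_pos[sel]
      acc_var[[nres]] <- e$variant[sel]
      acc_qpos[[nres]] <- rep.int(tp$q_pos[k], length(sel))
      acc_qvar[[nres]] <- rep.int(tp$q_variant[k], length(sel))
    }
  }
  if (!nres) {
    return(tibble::tibble(ref = integer(0), ref_id = character(0),
                          orientation = character(0), r_pos = integer(0),
                          variant = character(0), q_pos = integer(0),
                          q_variant = character(0), seed_errors = integer(0)))
  }
  hits <- tibble::tibble(
    ref = unlist(acc_ref), r_pos = unlist(acc_rpos),
    variant = c("plain", "merge12", "merge23")[unlist(acc_var)],
    q_pos = unlist(acc_qpos), q_variant = unlist(acc_qvar))
  hits$ref_id <- index$refs$ref_id[hits$ref]
  hits$orientation <- if ("orientation" %in% names(index$refs)) {
    index$refs$orientation[hits$ref]
  } else "forward"
  hits$seed_errors <- (hits$variant != "plain") + (hits$q_variant != "plain")
  hits[, c("ref", "ref_id", "orientation", "r_pos", "variant",
           "q_pos", "q_variant", "seed_errors")]
}
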