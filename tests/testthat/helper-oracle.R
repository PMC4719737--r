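# Independent brute-force oracle for seed extension: exhaustively enumerates
# every glocal alignment that contains the seed matches, applying the match
# admissibility rules from the method's definition (feasibility bound,
# per-match band limits, small-fragment gap rule with the chi-square halving
# gate, one-sided end matches as fallback), and minimizes
# (cut errors, chi2) lexicographically over the full enumeration.
#
# Alignments are summarized as a table mapping total cut errors -> minimal
# chi2; both the lexicographic optimum and the minimum of the combined
# score C_ce * ce + chi2 are exact functions of that table because both
# objectives are additive and monotone per component.

oracle_match_variants <- function(o_sum, f, s2, l, t, at_query_end, params) {
  pfr <- sum(f[l:t])
  pvr <- sum(s2[l:t])
  d <- o_sum - pfr
  lim <- params$C_sigma * sqrt(pvr)
  variants <- list()
  if (abs(d) <= lim) {
    variants[[1]] <- list(chi2 = d^2 / pvr)
  }
  base_feas <- length(variants) > 0
  base_chi2 <- if (base_feas) variants[[1]]$chi2 else Inf
  smalls <- which(f <= params$small_fragment_bp)
  smalls <- smalls[smalls > l & smalls < t]
  if (length(smalls) > 0 && length(smalls) <= 8) {
    for (msk in seq_len(2^length(smalls) - 1)) {
      g <- smalls[bitwAnd(msk, 2^(seq_along(smalls) - 1)) > 0]
      runs <- rle(diff(c(-10, g)) == 1)
      maxrun <- max(c(1, runs$lengths[runs$values] + 1))
      if (maxrun > params$gap_max_run) next
      rs <- pfr - sum(f[g])
      rv <- pvr - sum(s2[g])
      if (rv <= 0) next
      dg <- o_sum - rs
      if (abs(dg) > params$C_sigma * sqrt(rv)) next
      ch <- dg^2 / rv
      if (base_feas && ch > 0.5 * base_chi2) next
      variants[[length(variants) + 1]] <- list(chi2 = ch)
    }
  }
  if (!length(variants) && at_query_end && d <= lim) {
    variants[[1]] <- list(
      chi2 = if (params$include_truncated_chi2) d^2 / pvr else 0)
  }
  variants
}

# merge a (ce -> min chi2) table entry
tab_add <- function(tab, ce, chi2) {
  key <- as.character(ce)
  if (is.null(tab[[key]]) || chi2 < tab[[key]]) tab[[key]] <- chi2
  tab
}

# all extensions covering query fragments qs..m (rightwards) after reference
# fragment t0, as a (ce -> min chi2) table; empty list when infeasible
oracle_side <- function(o, f, s2, qs, t0, params, memo = new.env()) {
  m <- length(o)
  n <- length(f)
  if (qs > m) return(list(`0` = 0))
  key <- paste(qs, t0)
  if (!is.null(memo[[key]])) return(memo[[key]])
  tab <- list()
  for (qe in qs:min(m, qs + params$max_false_cuts)) {
    o_sum <- sum(o[qs:qe])
    if (t0 + 1 > n) break
    for (te in (t0 + 1):min(n, t0 + 1 + params$max_missing_cuts)) {
      vs <- oracle_match_variants(o_sum, f, s2, t0 + 1, te, qe == m, params)
      if (!length(vs)) next
      rest <- oracle_side(o, f, s2, qe + 1, te, params, memo)
      ce_m <- (qe - qs) + (te - t0 - 1)
      for (v in vs) {
        for (rk in names(rest)) {
          tab <- tab_add(tab, ce_m + as.integer(rk), v$chi2 + rest[[rk]])
        }
      }
    }
  }
  memo[[key]] <- tab
  tab
}

oracle_extend <- function(o, f, sigmas, seed_mat, params) {
  s2 <- sigmas^2
  m <- length(o)
  seed_ce <- 0
  seed_chi2 <- 0
  for (k in seq_len(nrow(seed_mat))) {
    qs <- seed_mat[k, 1]; qe <- seed_mat[k, 2]
    rs <- seed_mat[k, 3]; re <- seed_mat[k, 4]
    o_sum <- sum(o[qs:qe])
    rsum <- sum(f[rs:re])
    rv <- sum(s2[rs:re])
    if (abs(o_sum - rsum) > params$C_sigma * sqrt(rv)) {
      return(list(found = FALSE))
    }
    seed_ce <- seed_ce + (qe - qs) + (re - rs)
    seed_chi2 <- seed_chi2 + (o_sum - rsum)^2 / rv
  }
  q0 <- seed_mat[1, 1]; q1 <- seed_mat[nrow(seed_mat), 2]
  r0 <- seed_mat[1, 3]; r1 <- seed_mat[nrow(seed_mat), 4]
  right <- oracle_side(o, f, s2, q1 + 1, r1, params)
  left <- oracle_side(rev(o[seq_len(q0 - 1)]), rev(f[seq_len(r0 - 1)]),
                      rev(s2[seq_len(r0 - 1)]), 1, 0, params)
  if (!length(right) || !length(left)) return(list(found = FALSE))
  ce <- numeric(0)
  chi2 <- numeric(0)
  for (lk in names(left)) {
    for (rk in names(right)) {
      ce <- c(ce, as.integer(lk) + as.integer(rk) + seed_ce)
      chi2 <- c(chi2, left[[lk]] + right[[rk]] + seed_chi2)
    }
  }
  agg <- tapply(chi2, ce, min)
  ce_u <- as.integer(names(agg))
  chi_u <- as.numeric(agg)
  ord <- order(ce_u, chi_u)
  C_ce <- params$C_sigma^2 * m + 1
  list(found = TRUE, ce = ce_u[ord[1]], chi2 = chi_u[ord[1]],
       score = C_ce * ce_u[ord[1]] + chi_u[ord[1]],
       eq2_min = min(C_ce * ce_u + chi_u))
}

# random small alignment instance with a known-good seed; the query is a
# perturbed copy of a reference slice with occasional merged cuts
random_dp_instance <- function(max_m = 6, max_n = 12) {
  n <- sample(8:max_n, 1)
  f <- pmax(500, stats::rexp(n, 1 / 12000))
  if (stats::runif(1) < 0.4) {
    f[sample(2:(n - 1), 1)] <- stats::runif(1, 500, 1900)
  }
  sigmas <- pmax(300, 0.05 * f)
  m <- sample(4:max_m, 1)
  l0 <- sample(seq_len(n - m - 1), 1)
  o <- numeric(0)
  truth_pos <- integer(0) # reference index of each 1:1 query fragment
  j <- l0
  while (length(o) < m && j <= n) {
    if (length(o) < m - 1 && j < n && stats::runif(1) < 0.2) {
      o <- c(o, f[j] + f[j + 1]) # merged (missing cut)
      truth_pos <- c(truth_pos, NA)
      j <- j + 2
    } else {
      o <- c(o, f[j])
      truth_pos <- c(truth_pos, j)
      j <- j + 1
    }
  }
  m <- length(o)
  o <- o * (1 + 0.02 * stats::rnorm(m))
  pair <- which(!is.na(truth_pos[-m]) & !is.na(truth_pos[-1]) &
                  diff(truth_pos) == 1)
  if (!length(pair)) return(NULL)
  i <- pair[1]
  seed <- cbind(c(i, i + 1L), c(i, i + 1L),
                c(truth_pos[i], truth_pos[i + 1]),
                c(truth_pos[i], truth_pos[i + 1]))
  list(o = o, f = f, sigmas = sigmas, seed = seed)
}
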