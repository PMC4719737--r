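#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
#' @import Rcpp
#' @useDynLib rmapalign, .registration = TRUE
NULL

new_map_tbl <- function(map_id, fragments) {
  tibble::tibble(
    map_id = as.character(map_id),
    n_fragments = vapply(fragments, length, integer(1)),
    total_bp = vapply(fragments, sum, numeric(1)),
    fragments = fragments
  )
}

#' Construct a table of experimental maps
#'
#' An experimental (optical) map is an ordered list of positive fragment
#' sizes in bp. Collections of maps are represented as tibbles with one row
#' per map and a list-column `fragments`.
#'
#' @param map_id Character vector of identifiers.
#' @param fragments List of numeric vectors, fragment sizes in bp.
#' @return A tibble with columns `map_id`, `n_fragments`, `total_bp`,
#'   `fragments`.
#' @examples
#' experimental_maps("m1", list(c(10000, 20000)))
#' @export
experimental_maps <- function(map_id, fragments) {
  if (!is.list(fragments)) fragments <- list(fragments)
  ok <- vapply(fragments, function(f) length(f) > 0 && all(is.finite(f)) && all(f > 0),
               logical(1))
  if (!all(ok)) stop("all fragment sizes must be finite and > 0")
  new_map_tbl(map_id, lapply(fragments, as.numeric))
}

#' Construct a table of reference (in-silico) maps
#'
#' A reference map carries, besides ordered fragment sizes, a per-fragment
#' standard deviation used by all feasibility tests. If `sigmas` is omitted
#' they are derived with `sigma`.
#'
#' @param ref_id Character vector of identifiers.
#' @param fragments List of numeric vectors, fragment sizes in bp.
#' @param sigmas Optional list of numeric vectors aligned 1:1 with
#'   `fragments`.
#' @param orientation `"forward"` or `"reverse"`, recycled.
#' @param sigma A [sigma_model()] function, used when `sigmas` is `NULL`.
#' @return A tibble with columns `ref_id`, `orientation`, `n_fragments`,
#'   `total_bp`, `fragments`, `sigmas`.
#' @examples
#' reference_maps("chrTest", list(c(5000, 7000)))
#' @export
reference_maps <- function(ref_id, fragments, sigmas = NULL,
                           orientation = "forward", sigma = sigma_model()) {
  if (!is.list(fragments)) fragments <- list(fragments)
  fragments <- lapply(fragments, as.numeric)
  ok <- vapply(fragments, function(f) length(f) > 0 && all(is.finite(f)) && all(f > 0),
               logical(1))
  if (!all(ok)) stop("all fragment sizes must be finite and > 0")
  if (is.null(sigmas)) {
    sigmas <- lapply(fragments, sigma)
  } else {
    if (!is.list(sigmas)) sigmas <- list(sigmas)
    stopifnot(length(sigmas) == length(fragments))
    if (!all(mapply(function(f, s) length(f) == length(s) && all(s >= 0),
                    fragments, sigmas))) {
      stop("sigmas must align 1:1 with fragments and be non-negative")
    }
  }
  orientation <- rep_len(match.arg(orientation, c("forward", "reverse"),
                                   several.ok = FALSE), length(fragments))
  tibble::tibble(
    ref_id = as.character(ref_id),
    orientation = orientation,
    n_fragments = vapply(fragments, length, integer(1)),
    total_bp = vapply(fragments, sum, numeric(1)),
    fragments = fragments,
    sigmas = lapply(sigmas, as.numeric)
  )
}

#' Sum and variance of a reference fragment range
#'
#' Returns the fragment-size sum and the sizing variance of reference
#' fragments `l..t`, excluding any indices in `gaps` (fragments treated as
#' missing). Computed from prefix sums, so repeated queries are O(#gaps).
#'
#' @param fragments Numeric vector of reference fragment sizes (bp).
#' @param sigmas Numeric vector of per-fragment standard deviations (bp).
#' @param l,t 1-based inclusive fragment index range, `l <= t`.
#' @param gaps Integer vector of indices within `[l, t]` to exclude.
#' @return A named numeric vector `c(sum = , var = )` in bp and bp^2.
#' @examples
#' range_stats(c(5000, 7000), c(500, 700), 1, 2)
#' @export
range_stats <- function(fragments, sigmas, l, t, gaps = integer(0)) {
  n <- length(fragments)
  if (l < 1 || t > n || l > t) stop("index range out of bounds")
  if (length(gaps) && (any(gaps < l) || any(gaps > t))) {
    stop("gaps must lie within [l, t]")
  }
  pf <- c(0, cumsum(fragments))
  pv <- c(0, cumsum(sigmas^2))
  s <- pf[t + 1] - pf[l] - sum(fragments[gaps])
  v <- pv[t + 1] - pv[l] - sum(sigmas[gaps]^2)
  c(sum = s, var = v)
}

#' Feasibility test for a match
#'
#' A block of experimental fragments summing to `o_sum` may be matched to a
#' block of reference fragments summing to `r_sum` with sizing variance
#' `r_var` when the deviation is within `C` reference standard deviations.
#' Matches at map ends may be truncated, in which case only a one-sided bound
#' applies: `"upper"` caps the positive excess of the experimental sum
#' (truncated experimental end), `"lower"` caps the deficit (truncated
#' in-silico end).
#'
#' @param o_sum,r_sum Fragment-size sums in bp.
#' @param r_var Reference sizing variance in bp^2; must be positive.
#' @param C Bound in standard deviations.
#' @param mode `"two_sided"`, `"upper"` or `"lower"`.
#' @return Logical.
#' @examples
#' feasible(10500, 10000, 250000, 3)
#' @export
feasible <- function(o_sum, r_sum, r_var, C, mode = c("two_sided", "upper", "lower")) {
  mode <- match.arg(mode)
  if (any(r_var <= 0)) stop("degenerate variance: r_var must be > 0")
  d <- o_sum - r_sum
  lim <- C * sqrt(r_var)
  switch(mode,
    two_sided = abs(d) <= lim,
    upper     = d <= lim,
    lower     = d >= -lim
  )
}

#' Reverse a map table
#'
#' Reverses the fragment (and sigma) order of every map and flips the
#' orientation label of reference maps. Applying twice is the identity.
#'
#' @param maps A tibble from [experimental_maps()], [reference_maps()],
#'   [read_maps()] or [digest_fasta()].
#' @return A tibble of the same shape.
#' @examples
#' reverse_maps(experimental_maps("m", list(c(1, 2, 3))))$fragments[[1]]
#' @export
reverse_maps <- function(maps) {
  maps$fragments <- lapply(maps$fragments, rev)
  if ("sigmas" %in% names(maps)) maps$sigmas <- lapply(maps$sigmas, rev)
  if ("orientation" %in% names(maps)) {
    maps$orientation <- ifelse(maps$orientation == "forward", "reverse", "forward")
  }
  maps
}

#' Read maps from an om-tsv file
#'
#' The om-tsv format stores one map per line:
#' `map_id<TAB>num_fragments<TAB>comma-separated fragment sizes in bp`.
#' Lines starting with `#` are comments. Sizes may be integers or decimals.
#'
#' @param path Path to an om-tsv file.
#' @param as `"experimental"` (default) or `"reference"`; the latter attaches
#'   sigmas via `sigma`.
#' @param sigma A [sigma_model()] used when `as = "reference"`.
#' @return A maps tibble.
#' @export
read_maps <- function(path, as = c("experimental", "reference"),
                      sigma = sigma_model()) {
  as <- match.arg(as)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    empty <- new_map_tbl(character(0), list())
    if (as == "reference") {
      empty <- tibble::tibble(ref_id = character(0), orientation = character(0),
                              n_fragments = integer(0), total_bp = numeric(0),
                              fragments = list(), sigmas = list())
    }
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad)) {
    stop(sprintf("malformed om-tsv line %d: expected 3 tab-separated fields",
                 lineno[bad[1]]))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  ns <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2)))
  frags <- lapply(parts, function(p) {
    suppressWarnings(as.numeric(strsplit(p[[3]], ",", fixed = TRUE)[[1]]))
  })
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    if (anyNA(f) || is.na(ns[i]) || length(f) != ns[i]) {
      stop(sprintf("malformed om-tsv line %d: fragment list does not parse or count mismatch",
                   lineno[i]))
    }
    if (any(f <= 0)) {
      stop(sprintf("invalid map at line %d: fragment sizes must be > 0", lineno[i]))
    }
  }
  if (as == "experimental") experimental_maps(ids, frags)
  else reference_maps(ids, frags, sigma = sigma)
}

#' Write maps to an om-tsv file
#'
#' @param maps A maps tibble (experimental or reference).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path) {
  id <- if ("map_id" %in% names(maps)) maps$map_id else maps$ref_id
  lines <- mapply(function(i, f) {
    sizes <- formatC(round(f, 1), format = "fg", big.mark = "", digits = 15)
    sizes <- sub("\\.0$", "", sizes)
    paste(i, length(f), paste(sizes, collapse = ","), sep = "\t")
  }, id, maps$fragments)
  writeLines(as.character(lines), path, useBytes = TRUE)
  invisible(path)
}
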