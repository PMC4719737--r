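#' Recognition site
#'
#' A restriction-enzyme recognition pattern in IUPAC nucleotide code together
#' with the cut position inside it. The KpnI site, for example, is
#' `GGTAC'C`: pattern `GGTACC`, cut offset 5.
#'
#' @param pattern IUPAC nucleotide string, length >= 4.
#' @param cut_offset Integer offset of the cut within the pattern,
#'   `0 <= cut_offset <= nchar(pattern)`.
#' @return A list of class `"om_site"`.
#' @examples
#' recognition_site("GGTACC", 5)
#' parse_site("GGTAC^C")
#' @export
recognition_site <- function(pattern, cut_offset) {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4) stop("recognition pattern must be at least 4 bases")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", pattern)) {
    stop("pattern must use IUPAC nucleotide codes")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(pattern)) {
    stop("cut_offset must lie within the pattern")
  }
  structure(list(pattern = pattern, cut_offset = cut_offset), class = "om_site")
}

#' @rdname recognition_site
#' @param spec A string with `^` (or `'`) marking the cut, e.g. `"GGTAC^C"`.
#' @export
parse_site <- function(spec) {
  off <- regexpr("[\\^']", spec)
  if (off < 0) stop("site spec must mark the cut with ^ or '")
  recognition_site(gsub("[\\^']", "", spec), off - 1L)
}

#' Digest a nucleotide sequence in silico
#'
#' Locates every occurrence of the recognition pattern on the forward strand
#' (IUPAC-aware: pattern ambiguity codes match their base sets, while `N` in
#' the sequence matches nothing, so assembly gaps never produce cuts) and
#' returns the fragment sizes between consecutive cut positions. Zero-length
#' end fragments (a cut at the first or last position) are dropped. For
#' palindromic sites such as GGTACC both strands yield identical cuts.
#'
#' @param sequence A nucleotide string or `Biostrings::DNAString`.
#' @param site A [recognition_site()].
#' @param ref_id Identifier for the resulting map.
#' @param sigma A [sigma_model()].
#' @return A one-row [reference_maps()] tibble.
#' @examples
#' digest("AAGGTACCTT", recognition_site("GGTACC", 5))$fragments[[1]]
#' @export
digest <- function(sequence, site, ref_id = "seq", sigma = sigma_model()) {
  if (is.character(sequence)) {
    if (!nzchar(sequence)) stop("empty sequence")
    if (!grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]*$", sequence)) {
      stop("sequence contains characters outside the IUPAC alphabet")
    }
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  L <- length(sequence)
  if (L == 0) stop("empty sequence")
  hits <- Biostrings::matchPattern(site$pattern, sequence, fixed = "subject")
  cuts <- Biostrings::start(hits) - 1L + site$cut_offset
  cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  frags <- diff(c(0, cuts, L))
  reference_maps(ref_id, list(frags), sigma = sigma)
}

#' Digest every sequence of a FASTA file
#'
#' @param fasta Path to a (possibly multi-record, line-wrapped) FASTA file.
#' @param site A [recognition_site()] or a spec string for [parse_site()].
#' @param both_orientations Also emit the reversed map of each sequence, the
#'   convention used when counting genome-wide fragments over both strands.
#' @param sigma A [sigma_model()].
#' @return A [reference_maps()] tibble, forward maps in input order followed
#'   by reversed maps when requested.
#' @export
digest_fasta <- function(fasta, site, both_orientations = FALSE,
                         sigma = sigma_model()) {
  if (is.character(site)) site <- parse_site(site)
  seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                   error = function(e) stop("unreadable FASTA: ", conditionMessage(e)))
  if (!length(seqs)) stop("FASTA contains no sequences")
  ids <- sub("\\s.*$", "", names(seqs))
  fwd <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    digest(seqs[[i]], site, ref_id = ids[i], sigma = sigma)
  }))
  if (!both_orientations) return(fwd)
  dplyr::bind_rows(fwd, reverse_maps(fwd))
}
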