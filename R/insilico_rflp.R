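# In-silico DraI PCR-RFLP: locate the E2/H2 amplicon and compute the
# restriction fragments produced by digesting it with DraI (TTTAAA).
# Digestion is linear (the assay digests a PCR product, not the circular
# mitochondrial genome).

#' Restriction enzyme specification
#'
#' @param name enzyme name.
#' @param recognition recognition sequence on the top strand.
#' @param cut_offset cut position, counted from the start of the recognition
#'   site on the top strand (0..nchar(recognition)).
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  stopifnot(nzchar(name), grepl("^[ACGT]+$", recognition))
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stopf("cut_offset must be within 0..%d", nchar(recognition))
  }
  structure(list(name = name, recognition = recognition, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' DraI (TTTAAA, blunt cut after position 3)
#'
#' DraI's recognition site is its own reverse complement, so scanning the top
#' strand finds every site.
#'
#' @return a [restriction_enzyme()].
#' @export
dra_i <- function() restriction_enzyme("DraI", "TTTAAA", 3L)

#' Locate the E2/H2 amplicon span on an oriented record
#'
#' Returns the half-open span from the start of the E2 match to the end of
#' the reverse-complemented H2 match (0-based). A record carrying no primer
#' sites is treated as a bare amplicon: the full span is returned with a
#' `"primers-not-found, full-length assumed"` warning attribute. Primers
#' found in inverted order (H2 site upstream of E2) raise an error.
#'
#' @param seq oriented DNA string.
#' @param primers a [coi_primers()] pair.
#' @param max_mismatch mismatch tolerance per primer.
#' @return integer vector `c(start, end)` with a `warning` attribute when the
#'   full length was assumed.
#' @export
find_amplicon <- function(seq, primers = coi_primers(), max_mismatch = 2L) {
  seq <- toupper(seq)
  s <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(primers$forward, s,
                                  max.mismatch = max_mismatch, with.indels = FALSE)
  rev <- Biostrings::matchPattern(reverse_complement(primers$reverse), s,
                                  max.mismatch = max_mismatch, with.indels = FALSE)
  if (length(fwd) == 0L && length(rev) == 0L) {
    span <- c(0L, nchar(seq))
    attr(span, "warning") <- "primers-not-found, full-length assumed"
    return(span)
  }
  if (length(fwd) == 0L || length(rev) == 0L) {
    missing <- if (length(fwd) == 0L) primers$name_forward else primers$name_reverse
    span <- c(0L, nchar(seq))
    attr(span, "warning") <- sprintf("%s site not found, full-length assumed", missing)
    return(span)
  }
  fs <- min(Biostrings::start(fwd)) - 1L
  ok <- Biostrings::start(rev) - 1L > fs
  if (!any(ok)) {
    stopf("primers found in inverted order (%s site upstream of %s)",
          primers$name_reverse, primers$name_forward)
  }
  re <- max(Biostrings::end(rev)[ok])
  c(fs, re)
}

#' Digest a linear sequence in silico
#'
#' Scans the top strand for every occurrence of the recognition string
#' (step-1 sliding window, so overlapping occurrences all count); cut
#' coordinates are `site start + cut_offset`, deduplicated, and cuts falling
#' on the sequence ends are dropped so all fragments have positive length.
#' Ambiguity code N never matches the recognition site.
#'
#' @param seq amplicon DNA string (linear).
#' @param enzyme a [restriction_enzyme()].
#' @param record_id id stored on the profile.
#' @param amplicon_span optional `(start, end)` of the amplicon on the source
#'   record, for bookkeeping.
#' @return object of class `restriction_profile`: list with `record_id`,
#'   `amplicon_span`, `site_positions` (0-based cut coordinates on the
#'   amplicon) and `fragment_lengths` (5'->3'; `sorted_lengths` gives the
#'   gel-like descending view).
#' @export
digest_sequence <- function(seq, enzyme = dra_i(), record_id = NA_character_,
                            amplicon_span = NULL) {
  seq <- toupper(seq)
  n <- nchar(seq)
  hits <- Biostrings::matchPattern(enzyme$recognition, Biostrings::DNAString(seq),
                                   fixed = TRUE)
  cuts <- sort(unique(Biostrings::start(hits) - 1L + enzyme$cut_offset))
  cuts <- cuts[cuts > 0L & cuts < n]
  frags <- diff(c(0L, cuts, n))
  stopifnot(sum(frags) == n, all(frags > 0L),
            length(frags) == length(cuts) + 1L)
  structure(
    list(record_id = record_id,
         amplicon_span = amplicon_span %||% c(0L, n),
         site_positions = cuts,
         fragment_lengths = as.integer(frags),
         sorted_lengths = sort(as.integer(frags), decreasing = TRUE)),
    class = "restriction_profile"
  )
}

#' DraI profile of a record
#'
#' Composes [find_amplicon()] and [digest_sequence()]; cut coordinates are
#' reported on the amplicon (0-based).
#'
#' @param record one-row record data.frame (or bare DNA string).
#' @param primers a [coi_primers()] pair.
#' @param enzyme a [restriction_enzyme()].
#' @param max_mismatch primer mismatch tolerance.
#' @return a `restriction_profile`.
#' @export
drai_profile <- function(record, primers = coi_primers(), enzyme = dra_i(),
                         max_mismatch = 2L) {
  if (is.character(record)) record <- new_coi_records("seq", record)
  span <- find_amplicon(record$bases, primers, max_mismatch)
  amp <- substr(record$bases, span[1] + 1L, span[2])
  prof <- digest_sequence(amp, enzyme, record_id = record$sample_id,
                          amplicon_span = c(span[1], span[2]))
  if (!is.null(attr(span, "warning"))) {
    attr(prof, "warning") <- attr(span, "warning")
  }
  prof
}

#' Tabulate restriction profiles
#'
#' @param profiles list of `restriction_profile`.
#' @return data.frame with sample_id, n_sites, fragment_lengths
#'   ("/"-joined, 5'->3').
#' @export
rflp_table <- function(profiles) {
  data.frame(
    sample_id = vapply(profiles, `[[`, "", "record_id"),
    n_sites = vapply(profiles, function(p) length(p$site_positions), 0L),
    fragment_lengths = vapply(profiles, function(p)
      paste(p$fragment_lengths, collapse = "/"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
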