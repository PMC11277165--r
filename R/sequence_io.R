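# Reading, writing, orienting and quality-filtering amplicon sequences.
#
# A sequence set is a plain data.frame with columns
#   sample_id, bases, region, subspecies, source
# (one row per haploid drone; drones carry a single mitotype, so one
# sequence per individual with no heteroplasmy handling).

COI_ALPHABET <- c("A", "C", "G", "T", "N")

#' E2/H2 primer pair for the COI-COII intergenic amplicon
#'
#' The standard primer pair amplifying the tRNA-leu / COI-COII intergenic
#' region: E2 anneals at the 3' end of COI, H2 (given 5'->3' on the opposite
#' strand) at the start of COII.
#'
#' @param forward,reverse primer sequences 5'->3'.
#' @param name_forward,name_reverse primer names.
#' @return object of class `primer_pair`.
#' @export
coi_primers <- function(forward = "GGCAGAATAAGTGCATTG",
                        reverse = "CAATATCATTGATGACC",
                        name_forward = "E2", name_reverse = "H2") {
  stopifnot(nzchar(forward), nzchar(reverse))
  structure(
    list(forward = toupper(forward), reverse = toupper(reverse),
         name_forward = name_forward, name_reverse = name_reverse),
    class = "primer_pair"
  )
}

#' Construct a sequence record set
#'
#' @param sample_id unique record ids.
#' @param bases DNA strings over `{A,C,G,T,N}`.
#' @param region,subspecies optional metadata (recycled).
#' @param source provenance: `sampled`, `reference` or `synthetic`.
#' @return data.frame with one row per record.
#' @export
new_coi_records <- function(sample_id, bases, region = NA_character_,
                            subspecies = NA_character_, source = "sampled") {
  data.frame(
    sample_id = as.character(sample_id),
    bases = toupper(as.character(bases)),
    region = rep_len(as.character(region), length(sample_id)),
    subspecies = rep_len(as.character(subspecies), length(sample_id)),
    source = rep_len(as.character(source), length(sample_id)),
    stringsAsFactors = FALSE
  )
}

validate_coi_records <- function(records, allow_gaps = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "bases") %in% names(records)))
  if (anyDuplicated(records$sample_id)) {
    dup <- unique(records$sample_id[duplicated(records$sample_id)])
    stopf("duplicate sample_id: %s", paste(dup, collapse = ", "))
  }
  pat <- if (allow_gaps) "^[ACGTN-]+$" else "^[ACGTN]+$"
  bad <- !grepl(pat, records$bases)
  if (any(bad)) {
    stopf("illegal characters in sequence(s): %s",
          paste(records$sample_id[bad], collapse = ", "))
  }
  invisible(records)
}

#' Read amplicon sequences from a FASTA file
#'
#' Record descriptions are parsed as `sample_id` followed by optional free
#' text. Bases are upper-cased and U is mapped to T; any residue outside
#' `{A,C,G,T,N}` is a parse error naming the offending line.
#'
#' @param path FASTA file.
#' @param source provenance label stored on each record.
#' @return data.frame of sequence records.
#' @export
read_coi_fasta <- function(path, source = "sampled") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(trimws(lines))]
  if (length(body) == 0L) stopf("empty FASTA dataset: %s", path)
  if (!startsWith(trimws(body[[1]]), ">")) {
    stopf("malformed FASTA (%s): line 1 does not start with '>'", path)
  }
  # Biostrings silently drops illegal letters, so validate lines first
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    if (!grepl("^[ACGTUNacgtun-]+$", ln)) {
      stopf("malformed FASTA (%s): illegal sequence characters on line %d", path, i)
    }
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA dataset: %s", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  bases <- toupper(as.character(set))
  bases <- gsub("U", "T", bases, fixed = TRUE)
  bases <- gsub("-", "", bases, fixed = TRUE)
  if (any(!nzchar(bases))) {
    stopf("empty sequence for record(s): %s",
          paste(ids[!nzchar(bases)], collapse = ", "))
  }
  rec <- new_coi_records(ids, bases, source = source)
  validate_coi_records(rec)
  rec
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `sample_id` and `bases` columns.
#' @param path output file.
#' @param line_width wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_coi_fasta <- function(records, path, line_width = 60L) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stopf("cannot write an empty record set")
  }
  set <- Biostrings::BStringSet(records$bases)
  names(set) <- records$sample_id
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Read a sample manifest
#'
#' Comma-separated table with header `sample_id,region,subspecies,country`.
#'
#' @param path CSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "subspecies", "country")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stopf("manifest has duplicate sample_id values")
  m
}

# locate primer layout on one strand; returns NULL or 0-based coordinates
find_primer_layout <- function(seq, primers, max_mismatch = 2L) {
  s <- Biostrings::DNAString(seq)
  fwd <- Biostrings::matchPattern(primers$forward, s,
                                  max.mismatch = max_mismatch, with.indels = FALSE)
  rev <- Biostrings::matchPattern(reverse_complement(primers$reverse), s,
                                  max.mismatch = max_mismatch, with.indels = FALSE)
  if (length(fwd) == 0L || length(rev) == 0L) return(NULL)
  fs <- min(Biostrings::start(fwd))
  # reverse site must lie downstream of the forward site
  ok <- Biostrings::start(rev) > fs
  if (!any(ok)) return(NULL)
  re <- max(Biostrings::end(rev)[ok])
  fwd_end <- min(Biostrings::end(fwd))
  rev_start <- max(Biostrings::start(rev)[ok])
  list(fwd_start = fs - 1L, fwd_end = fwd_end,
       rev_start = rev_start - 1L, rev_end = re)
}

#' Orient a record onto the E2-first strand
#'
#' Returns the strand on which the forward primer matches upstream of the
#' reverse-complemented reverse primer (at most `max_mismatch` mismatches, no
#' indels). Sequences are always stored on the + (E2-first) orientation after
#' this call; primer match coordinates are 0-based half-open.
#'
#' @param record one-row record data.frame.
#' @param primers a [coi_primers()] pair.
#' @param max_mismatch mismatch tolerance per primer.
#' @return the record with columns `strand`, `oriented`, `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end` added; `oriented = FALSE` flags
#'   orientation failure (record excluded downstream, not an error).
#' @export
orient_record <- function(record, primers = coi_primers(), max_mismatch = 2L) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  if (grepl("-", record$bases, fixed = TRUE)) stopf("orient_record expects unaligned input")
  lay <- find_primer_layout(record$bases, primers, max_mismatch)
  strand <- "+"
  if (is.null(lay)) {
    rc <- reverse_complement(record$bases)
    lay <- find_primer_layout(rc, primers, max_mismatch)
    if (!is.null(lay)) {
      record$bases <- rc
      strand <- "-"
    }
  }
  if (is.null(lay)) {
    record$strand <- NA_character_
    record$oriented <- FALSE
    record$fwd_start <- record$fwd_end <- record$rev_start <- record$rev_end <- NA_integer_
  } else {
    record$strand <- strand
    record$oriented <- TRUE
    record$fwd_start <- lay$fwd_start
    record$fwd_end <- lay$fwd_end
    record$rev_start <- lay$rev_start
    record$rev_end <- lay$rev_end
  }
  record
}

#' Orient a whole record set
#'
#' @inheritParams orient_record
#' @param records record data.frame.
#' @return data.frame of all records with orientation columns; failures are
#'   flagged (`oriented = FALSE`) and logged, never dropped here.
#' @export
orient_records <- function(records, primers = coi_primers(), max_mismatch = 2L) {
  validate_coi_records(records)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    orient_record(records[i, , drop = FALSE], primers, max_mismatch)
  }))
  rownames(out) <- NULL
  n_fail <- sum(!out$oriented)
  if (n_fail > 0L) {
    coi_log("orientation failed for %d record(s): %s", n_fail,
            paste(out$sample_id[!out$oriented], collapse = ", "), level = "WARN")
  }
  out
}

#' Quality filter
#'
#' Retains records with length >= `min_length` and N fraction <=
#' `max_n_fraction`; the removal report lists every removed record with its
#' reason(s). The input is partitioned: `nrow(retained) + nrow(report)` equals
#' the input size.
#'
#' @param records oriented record data.frame (unoriented records are removed
#'   with reason `"orientation"` when an `oriented` column is present).
#' @param min_length minimum sequence length in bp.
#' @param max_n_fraction maximum tolerated fraction of N calls.
#' @return list with elements `retained` (data.frame) and `report`
#'   (data.frame of sample_id, reason).
#' @export
qc_filter <- function(records, min_length = 300L, max_n_fraction = 0.02) {
  validate_coi_records(records)
  len <- nchar(records$bases)
  n_frac <- vapply(records$bases, function(b) {
    mean(chars(b) == "N")
  }, 0, USE.NAMES = FALSE)
  reasons <- lapply(seq_len(nrow(records)), function(i) {
    r <- character()
    if (!is.null(records$oriented) && !isTRUE(records$oriented[i])) r <- c(r, "orientation")
    if (len[i] < min_length) r <- c(r, "min_length")
    if (n_frac[i] > max_n_fraction) r <- c(r, "max_n_fraction")
    r
  })
  removed <- lengths(reasons) > 0L
  report <- data.frame(
    sample_id = records$sample_id[removed],
    reason = vapply(reasons[removed], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  retained <- records[!removed, , drop = FALSE]
  rownames(retained) <- NULL
  if (nrow(retained) == 0L) warnf("qc_filter retained no records")
  list(retained = retained, report = report)
}
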