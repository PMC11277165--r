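# Decomposition of an oriented amplicon into structural elements
# (tRNA-leu stub, P/P0/P1 element, tandem Q units, COII stub), the derived
# structure string (e.g. "P0QQ") and the evolutionary lineage call.
#
# Lineage rules for the COI-COII region: the African A lineage carries the
# P0 or P1 form of the P element, the West-European M lineage the full P
# element, and the East-European C lineage lacks the P element entirely.

UNIT_LABELS <- c("TRNA_LEU", "P", "P0", "P1", "Q", "COX2_STUB")
STRUCTURAL_LABELS <- c("P", "P0", "P1", "Q")
P_VARIANTS <- c("P", "P0", "P1")

#' Construct a structural-unit reference library
#'
#' @param units named character vector of reference sequences; names must be
#'   a subset of `TRNA_LEU, P, P0, P1, Q, COX2_STUB` and must include `Q`.
#' @param min_identity minimum alignment identity (matches / reference
#'   length) for a unit match to be accepted.
#' @param p_margin identity margin under which the two best P-variant calls
#'   are flagged ambiguous.
#' @return object of class `unit_library`.
#' @export
unit_library <- function(units, min_identity = 0.75, p_margin = 0.02) {
  stopifnot(is.character(units), !is.null(names(units)))
  bad <- setdiff(names(units), UNIT_LABELS)
  if (length(bad)) stopf("unknown unit label(s): %s", paste(bad, collapse = ", "))
  if (!"Q" %in% names(units)) stopf("unit library must define a Q reference")
  if (any(!nzchar(units))) stopf("unit reference sequences must be non-empty")
  if (min_identity <= 0 || min_identity > 1) stopf("min_identity must be in (0, 1]")
  structure(
    list(units = toupper(units), min_identity = min_identity, p_margin = p_margin),
    class = "unit_library"
  )
}

# identity of reference `ref` against its best semi-global placement in
# `sub`: matches / aligned length including internal gaps (PID1), so a
# deletion derivative never scores as identical to its parent
unit_identity <- function(ref, sub) {
  pa <- coi_align(Biostrings::DNAString(ref), Biostrings::DNAString(sub),
                  type = "global-local")
  Biostrings::pid(pa, type = "PID1") / 100
}

#' Read / write a unit library as FASTA (record ids are unit labels)
#' @param path FASTA file.
#' @param min_identity,p_margin see [unit_library()].
#' @return a `unit_library`.
#' @export
read_unit_library <- function(path, min_identity = 0.75, p_margin = 0.02) {
  set <- Biostrings::readDNAStringSet(path)
  unit_library(stats::setNames(as.character(set), names(set)),
               min_identity = min_identity, p_margin = p_margin)
}

#' @rdname read_unit_library
#' @param library a `unit_library`.
#' @export
write_unit_library <- function(library, path) {
  set <- Biostrings::DNAStringSet(library$units)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# one vectorized semi-global alignment of every unit against a window;
# returns a data.frame of candidate matches with 0-based coordinates
align_units_to_window <- function(units, window, offset0) {
  pa <- coi_align(Biostrings::DNAStringSet(units), Biostrings::DNAString(window),
                  type = "global-local")
  data.frame(
    label = names(units),
    start = offset0 + Biostrings::start(Biostrings::subject(pa)) - 1L,
    end = offset0 + Biostrings::end(Biostrings::subject(pa)),
    identity = Biostrings::pid(pa, type = "PID1") / 100,
    stringsAsFactors = FALSE
  )
}

# pick the accepted candidate under the declared tie-breaks:
# highest identity, then longer reference, then lexicographic label
pick_candidate <- function(cand, units) {
  cand$ref_len <- nchar(units[cand$label])
  ord <- order(-cand$identity, -cand$ref_len, cand$label)
  cand[ord[1L], , drop = FALSE]
}

#' Tile a sequence with structural units
#'
#' Greedy left-to-right tiling: at each cursor position every library unit is
#' aligned semi-globally (free end gaps on the amplicon side) inside a local
#' window; the highest-identity unit with identity >= `min_identity` is
#' accepted and the cursor advances to its end. Ties are broken by longer
#' reference, then lexicographic label. Unmatched gaps shorter than
#' `gap_tol` bp between units are tolerated (logged); larger unmatched
#' stretches are reported as annotation warnings. Coordinates are 0-based,
#' half-open.
#'
#' @param seq oriented, QC-passed DNA string.
#' @param library a [unit_library()].
#' @param gap_tol tolerated unmatched gap between consecutive units (bp).
#' @param window_slack extra bp beyond the reference length searched at each
#'   cursor position.
#' @return list with `matches` (data.frame: label, start, end, identity) and
#'   `warnings` (character).
#' @export
tile_units <- function(seq, library, gap_tol = 10L, window_slack = 30L) {
  stopifnot(inherits(library, "unit_library"))
  seq <- toupper(seq)
  units <- library$units
  n <- nchar(seq)
  max_len <- max(nchar(units))
  cursor <- 0L
  rows <- list()
  warn <- character()
  seen_unit <- FALSE
  repeat {
    if (cursor >= n) break
    win_end <- min(n, cursor + max_len + window_slack)
    if (win_end - cursor < 8L) break
    window <- substr(seq, cursor + 1L, win_end)
    cand <- align_units_to_window(units, window, cursor)
    cand <- cand[cand$identity >= library$min_identity &
                   cand$start - cursor <= gap_tol, , drop = FALSE]
    if (nrow(cand) == 0L && !seen_unit) {
      # anchor search: the first unit may sit past a long flank
      rest <- substr(seq, cursor + 1L, n)
      cand <- align_units_to_window(units, rest, cursor)
      cand <- cand[cand$identity >= library$min_identity, , drop = FALSE]
      if (nrow(cand) > 0L) {
        cand <- cand[cand$start == min(cand$start), , drop = FALSE]
        warn <- c(warn, sprintf(
          "unmatched stretch of %d bp before first unit", min(cand$start) - cursor))
      }
    }
    if (nrow(cand) == 0L) break
    best <- pick_candidate(cand, units)
    # ambiguity among P variants must stay visible
    if (best$label %in% P_VARIANTS) {
      pv <- cand[cand$label %in% P_VARIANTS, , drop = FALSE]
      if (nrow(pv) >= 2L) {
        top2 <- sort(pv$identity, decreasing = TRUE)[1:2]
        if (top2[1] - top2[2] < library$p_margin) {
          warn <- c(warn, sprintf("ambiguous-P call at %d (margin %.3f)",
                                  best$start, top2[1] - top2[2]))
        }
      }
    }
    gap <- best$start - cursor
    if (gap > 0L && seen_unit) {
      msg <- sprintf("unmatched gap of %d bp before %s at %d", gap, best$label, best$start)
      if (gap >= gap_tol) warn <- c(warn, msg) else coi_log("%s", msg, level = "DEBUG")
    }
    rows[[length(rows) + 1L]] <- best[, c("label", "start", "end", "identity")]
    cursor <- best$end
    seen_unit <- TRUE
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), start = integer(), end = integer(),
               identity = numeric(), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, warnings = warn)
}

#' Derive the structure string from unit matches
#'
#' Concatenates match labels restricted to the structural elements
#' `P, P0, P1, Q` in positional order (Q repeats rendered as repeated "Q").
#'
#' @param matches data.frame from [tile_units()].
#' @return structure string such as `"P0QQ"`.
#' @export
structure_string <- function(matches) {
  if (!is.data.frame(matches) || nrow(matches) == 0L) {
    stopf("structure_string: empty match list")
  }
  m <- matches[order(matches$start), , drop = FALSE]
  paste(m$label[m$label %in% STRUCTURAL_LABELS], collapse = "")
}

#' Assign the evolutionary lineage from a structure string
#'
#' Structures starting with `P0` or `P1` are African (A); starting with `P`
#' (full element) West-European (M); starting with `Q` (no P element)
#' East-European (C); anything else is `UNRESOLVED`.
#'
#' @param structure structure string over tokens `P, P0, P1, Q`.
#' @return one of `"A"`, `"M"`, `"C"`, `"UNRESOLVED"`.
#' @export
assign_lineage <- function(structure) {
  if (length(structure) != 1L || is.na(structure) || !nzchar(structure)) {
    stopf("assign_lineage: empty structure")
  }
  if (startsWith(structure, "P0") || startsWith(structure, "P1")) return("A")
  if (startsWith(structure, "P")) return("M")
  if (startsWith(structure, "Q")) return("C")
  "UNRESOLVED"
}

#' Annotate one record
#'
#' Composes [tile_units()], [structure_string()] and [assign_lineage()].
#' When a primer pair is supplied and both primer sites are present, tiling
#' runs on the interior between the primers (coordinates are reported on the
#' full record). A record in which no Q unit is found is flagged
#' `UNRESOLVED` (structure-resolution failure, excluded from haplotyping)
#' rather than raising an error.
#'
#' @param record one-row record data.frame (or a bare DNA string).
#' @param library a [unit_library()].
#' @param primers optional [coi_primers()] pair used to trim primer flanks
#'   before tiling.
#' @param ... passed to [tile_units()].
#' @return object of class `structure_annotation`: list with `record_id`,
#'   `matches`, `structure`, `lineage`, `warnings`.
#' @export
annotate_structure <- function(record, library, primers = coi_primers(), ...) {
  if (is.character(record)) {
    record <- new_coi_records("seq", record, source = "reference")
  }
  seq <- record$bases
  id <- record$sample_id
  inner_start <- 0L
  inner_end <- nchar(seq)
  warn <- character()
  if (!is.null(primers)) {
    lay <- find_primer_layout(seq, primers, max_mismatch = 2L)
    if (!is.null(lay)) {
      inner_start <- lay$fwd_end
      inner_end <- lay$rev_start
    }
  }
  tiled <- tile_units(substr(seq, inner_start + 1L, inner_end), library, ...)
  matches <- tiled$matches
  if (nrow(matches)) {
    matches$start <- matches$start + inner_start
    matches$end <- matches$end + inner_start
  }
  warn <- c(warn, tiled$warnings)
  structural <- matches[matches$label %in% STRUCTURAL_LABELS, , drop = FALSE]
  if (nrow(structural) == 0L || !any(structural$label == "Q")) {
    structure_str <- NA_character_
    lineage <- "UNRESOLVED"
    warn <- c(warn, "structure-resolution failure: no Q unit found")
  } else {
    structure_str <- structure_string(matches)
    lineage <- assign_lineage(structure_str)
  }
  structure(
    list(record_id = id, matches = matches, structure = structure_str,
         lineage = lineage, warnings = warn),
    class = "structure_annotation"
  )
}

#' Annotate a record set
#'
#' @param records record data.frame.
#' @inheritParams annotate_structure
#' @return list of `structure_annotation`, named by sample_id.
#' @export
annotate_structures <- function(records, library, primers = coi_primers(), ...) {
  validate_coi_records(records)
  anns <- lapply(seq_len(nrow(records)), function(i) {
    annotate_structure(records[i, , drop = FALSE], library, primers, ...)
  })
  stats::setNames(anns, records$sample_id)
}

#' Tabulate annotations
#'
#' @param annotations list of `structure_annotation`.
#' @return data.frame with sample_id, structure, lineage, warnings.
#' @export
annotation_table <- function(annotations) {
  data.frame(
    sample_id = vapply(annotations, `[[`, "", "record_id"),
    structure = vapply(annotations, function(a) a$structure %||% NA_character_, ""),
    lineage = vapply(annotations, `[[`, "", "lineage"),
    warnings = vapply(annotations, function(a) paste(a$warnings, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' BED-like interval export of unit matches
#'
#' @param annotations list of `structure_annotation`.
#' @return data.frame with sample_id, start, end, label, identity
#'   (0-based half-open coordinates).
#' @export
annotation_intervals <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$matches) == 0L) return(NULL)
    cbind(sample_id = a$record_id, a$matches)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("sample_id", "start", "end", "label", "identity")]
}

#' Fetch sequences from GenBank by accession (online helper)
#'
#' Downloads nucleotide records via NCBI efetch and reads them as a record
#' set. Used only for optional validation against deposited haplotype
#' sequences; all default analyses are offline.
#'
#' @param accessions character vector of accessions.
#' @return record data.frame with `source = "reference"`.
#' @export
fetch_genbank_fasta <- function(accessions) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?",
    "db=nuccore&rettype=fasta&retmode=text&id=", paste(accessions, collapse = ",")
  )
  tf <- tempfile(fileext = ".fasta")
  utils::download.file(url, tf, quiet = TRUE)
  read_coi_fasta(tf, source = "reference")
}
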