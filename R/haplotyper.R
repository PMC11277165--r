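# Haplotype identification within a structure class: unit-anchored multiple
# alignment, identity collapse, catalog matching, and rule-based nomenclature
# anchored to the lineage-letter + number + lowercase-suffix naming scheme
# (A74, A74c, M4r, C2_d, ...).

#' Unit-anchored alignment within one structure class
#'
#' Each structural-unit occurrence is pairwise-aligned to its library
#' reference (global alignment; match +1, mismatch -1, gap open -4, gap
#' extend -1). Columns are the reference positions plus insertion columns
#' merged across records at the same reference offset (insertions
#' left-justified); concatenating the unit blocks in structure order yields
#' the full alignment. Every row's gap-free sequence equals the
#' concatenation of that record's structural-unit segments.
#'
#' @param records record data.frame (may include catalog-derived reference
#'   rows re-anchored alongside samples).
#' @param annotations list of `structure_annotation` named by sample_id,
#'   covering every record.
#' @param library the [unit_library()] used for annotation.
#' @return object of class `unit_alignment`: list with `structure_class`,
#'   `rows` (named character, equal lengths), `column_count`, `provenance`
#'   (per column: unit label, occurrence index, kind `ref`/`ins`, offset).
#' @export
align_within_class <- function(records, annotations, library) {
  validate_coi_records(records)
  ids <- records$sample_id
  anns <- annotations[ids]
  if (any(vapply(anns, is.null, TRUE))) {
    stopf("missing annotation for: %s",
          paste(ids[vapply(anns, is.null, TRUE)], collapse = ", "))
  }
  structs <- vapply(anns, `[[`, "", "structure")
  if (length(unique(structs)) != 1L || anyNA(structs)) {
    stopf("align_within_class requires a single structure class, got: %s",
          paste(unique(structs), collapse = ", "))
  }
  class_str <- structs[[1L]]

  # per record: list of structural segments in positional order
  seg_lists <- lapply(seq_along(ids), function(i) {
    m <- anns[[i]]$matches
    m <- m[m$label %in% STRUCTURAL_LABELS, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    lapply(seq_len(nrow(m)), function(k) {
      list(label = m$label[k],
           seq = substr(records$bases[i], m$start[k] + 1L, m$end[k]))
    })
  })
  n_units <- length(seg_lists[[1L]])

  blocks <- vector("list", n_units)
  prov <- vector("list", n_units)
  for (k in seq_len(n_units)) {
    label <- seg_lists[[1L]][[k]]$label
    ref <- library$units[[label]]
    reflen <- nchar(ref)
    ref_rows <- matrix("-", nrow = length(ids), ncol = reflen)
    ins <- vector("list", length(ids)) # per row: named list offset -> string
    for (i in seq_along(ids)) {
      seg <- seg_lists[[i]][[k]]$seq
      pa <- coi_align(Biostrings::DNAString(ref), Biostrings::DNAString(seg),
                      type = "global")
      p <- chars(as.character(Biostrings::pattern(pa)))
      s <- chars(as.character(Biostrings::subject(pa)))
      off <- 0L
      row_ins <- list()
      for (j in seq_along(p)) {
        if (p[j] == "-") {
          key <- as.character(off)
          row_ins[[key]] <- paste0(row_ins[[key]] %||% "", s[j])
        } else {
          off <- off + 1L
          ref_rows[i, off] <- s[j]
        }
      }
      ins[[i]] <- row_ins
    }
    # merged insertion lengths per reference offset
    all_off <- sort(unique(as.integer(unlist(lapply(ins, names)))))
    ins_len <- stats::setNames(integer(length(all_off)), as.character(all_off))
    for (o in names(ins_len)) {
      ins_len[[o]] <- max(vapply(ins, function(ri) nchar(ri[[o]] %||% ""), 0L))
    }
    pad <- function(x, w) paste0(x, strrep("-", w - nchar(x))) # left-justified
    block_rows <- character(length(ids))
    prov_cols <- list()
    for (i in seq_along(ids)) {
      parts <- character()
      for (o in 0:reflen) {
        key <- as.character(o)
        if (!is.na(ins_len[key])) {
          parts <- c(parts, pad(ins[[i]][[key]] %||% "", ins_len[[key]]))
        }
        if (o < reflen) parts <- c(parts, ref_rows[i, o + 1L])
      }
      block_rows[i] <- paste(parts, collapse = "")
    }
    for (o in 0:reflen) {
      key <- as.character(o)
      if (!is.na(ins_len[key])) {
        prov_cols[[length(prov_cols) + 1L]] <- data.frame(
          unit = label, occurrence = k, kind = "ins",
          offset = rep(o, ins_len[[key]]), stringsAsFactors = FALSE)
      }
      if (o < reflen) {
        prov_cols[[length(prov_cols) + 1L]] <- data.frame(
          unit = label, occurrence = k, kind = "ref", offset = o + 1L,
          stringsAsFactors = FALSE)
      }
    }
    blocks[[k]] <- block_rows
    prov[[k]] <- do.call(rbind, prov_cols)
  }
  rows <- stats::setNames(do.call(paste0, blocks), ids)
  stopifnot(length(unique(nchar(rows))) == 1L)
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  structure(
    list(structure_class = class_str, rows = rows,
         column_count = nchar(rows[[1L]]), provenance = provenance),
    class = "unit_alignment"
  )
}

# pairwise differences on a gapped alignment: SNP columns (both non-gap,
# different, N mismatches everything including N) and indel columns
# (exactly one of the two gapped)
aligned_differences <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  stopifnot(length(ca) == length(cb))
  gap_a <- ca == "-"; gap_b <- cb == "-"
  both <- !gap_a & !gap_b
  snp <- sum(both & (ca != cb | (ca == "N" & cb == "N")))
  indel <- sum(xor(gap_a, gap_b))
  list(snp = snp, indel_cols = indel)
}

#' Collapse an alignment into haplotype groups
#'
#' Rows with identical aligned strings form one group. Rows containing N are
#' flagged low-confidence and only group together when byte-identical (an N
#' could hide a real difference). Groups are sorted by descending size, then
#' by representative sequence.
#'
#' @param alignment a `unit_alignment`.
#' @return data.frame with columns `representative`, `size`, `members`
#'   (list-column of sample ids), `has_n`.
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(inherits(alignment, "unit_alignment"))
  rows <- alignment$rows
  if (length(rows) == 0L) stopf("collapse_haplotypes: empty alignment")
  grp <- split(names(rows), unname(rows))
  out <- data.frame(representative = names(grp), stringsAsFactors = FALSE)
  out$size <- lengths(grp)
  out$members <- I(lapply(grp, sort))
  out$has_n <- grepl("N", out$representative, fixed = TRUE)
  out <- out[order(-out$size, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$has_n)) {
    coi_log("%d haplotype group(s) contain N and are flagged low-confidence",
            sum(out$has_n), level = "WARN")
  }
  out
}

## --- haplotype catalog ----------------------------------------------------

PRIME <- "\u2032"

#' Parse a haplotype name
#'
#' Name grammar: lineage letter + integer + optional lowercase suffix
#' (an underscore before the suffix, as in the published alias `C2_d`, is
#' accepted) + optional prime mark (e.g. A77 followed by U+2032).
#'
#' @param name haplotype name.
#' @return list with `letter`, `number`, `suffix` (`""` if none), `prime`.
#' @export
parse_haplotype_name <- function(name) {
  m <- regmatches(name, regexec(
    paste0("^([A-Z])([0-9]+)_?([a-z]?)(", PRIME, "?)$"), name))[[1L]]
  if (length(m) == 0L) stopf("invalid haplotype name: %s", name)
  list(letter = m[2L], number = as.integer(m[3L]), suffix = m[4L],
       prime = nzchar(m[5L]))
}

#' Create / read / write a haplotype catalog
#'
#' A catalog holds named haplotypes (name, lineage, structure, aligned
#' sequence, provenance). The FASTA representation uses record ids
#' `name|lineage|structure`.
#'
#' @param name,lineage,structure,sequence,provenance vectors of equal length.
#' @return data.frame of class `haplotype_catalog`.
#' @export
haplotype_catalog <- function(name = character(), lineage = character(),
                              structure = character(), sequence = character(),
                              provenance = character()) {
  if (anyDuplicated(name)) stopf("catalog names must be unique")
  for (i in seq_along(name)) {
    p <- parse_haplotype_name(name[i])
    if (p$letter != lineage[i]) {
      stopf("catalog name %s inconsistent with lineage %s", name[i], lineage[i])
    }
    if (nzchar(structure[i]) && assign_lineage(structure[i]) != lineage[i]) {
      stopf("catalog entry %s: structure %s implies lineage %s, not %s",
            name[i], structure[i], assign_lineage(structure[i]), lineage[i])
    }
  }
  out <- data.frame(name = name, lineage = lineage, structure = structure,
                    sequence = toupper(sequence),
                    provenance = rep_len(provenance, length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("haplotype_catalog", "data.frame")
  out
}

#' @rdname haplotype_catalog
#' @param path catalog FASTA file.
#' @export
read_catalog <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stopf("catalog ids must be name|lineage|structure")
  haplotype_catalog(
    name = vapply(parts, `[[`, "", 1L),
    lineage = vapply(parts, `[[`, "", 2L),
    structure = vapply(parts, `[[`, "", 3L),
    sequence = as.character(set),
    provenance = "published"
  )
}

#' @rdname haplotype_catalog
#' @param catalog a `haplotype_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  set <- Biostrings::BStringSet(catalog$sequence)
  names(set) <- paste(catalog$name, catalog$lineage, catalog$structure, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Match a representative sequence against the catalog
#'
#' Catalog entries must share the representative's structure class and
#' column space (re-anchor them via [align_within_class()] with the catalog
#' sequences included). Returns the exact-match name at distance 0, else the
#' nearest same-lineage entry with its SNP distance and whether any indel
#' column differs.
#'
#' @param representative aligned haplotype sequence.
#' @param catalog a [haplotype_catalog()].
#' @param structure structure class of the representative.
#' @return list with `name` (or `NA`), `snp`, `indel` (logical).
#' @export
match_catalog <- function(representative, catalog, structure) {
  lineage <- assign_lineage(structure)
  sub <- catalog[catalog$structure == structure & catalog$lineage == lineage, ,
                 drop = FALSE]
  sub <- sub[nchar(sub$sequence) == nchar(representative), , drop = FALSE]
  if (nrow(sub) == 0L) return(list(name = NA_character_, snp = Inf, indel = FALSE))
  exact <- sub$name[sub$sequence == representative]
  if (length(exact)) return(list(name = exact[[1L]], snp = 0L, indel = FALSE))
  d <- lapply(sub$sequence, aligned_differences, b = representative)
  snp <- vapply(d, `[[`, 0, "snp")
  ind <- vapply(d, `[[`, 0, "indel_cols")
  ord <- order(snp, ind, sub$name)
  i <- ord[[1L]]
  list(name = sub$name[i], snp = as.integer(snp[i]), indel = ind[i] > 0L)
}

next_suffix <- function(catalog, letter, number) {
  pat <- sprintf("^%s%d_?([a-z]?)%s?$", letter, number, PRIME)
  hits <- regmatches(catalog$name, regexec(pat, catalog$name))
  used <- vapply(hits[lengths(hits) > 0L], `[[`, "", 2L)
  free <- setdiff(letters, used[nzchar(used)])
  if (length(free) == 0L) stopf("suffix series exhausted for %s%d", letter, number)
  free[[1L]]
}

next_number <- function(catalog, letter) {
  nums <- suppressWarnings(as.integer(sub(
    sprintf("^%s([0-9]+).*$", letter), "\\1",
    catalog$name[startsWith(catalog$name, letter)])))
  max(c(0L, nums), na.rm = TRUE) + 1L
}

#' Assign haplotype names to collapsed groups
#'
#' For each group (in group sort order): an exact catalog match keeps the
#' existing name (`known`); a nearest same-lineage neighbour within
#' `max_suffix_snp` SNPs and no indel difference takes that neighbour's base
#' name plus the next unused lowercase suffix in a-z order
#' (`renamed_alias`; a base name with no suffix occupies no suffix, so after
#' A74, A74a, A74b the next variant gets `A74c`); anything else opens the
#' next number in the lineage series (`novel`). New entries are appended to
#' the catalog with provenance `this_run`, so re-running on the same input
#' with the updated catalog is idempotent (all `known`). Newly generated
#' names never carry a prime mark.
#'
#' @param groups data.frame from [collapse_haplotypes()].
#' @param catalog a [haplotype_catalog()] whose sequences share the groups'
#'   column space.
#' @param structure structure class of the groups.
#' @param max_suffix_snp maximum SNP distance treated as a suffix variant.
#' @return list with `assignments` (data.frame: sample_id, haplotype_name,
#'   novelty, snp_distance, indel_flag, note) and `catalog` (updated).
#' @export
assign_names <- function(groups, catalog, structure, max_suffix_snp = 2L) {
  lineage <- assign_lineage(structure)
  if (lineage == "UNRESOLVED") stopf("cannot name haplotypes of unresolved structure")
  assigns <- list()
  for (g in seq_len(nrow(groups))) {
    rep_seq <- groups$representative[g]
    m <- match_catalog(rep_seq, catalog, structure)
    note <- ""
    if (!is.na(m$name) && m$snp == 0L && !m$indel) {
      nm <- m$name
      novelty <- "known"
    } else if (!is.na(m$name) && m$snp <= max_suffix_snp && !m$indel) {
      p <- parse_haplotype_name(m$name)
      nm <- paste0(p$letter, p$number, next_suffix(catalog, p$letter, p$number))
      novelty <- "renamed_alias"
    } else {
      if (!is.na(m$name) && m$snp <= max_suffix_snp && m$indel) {
        note <- sprintf(
          "within %d SNPs of %s but indel-distinct; named as new series", m$snp, m$name)
      }
      nm <- paste0(lineage, next_number(catalog, lineage))
      novelty <- "novel"
    }
    if (novelty != "known") {
      catalog <- rbind(catalog, haplotype_catalog(
        name = nm, lineage = lineage, structure = structure,
        sequence = rep_seq, provenance = "this_run"))
      class(catalog) <- c("haplotype_catalog", "data.frame")
    }
    assigns[[g]] <- data.frame(
      sample_id = groups$members[[g]],
      haplotype_name = nm,
      novelty = novelty,
      snp_distance = if (is.finite(m$snp)) as.integer(m$snp) else NA_integer_,
      indel_flag = isTRUE(m$indel),
      note = note,
      stringsAsFactors = FALSE
    )
  }
  assignments <- do.call(rbind, assigns)
  rownames(assignments) <- NULL
  list(assignments = assignments, catalog = catalog)
}

## --- summaries ------------------------------------------------------------

#' Structure frequency table per population group
#'
#' @param annotations list of `structure_annotation` (resolved records only
#'   contribute; unresolved ones are dropped with a log line).
#' @param manifest manifest data.frame.
#' @param group_field manifest column defining the population groups.
#' @return data.frame with group, structure, n, pct (one decimal; per-group
#'   percentages sum to 100 up to rounding).
#' @export
summarize_structures <- function(annotations, manifest, group_field = "country") {
  tab <- annotation_table(annotations)
  drop <- is.na(tab$structure)
  if (any(drop)) {
    coi_log("dropping %d unresolved record(s) from structure summary",
            sum(drop), level = "WARN")
  }
  tab <- tab[!drop, , drop = FALSE]
  tab$group <- manifest[[group_field]][match(tab$sample_id, manifest$sample_id)]
  if (anyNA(tab$group)) {
    stopf("sample(s) missing from manifest: %s",
          paste(tab$sample_id[is.na(tab$group)], collapse = ", "))
  }
  cnt <- as.data.frame(table(group = tab$group, structure = tab$structure),
                       stringsAsFactors = FALSE)
  cnt <- cnt[cnt$Freq > 0L, , drop = FALSE]
  names(cnt)[names(cnt) == "Freq"] <- "n"
  tot <- tapply(cnt$n, cnt$group, sum)
  cnt$pct <- round(100 * cnt$n / as.numeric(tot[cnt$group]), 1)
  cnt <- cnt[order(cnt$group, -cnt$n, cnt$structure), , drop = FALSE]
  rownames(cnt) <- NULL
  cnt
}

#' Haplotype frequency table per population group
#'
#' @param assignments assignment data.frame from [assign_names()] (possibly
#'   concatenated over structure classes).
#' @param manifest manifest data.frame.
#' @param group_field manifest column defining the population groups.
#' @return data.frame with group, haplotype, n, pct, regions and subspecies
#'   carrying the haplotype; ordered by descending count within group.
#' @export
summarize_haplotypes <- function(assignments, manifest, group_field = "country") {
  a <- assignments
  idx <- match(a$sample_id, manifest$sample_id)
  if (anyNA(idx)) {
    stopf("sample(s) missing from manifest: %s",
          paste(a$sample_id[is.na(idx)], collapse = ", "))
  }
  a$group <- manifest[[group_field]][idx]
  a$region <- manifest$region[idx]
  a$subspecies <- manifest$subspecies[idx]
  keys <- split(a, list(a$group, a$haplotype_name), drop = TRUE)
  out <- do.call(rbind, lapply(keys, function(k) {
    data.frame(
      group = k$group[[1L]],
      haplotype = k$haplotype_name[[1L]],
      n = nrow(k),
      regions = paste(sort(unique(k$region)), collapse = ";"),
      subspecies = paste(sort(unique(k$subspecies)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  tot <- tapply(out$n, out$group, sum)
  out$pct <- round(100 * out$n / as.numeric(tot[out$group]), 1)
  out <- out[order(out$group, -out$n, out$haplotype), ,
             drop = FALSE][, c("group", "haplotype", "n", "pct", "regions", "subspecies")]
  rownames(out) <- NULL
  out
}

#' Deposited novel-haplotype metadata
#'
#' Name, lineage, structure and GenBank accession for the 17 deposited
#' novel-haplotype representatives (PP667401-PP667417). Sequences are not
#' bundled; [fetch_genbank_fasta()] retrieves them for optional online
#' validation.
#'
#' @return data.frame with name, lineage, structure, accession.
#' @export
deposited_haplotypes <- function() {
  utils::read.csv(system.file("extdata", "deposited_haplotypes.csv",
                              package = "coicoii"),
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}
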