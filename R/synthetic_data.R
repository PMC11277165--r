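# Seeded generator for populations of COI-COII amplicon sequences with known
# architecture, haplotype identity and replayable mutation history. The
# generator and the annotator share the same unit library by default, so the
# whole pipeline is testable without any external data.

DEFAULT_UNIT_LENGTHS <- c(TRNA_LEU = 68L, P = 67L, Q = 196L, COX2_STUB = 55L)

#' Generate a synthetic structural-unit library
#'
#' Founder sequences are drawn uniformly at random per seed. The P0 variant
#' is a strict 15-bp-deletion derivative of P; P1 is derived from P by one
#' single-base deletion plus seeded substitutions so that every P-variant
#' pair stays below 0.9 identity (the annotator's ambiguous-P margin would
#' otherwise flag every P/P1 call). Unit lengths are declared testing
#' approximations and are configurable.
#'
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param unit_lengths named lengths for TRNA_LEU, P, Q, COX2_STUB.
#' @param p0_deletion length of the block deleted from P to derive P0.
#' @param min_identity,p_margin forwarded to [unit_library()].
#' @return a [unit_library()], identical on every call with the same seed.
#' @export
make_unit_library <- function(seed = 1L, unit_lengths = DEFAULT_UNIT_LENGTHS,
                              p0_deletion = 15L, min_identity = 0.75,
                              p_margin = 0.02) {
  lens <- DEFAULT_UNIT_LENGTHS
  lens[names(unit_lengths)] <- unit_lengths
  if (lens[["P"]] < p0_deletion + 20L) {
    stopf("P length %d too short to carve a %d bp deletion and stay distinguishable",
          lens[["P"]], p0_deletion)
  }
  with_seed(seed, {
    p <- random_dna(lens[["P"]])
    # central deletion so both flanks anchor the alignment unambiguously
    del_start <- (lens[["P"]] - p0_deletion) %/% 2L
    p0 <- paste0(substr(p, 1L, del_start - 1L),
                 substr(p, del_start + p0_deletion, lens[["P"]]))
    # P1: one single-base deletion, then substitutions until <= 0.9 identity to P
    del1 <- sample(seq_len(lens[["P"]]), 1L)
    p1 <- paste0(substr(p, 1L, del1 - 1L), substr(p, del1 + 1L, lens[["P"]]))
    n_sub <- ceiling(0.12 * lens[["P"]])
    pos <- sample(seq_len(nchar(p1)), n_sub)
    cs <- chars(p1)
    for (i in pos) cs[i] <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1L)
    p1 <- paste(cs, collapse = "")
    lib <- unit_library(
      c(TRNA_LEU = random_dna(lens[["TRNA_LEU"]]),
        P = p, P0 = p0, P1 = p1,
        Q = random_dna(lens[["Q"]]),
        COX2_STUB = random_dna(lens[["COX2_STUB"]])),
      min_identity = min_identity, p_margin = p_margin
    )
    for (x in P_VARIANTS) {
      for (y in setdiff(P_VARIANTS, x)) {
        if (unit_identity(lib$units[[x]], lib$units[[y]]) > 0.9) {
          stopf("unit lengths too short: %s vs %s identity exceeds 0.9", x, y)
        }
      }
    }
    lib
  })
}

#' Compose an amplicon from an architecture string
#'
#' Concatenates (optionally) the E2 primer site, the tRNA-leu stub, the named
#' structural units in order, the COII stub and the reverse-complemented H2
#' site. [annotate_structure()] on the output returns exactly the input
#' architecture (closure property).
#'
#' @param architecture string matching `(P|P0|P1)?Q+`.
#' @param library a [unit_library()].
#' @param with_flanks include primer-bearing coding-gene stubs.
#' @param primers primer pair for the flanks.
#' @return DNA string with attributes `fwd_primer` and `rev_primer`
#'   (0-based half-open primer spans) when flanked.
#' @export
compose_sequence <- function(architecture, library, with_flanks = TRUE,
                             primers = coi_primers()) {
  toks <- parse_architecture(architecture)
  units <- vapply(toks, function(t) library$units[[t]], "")
  core <- paste(units, collapse = "")
  if (!with_flanks) return(core)
  fwd <- primers$forward
  rev_site <- reverse_complement(primers$reverse)
  seq <- paste0(fwd, library$units[["TRNA_LEU"]], core,
                library$units[["COX2_STUB"]], rev_site)
  attr(seq, "fwd_primer") <- c(0L, nchar(fwd))
  attr(seq, "rev_primer") <- c(nchar(seq) - nchar(rev_site), nchar(seq))
  seq
}

parse_architecture <- function(architecture) {
  if (length(architecture) != 1L ||
      !grepl("^(P0|P1|P)?Q+$", architecture)) {
    stopf("malformed architecture string: %s", architecture)
  }
  toks <- regmatches(architecture, gregexpr("P0|P1|P|Q", architecture))[[1L]]
  stopifnot(paste(toks, collapse = "") == architecture)
  toks
}

#' Apply random substitutions and at most one short indel
#'
#' Substitutions are i.i.d. per base to a uniformly chosen different base;
#' with probability `indel_rate` one 1-3 bp insertion or deletion is applied,
#' never inside a protected range (primer sites). The RNG stream is consumed
#' in a fixed order (substitution scan, then indel), and the returned log
#' replays exactly: substitutions are logged on original coordinates and
#' applied first, the indel on the substituted sequence.
#'
#' @param seq DNA string.
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-sequence probability of one indel.
#' @param protected list of 0-based half-open `(start, end)` ranges to leave
#'   untouched.
#' @return list with `seq` (mutated string) and `log` (data.frame: type,
#'   position, ref, alt; `position` is 1-based, for `ins` the base after
#'   which the insertion lands).
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate,
                            protected = list()) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  n <- nchar(seq)
  prot <- unlist(lapply(protected, function(r) seq.int(r[1] + 1L, r[2])))
  free <- setdiff(seq_len(n), prot)
  log_rows <- list()
  cs <- chars(seq)
  hits <- free[stats::runif(length(free)) < substitution_rate]
  for (i in hits) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1L)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      type = "sub", position = i, ref = cs[i], alt = alt,
      stringsAsFactors = FALSE)
    cs[i] <- alt
  }
  out <- paste(cs, collapse = "")
  if (stats::runif(1L) < indel_rate) {
    type <- sample(c("ins", "del"), 1L)
    len <- sample(1:3, 1L)
    if (type == "del") {
      ok <- free[vapply(free, function(s)
        s + len - 1L <= n && all(seq.int(s, s + len - 1L) %in% free), TRUE)]
      if (length(ok)) {
        pos <- ok[sample.int(length(ok), 1L)]
        ref <- substr(out, pos, pos + len - 1L)
        out <- paste0(substr(out, 1L, pos - 1L), substr(out, pos + len, nchar(out)))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          type = "del", position = pos, ref = ref, alt = "",
          stringsAsFactors = FALSE)
      }
    } else {
      pos <- free[sample.int(length(free), 1L)]
      alt <- random_dna(len)
      out <- paste0(substr(out, 1L, pos), alt, substr(out, pos + 1L, nchar(out)))
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = "ins", position = pos, ref = "", alt = alt,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(type = character(), position = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  list(seq = out, log = log)
}

#' Replay a mutation log
#'
#' @param seq founder DNA string.
#' @param log mutation log from [mutate_sequence()].
#' @return the mutated sequence (identical to the emitted record).
#' @export
replay_mutations <- function(seq, log) {
  cs <- chars(seq)
  for (r in seq_len(nrow(log))) {
    row <- log[r, ]
    if (row$type == "sub") {
      stopifnot(cs[row$position] == row$ref)
      cs[row$position] <- row$alt
    } else if (row$type == "del") {
      out <- paste(cs, collapse = "")
      stopifnot(substr(out, row$position, row$position + nchar(row$ref) - 1L) == row$ref)
      cs <- chars(paste0(substr(out, 1L, row$position - 1L),
                         substr(out, row$position + nchar(row$ref), nchar(out))))
    } else if (row$type == "ins") {
      out <- paste(cs, collapse = "")
      cs <- chars(paste0(substr(out, 1L, row$position), row$alt,
                         substr(out, row$position + 1L, nchar(out))))
    }
  }
  paste(cs, collapse = "")
}

#' Specify a synthetic population
#'
#' @param groups list of group specs; each a list with `label` (population /
#'   country), `architecture`, `n_records`, `n_haplotypes`, and either
#'   `haplotype_counts` (exact per-haplotype record counts summing to
#'   `n_records`) or `haplotype_weights` (sampling weights summing to 1;
#'   every haplotype is seeded at least once when `n_records >=
#'   n_haplotypes`); optional `subspecies` and `regions` (cycled over
#'   records).
#' @param substitution_rate per-base substitution probability.
#' @param indel_rate per-sequence probability of one 1-3 bp indel.
#' @param seed integer seed; one global stream per [generate_population()]
#'   call, consumed group by group.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(groups, substitution_rate = 0.005,
                            indel_rate = 0.02, seed = 1L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, length(groups) >= 1L)
  for (g in groups) {
    stopifnot(!is.null(g$label), !is.null(g$architecture),
              !is.null(g$n_records), !is.null(g$n_haplotypes))
    parse_architecture(g$architecture)
    if (!is.null(g$haplotype_counts)) {
      stopifnot(length(g$haplotype_counts) == g$n_haplotypes,
                sum(g$haplotype_counts) == g$n_records,
                all(g$haplotype_counts >= 1L))
    } else if (!is.null(g$haplotype_weights)) {
      stopifnot(length(g$haplotype_weights) == g$n_haplotypes,
                abs(sum(g$haplotype_weights) - 1) < 1e-8,
                all(g$haplotype_weights >= 0))
    }
  }
  structure(list(groups = groups, substitution_rate = substitution_rate,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic population
#'
#' Per group, `n_haplotypes` founder sequences are derived from the composed
#' architecture by planting three substitutions each at disjoint positions
#' inside the structural units, so founders are pairwise at least 3 SNPs
#' apart and the 1-2-SNP naming rule cannot merge them. Records are drawn by
#' exact counts or weights, then noise is applied. Deterministic per seed.
#'
#' @param spec a [population_spec()].
#' @param library a [unit_library()] (defaults to [make_unit_library()] with
#'   the spec's seed).
#' @param primers primer pair used for the flanks.
#' @return list with `records` (data.frame, `source = "synthetic"`),
#'   `truth` (data.frame with list-column `mutations`), `manifest`
#'   (data.frame) and `founders` (named list of founder sequences).
#' @export
generate_population <- function(spec, library = NULL, primers = coi_primers()) {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(library)) library <- make_unit_library(spec$seed)
  with_seed(spec$seed, {
    recs <- list(); truth <- list(); man <- list(); founders <- list()
    for (gi in seq_along(spec$groups)) {
      g <- spec$groups[[gi]]
      base <- compose_sequence(g$architecture, library, TRUE, primers)
      fwd <- attr(base, "fwd_primer"); rev <- attr(base, "rev_primer")
      core_start <- fwd[2] + nchar(library$units[["TRNA_LEU"]])
      core_end <- rev[1] - nchar(library$units[["COX2_STUB"]])
      pool <- seq.int(core_start + 1L, core_end) # 1-based positions in units
      if (length(pool) < 3L * g$n_haplotypes) {
        stopf("group %s: structural region too short for %d founders",
              g$label, g$n_haplotypes)
      }
      planted <- sample(pool, 3L * g$n_haplotypes)
      g_founders <- character(g$n_haplotypes)
      for (h in seq_len(g$n_haplotypes)) {
        cs <- chars(as.character(base))
        for (i in planted[(3L * (h - 1L) + 1L):(3L * h)]) {
          cs[i] <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1L)
        }
        g_founders[h] <- paste(cs, collapse = "")
      }
      founders[[sprintf("g%d_%s", gi, g$architecture)]] <- g_founders
      idx <- if (!is.null(g$haplotype_counts)) {
        rep(seq_len(g$n_haplotypes), g$haplotype_counts)
      } else {
        w <- g$haplotype_weights %||% rep(1 / g$n_haplotypes, g$n_haplotypes)
        if (g$n_records >= g$n_haplotypes) {
          extra <- g$n_records - g$n_haplotypes
          c(seq_len(g$n_haplotypes),
            if (extra > 0L) sample(seq_len(g$n_haplotypes), extra,
                                   replace = TRUE, prob = w))
        } else {
          sample(seq_len(g$n_haplotypes), g$n_records, replace = TRUE, prob = w)
        }
      }
      regions <- g$regions %||% g$label
      for (i in seq_along(idx)) {
        sid <- sprintf("%s_g%d_%03d", g$label, gi, i)
        mut <- mutate_sequence(g_founders[idx[i]], spec$substitution_rate,
                               spec$indel_rate, protected = list(fwd, rev))
        recs[[sid]] <- mut$seq
        truth[[sid]] <- data.frame(
          sample_id = sid, group_label = g$label,
          architecture = g$architecture, haplotype = idx[i],
          haplotype_key = sprintf("g%d_%s_h%d", gi, g$architecture, idx[i]),
          fwd_start = fwd[1], fwd_end = fwd[2],
          rev_start = rev[1], rev_end = rev[2],
          stringsAsFactors = FALSE)
        truth[[sid]]$mutations <- I(list(mut$log))
        man[[sid]] <- data.frame(
          sample_id = sid,
          region = regions[((i - 1L) %% length(regions)) + 1L],
          subspecies = g$subspecies %||% NA_character_,
          country = g$label, stringsAsFactors = FALSE)
      }
    }
    records <- new_coi_records(names(recs), unlist(recs), source = "synthetic")
    manifest <- do.call(rbind, man)
    records$region <- manifest$region
    records$subspecies <- manifest$subspecies
    truth_df <- do.call(rbind, truth)
    rownames(truth_df) <- rownames(manifest) <- NULL
    list(records = records, truth = truth_df, manifest = manifest,
         founders = founders)
  })
}

#' Algeria-like survey composition
#'
#' A 68-record population over three architectures (24 P0Q, 42 P0QQ,
#' 2 P0QQQ) planted with 24 haplotypes split 5/18/1 across the structures,
#' with exact per-haplotype counts (the dominant P0QQ haplotype carries 16
#' of 68 records, the dominant P0Q one 7 of 68) - a frequency profile
#' realistic for an all-A-lineage Algerian drone sample of this size.
#'
#' @param substitution_rate,indel_rate noise rates (default noise-free).
#' @param seed integer seed.
#' @return a [population_spec()].
#' @export
algeria_population_spec <- function(substitution_rate = 0, indel_rate = 0,
                                    seed = 1L) {
  population_spec(
    groups = list(
      list(label = "Algeria", architecture = "P0Q", n_records = 24L,
           n_haplotypes = 5L, haplotype_counts = c(7L, 5L, 4L, 4L, 4L),
           subspecies = "intermissa"),
      list(label = "Algeria", architecture = "P0QQ", n_records = 42L,
           n_haplotypes = 18L,
           haplotype_counts = c(16L, rep(2L, 9L), rep(1L, 8L)),
           subspecies = "intermissa"),
      list(label = "Algeria", architecture = "P0QQQ", n_records = 2L,
           n_haplotypes = 1L, haplotype_counts = 2L,
           subspecies = "intermissa")
    ),
    substitution_rate = substitution_rate, indel_rate = indel_rate, seed = seed
  )
}
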