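# helper: build an aligned record set for one architecture with optional
# per-record edits, via the standard annotate + align path
aligned_fixture <- function(arch, n, edit = NULL, lib = fx_library(),
                            prefix = "s") {
  base <- as.character(compose_sequence(arch, lib))
  bases <- rep(base, n)
  if (!is.null(edit)) bases <- edit(bases)
  recs <- new_coi_records(paste0(prefix, seq_len(n)), bases)
  anns <- annotate_structures(recs, lib)
  align_within_class(recs, anns, lib)
}

test_that("identical records align with zero gap columns", {
  aln <- aligned_fixture("P0Q", 4L)
  expect_length(unique(aln$rows), 1L)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))
  # row content equals the structural region of the amplicon
  lib <- fx_library()
  expect_equal(unname(aln$rows[1]),
               paste0(lib$units[["P0"]], lib$units[["Q"]]))
})

test_that("a planted deletion yields exactly one gap block in that row", {
  lib <- fx_library()
  aln <- aligned_fixture("P0Q", 3L, edit = function(b) {
    # 2 bp deletion inside the Q unit of record 2
    pos <- nchar(coi_primers()$forward) + nchar(lib$units[["TRNA_LEU"]]) +
      nchar(lib$units[["P0"]]) + 80L
    b[2] <- paste0(substr(b[2], 1, pos), substr(b[2], pos + 3L, nchar(b[2])))
    b
  })
  gaps <- gregexpr("-+", aln$rows[[2]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 2L)
  expect_false(any(grepl("-", aln$rows[c(1, 3)], fixed = TRUE)))
  # gap-free row equals the record's structural segment concatenation
  expect_equal(nchar(gsub("-", "", aln$rows[[2]])), aln$column_count - 2L)
})

test_that("insertions open merged, left-justified columns for all rows", {
  lib <- fx_library()
  aln <- aligned_fixture("P0Q", 3L, edit = function(b) {
    pos <- nchar(coi_primers()$forward) + nchar(lib$units[["TRNA_LEU"]]) + 20L
    b[3] <- paste0(substr(b[3], 1, pos), "GG", substr(b[3], pos + 1L, nchar(b[3])))
    b
  })
  expect_length(unique(nchar(aln$rows)), 1L)
  expect_equal(sum(aln$provenance$kind == "ins"), 2L)
  expect_false(any(grepl("-", aln$rows[[3]], fixed = TRUE)))
  expect_equal(length(gregexpr("-+", aln$rows[[1]])[[1]]), 1L)
})

test_that("mixed structure classes are rejected", {
  lib <- fx_library()
  recs <- new_coi_records(c("a", "b"), c(
    as.character(compose_sequence("P0Q", lib)),
    as.character(compose_sequence("P0QQ", lib))))
  anns <- annotate_structures(recs, lib)
  expect_error(align_within_class(recs, anns, lib), "single structure class")
})

test_that("collapse groups identical rows and respects planted counts", {
  aln <- aligned_fixture("P0Q", 5L)
  grp <- collapse_haplotypes(aln)
  expect_equal(nrow(grp), 1L)
  expect_equal(grp$size, 5L)
  expect_setequal(grp$members[[1]], paste0("s", 1:5))

  # one SNP (inside the structural units) separates groups
  aln2 <- aligned_fixture("P0Q", 2L, edit = function(b) {
    substr(b[2], 120, 120) <- if (substr(b[2], 120, 120) == "A") "C" else "A"
    b
  })
  expect_equal(nrow(collapse_haplotypes(aln2)), 2L)
})

test_that("collapse recovers the planted haplotype count (property sweep)", {
  set.seed(19)
  for (k in c(1L, 4L, 11L, 23L, 30L)) {
    n <- max(k, sample(10:60, 1L))
    spec <- population_spec(
      groups = list(list(label = "pop", architecture = "P0QQ",
                         n_records = n, n_haplotypes = k)),
      substitution_rate = 0, indel_rate = 0, seed = 100L + k)
    pop <- generate_population(spec, fx_library())
    anns <- annotate_structures(pop$records, fx_library())
    aln <- align_within_class(pop$records, anns, fx_library())
    grp <- collapse_haplotypes(aln)
    expect_equal(nrow(grp), k, info = paste("k =", k))
    # conservation: every record in exactly one group
    expect_setequal(unlist(grp$members), pop$records$sample_id)
    expect_equal(sum(grp$size), n)
  }
})

test_that("N-bearing rows only merge when byte-identical", {
  aln <- aligned_fixture("P0Q", 3L, edit = function(b) {
    substr(b[2], 130, 130) <- "N"
    substr(b[3], 130, 130) <- "N"
    b
  })
  grp <- collapse_haplotypes(aln)
  expect_equal(nrow(grp), 2L)
  expect_true(any(grp$has_n))
  expect_setequal(grp$members[[match(TRUE, grp$has_n)]], c("s2", "s3"))
})

test_that("haplotype names parse under the published grammar", {
  expect_equal(parse_haplotype_name("A74")$number, 74L)
  expect_equal(parse_haplotype_name("A74c")$suffix, "c")
  expect_equal(parse_haplotype_name("C2_d")$suffix, "d")
  expect_equal(parse_haplotype_name("M4r")$suffix, "r")
  expect_true(parse_haplotype_name("A77′")$prime)
  expect_error(parse_haplotype_name("74A"), "invalid")
})

test_that("catalog round-trips through FASTA and validates consistency", {
  cat0 <- haplotype_catalog(
    name = c("A1", "M4"), lineage = c("A", "M"), structure = c("P0Q", "PQ"),
    sequence = c("ACGT", "ACGG"), provenance = "published")
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_catalog(cat0, tf)
  back <- read_catalog(tf)
  expect_equal(back$name, cat0$name)
  expect_equal(back$structure, cat0$structure)
  expect_error(haplotype_catalog("A1", "A", "PQ", "ACGT", "x"),
               "implies lineage")
  expect_error(haplotype_catalog(c("A1", "A1"), c("A", "A"),
                                 c("P0Q", "P0Q"), c("A", "C"), "x"), "unique")
})

test_that("catalog matching returns exact hits and nearest neighbours", {
  cat0 <- haplotype_catalog(
    name = c("A1", "A2"), lineage = c("A", "A"), structure = c("P0Q", "P0Q"),
    sequence = c("AAAAAA", "AAAGGG"), provenance = "published")
  expect_equal(match_catalog("AAAAAA", cat0, "P0Q")$name, "A1")
  expect_equal(match_catalog("AAAAAA", cat0, "P0Q")$snp, 0L)
  m <- match_catalog("AAAAAC", cat0, "P0Q")
  expect_equal(m$name, "A1")
  expect_equal(m$snp, 1L)
  expect_false(m$indel)
  empty <- match_catalog("AAAAAA", haplotype_catalog(), "P0Q")
  expect_true(is.na(empty$name))
  expect_equal(empty$snp, Inf)
})

test_that("nomenclature: suffix rule, new-number rule, idempotence", {
  base <- strrep("ACGT", 25)
  snp_at <- function(s, i, to) { substr(s, i, i) <- to; s }
  cat0 <- haplotype_catalog(
    name = c("A74", "A74a", "A74b", "A76"), lineage = rep("A", 4),
    structure = rep("P0QQ", 4),
    sequence = c(base, snp_at(base, 5, "T"), snp_at(base, 9, "T"),
                 snp_at(snp_at(snp_at(snp_at(base, 13, "T"), 17, "T"), 21, "T"), 25, "T")),
    provenance = "published")

  groups <- data.frame(representative = snp_at(base, 30, "T"), size = 2L,
                       stringsAsFactors = FALSE)
  groups$members <- I(list(c("x1", "x2")))
  groups$has_n <- FALSE
  res <- assign_names(groups, cat0, "P0QQ")
  # 1 SNP from A74 while A74, A74a, A74b are occupied -> A74c
  expect_equal(unique(res$assignments$haplotype_name), "A74c")
  expect_equal(unique(res$assignments$novelty), "renamed_alias")

  # >= 3 SNPs from everything in lineage A, catalog max A76 -> A77
  far <- snp_at(snp_at(snp_at(base, 40, "C"), 44, "C"), 48, "C")
  groups2 <- data.frame(representative = far, size = 1L, stringsAsFactors = FALSE)
  groups2$members <- I(list("y1"))
  groups2$has_n <- FALSE
  res2 <- assign_names(groups2, res$catalog, "P0QQ")
  expect_equal(unique(res2$assignments$haplotype_name), "A77")
  expect_equal(unique(res2$assignments$novelty), "novel")

  # exact match to a known name stays known
  groups3 <- data.frame(representative = cat0$sequence[2], size = 1L,
                        stringsAsFactors = FALSE)
  groups3$members <- I(list("z1"))
  groups3$has_n <- FALSE
  res3 <- assign_names(groups3, res2$catalog, "P0QQ")
  expect_equal(res3$assignments$haplotype_name, "A74a")
  expect_equal(res3$assignments$novelty, "known")

  # idempotence: re-running with the updated catalog yields all known
  rerun <- assign_names(rbind(groups, groups2), res2$catalog, "P0QQ")
  expect_true(all(rerun$assignments$novelty == "known"))
  expect_setequal(unique(rerun$assignments$haplotype_name), c("A74c", "A77"))

  # indel-distinct near neighbour goes to a new series, with a note
  gapd <- paste0(substr(base, 1, 50), "--", substr(base, 53, 100))
  cat_g <- haplotype_catalog("A9", "A", "P0QQ", base, "published")
  groups4 <- data.frame(representative = gapd, size = 1L, stringsAsFactors = FALSE)
  groups4$members <- I(list("w1"))
  groups4$has_n <- FALSE
  res4 <- assign_names(groups4, cat_g, "P0QQ")
  expect_equal(res4$assignments$novelty, "novel")
  expect_match(res4$assignments$note, "indel-distinct")
})

test_that("emitted names obey the grammar and never collide", {
  hap <- fx_algeria_haplotypes()
  nm <- unique(hap$assignments$haplotype_name)
  expect_true(all(grepl("^[AMC][0-9]+[a-z]?$", nm)))
  expect_equal(anyDuplicated(hap$catalog$name), 0L)
  # every structure-resolved record got exactly one assignment
  expect_equal(sort(hap$assignments$sample_id), sort(fx_algeria()$records$sample_id))
})

test_that("structure and haplotype summaries report exact percentages", {
  pop <- fx_algeria()
  anns <- fx_algeria_annotations()
  ss <- summarize_structures(anns, pop$manifest)
  expect_equal(ss$structure, c("P0QQ", "P0Q", "P0QQQ"))
  expect_equal(ss$n, c(42L, 24L, 2L))
  expect_equal(ss$pct, c(61.8, 35.3, 2.9))
  expect_true(abs(sum(ss$pct) - 100) <= 0.2)

  hap <- fx_algeria_haplotypes()
  hs <- summarize_haplotypes(hap$assignments, pop$manifest)
  expect_equal(hs$n[1], 16L)
  expect_equal(hs$pct[1], 23.5)
  expect_equal(sum(hs$n), 68L)
  expect_true(all(diff(hs$n) <= 0))

  # single-structure group reports 100%
  one <- summarize_structures(anns[pop$truth$architecture == "P0QQQ"],
                              pop$manifest)
  expect_equal(one$pct, 100)
})

test_that("haplotypes shared across subspecies list both labels", {
  lib <- fx_library()
  base <- as.character(compose_sequence("P0QQ", lib))
  recs <- new_coi_records(c("i1", "i2"), c(base, base))
  anns <- annotate_structures(recs, lib)
  hap <- haplotype_records(recs, anns, lib)
  manifest <- data.frame(sample_id = c("i1", "i2"), region = c("r1", "r2"),
                         subspecies = c("intermissa", "sahariensis"),
                         country = "Algeria", stringsAsFactors = FALSE)
  hs <- summarize_haplotypes(hap$assignments, manifest)
  expect_equal(hs$subspecies, "intermissa;sahariensis")
})
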