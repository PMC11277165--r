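# Shared fixtures (memoized: built once per test run) and independent
# brute-force oracles kept deliberately naive and separate from the package
# implementation paths they check.

.fx <- new.env(parent = emptyenv())

fx_library <- function(seed = 1L) {
  key <- paste0("lib", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- make_unit_library(seed)
  .fx[[key]]
}

fx_algeria <- function() {
  if (is.null(.fx$alg)) {
    .fx$alg <- generate_population(algeria_population_spec(seed = 1L))
  }
  .fx$alg
}

fx_algeria_annotations <- function() {
  if (is.null(.fx$alg_ann)) {
    .fx$alg_ann <- annotate_structures(fx_algeria()$records, fx_library(1L))
  }
  .fx$alg_ann
}

fx_algeria_haplotypes <- function() {
  if (is.null(.fx$alg_hap)) {
    .fx$alg_hap <- haplotype_records(fx_algeria()$records,
                                     fx_algeria_annotations(), fx_library(1L))
  }
  .fx$alg_hap
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive reverse complement, independent of Biostrings
oracle_revcomp <- function(x) {
  paste(rev(str_chars(chartr("ACGTN", "TGCAN", x))), collapse = "")
}

# brute-force sliding-window digestion oracle: test every window position
oracle_digest <- function(seq, recognition = "TTTAAA", cut_offset = 3L) {
  n <- nchar(seq)
  k <- nchar(recognition)
  cuts <- integer()
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      if (substr(seq, i, i + k - 1L) == recognition) {
        cuts <- c(cuts, i - 1L + cut_offset)
      }
    }
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts > 0L & cuts < n]
  as.integer(diff(c(0L, cuts, n)))
}

# naive double-loop Hamming distance matrix
oracle_hamming <- function(rows) {
  n <- length(rows)
  d <- matrix(0L, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- str_chars(rows[[i]]); b <- str_chars(rows[[j]])
      d[i, j] <- sum(a != b)
    }
  }
  d
}

# independent pairwise difference count on a gapped alignment:
# SNP columns (both bases, different) plus indel columns (exactly one gap)
oracle_gapped_diffs <- function(a, b) {
  ca <- str_chars(a); cb <- str_chars(b)
  snp <- 0L; indel <- 0L
  for (j in seq_along(ca)) {
    ga <- ca[j] == "-"; gb <- cb[j] == "-"
    if (ga && gb) next
    if (ga != gb) indel <- indel + 1L
    else if (ca[j] != cb[j]) snp <- snp + 1L
  }
  snp + indel
}

# hand-written Prim MST cost over sequences (independent of igraph)
oracle_mst_cost <- function(seqs) {
  n <- length(seqs)
  if (n <= 1L) return(0L)
  d <- oracle_hamming(seqs)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  cost <- 0L
  while (!all(in_tree)) {
    best <- Inf; pick <- NA_integer_
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        if (d[i, j] < best) { best <- d[i, j]; pick <- j }
      }
    }
    cost <- cost + best
    in_tree[pick] <- TRUE
  }
  as.integer(cost)
}

# random gapped alignment whose gapped columns carry at most 3 distinct
# bases (the recoding precondition), built column by column
random_gapped_alignment <- function(n_rows, n_cols, gap_col_prob = 0.2) {
  mat <- matrix("", n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    if (stats::runif(1) < gap_col_prob) {
      pool <- sample(c("A", "C", "G", "T"), sample(1:3, 1L))
      col <- sample(c(pool, "-"), n_rows, replace = TRUE)
      if (!any(col == "-")) col[sample.int(n_rows, 1L)] <- "-"
      mat[, j] <- col
    } else {
      mat[, j] <- sample(c("A", "C", "G", "T"), n_rows, replace = TRUE)
    }
  }
  stats::setNames(apply(mat, 1L, paste, collapse = ""),
                  paste0("r", seq_len(n_rows)))
}

# minimal NEXUS block-structure checker: header, balanced BEGIN/END,
# semicolon-terminated statements
check_nexus_grammar <- function(path) {
  lines <- readLines(path)
  if (toupper(trimws(lines[[1]])) != "#NEXUS") return(FALSE)
  body <- paste(lines[-1], collapse = "\n")
  stmts <- strsplit(body, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  depth <- 0L
  for (s in stmts) {
    first <- toupper(strsplit(trimws(s), "[[:space:]]+")[[1]][1])
    if (first == "BEGIN") depth <- depth + 1L
    if (first == "END") depth <- depth - 1L
    if (depth < 0L) return(FALSE)
  }
  depth == 0L && grepl(";[[:space:]]*$", body)
}

# small helper: igraph view of a network for connectivity checks
network_to_igraph_for_test <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$name, stringsAsFactors = FALSE))
}
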