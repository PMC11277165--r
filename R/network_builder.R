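# Indel re-coding and median-joining haplotype networks, one per structure
# class. Gap states are replaced by surrogate bases so network construction
# counts indels as characters instead of masking gapped or partially missing
# columns; the median-joining step follows the Bandelt scheme (epsilon-relaxed
# minimum spanning network + quasi-median vectors that reduce total cost).

#' Re-code a gapped alignment into four-letter rows
#'
#' Per column containing gaps, gaps are replaced by one fixed surrogate base
#' chosen deterministically as the alphabetically first base in `{A,C,G,T}`
#' absent from that column's observed bases. Gap-free columns pass through
#' unchanged; a recoding note is stored per altered column. Rows containing
#' N are excluded before recoding (with a logged list): no surrogate is
#' defined for missing data. Recoded column count always equals the original
#' column count, so no site can be masked, and pairwise Hamming distance on
#' recoded rows equals SNP differences plus indel-column differences on the
#' gapped original.
#'
#' @param alignment a `unit_alignment`, or a named character vector of
#'   equal-length aligned rows.
#' @param structure_class stored on the result when `alignment` is a bare
#'   vector.
#' @return object of class `recoded_alignment`: list with `structure_class`,
#'   `rows` (gap- and N-free), `notes` (data.frame: column, surrogate,
#'   observed), `excluded_n` (row names dropped for N content).
#' @export
recode_alignment <- function(alignment, structure_class = NA_character_) {
  if (inherits(alignment, "unit_alignment")) {
    rows <- alignment$rows
    structure_class <- alignment$structure_class
  } else {
    rows <- alignment
  }
  stopifnot(is.character(rows), !is.null(names(rows)),
            length(unique(nchar(rows))) == 1L)
  has_n <- grepl("N", rows, fixed = TRUE)
  excluded <- names(rows)[has_n]
  if (length(excluded)) {
    coi_log("excluding %d N-bearing row(s) from recoding: %s",
            length(excluded), paste(excluded, collapse = ", "), level = "WARN")
  }
  rows <- rows[!has_n]
  if (length(rows) == 0L) stopf("recode_alignment: no rows left after N exclusion")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  notes <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (!any(col == "-")) next
    observed <- sort(unique(col[col != "-"]))
    surrogate <- setdiff(c("A", "C", "G", "T"), observed)
    if (length(surrogate) == 0L) {
      stopf("recoding impossible at column %d: all four bases present alongside gaps", j)
    }
    mat[col == "-", j] <- surrogate[[1L]]
    notes[[length(notes) + 1L]] <- data.frame(
      column = j, surrogate = surrogate[[1L]],
      observed = paste(observed, collapse = ""), stringsAsFactors = FALSE)
  }
  out_rows <- stats::setNames(apply(mat, 1L, paste, collapse = ""), names(rows))
  notes <- if (length(notes)) do.call(rbind, notes) else
    data.frame(column = integer(), surrogate = character(),
               observed = character(), stringsAsFactors = FALSE)
  structure(
    list(structure_class = structure_class, rows = out_rows,
         notes = notes, excluded_n = excluded),
    class = "recoded_alignment"
  )
}

#' Pairwise Hamming distance matrix
#'
#' @param x a `recoded_alignment` or named character vector of equal-length
#'   strings.
#' @return symmetric integer matrix with zero diagonal.
#' @export
hamming_matrix <- function(x) {
  rows <- if (inherits(x, "recoded_alignment")) x$rows else x
  stopifnot(is.character(rows), length(unique(nchar(rows))) == 1L)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- length(rows)
  d <- matrix(0L, n, n, dimnames = list(names(rows), names(rows)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  d
}

# minimum-spanning-tree cost over a set of sequences (complete graph on
# Hamming distances); the network's total-cost criterion
mst_cost <- function(seqs) {
  if (length(seqs) <= 1L) return(0L)
  d <- hamming_matrix(seqs)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

#' Epsilon-relaxed minimum spanning network
#'
#' An edge (u, v) of weight w joins the network when u and v are not yet
#' connected by pairs at distance below w - epsilon; at epsilon = 0 this is
#' the union of all minimum spanning trees.
#'
#' @param seqs named character vector of distinct equal-length sequences.
#' @param epsilon non-negative relaxation (integer).
#' @return data.frame of edges (from, to, weight).
#' @export
minimum_spanning_network <- function(seqs, epsilon = 0L) {
  stopifnot(epsilon >= 0L)
  n <- length(seqs)
  nm <- names(seqs)
  if (n <= 1L) {
    return(data.frame(from = character(), to = character(), weight = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- hamming_matrix(seqs)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs], nm[pairs[, 1L]], nm[pairs[, 2L]])
  pairs <- pairs[ord, , drop = FALSE]
  w <- d[pairs]
  edges <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    # components of the threshold graph at distance < w - epsilon
    thr <- d < (w[k] - epsilon)
    diag(thr) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(thr, mode = "undirected")
    comp <- igraph::components(g)$membership
    if (comp[i] != comp[j]) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = nm[i], to = nm[j], weight = as.integer(w[k]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), weight = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# quasi-medians of a sequence triplet: per-column majority where one exists;
# columns where all three states differ contribute the states of the triplet
# members (combinations capped: beyond cap, only the three parent-copy
# resolutions are enumerated)
quasi_medians <- function(a, b, c, cap = 4L) {
  ca <- chars(a); cb <- chars(b); cc <- chars(c)
  maj <- ifelse(ca == cb | ca == cc, ca, ifelse(cb == cc, cb, NA_character_))
  amb <- which(is.na(maj))
  if (length(amb) == 0L) return(paste(maj, collapse = ""))
  if (length(amb) <= cap) {
    grid <- expand.grid(lapply(amb, function(j) c(ca[j], cb[j], cc[j])),
                        stringsAsFactors = FALSE)
    res <- apply(grid, 1L, function(choice) {
      m <- maj
      m[amb] <- as.character(choice)
      paste(m, collapse = "")
    })
  } else {
    res <- vapply(list(ca, cb, cc), function(parent) {
      m <- maj
      m[amb] <- parent[amb]
      paste(m, collapse = "")
    }, "")
  }
  sort(unique(res))
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: (1) build the epsilon-relaxed minimum
#' spanning network over the observed haplotypes; (2) for every connected
#' triplet (a node and two of its neighbours) compute quasi-medians;
#' (3) add the median vector that most reduces the total cost (minimum
#' spanning tree cost over observed + median nodes), iterating to a fixed
#' point; (4) delete obsolete median nodes (degree <= 2 whose removal does
#' not disconnect observed nodes or increase cost). All tie-breaks are
#' lexicographic on node sequence, so the result is deterministic. Median
#' nodes are labeled mv1, mv2, ... in insertion order.
#'
#' @param seqs named character vector of distinct haplotype sequences over
#'   `{A,C,G,T}` (names are haplotype names).
#' @param epsilon non-negative integer relaxation parameter.
#' @param max_medians safety bound on the number of median vectors added.
#' @return object of class `haplotype_network`: list with `nodes`
#'   (data.frame: name, sequence, type observed/median), `edges` (data.frame:
#'   from, to, weight = Hamming distance of endpoints), `epsilon`,
#'   `total_cost`.
#' @export
median_joining <- function(seqs, epsilon = 0L, max_medians = 50L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(seqs)) stopf("median_joining: duplicate node sequences")
  nodes <- seqs
  observed <- names(seqs)
  n_med <- 0L
  repeat {
    edges <- minimum_spanning_network(nodes, epsilon)
    cur <- mst_cost(nodes)
    cands <- character()
    if (nrow(edges) > 0L) {
      nbr <- split(c(edges$to, edges$from), c(edges$from, edges$to))
      seen <- new.env(parent = emptyenv())
      for (v in names(nbr)) {
        nb <- sort(unique(nbr[[v]]))
        if (length(nb) < 2L) next
        for (i in seq_len(length(nb) - 1L)) {
          for (j in (i + 1L):length(nb)) {
            key <- paste(sort(c(nb[i], v, nb[j])), collapse = "\r")
            if (!is.null(seen[[key]])) next
            seen[[key]] <- TRUE
            cands <- c(cands, quasi_medians(nodes[[nb[i]]], nodes[[v]], nodes[[nb[j]]]))
          }
        }
      }
    }
    cands <- setdiff(sort(unique(cands)), nodes)
    if (length(cands) == 0L || n_med >= max_medians) break
    costs <- vapply(cands, function(m) mst_cost(c(nodes, m)), 0)
    best <- min(costs)
    if (best >= cur) break
    pick <- cands[costs == best][[1L]] # lexicographically smallest
    n_med <- n_med + 1L
    nodes <- c(nodes, stats::setNames(pick, paste0("mv", n_med)))
  }
  # prune obsolete medians
  repeat {
    edges <- minimum_spanning_network(nodes, epsilon)
    med <- setdiff(names(nodes), observed)
    if (length(med) == 0L) break
    deg <- table(factor(c(edges$from, edges$to), levels = names(nodes)))
    cur <- mst_cost(nodes)
    dropped <- FALSE
    for (m in med) {
      if (deg[[m]] <= 2L && mst_cost(nodes[names(nodes) != m]) <= cur) {
        nodes <- nodes[names(nodes) != m]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  # relabel surviving medians in insertion order
  med <- setdiff(names(nodes), observed)
  if (length(med)) {
    names(nodes)[match(med, names(nodes))] <- paste0("mv", seq_along(med))
  }
  edges <- minimum_spanning_network(nodes, epsilon)
  structure(
    list(
      nodes = data.frame(
        name = names(nodes), sequence = unname(nodes),
        type = ifelse(names(nodes) %in% observed, "observed", "median"),
        stringsAsFactors = FALSE),
      edges = edges,
      epsilon = as.integer(epsilon),
      total_cost = mst_cost(nodes)
    ),
    class = "haplotype_network"
  )
}

#' Build one median-joining network per structure class
#'
#' Classes are never mixed; empty classes are skipped with a warning. Node
#' frequency and population annotations are attached when `assignments` and
#' a manifest are supplied.
#'
#' @param recoded_by_class named list of `recoded_alignment`, keyed by
#'   structure class, with one row per haplotype (names are haplotype names).
#' @param epsilon relaxation parameter passed to [median_joining()].
#' @param assignments optional assignment table (sample_id, haplotype_name).
#' @param manifest optional manifest for population composition.
#' @param group_field manifest column used for population composition.
#' @return named list of `haplotype_network`.
#' @export
build_networks <- function(recoded_by_class, epsilon = 0L, assignments = NULL,
                           manifest = NULL, group_field = "country") {
  out <- list()
  for (cls in names(recoded_by_class)) {
    rec <- recoded_by_class[[cls]]
    if (length(rec$rows) == 0L) {
      warnf("structure class %s is empty; skipped", cls)
      next
    }
    net <- median_joining(rec$rows, epsilon)
    if (!is.null(assignments)) {
      freq <- table(assignments$haplotype_name)
      net$nodes$frequency <- ifelse(net$nodes$type == "observed",
                                    as.integer(freq[net$nodes$name]), 0L)
      net$nodes$frequency[is.na(net$nodes$frequency)] <- 0L
      if (!is.null(manifest)) {
        grp <- manifest[[group_field]][match(assignments$sample_id, manifest$sample_id)]
        comp <- tapply(grp, assignments$haplotype_name, function(g)
          paste(sort(unique(g)), collapse = ";"))
        net$nodes$populations <- ifelse(net$nodes$type == "observed",
                                        unname(comp[net$nodes$name]), "")
        net$nodes$populations[is.na(net$nodes$populations)] <- ""
      }
    }
    net$structure_class <- cls
    out[[cls]] <- net
  }
  out
}

network_to_igraph <- function(network) {
  v <- network$nodes
  if (is.null(v$frequency)) v$frequency <- 0L
  if (is.null(v$populations)) v$populations <- ""
  v$sequence <- as.character(v$sequence)
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = v)
}

#' Export a haplotype network
#'
#' GraphML (via igraph; round-trips topology, node attributes and edge
#' weights) or a NEXUS `Network` block.
#'
#' @param network a `haplotype_network`.
#' @param path output file.
#' @param format `"graphml"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "nexus")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    v <- network$nodes
    e <- network$edges
    idx <- stats::setNames(seq_len(nrow(v)), v$name)
    lines <- c(
      "#NEXUS",
      "BEGIN NETWORK;",
      sprintf("  DIMENSIONS NVERTICES=%d NEDGES=%d;", nrow(v), nrow(e)),
      sprintf("  FORMAT EPSILON=%d;", network$epsilon),
      "  VERTICES",
      sprintf("    %d %s %s,", seq_len(nrow(v)), v$name, v$type),
      "  ;",
      "  EDGES",
      if (nrow(e)) sprintf("    %d %d %d,", idx[e$from], idx[e$to], e$weight) else character(),
      "  ;",
      "END;"
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a GraphML network back (round-trip helper)
#'
#' @param path GraphML file written by [export_network()].
#' @return a `haplotype_network` (without recomputing medians).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  el <- igraph::as_data_frame(g, what = "edges")
  structure(
    list(
      nodes = data.frame(name = va$name, sequence = va$sequence, type = va$type,
                         stringsAsFactors = FALSE),
      edges = data.frame(from = el$from, to = el$to,
                         weight = as.integer(el$weight), stringsAsFactors = FALSE),
      epsilon = NA_integer_,
      total_cost = NA_integer_
    ),
    class = "haplotype_network"
  )
}
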