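# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

coi_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[coicoii %s] %s", level, sprintf(fmt, ...)))
}

# scoring shared by all unit-anchored alignments: match +1, mismatch -1,
# gap open -4, gap extend -1 (fixed so outputs are bit-reproducible)
coi_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE
      )
    }
    cache
  }
})

coi_align <- function(pattern, subject, type = "global") {
  Biostrings::pairwiseAlignment(
    pattern, subject,
    type = type,
    substitutionMatrix = coi_submat(),
    gapOpening = 4, gapExtension = 1
  )
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# uniform random DNA drawn from the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# preserve caller RNG state while using a local seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
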