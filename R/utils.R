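## Internal helpers shared across modules.

#' @useDynLib retroinvade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist median prcomp rbinom runif sd setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Substitute `n_mut` (or rate `rate`) random positions with a different base.
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  ca <- charToRaw(a)
  cb <- charToRaw(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
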