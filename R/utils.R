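#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n, len) {
  vapply(
    seq_len(n),
    function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Unique 2-bit-encoded k-mers of one sequence (numeric keys).
kmer_keys <- function(seq, k) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1
  L <- length(codes)
  if (L < k || anyNA(codes)) {
    codes <- codes[!is.na(codes)]
    L <- length(codes)
    if (L < k) return(numeric(0))
  }
  np <- L - k + 1
  out <- numeric(np)
  for (o in 0:(k - 1)) out <- out * 4 + codes[(1 + o):(np + o)]
  unique(out)
}

jaccard_keys <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

#' Translate nucleotide sequences with the standard codon table
#'
#' @param x Character vector of nucleotide sequences. Elements whose length
#'   is not a multiple of three (or that are empty/NA) translate to `NA`.
#' @return Character vector of amino-acid sequences; stop codons are `*`.
#' @export
translate_nt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & nzchar(x) & nchar(x) %% 3 == 0 &
    !grepl("[^ACGT]", x)
  if (any(ok)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(x[ok]),
      no.init.codon = TRUE
    )
    out[ok] <- as.character(aa)
  }
  out
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "clonospace_io_error")
  }
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
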