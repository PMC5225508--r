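# Low-level sequence helpers shared across modules. All coordinates in this
# package are 0-based half-open; conversion to 1-based inclusive happens only
# at file boundaries (GFF3) and in user-facing substring helpers.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Uniform random DNA string
#'
#' Background sequence is i.i.d. uniform over A/C/G/T; draws come from the
#' current RNG stream so callers control reproducibility via seeds.
#'
#' @param n length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a submodule seed from a global one; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGTN symbols", what), call. = FALSE)
  }
  invisible(x)
}

# substring in 0-based half-open coordinates
subseq0 <- function(s, start, end) {
  substr(s, start + 1L, end)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# codon -> amino acid lookup over the ACGTN alphabet; codons containing N
# translate to 'X'. Built once per session from the standard genetic code.
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      bases <- c("A", "C", "G", "T", "N")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      aa <- rep("X", length(codons))
      names(aa) <- codons
      aa[names(gc)] <- unname(gc)
      tab <<- aa
    }
    tab
  }
})

translate_dna <- function(seq) {
  n <- nchar(seq)
  n <- n - n %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  paste(codon_table()[codons], collapse = "")
}

# longest common prefix / suffix lengths of two strings
lcp_len <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  n <- min(length(ca), length(cb))
  if (n == 0L) return(0L)
  neq <- which(ca[seq_len(n)] != cb[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) {
  lcp_len(paste(rev(seq_chars(a)), collapse = ""),
          paste(rev(seq_chars(b)), collapse = ""))
}

# scoring matrices -----------------------------------------------------------

#' Nucleotide substitution matrix over the A/C/G/T/N alphabet
#'
#' Match/mismatch scoring with an absorbing penalty for N so that ambiguous
#' bases never contribute to TIR or TSD evidence.
#'
#' @param match,mismatch,n_score scores; `n_score` applies to any comparison
#'   involving N, including N vs N.
#' @return integer matrix with alphabet row/column names.
#' @export
nuc_submat <- function(match = 2L, mismatch = -3L, n_score = -4L) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(as.integer(mismatch), 5, 5, dimnames = list(ab, ab))
  diag(m) <- as.integer(match)
  m["N", ] <- as.integer(n_score)
  m[, "N"] <- as.integer(n_score)
  m
}

#' BLOSUM62 with BLAST-like handling of unknown residues
#'
#' The standard BLOSUM62 matrix with the X and * rows and columns overridden
#' to a flat -4 so unknown residues and stops never score positively.
#'
#' @return integer matrix over the 25-letter protein alphabet.
#' @export
protein_submat <- function() {
  bl <- get_blosum62()
  m <- bl
  for (s in c("X", "*")) {
    m[s, ] <- -4L
    m[, s] <- -4L
  }
  storage.mode(m) <- "integer"
  m
}

get_blosum62 <- local({
  bl <- NULL
  function() {
    if (is.null(bl)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      bl <<- e$BLOSUM62
    }
    bl
  }
})

# map residues outside the matrix alphabet to X
sanitize_peptide <- function(p, alphabet) {
  chars <- unique(seq_chars(p))
  bad <- setdiff(chars, seq_chars(alphabet))
  for (b in bad) p <- gsub(b, "X", p, fixed = TRUE)
  p
}
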