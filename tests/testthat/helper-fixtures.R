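# Shared fixtures (built once per run) and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fix <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

tp <- function() cached("tp", synthetic_transposase())

# one mid-sized synthetic genome reused across discovery tests
demo_genome <- function() cached(
  "demo_genome",
  generate_genome(n_scaffolds = 3, scaffold_len = 60000, n_full_copies = 4,
                  n_derivatives = 10, n_genes = 8, seed = 7))

# Independent global affine-gap DP (three-state, plain R); gap of length k
# costs go + k * ge. Written separately from the package's aligner.
bf_global_affine <- function(a, b, submat, go = 10, ge = 1) {
  n <- nchar(a); m <- nchar(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  for (i in 1:(n + 1)) {
    for (j in 1:(m + 1)) {
      if (i > 1 && j > 1)
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
          submat[ca[i - 1], cb[j - 1]]
      if (i > 1) X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      if (j > 1) Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force local score: maximum over all substring pairs of the global
# score (plus the empty alignment at 0).
bf_local_affine <- function(a, b, submat, go = 10, ge = 1) {
  best <- 0
  for (i1 in 1:nchar(a)) {
    for (i2 in i1:nchar(a)) {
      sa <- substr(a, i1, i2)
      for (j1 in 1:nchar(b)) {
        for (j2 in j1:nchar(b)) {
          best <- max(best, bf_global_affine(sa, substr(b, j1, j2),
                                             submat, go, ge))
        }
      }
    }
  }
  best
}

build_tir_fixture <- function(seed = 55) {
  withr::with_seed(seed, build_full_element(element_template()))$tir
}

random_dna_fixture <- function(n, seed = 99) {
  withr::with_seed(seed, random_dna(n))
}

random_peptide <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}
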