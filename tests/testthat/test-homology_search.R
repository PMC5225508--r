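test_that("six-frame translation renders frames and stops correctly", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr$peptide[fr$strand == "+" & fr$frame == 0], "MA")
  expect_equal(six_frame_translate("TAA")$peptide[1], "*")
  expect_error(six_frame_translate("ACGU"), "non-ACGTN")
  expect_error(six_frame_translate("AC"), "shorter")

  s <- random_dna_fixture(120, seed = 17)
  a <- six_frame_translate(s)
  b <- six_frame_translate(revcomp(s))
  for (f in 0:2) {
    expect_equal(a$peptide[a$strand == "-" & a$frame == f],
                 b$peptide[b$strand == "+" & b$frame == f])
  }
})

test_that("frame coordinate maps invert exactly", {
  s <- random_dna_fixture(90, seed = 18)
  fr <- six_frame_translate(s)
  for (k in seq_len(nrow(fr))) {
    pep <- fr$peptide[k]
    for (p in c(0L, 3L, nchar(pep) - 3L)) {
      span <- frame_to_genomic(p, p + 3L, fr$strand[k], fr$frame[k], nchar(s))
      sub <- substr(s, span[1] + 1, span[2])
      if (fr$strand[k] == "-") sub <- revcomp(sub)
      expect_equal(six_frame_translate(sub)$peptide[1],
                   substr(pep, p + 1, p + 3))
    }
  }
})

test_that("local protein alignment matches self-scores and handles edge cases", {
  sm <- protein_submat()
  q <- "MKVLHWRDEY"
  al <- local_align_protein(q, q)
  expect_equal(al$score,
               sum(vapply(strsplit(q, "")[[1]], function(a) sm[a, a],
                          numeric(1))))
  # disjoint residue usage with all-negative cross scores -> empty alignment
  al2 <- local_align_protein("WWWW", "DDDD")
  expect_equal(al2$score, 0)
  expect_equal(al2$query_aln, "")
  expect_error(local_align_protein("", "AA"), "empty")
})

test_that("Smith-Waterman equals the brute-force substring oracle", {
  sm <- protein_submat()
  withr::with_seed(101, {
    lens <- c(rbind(sample(3:7, 10, replace = TRUE),
                    sample(3:7, 10, replace = TRUE)))
    for (i in 1:10) {
      a <- random_peptide(lens[2 * i - 1])
      b <- random_peptide(lens[2 * i])
      expect_equal(local_align_protein(a, b)$score,
                   bf_local_affine(a, b, sm), info = paste(a, b))
    }
    # and on full 12-mers, plus the independent Biostrings implementation
    for (i in 1:3) {
      a <- random_peptide(12)
      b <- random_peptide(12)
      s <- local_align_protein(a, b)$score
      expect_equal(s, bf_local_affine(a, b, sm), info = paste(a, b))
      expect_equal(s, Biostrings::score(Biostrings::pairwiseAlignment(
        a, b, type = "local", substitutionMatrix = sm,
        gapOpening = 10, gapExtension = 1)))
    }
  })
})

test_that("translated search recovers planted queries and stays quiet on noise", {
  g <- demo_genome()
  hits <- dedup_hits(filter_hits(search_dde(g$genome, tp()$dde_domain)))
  full <- g$truth[g$truth$kind == "full", ]
  expect_gte(nrow(hits), nrow(full))
  # every planted copy is covered by a hit
  for (r in seq_len(nrow(full))) {
    cov <- hits$scaffold == full$scaffold[r] &
      hits$start >= full$start[r] & hits$end <= full$end[r]
    expect_equal(sum(cov), 1)
  }
  expect_equal(nrow(search_dde(genome_set(c(x = strrep("A", 100))),
                               tp()$dde_domain)), 0)
})

test_that("random genomes yield no significant DDE hits", {
  n_empty <- 0L
  for (s in 1:20) {
    g <- withr::with_seed(1000 + s,
                          genome_set(c(chr = random_dna(100000))))
    h <- search_dde(g, tp()$dde_domain, evalue_cutoff = 1e-15)
    if (nrow(h) == 0) n_empty <- n_empty + 1L
  }
  expect_gte(n_empty, 19)
})

test_that("search is strand-symmetric", {
  g <- generate_genome(n_scaffolds = 1, scaffold_len = 30000,
                       n_full_copies = 2, n_derivatives = 0, n_genes = 3,
                       seed = 21)
  h1 <- search_dde(g$genome, tp()$dde_domain, evalue_cutoff = 1e-15)
  L <- g$genome$lengths[[1]]
  grc <- genome_set(setNames(revcomp(g$genome$scaffolds[[1]]),
                             names(g$genome$scaffolds)))
  h2 <- search_dde(grc, tp()$dde_domain, evalue_cutoff = 1e-15)
  expect_equal(nrow(h1), nrow(h2))
  m1 <- sort(h1$start)
  m2 <- sort(L - h2$end)
  expect_equal(m1, m2)
  expect_equal(sort(h1$score), sort(h2$score))
})

test_that("duplicate-hit removal keeps the maximal-score compatible set", {
  base <- data.frame(scaffold = "c", strand = "+", frame = 0,
                     evalue = 1e-20, subject_peptide = "X")
  two <- rbind(cbind(base, start = 100L, end = 200L, score = 50),
               cbind(base, start = 100L, end = 200L, score = 40))
  expect_equal(nrow(dedup_hits(two)), 1)
  expect_equal(dedup_hits(two)$score, 50)

  disjoint <- rbind(cbind(base, start = 0L, end = 100L, score = 30),
                    cbind(base, start = 500L, end = 600L, score = 20))
  expect_equal(nrow(dedup_hits(disjoint)), 2)

  # staggered: overlaps 0.6 and 0.4 of a 100-bp window
  stag <- rbind(cbind(base, start = 0L, end = 100L, score = 50),
                cbind(base, start = 40L, end = 140L, score = 45),
                cbind(base, start = 100L, end = 200L, score = 40))
  kept <- dedup_hits(stag)
  # brute force over subsets: maximal total score among conflict-free sets
  ok_pair <- function(i, j) {
    ov <- min(stag$end[i], stag$end[j]) - max(stag$start[i], stag$start[j])
    !(ov / 100 >= 0.5 && ov / 100 >= 0.5)
  }
  best <- NULL
  for (mask in 1:7) {
    set <- which(bitwAnd(mask, c(1, 2, 4)) > 0)
    if (length(set) > 1 &&
        !all(apply(combn(set, 2), 2, function(p) ok_pair(p[1], p[2])))) next
    sc <- sum(stag$score[set])
    if (is.null(best) || sc > best$sc) best <- list(sc = sc, set = set)
  }
  expect_equal(sort(kept$start), sort(stag$start[best$set]))
})
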