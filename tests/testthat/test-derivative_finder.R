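plant_at <- function(bg, inserts) {
  # splice sequences into a background string at given 0-based points
  inserts <- inserts[order(inserts$pos), ]
  out <- character(); cur <- 0L
  for (i in seq_len(nrow(inserts))) {
    out <- c(out, substr(bg, cur + 1, inserts$pos[i]), inserts$seq[i])
    cur <- inserts$pos[i]
  }
  paste(c(out, substr(bg, cur + 1, nchar(bg))), collapse = "")
}

test_that("terminal seed search finds planted termini on both strands", {
  term <- random_dna_fixture(50, seed = 71)
  bg <- random_dna_fixture(20000, seed = 72)
  ins <- data.frame(pos = c(1000L, 5000L, 9000L, 15000L),
                    seq = c(term, term, term, revcomp(term)))
  g <- genome_set(c(chr = plant_at(bg, ins)))
  h <- terminal_seed_search(g, term, max_mismatches = 0)
  expect_equal(nrow(h), 4)
  expect_equal(sum(h$orientation == "fwd"), 3)
  expect_equal(sum(h$orientation == "rc"), 1)

  # mismatch bound is respected
  term_mut <- term
  for (i in c(5, 20, 45)) {
    substr(term_mut, i, i) <- chartr("ACGT", "TGCA", substr(term_mut, i, i))
  }
  g2 <- genome_set(c(chr = plant_at(bg, data.frame(pos = 3000L,
                                                   seq = term_mut))))
  expect_equal(nrow(terminal_seed_search(g2, term, max_mismatches = 5)), 1)
  expect_equal(terminal_seed_search(g2, term, max_mismatches = 5)$mismatches, 3)
  expect_equal(nrow(terminal_seed_search(g2, term, max_mismatches = 2)), 0)
  expect_error(terminal_seed_search(g2, "ACGT"), "exactly 50")
})

test_that("random genomes contain no terminus matches", {
  term <- random_dna_fixture(50, seed = 73)
  n_empty <- 0L
  for (s in 1:20) {
    g <- withr::with_seed(500 + s, genome_set(c(chr = random_dna(50000))))
    if (nrow(terminal_seed_search(g, term, max_mismatches = 0)) == 0)
      n_empty <- n_empty + 1L
  }
  expect_gte(n_empty, 19)
})

test_that("end pairing is convergent, bounded, and nesting-aware", {
  hit <- function(start, orient) {
    data.frame(scaffold = "c", start = start, end = start + 50L,
               orientation = orient, mismatches = 0L)
  }
  one <- rbind(hit(100, "fwd"), hit(1550, "rc"))
  p1 <- pair_ends(one)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$start, p1$end), c(100, 1600))

  divergent <- rbind(hit(100, "rc"), hit(1000, "fwd"))
  expect_equal(nrow(pair_ends(divergent)), 0)

  too_far <- rbind(hit(0, "fwd"), hit(30000, "rc"))
  expect_equal(nrow(pair_ends(too_far)), 0)

  # nested elements: outer 5' ... inner 5' ... inner 3' ... outer 3'
  nested <- rbind(hit(0, "fwd"), hit(300, "fwd"), hit(800, "rc"),
                  hit(1500, "rc"))
  pn <- pair_ends(nested)
  expect_equal(nrow(pn), 2)
  expect_true(any(pn$start == 300 & pn$end == 850))   # inner
  expect_true(any(pn$start == 0 & pn$end == 1550))    # outer
  expect_equal(sum(pn$nested), 2)
})

test_that("TSD verification partitions candidates correctly", {
  g <- demo_genome()
  full_spans <- g$truth[g$truth$kind == "full", c("scaffold", "start", "end")]
  res <- find_derivatives(g$genome, g$element$seq,
                          exclude_spans = full_spans)
  truth_d <- g$truth[g$truth$kind == "derivative", ]
  expect_equal(nrow(res$candidates), nrow(truth_d))
  expect_equal(length(res$verified), sum(truth_d$perfect_tsd))
  got <- sort(vapply(res$verified, function(d)
    sprintf("%s:%d-%d", d$scaffold, d$span[1], d$span[2]), character(1)))
  want <- with(truth_d[truth_d$perfect_tsd, ],
               sort(sprintf("%s:%d-%d", scaffold, start, end)))
  expect_identical(got, want)
  for (d in res$verified) expect_true(d$tsd$length %in% 8:10)

  # scrambling one right flank unverifies that candidate
  v1 <- res$verified[[1]]
  sc <- v1$scaffold
  seq <- g$genome$scaffolds[[sc]]
  k <- v1$tsd$length
  scrambled <- seq
  substr(scrambled, v1$span[2] + 1, v1$span[2] + k) <- strrep("A", k)
  g2 <- g$genome
  g2$scaffolds[[sc]] <- scrambled
  res2 <- verify_and_annotate(res$candidates, g2)
  keys <- vapply(res2, function(d) sprintf("%s:%d-%d", d$scaffold,
                                           d$span[1], d$span[2]), character(1))
  idx <- which(keys == sprintf("%s:%d-%d", sc, v1$span[1], v1$span[2]))
  expect_false(res2[[idx]]$verified)
})

test_that("verified counts are invariant to scaffold order", {
  g <- demo_genome()
  res <- find_derivatives(g$genome, g$element$seq)
  g2 <- genome_set(g$genome$scaffolds[rev(seq_along(g$genome$scaffolds))])
  res2 <- find_derivatives(g2, g$element$seq)
  expect_equal(length(res2$verified), length(res$verified))
})

test_that("pack content is detected at the quantified example scale", {
  host <- random_dna_fixture(1500, seed = 81)
  pk <- generate_pack_derivative(element_template(), host, fragment_len = 276,
                                 identity = 0.975, seed = 12)
  bg <- random_dna_fixture(6000, seed = 82)
  tsd <- "ATTCAATG"
  chr <- paste0(substr(bg, 1, 3000), tsd, pk$seq, tsd,
                substr(bg, 3001, 6000))
  g <- genome_set(c(chr = chr))
  span <- c(3000L + 8L, 3000L + 8L + nchar(pk$seq))
  d <- verify_and_annotate(data.frame(scaffold = "chr", start = span[1],
                                      end = span[2], nested = FALSE), g)[[1]]
  expect_true(d$verified)
  hits <- classify_pack_content(d, g, c(kinase = host))
  expect_equal(nrow(hits), 1)
  expect_gte(hits$length, 250)
  expect_gte(hits$identity, 0.9)

  # a plain random internal region reports nothing
  d0 <- withr::with_seed(83, build_derivative(build_tir_fixture(), 600))
  chr0 <- paste0(substr(bg, 1, 2000), d0$seq, substr(bg, 2001, 6000))
  g0 <- genome_set(c(chr = chr0))
  dd <- verify_and_annotate(data.frame(scaffold = "chr", start = 2000L,
                                       end = 2000L + nchar(d0$seq),
                                       nested = FALSE), g0)[[1]]
  expect_equal(nrow(classify_pack_content(dd, g0, c(kinase = host))), 0)

  # thresholds are monotone: raising them can only drop hits
  h_loose <- classify_pack_content(d, g, c(kinase = host),
                                   min_identity = 0.5, min_len = 50)
  h_tight <- classify_pack_content(d, g, c(kinase = host),
                                   min_identity = 0.99, min_len = 300)
  expect_gte(nrow(h_loose), nrow(hits))
  expect_lte(nrow(h_tight), nrow(hits))
})
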