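test_that("identical seeds give byte-identical genomes", {
  a <- generate_genome(n_scaffolds = 2, scaffold_len = 25000,
                       n_full_copies = 2, n_derivatives = 4, n_genes = 5,
                       window = 2000, seed = 42)
  b <- generate_genome(n_scaffolds = 2, scaffold_len = 25000,
                       n_full_copies = 2, n_derivatives = 4, n_genes = 5,
                       window = 2000, seed = 42)
  expect_identical(a$genome$scaffolds, b$genome$scaffolds)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genes, b$genes)
  c <- generate_genome(n_scaffolds = 2, scaffold_len = 25000,
                       n_full_copies = 2, n_derivatives = 4, n_genes = 5,
                       window = 2000, seed = 43)
  expect_false(identical(a$genome$scaffolds, c$genome$scaffolds))
})

test_that("planted elements are self-consistent with the annotators", {
  g <- demo_genome()
  tmpl <- g$template
  full <- g$truth[g$truth$kind == "full", ]
  expect_gt(nrow(full), 0)
  for (r in seq_len(nrow(full))) {
    seq <- g$genome$scaffolds[[full$scaffold[r]]]
    el <- substr(seq, full$start[r] + 1, full$end[r])
    tir <- find_tir(el)
    expect_equal(tir$length, tmpl$tir_len)
    expect_equal(tir$identity, 1)
    lf <- substr(seq, full$start[r] - 11, full$start[r])
    rf <- substr(seq, full$end[r] + 1, full$end[r] + 12)
    tsd <- call_tsd(lf, rf)
    expect_equal(tsd$length, tmpl$tsd_len)
    expect_true(tsd$perfect)
    expect_equal(tsd$left, full$tsd_seq[r])
  }
  # flanks literally contain the TSD on both sides (truth invariant)
  both <- g$truth[g$truth$perfect_tsd, ]
  for (r in seq_len(nrow(both))) {
    seq <- g$genome$scaffolds[[both$scaffold[r]]]
    k <- both$tsd_len[r]
    expect_identical(substr(seq, both$start[r] - k + 1, both$start[r]),
                     both$tsd_seq[r])
    expect_identical(substr(seq, both$end[r] + 1, both$end[r] + k),
                     both$tsd_seq[r])
  }
})

test_that("genic fraction of planted sites matches the request exactly", {
  g <- demo_genome()
  n_sites <- nrow(g$truth)
  expect_equal(sum(g$truth$genic), round(0.643 * n_sites))
  # and the final-coordinate classification agrees with the truth flags
  cl <- classify_proximity(data.frame(scaffold = g$truth$scaffold,
                                      pos = g$truth$start),
                           g$genes, window = 5000)
  expect_identical(cl != "distal", g$truth$genic)
})

test_that("an empty plant yields a quiet genome", {
  g <- generate_genome(n_scaffolds = 2, scaffold_len = 20000,
                       n_full_copies = 0, n_derivatives = 0, n_genes = 4,
                       seed = 5)
  expect_equal(nrow(g$truth), 0)
  hits <- search_dde(g$genome, tp()$dde_domain, evalue_cutoff = 1e-15)
  expect_equal(nrow(hits), 0)
})

test_that("family copies at divergence 0 are identical", {
  g <- generate_genome(n_scaffolds = 2, scaffold_len = 40000,
                       n_full_copies = 7, n_derivatives = 0, n_genes = 4,
                       seed = 13)
  full <- g$truth
  seqs <- vapply(seq_len(nrow(full)), function(r) {
    substr(g$genome$scaffolds[[full$scaffold[r]]], full$start[r] + 1,
           full$end[r])
  }, character(1))
  expect_equal(length(unique(seqs)), 1)
  # and with divergence > 0 copies differ by at most that many substitutions
  tmpl <- element_template(family_divergence = 5L)
  g2 <- generate_genome(template = tmpl, n_scaffolds = 2,
                        scaffold_len = 40000, n_full_copies = 3,
                        n_derivatives = 0, n_genes = 4, seed = 13)
  f2 <- g2$truth
  s2 <- vapply(seq_len(nrow(f2)), function(r) {
    substr(g2$genome$scaffolds[[f2$scaffold[r]]], f2$start[r] + 1, f2$end[r])
  }, character(1))
  dmax <- max(vapply(s2, function(x)
    sum(utf8ToInt(x) != utf8ToInt(g2$element$seq)), numeric(1)))
  expect_lte(dmax, 5)
})

test_that("pack derivatives embed host fragments at the requested identity", {
  host <- random_dna_fixture(1200, seed = 31)
  d <- generate_pack_derivative(element_template(), host, fragment_len = 276,
                                identity = 0.975, seed = 8)
  expect_true(d$pack)
  expect_equal(d$n_mismatches, 7)     # 276 * 0.025 rounds to 7
  frag <- substr(d$seq, d$fragment_span[1] + 1, d$fragment_span[2])
  src <- substr(host, d$source_span[1] + 1, d$source_span[2])
  expect_equal(sum(utf8ToInt(frag) != utf8ToInt(src)), 7)

  d1 <- generate_pack_derivative(element_template(), host, 150,
                                 identity = 1, seed = 9)
  frag1 <- substr(d1$seq, d1$fragment_span[1] + 1, d1$fragment_span[2])
  expect_true(grepl(frag1, host, fixed = TRUE))

  d0 <- generate_pack_derivative(element_template(), host, 0, seed = 10)
  expect_false(d0$pack)
  expect_error(generate_pack_derivative(element_template(), host, 100,
                                        identity = 1.2), "identity")
  expect_error(generate_pack_derivative(element_template(), host, 9999),
               "exceeds")
})

test_that("assay fixtures honor class counts and the no-TSD precise form", {
  fx <- generate_assay_fixtures(c(precise = 4, nonprecise = 34), tsd = NULL,
                                seed = 3)
  expect_equal(nrow(fx$junctions), 38)
  empty <- paste0(fx$donor$flank_left, fx$donor$flank_right)
  expect_equal(sum(fx$junctions$seq == empty), 4)

  fx2 <- generate_assay_fixtures(c(precise = 27), tsd = "ATTCAATAG", seed = 4)
  joint <- paste0(fx2$donor$flank_left, "ATTCAATAG", fx2$donor$flank_right)
  expect_true(all(fx2$junctions$seq == joint))
  expect_true(all(vapply(fx2$junctions$seq, function(s)
    lengths(regmatches(s, gregexpr("ATTCAATAG", s, fixed = TRUE))) == 1,
    logical(1))))

  expect_error(generate_assay_fixtures(c(bogus = 3)), "unknown")
})

test_that("reinsertion fixtures carry the requested 8/9-bp TSD mix", {
  g <- cached("plain_genome",
              generate_genome(n_scaffolds = 2, scaffold_len = 50000,
                              n_full_copies = 0, n_derivatives = 0,
                              n_genes = 5, seed = 9))
  sites <- generate_reinsertion_flanks(21, 39, g$genome, seed = 5)
  expect_equal(nrow(sites), 60)
  expect_equal(unname(table(sites$tsd_len)[c("8", "9")]), c(21L, 39L),
               ignore_attr = TRUE)
  # the junction flanks literally share the k-mer duplication
  for (r in seq_len(nrow(sites))) {
    k <- sites$tsd_len[r]
    lf <- sites$left_flank[r]
    expect_identical(substr(lf, nchar(lf) - k + 1, nchar(lf)),
                     substr(sites$right_flank[r], 1, k))
  }
})
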