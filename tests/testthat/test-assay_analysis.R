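test_that("excision frequency reproduces the dilution arithmetic", {
  # 20 colonies from 100 ul of a 1e5 dilution of a 500-ul resuspension
  # -> 1e7 viable cells; 244 revertants -> 2.44e-5 events/cell
  ar <- excision_frequency(244, data.frame(dilution = 1e5, colonies = 20,
                                           volume_ul = 100))
  expect_equal(ar$viable, 1e7)
  expect_equal(ar$frequency, 2.44e-5)

  expect_equal(excision_frequency(0, data.frame(dilution = 1e5, colonies = 5,
                                                volume_ul = 100))$frequency, 0)

  two <- data.frame(dilution = c(1e5, 1e6), colonies = c(20, 2),
                    volume_ul = 100)
  expect_equal(excision_frequency(244, two)$frequency, 2.44e-5)

  expect_error(excision_frequency(10, data.frame(dilution = 1e5, colonies = 0,
                                                 volume_ul = 100)),
               "no viable")
})

test_that("reintegration ratios and proportions match printed derivations", {
  expect_equal(reintegration_ratio(2.71e-6, 2.44e-5), 11L)
  expect_equal(reintegration_ratio(1e-5, 1e-5), 100L)
  expect_equal(reintegration_ratio(proportion(41, 300)$percent, 100), 14L)
  expect_error(reintegration_ratio(1e-6, 0), "> 0")

  expect_equal(proportion(4, 38)$percent, 100 * 4 / 38)
  expect_equal(floor(proportion(4, 38)$percent), 10)
  expect_equal(round(proportion(27, 29)$percent, 1), 93.1)
  p0 <- proportion(0, 10)
  expect_equal(p0$percent, 0)
  expect_equal(p0$se, 0)
  expect_error(proportion(5, 0), "> 0")
  expect_error(proportion(11, 10), "count")
})

test_that("footprint classification recovers every fixture class", {
  combos <- list(
    list(counts = c(precise = 4, nonprecise = 34), tsd = NULL),
    list(counts = c(precise = 25, flank_deletion = 2, tir_remnant = 2),
         tsd = "TTCAATAG"),
    list(counts = c(precise = 27, insertion = 2), tsd = "ATTCAATAG"),
    list(counts = c(flank_deletion = 10, insertion = 5, tir_remnant = 10),
         tsd = "CGGTAACTC"))
  for (seed in c(1, 2, 3)) {
    for (cmb in combos) {
      fx <- generate_assay_fixtures(cmb$counts, tsd = cmb$tsd, seed = seed)
      res <- classify_fixture_set(fx)
      expect_identical(res$called_class, res$class,
                       label = sprintf("seed %d tsd %s", seed,
                                       cmb$tsd %||% "none"))
    }
  }
})

test_that("precise calls track TSD copy retention and tolerate extra flank", {
  fx <- generate_assay_fixtures(c(precise = 1), tsd = "ATTCAATAG", seed = 6)
  call <- classify_footprint(fx$junctions$seq[1], fx$donor)
  expect_equal(call$class, "precise")
  expect_equal(call$tsd_copies_remaining, 1L)

  fx0 <- generate_assay_fixtures(c(precise = 1), tsd = NULL, seed = 6)
  call0 <- classify_footprint(fx0$junctions$seq[1], fx0$donor)
  expect_equal(call0$class, "precise")
  expect_equal(call0$tsd_copies_remaining, 0L)

  # trimming up to 50 bp of correct flank leaves the call invariant
  s <- fx$junctions$seq[1]
  for (trim in c(10, 25, 40)) {
    s2 <- substr(s, trim + 1, nchar(s) - trim)
    expect_equal(classify_footprint(s2, fx$donor)$class, "precise")
  }
})

test_that("per-side deletion accounting and remnant lengths are exact", {
  donor <- list(flank_left = random_dna_fixture(60, 21),
                flank_right = random_dna_fixture(60, 22),
                element = paste0("GCTAGCATCG", random_dna_fixture(200, 23),
                                 revcomp("GCTAGCATCG")),
                tsd = NULL)
  ref_l <- donor$flank_left; ref_r <- donor$flank_right
  # 3 bp lost left, 1 bp right
  jd <- paste0(substr(ref_l, 1, 57), substr(ref_r, 2, 60))
  cd <- classify_footprint(jd, donor)
  expect_equal(cd$class, "flank_deletion")
  expect_equal(c(cd$left_lost, cd$right_lost), c(3L, 1L))

  # 13 terminal bases of the element left at the junction
  jr <- paste0(ref_l, substr(donor$element, 1, 13), ref_r)
  cr <- classify_footprint(jr, donor)
  expect_equal(cr$class, "tir_remnant")
  expect_equal(cr$remnant_len, 13L)

  # longer terminal leftovers fall outside the modeled classes
  jc <- paste0(ref_l, substr(donor$element, 1, 20), ref_r)
  expect_equal(classify_footprint(jc, donor)$class, "complex")

  # un-excised element is an error, not a footprint
  full <- paste0(ref_l, donor$element, ref_r)
  expect_error(classify_footprint(full, donor), "not excised")
})

test_that("display reads map uniquely, ambiguously, or not at all", {
  g <- cached("plain_genome",
              generate_genome(n_scaffolds = 2, scaffold_len = 50000,
                              n_full_copies = 0, n_derivatives = 0,
                              n_genes = 5, seed = 9))
  term <- random_dna_fixture(20, 24)
  flank <- substr(g$genome$scaffolds[[1]], 10001, 10030)
  m <- map_display_read(paste0(term, flank), g$genome, term)
  expect_equal(m$status, "mapped")
  expect_equal(m$scaffold, names(g$genome$scaffolds)[1])
  expect_equal(m$start, 10000L)
  expect_equal(m$strand, "+")

  mrc <- map_display_read(paste0(term, revcomp(flank)), g$genome, term)
  expect_equal(mrc$status, "mapped")
  expect_equal(mrc$strand, "-")

  # a duplicated flank is ambiguous
  dup <- g$genome
  dup$scaffolds[[2]] <- paste0(dup$scaffolds[[2]], flank)
  expect_equal(map_display_read(paste0(term, flank), genome_set(dup$scaffolds),
                                term)$status, "ambiguous")

  # plasmid-derived flank absent from the genome
  expect_equal(map_display_read(paste0(term, random_dna_fixture(30, 25)),
                                g$genome, term)$status, "unmapped")

  expect_error(map_display_read(paste0(term, "ACGTACGTAC"), g$genome, term),
               "< 20 bp")
  expect_error(map_display_read(paste0("ACGTACGTAA", flank), g$genome, term),
               "terminus")
})

test_that("reinsertion TSD census reproduces the planted 8/9 mixture", {
  g <- cached("plain_genome",
              generate_genome(n_scaffolds = 2, scaffold_len = 50000,
                              n_full_copies = 0, n_derivatives = 0,
                              n_genes = 5, seed = 9))
  term <- substr(g$element$seq, 1, 20)
  sites <- generate_reinsertion_flanks(21, 39, g$genome, seed = 5,
                                       terminus = term)
  cen <- tsd_census(sites, g$genome, term)
  expect_equal(unname(cen$census[c("8", "9")]), c(21L, 39L),
               ignore_attr = TRUE)
  expect_true(all(!cen$calls$ambiguous))
  expect_true(all(cen$calls$status == "ok"))

  # flanks disagreeing with the genome are flagged and excluded
  bad <- sites[1, ]
  bad$left_flank <- random_dna_fixture(40, 26)
  lm <- map_display_read(bad$right_read, g$genome, term)
  loc <- list(scaffold = bad$scaffold, left_end = bad$pos + bad$tsd_len,
              right_start = bad$pos)
  ex <- extract_reinsertion_tsd(loc, g$genome, left_read_flank = bad$left_flank)
  expect_equal(ex$status, "flank_mismatch")
})

test_that("a coincidental longer duplication is reported with an ambiguity flag", {
  # construct a locus where an 8-bp event sits in a 10-bp homopolymer so the
  # longest-match rule extends to 9 with the geometric length still 8
  bg <- random_dna_fixture(400, 27)
  chr <- paste0(substr(bg, 1, 200), strrep("G", 10), substr(bg, 201, 400))
  g <- genome_set(c(chr = chr))
  pos <- 201L   # junction inside the homopolymer
  loc <- list(scaffold = "chr", left_end = pos + 8L, right_start = pos)
  ex <- extract_reinsertion_tsd(loc, g)
  expect_equal(ex$geometric_length, 8L)
  expect_gte(ex$length, 9L)
  expect_true(ex$ambiguous)
})
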