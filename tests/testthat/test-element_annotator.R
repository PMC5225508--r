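make_copy_pair <- function(element, flank = 800, seed = 1, divergence = 0) {
  # two copies of one element in unrelated flanks whose element-adjacent
  # bases are forced to differ so the boundary is sharp by construction
  withr::with_seed(seed, {
    fa1 <- random_dna(flank); fa2 <- random_dna(flank)
    fb1 <- random_dna(flank); fb2 <- random_dna(flank)
    force_diff <- function(x, y, at) {
      for (i in at) {
        if (substr(x, i, i) == substr(y, i, i)) {
          substr(y, i, i) <- setdiff(c("A", "C", "G", "T"),
                                     substr(x, i, i))[1]
        }
      }
      y
    }
    fb1 <- force_diff(fa1, fb1, flank - 0:2)      # left flank edge bases
    fb2 <- force_diff(fa2, fb2, 1:3)              # right flank edge bases
    el2 <- if (divergence > 0) {
      ch <- strsplit(element, "")[[1]]
      idx <- sample(length(ch), round(divergence * length(ch)))
      for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      paste(ch, collapse = "")
    } else element
    list(a = paste0(fa1, element, fa2), b = paste0(fb1, el2, fb2),
         span = c(flank, flank + nchar(element)))
  })
}

test_that("boundary detection finds planted edges between two copies", {
  el <- withr::with_seed(2, build_full_element(element_template()))$seq
  cp <- make_copy_pair(el, seed = 3)
  b <- detect_boundaries(cp$a, cp$b)
  expect_equal(b$a, cp$span)
  expect_equal(b$b, cp$span)

  cp2 <- make_copy_pair(el, seed = 4, divergence = 0.01)
  b2 <- detect_boundaries(cp2$a, cp2$b)
  expect_lte(max(abs(b2$a - cp2$span)), 5)

  expect_error(detect_boundaries(cp$a, cp$a), "cannot resolve")
})

test_that("TIR discovery reports planted arm lengths exactly", {
  tm1 <- element_template()
  el1 <- withr::with_seed(5, build_full_element(tm1))$seq
  t1 <- find_tir(el1)
  expect_equal(t1$length, 145)
  expect_equal(t1$identity, 1)
  expect_equal(t1$arm5, c(0, 145))
  expect_equal(t1$arm3, c(nchar(el1) - 145, nchar(el1)))

  # a longer-TIR template (151 bp, 9 x 15-bp subterminal repeats)
  tm2 <- element_template(total_len = 3496, tir_len = 151, tsd_len = 8,
                          subrepeat_unit_len = 15, subrepeat_copies = 9,
                          spacer_len_range = c(0, 1))
  el2 <- withr::with_seed(6, build_full_element(tm2))$seq
  expect_equal(find_tir(el2)$length, 151)

  # strand symmetry: a TIR looks the same from either strand
  t1rc <- find_tir(revcomp(el1))
  expect_equal(t1rc$length, t1$length)
  expect_equal(t1rc$identity, t1$identity)
})

test_that("random sequence does not fake a TIR", {
  n_none <- 0L
  for (s in 1:20) {
    x <- withr::with_seed(300 + s, random_dna(2000))
    if (is.null(find_tir(x))) n_none <- n_none + 1L
  }
  expect_gte(n_none, 19)
})

test_that("TSD calling takes the longest exact duplication", {
  left <- paste0(random_dna_fixture(20, 61), "ATTCAATAG")
  right <- paste0("ATTCAATAG", random_dna_fixture(20, 62))
  tsd <- call_tsd(left, right)
  expect_equal(tsd$length, 9)
  expect_equal(tsd$left, "ATTCAATAG")
  expect_true(tsd$perfect)

  l8 <- paste0(random_dna_fixture(20, 63), "CGATTCAA")
  r8 <- paste0("CGATTCAA", random_dna_fixture(20, 64))
  expect_equal(call_tsd(l8, r8)$length, 8)

  expect_null(call_tsd(random_dna_fixture(15, 65), random_dna_fixture(15, 66)))

  # strand symmetry: reverse-complementing the locus preserves the call
  withr::with_seed(67, {
    for (i in 1:20) {
      k <- sample(8:10, 1)
      t <- random_dna(k)
      lf <- paste0(random_dna(15), t)
      rf <- paste0(t, random_dna(15))
      a <- call_tsd(lf, rf)
      b <- call_tsd(revcomp(rf), revcomp(lf))
      expect_equal(a$length, b$length)
      expect_equal(b$left, revcomp(a$left))
    }
  })

  # an imperfect candidate is flagged, never reported as perfect
  l1 <- paste0(random_dna_fixture(15, 68), "ATTCAATAG")
  r1 <- paste0("ATTCAATAC", random_dna_fixture(15, 69))
  imp <- call_tsd(l1, r1)
  if (!is.null(imp)) expect_false(imp$perfect)
})

test_that("subterminal repeat arrays are recovered with unit, copies, spacers", {
  tm <- element_template()
  el <- withr::with_seed(8, build_full_element(tm))
  arm <- substr(el$seq, 1, 145)
  sub <- find_subterminal_repeats(arm)
  expect_equal(sub$unit_len, 12)
  expect_equal(sub$copies, 9)
  expect_true(all(sub$spacers %in% 3:4))
  expect_equal(sub$start, 10)

  tm15 <- element_template(total_len = 3496, tir_len = 151, tsd_len = 8,
                           subrepeat_unit_len = 15, subrepeat_copies = 9,
                           spacer_len_range = c(0, 1))
  el15 <- withr::with_seed(9, build_full_element(tm15))
  sub15 <- find_subterminal_repeats(substr(el15$seq, 1, 151))
  expect_equal(sub15$unit_len, 15)
  expect_equal(sub15$copies, 9)

  n_none <- 0L
  for (s in 1:20) {
    if (is.null(find_subterminal_repeats(withr::with_seed(400 + s,
                                                          random_dna(145)))))
      n_none <- n_none + 1L
  }
  expect_gte(n_none, 19)
})

test_that("terminal palindrome scoring lists unpaired positions pairwise", {
  expect_equal(score_terminal_palindrome("GGGGAACCCC"), c(5L, 6L))
  expect_equal(score_terminal_palindrome("GAATTAATTC"), integer(0))
  expect_equal(score_terminal_palindrome(strrep("A", 10)), 1:10)
  expect_equal(score_terminal_palindrome("GGGGNACCCC"), c(5L, 6L))
  expect_error(score_terminal_palindrome("ACGT"), "exactly 10")
})

test_that("ORF/DDE location maps the catalytic triad to element coordinates", {
  tm <- element_template()
  el <- withr::with_seed(10, build_full_element(tm))
  q <- tp()
  cod <- locate_orf_dde(el$seq, q$dde_domain, dde_offsets = q$dde_offsets)
  expect_false(is.null(cod))
  expect_false(cod$interrupted)
  expect_equal(cod$strand, "+")
  # the domain starts at CDS residue 101; codon 50 is followed by a 60-bp
  # intron, so element offset = cds_start + 3*(residue-1) + 60
  expected <- el$cds_span[1] + 3 * (c(110, 160, 220) - 1) + 60
  expect_equal(cod$dde_element_offsets, expected)

  # a stop codon inside the domain flags the coding call as interrupted
  ch <- strsplit(el$seq, "")[[1]]
  stop_at <- el$cds_span[1] + 3 * (130 - 1) + 60   # codon between D110/D160
  ch[(stop_at + 1):(stop_at + 3)] <- c("T", "A", "A")
  interrupted <- paste(ch, collapse = "")
  cod2 <- locate_orf_dde(interrupted, q$dde_domain)
  expect_true(cod2$interrupted)

  # nonautonomous derivatives carry no coding signal
  d <- withr::with_seed(11, build_derivative(el$tir, internal_len = 600))
  expect_null(locate_orf_dde(d$seq, q$dde_domain))
})

test_that("TSD evidence refines an approximate span to the exact one", {
  g <- demo_genome()
  full <- g$truth[g$truth$kind == "full", ]
  for (r in seq_len(min(3, nrow(full)))) {
    rough <- c(full$start[r] - 7L, full$end[r] + 4L)
    ref <- refine_element_span(g$genome, full$scaffold[r], rough)
    expect_equal(ref$span, c(full$start[r], full$end[r]))
    expect_equal(ref$tsd$left, full$tsd_seq[r])
  }
})
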