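# Yeast transposition-assay analytics: excision/reintegration rates,
# excision-footprint classification against the reconstructed empty donor
# site, transposon-display read mapping, and reinsertion TSD extraction.

#' Excision frequency from colony counts and dilution platings
#'
#' Viable cells are estimated per dilution as
#' colonies x dilution / volume-fraction plated, averaged across
#' dilutions; frequency is revertant colonies per viable cell.
#'
#' @param revertants revertant colony count.
#' @param viable_dilutions data.frame with columns `dilution`, `colonies`,
#'   `volume_ul` (plated volume).
#' @param culture_volume_ul total resuspension volume.
#' @return an `AssayRates`: list with `revertants`, `viable` (mean
#'   estimate), `per_dilution`, `frequency`.
#' @export
excision_frequency <- function(revertants, viable_dilutions,
                               culture_volume_ul = 500) {
  stopifnot(revertants >= 0, nrow(viable_dilutions) >= 1,
            all(viable_dilutions$colonies >= 0))
  est <- viable_dilutions$colonies * viable_dilutions$dilution *
    (culture_volume_ul / viable_dilutions$volume_ul)
  if (all(est == 0)) stop("no viable colonies at any dilution")
  viable <- mean(est[est > 0])
  structure(list(revertants = revertants, viable = viable,
                 per_dilution = est, frequency = revertants / viable),
            class = "AssayRates")
}

#' @export
print.AssayRates <- function(x, ...) {
  cat(sprintf("AssayRates: %d revertants / %.3g viable cells = %.3g events/cell\n",
              x$revertants, x$viable, x$frequency))
  invisible(x)
}

#' Reintegration ratio from two frequencies
#'
#' 100 x selected / total, rounded to the nearest integer percent.
#'
#' @param freq_selected frequency of marker-retaining events.
#' @param freq_total total event frequency (> 0).
#' @return integer percent.
#' @export
reintegration_ratio <- function(freq_selected, freq_total) {
  if (freq_total <= 0) stop("total frequency must be > 0")
  as.integer(round(100 * freq_selected / freq_total))
}

#' Proportion with binomial standard error
#'
#' @param count,total nonnegative integers with count <= total, total > 0.
#' @return list with `percent`, `se` (both on the percent scale), `count`,
#'   `total`.
#' @export
proportion <- function(count, total) {
  if (total <= 0) stop("total must be > 0")
  if (count < 0 || count > total) stop("count must lie in [0, total]")
  p <- count / total
  list(percent = 100 * p, se = 100 * sqrt(p * (1 - p) / total),
       count = count, total = total)
}

# all decompositions of rev as ref with one contiguous insertion; returns
# the candidate inserted strings
insertion_candidates <- function(rev, ref) {
  r <- nchar(rev) - nchar(ref)
  if (r <= 0) return(character())
  nr <- nchar(rev); nf <- nchar(ref)
  out <- character()
  for (q in 0:nf) {
    if (substr(rev, 1, q) == substr(ref, 1, q) &&
        substr(rev, q + r + 1, nr) == substr(ref, q + 1, nf)) {
      out <- c(out, substr(rev, q + 1, q + r))
    }
  }
  unique(out)
}

#' Classify one revertant junction against the reconstructed donor site
#'
#' The empty-site reference is flank + one TSD copy + flank when the donor
#' carried a TSD, plain flank + flank otherwise. An exact match is
#' `precise`; missing flank bases give `flank_deletion` with per-side
#' accounting; extra bases that match a terminal segment of the element
#' (<= 13 bp) give `tir_remnant`; other extra bases give `insertion`;
#' mixtures (and terminal remnants longer than 13 bp) are `complex`.
#'
#' @param revertant_seq sequenced junction covering >= 20 bp on each side.
#' @param donor list with `flank_left`, `flank_right`, `element`, and
#'   `tsd` (string or NULL), as produced by [generate_assay_fixtures()].
#' @return a `FootprintCall`: list with `class`, `left_lost`, `right_lost`,
#'   `remnant_len`, `insert_seq`, `tsd_copies_remaining`.
#' @export
classify_footprint <- function(revertant_seq, donor) {
  el <- donor$element
  Lel <- nchar(el)
  probe5 <- substr(el, 1, min(40, Lel))
  probe3 <- substr(el, max(1, Lel - 39), Lel)
  if (grepl(probe5, revertant_seq, fixed = TRUE) &&
      grepl(probe3, revertant_seq, fixed = TRUE)) {
    stop("element not excised: revertant still contains both termini")
  }
  tsd <- if (is.null(donor$tsd)) "" else donor$tsd
  ref <- paste0(donor$flank_left, tsd, donor$flank_right)

  # anchor the revertant within the reference (reads may cover less flank)
  p <- 0L
  if (substr(revertant_seq, 1, 20) != substr(ref, 1, 20)) {
    hit <- regexpr(substr(revertant_seq, 1, 20), ref, fixed = TRUE)
    if (hit > 0) p <- as.integer(hit) - 1L
  }
  qend <- nchar(ref)
  tail20 <- substr(revertant_seq, nchar(revertant_seq) - 19,
                   nchar(revertant_seq))
  if (tail20 != substr(ref, nchar(ref) - 19, nchar(ref))) {
    hits <- gregexpr(tail20, ref, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits)) qend <- max(hits) + 19L
  }
  refw <- substr(ref, p + 1L, qend)
  junction <- nchar(donor$flank_left) + nchar(tsd) - p  # left-part length

  rev <- revertant_seq
  nr <- nchar(rev); nf <- nchar(refw)
  i <- lcp_len(rev, refw)
  j <- min(lcs_len(rev, refw), min(nr, nf) - i)
  inserted <- substr(rev, i + 1L, nr - j)
  deleted <- substr(refw, i + 1L, nf - j)

  tsd_remaining <- function(del_span) {
    if (!nzchar(tsd)) return(0L)
    t0 <- nchar(donor$flank_left) - p
    t1 <- t0 + nchar(tsd)
    if (is.null(del_span)) return(1L)
    if (del_span[1] <= t0 && del_span[2] >= t1) 0L else 1L
  }

  if (!nzchar(inserted) && !nzchar(deleted)) {
    return(structure(list(class = "precise", left_lost = 0L, right_lost = 0L,
                          remnant_len = 0L, insert_seq = "",
                          tsd_copies_remaining = if (nzchar(tsd)) 1L else 0L),
                     class = "FootprintCall"))
  }
  if (!nzchar(inserted)) {
    d <- nchar(deleted)
    left_lost <- max(0L, min(nf - j, junction) - i)
    right_lost <- d - left_lost
    return(structure(list(class = "flank_deletion", left_lost = left_lost,
                          right_lost = right_lost, remnant_len = 0L,
                          insert_seq = "",
                          tsd_copies_remaining = tsd_remaining(c(i, nf - j))),
                     class = "FootprintCall"))
  }
  if (!nzchar(deleted)) {
    cands <- insertion_candidates(rev, refw)
    r <- nchar(inserted)
    is_remnant <- any(vapply(cands, function(s) {
      s == substr(el, 1, r) || s == substr(el, Lel - r + 1, Lel)
    }, logical(1)))
    copies <- if (nzchar(tsd) && tsd %in% cands) 2L
              else if (nzchar(tsd)) 1L else 0L
    if (is_remnant && r <= 13L) {
      return(structure(list(class = "tir_remnant", left_lost = 0L,
                            right_lost = 0L, remnant_len = r,
                            insert_seq = inserted,
                            tsd_copies_remaining = copies),
                       class = "FootprintCall"))
    }
    if (is_remnant && r > 13L) {
      return(structure(list(class = "complex", left_lost = 0L,
                            right_lost = 0L, remnant_len = r,
                            insert_seq = inserted,
                            tsd_copies_remaining = copies),
                       class = "FootprintCall"))
    }
    return(structure(list(class = "insertion", left_lost = 0L,
                          right_lost = 0L, remnant_len = 0L,
                          insert_seq = inserted,
                          tsd_copies_remaining = copies),
                     class = "FootprintCall"))
  }
  structure(list(class = "complex", left_lost = NA_integer_,
                 right_lost = NA_integer_, remnant_len = 0L,
                 insert_seq = inserted,
                 tsd_copies_remaining = tsd_remaining(c(i, nf - j))),
            class = "FootprintCall")
}

#' Classify all junctions of an assay fixture set
#'
#' @param fixtures a [generate_assay_fixtures()] result.
#' @return data.frame with the fixture's truth columns plus `called_class`.
#' @export
classify_fixture_set <- function(fixtures) {
  calls <- vapply(fixtures$junctions$seq, function(s) {
    classify_footprint(s, fixtures$donor)$class
  }, character(1), USE.NAMES = FALSE)
  cbind(fixtures$junctions, called_class = calls)
}

#' Map a transposon-display read to the genome
#'
#' Trims the element-terminus prefix from the read and exact-searches the
#' remaining flank (>= 20 bp) against both strands.
#'
#' @param read display read: element terminus prefix followed by flanking
#'   sequence.
#' @param genome GenomeSet.
#' @param terminus element terminal sequence the read begins with.
#' @return list with `status` (`mapped`, `ambiguous`, `unmapped`), and for
#'   mapped reads `scaffold`, `start`, `end` (forward-strand span of the
#'   flank), `strand`.
#' @export
map_display_read <- function(read, genome, terminus) {
  k <- lcp_len(read, terminus)
  if (k < 10) stop("read does not begin with the element terminus")
  flank <- substr(read, k + 1L, nchar(read))
  if (nchar(flank) < 20) stop("flank after terminus trimming is < 20 bp")
  hits <- list()
  rc <- revcomp(flank)
  for (sc in names(genome$scaffolds)) {
    s <- genome$scaffolds[[sc]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") flank else rc
      pos <- gregexpr(pat, s, fixed = TRUE)[[1]]
      pos <- pos[pos > 0]
      for (pp in pos) {
        hits[[length(hits) + 1L]] <- list(scaffold = sc, start = pp - 1L,
                                          end = pp - 1L + nchar(flank),
                                          strand = strand)
      }
    }
  }
  if (!length(hits)) return(list(status = "unmapped"))
  if (length(hits) > 1) return(list(status = "ambiguous", n_hits = length(hits)))
  c(list(status = "mapped"), hits[[1]])
}

#' Resolve a reinsertion locus from the two junction mappings
#'
#' The element-adjacent end of each mapped flank defines the junction: for
#' a minus-strand flank match that is the match end, for a plus-strand
#' match the match start.
#'
#' @param left_map,right_map `mapped` results of [map_display_read()] for
#'   the left and right junction reads.
#' @return list with `scaffold`, `left_end`, `right_start`.
#' @export
reinsertion_locus <- function(left_map, right_map) {
  if (left_map$status != "mapped" || right_map$status != "mapped")
    stop("both junction reads must map uniquely")
  if (left_map$scaffold != right_map$scaffold)
    stop("junction reads map to different scaffolds")
  a <- if (left_map$strand == "-") left_map$end else left_map$start
  b <- if (right_map$strand == "+") right_map$start else right_map$end
  list(scaffold = left_map$scaffold, left_end = a, right_start = b)
}

#' Extract the TSD at a mapped reinsertion site
#'
#' Applies the longest-match TSD call to the genomic flanks at the mapped
#' junction. The geometric duplication length is `left_end - right_start`;
#' when the longest-match rule extends past it (a coincidental flanking
#' match) the longer length is reported with `ambiguous = TRUE`. Read
#' flanks that disagree with the genome are flagged and excluded from any
#' census.
#'
#' @param locus a [reinsertion_locus()] result.
#' @param genome GenomeSet.
#' @param left_read_flank,right_read_flank optional flank sequences in
#'   forward-genome orientation for verification.
#' @param len_range TSD length range.
#' @return list with `status` (`ok` or `flank_mismatch`), `length`, `seq`,
#'   `ambiguous`, `geometric_length`.
#' @export
extract_reinsertion_tsd <- function(locus, genome, left_read_flank = NULL,
                                    right_read_flank = NULL,
                                    len_range = c(8L, 10L)) {
  seq <- genome$scaffolds[[locus$scaffold]]
  a <- locus$left_end
  b <- locus$right_start
  if (!is.null(left_read_flank)) {
    n <- nchar(left_read_flank)
    if (subseq0(seq, a - n, a) != left_read_flank)
      return(list(status = "flank_mismatch"))
  }
  if (!is.null(right_read_flank)) {
    n <- nchar(right_read_flank)
    if (subseq0(seq, b, b + n) != right_read_flank)
      return(list(status = "flank_mismatch"))
  }
  w <- len_range[2] + 2L
  lf <- subseq0(seq, max(0L, a - w), a)
  rf <- subseq0(seq, b, min(nchar(seq), b + w))
  tsd <- call_tsd(lf, rf, len_range, allow_imperfect = FALSE)
  if (is.null(tsd)) return(list(status = "ok", length = NA_integer_,
                                seq = NA_character_, ambiguous = FALSE,
                                geometric_length = a - b))
  list(status = "ok", length = tsd$length, seq = tsd$left,
       ambiguous = tsd$length != (a - b), geometric_length = a - b)
}

#' TSD-length census over a set of reinsertion-site fixtures
#'
#' Maps both display reads of every site, resolves the locus, extracts the
#' TSD, and tabulates called lengths.
#'
#' @param sites a [generate_reinsertion_flanks()] result.
#' @param genome GenomeSet the sites live on.
#' @param terminus element terminal sequence used in the reads.
#' @return list with `calls` (per-site data.frame) and `census` (table of
#'   TSD lengths).
#' @export
tsd_census <- function(sites, genome, terminus) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    lm <- map_display_read(sites$left_read[i], genome, terminus)
    rm_ <- map_display_read(sites$right_read[i], genome, terminus)
    if (lm$status != "mapped" || rm_$status != "mapped") {
      return(data.frame(id = sites$id[i], length = NA_integer_,
                        ambiguous = NA, status = "unmapped"))
    }
    loc <- reinsertion_locus(lm, rm_)
    ex <- extract_reinsertion_tsd(loc, genome,
                                  left_read_flank = sites$left_flank[i],
                                  right_read_flank = sites$right_flank[i])
    data.frame(id = sites$id[i],
               length = if (ex$status == "ok") ex$length else NA_integer_,
               ambiguous = if (ex$status == "ok") ex$ambiguous else NA,
               status = ex$status)
  })
  calls <- do.call(rbind, rows)
  list(calls = calls, census = table(calls$length[calls$status == "ok"]))
}
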