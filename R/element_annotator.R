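# Structural annotation of candidate elements: boundary detection between
# two family copies, TIR discovery, TSD calling, subterminal tandem repeats,
# the terminal palindromic motif, and coding capacity.

#' Detect element boundaries by comparing two family copies
#'
#' Two closely related copies at different loci share the element but not
#' the flanks. Both windows are anchored on a shared exact k-mer, the
#' per-position match profile is computed on the ungapped offset, and each
#' boundary is placed where windowed similarity (default 20 bp at >= 80%
#' identity) collapses, refined to the outermost contiguously matching
#' position. Symmetric in argument order up to the shared anchor.
#'
#' @param copy_a,copy_b DNA strings: element plus flanking sequence.
#' @param window similarity window in bp.
#' @param min_identity windowed identity threshold.
#' @param anchor_k length of the exact anchor k-mer.
#' @return list with `a = c(start, end)` and `b = c(start, end)`: 0-based
#'   half-open boundary offsets within each input.
#' @export
detect_boundaries <- function(copy_a, copy_b, window = 20L,
                              min_identity = 0.8, anchor_k = 32L) {
  la <- nchar(copy_a); lb <- nchar(copy_b)
  if (la < anchor_k || lb < anchor_k) stop("copies shorter than anchor k-mer")
  # shared anchor: exact k-mer from the middle of copy_a located in copy_b
  anchor <- NA_integer_
  mid <- as.integer(la / 2)
  for (off in c(0L, seq_len(200L) * c(7L, -7L))) {
    s <- mid + off
    if (s < 0 || s + anchor_k > la) next
    kmer <- subseq0(copy_a, s, s + anchor_k)
    hit <- gregexpr(kmer, copy_b, fixed = TRUE)[[1]]
    if (hit[1] != -1 && length(hit) == 1) {
      anchor <- s
      anchor_b <- hit[1] - 1L
      break
    }
  }
  if (is.na(anchor)) stop("cannot resolve boundary: no shared anchor between copies")
  offset <- anchor_b - anchor

  ca <- seq_chars(copy_a); cb <- seq_chars(copy_b)
  lo <- max(0L, -offset)                # copy_a coords covered by both
  hi <- min(la, lb - offset)
  idx <- seq.int(lo + 1L, hi)
  m <- ca[idx] == cb[idx + offset] & ca[idx] != "N"

  collapse_side <- function(dir) {
    # dir = -1: scan left from the anchor; +1: scan right
    n <- length(m)
    a_pos <- anchor - lo + 1L          # anchor in match-vector coords
    cs <- cumsum(as.integer(m))
    win_id <- function(p) (cs[p + window - 1L] - if (p > 1) cs[p - 1L] else 0L) / window
    # X-drop refinement from a known-good interior position: +1 per match,
    # -3 per mismatch; the boundary is the argmax of the cumulative score.
    xdrop_walk <- function(start, step) {
      score <- 0; best <- 0; best_p <- start
      p <- start + step
      while (p >= 1L && p <= n) {
        score <- score + if (m[p]) 1 else -3
        if (score > best) { best <- score; best_p <- p }
        if (score < best - 9) break
        p <- p + step
      }
      best_p
    }
    if (dir < 0) {
      p <- a_pos
      first_fail <- 0L
      while (p >= 1L) {
        if (win_id(p) < min_identity) { first_fail <- p; break }
        p <- p - 1L
      }
      if (first_fail == 0L) return(NA_integer_)   # never collapsed
      xdrop_walk(min(first_fail + 2L * window, a_pos), -1L)
    } else {
      p <- a_pos
      first_fail <- 0L
      while (p + window - 1L <= n) {
        if (win_id(p) < min_identity) { first_fail <- p; break }
        p <- p + 1L
      }
      if (first_fail == 0L) return(NA_integer_)
      xdrop_walk(max(first_fail - window, a_pos), +1L)
    }
  }

  left <- collapse_side(-1L)
  right <- collapse_side(+1L)
  if (is.na(left) || is.na(right))
    stop("cannot resolve boundary: flanking similarity does not collapse ",
         "(copies may derive from the same locus)")
  a_start <- lo + left - 1L            # back to copy_a 0-based coords
  a_end <- lo + right
  list(a = c(a_start, a_end), b = c(a_start + offset, a_end + offset))
}

#' Find the terminal inverted repeat of an element
#'
#' Locally aligns the 5' prefix against the reverse complement of the 3'
#' suffix (search window `min(len/2, 1000)` bp) and reports the best
#' alignment anchored within 5 bp of both termini that meets the length and
#' identity thresholds.
#'
#' @param element element DNA string.
#' @param min_len minimum TIR length in bp.
#' @param min_identity minimum arm identity.
#' @return list with `length` (bp on the 5' arm), `identity`,
#'   `arm5`/`arm3` spans (0-based half-open element coordinates), or `NULL`
#'   when no TIR is found.
#' @export
find_tir <- function(element, min_len = 50L, min_identity = 0.8) {
  L <- nchar(element)
  if (L < 2 * min_len) return(NULL)
  w <- min(as.integer(L / 2), 1000L)
  prefix <- subseq0(element, 0L, w)
  suffix_rc <- revcomp(subseq0(element, L - w, L))
  al <- local_align_dna(prefix, suffix_rc)
  if (al$score <= 0) return(NULL)
  if (al$query_span[1] > 5L || al$subject_span[1] > 5L) return(NULL)
  cols <- seq_chars(al$query_aln)
  colsub <- seq_chars(al$subject_aln)
  matches <- sum(cols == colsub & cols != "-" & cols != "N")
  ident <- matches / length(cols)
  len5 <- al$query_span[2] - al$query_span[1]
  if (len5 < min_len || ident < min_identity) return(NULL)
  list(length = len5,
       identity = ident,
       arm5 = c(al$query_span[1], al$query_span[2]),
       arm3 = c(L - al$subject_span[2], L - al$subject_span[1]))
}

#' Call a target-site duplication from the immediate flanks
#'
#' Reports the LONGEST k in `len_range` for which the k-suffix of the left
#' flank equals the k-prefix of the right flank exactly (no N). When no
#' exact duplication exists, the best single-mismatch candidate is reported
#' with `perfect = FALSE`; such calls are never counted as TSDs by the
#' census functions. When more than one exact length matches, the longest
#' wins and `ambiguous` is set.
#'
#' @param left_flank,right_flank DNA immediately abutting the element span.
#' @param len_range integer c(min, max) duplication lengths to consider.
#' @param allow_imperfect also report single-mismatch candidates (flagged).
#' @return list with `length`, `left`, `right`, `perfect`, `ambiguous`, or
#'   `NULL` when nothing qualifies.
#' @export
call_tsd <- function(left_flank, right_flank, len_range = c(8L, 10L),
                     allow_imperfect = TRUE) {
  ks <- seq.int(len_range[2], len_range[1])
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  exact <- integer()
  for (k in ks) {
    if (nl < k || nr < k) next
    ls <- substr(left_flank, nl - k + 1L, nl)
    rs <- substr(right_flank, 1L, k)
    if (ls == rs && !grepl("N", ls, fixed = TRUE)) exact <- c(exact, k)
  }
  if (length(exact)) {
    k <- max(exact)
    s <- substr(left_flank, nl - k + 1L, nl)
    return(list(length = k, left = s, right = s, perfect = TRUE,
                ambiguous = length(exact) > 1))
  }
  if (allow_imperfect) {
    for (k in ks) {
      if (nl < k || nr < k) next
      ls <- substr(left_flank, nl - k + 1L, nl)
      rs <- substr(right_flank, 1L, k)
      if (grepl("N", ls, fixed = TRUE) || grepl("N", rs, fixed = TRUE)) next
      if (sum(utf8ToInt(ls) != utf8ToInt(rs)) == 1L) {
        return(list(length = k, left = ls, right = rs, perfect = FALSE,
                    ambiguous = FALSE))
      }
    }
  }
  NULL
}

#' Find subterminal tandem repeats within a TIR arm
#'
#' Scans candidate unit lengths (default 9-15 bp) and phases; for each seed
#' unit the occurrences are chained greedily, allowing 0-6 bp spacers
#' between copies and at most one mismatch per copy. The chain maximizing
#' copies x unit length is reported.
#'
#' @param tir_arm DNA of one TIR arm (5' orientation).
#' @param unit_range integer c(min, max) repeat unit lengths.
#' @param min_copies minimum copies for a reportable array.
#' @param max_spacer maximum spacer between adjacent copies, bp.
#' @param max_mismatch maximum mismatches per copy vs the seed unit.
#' @return list with `unit_len`, `unit` (majority consensus), `copies`,
#'   `spacers` (per junction), `start` (0-based offset of the first copy),
#'   or `NULL`.
#' @export
find_subterminal_repeats <- function(tir_arm, unit_range = c(9L, 15L),
                                     min_copies = 3L, max_spacer = 6L,
                                     max_mismatch = 1L) {
  L <- nchar(tir_arm)
  if (L < unit_range[1] * min_copies) return(NULL)
  arm_int <- utf8ToInt(tir_arm)
  best <- NULL
  for (u in seq.int(unit_range[1], unit_range[2])) {
    if (L < u * min_copies) next
    for (s in 0:(L - u * min_copies)) {
      unit <- arm_int[(s + 1L):(s + u)]
      pos <- s
      starts <- s
      spacers <- integer()
      mism <- 0L
      repeat {
        nxt <- NA_integer_
        for (sp in 0:max_spacer) {
          q <- pos + u + sp
          if (q + u > L) break
          cand <- arm_int[(q + 1L):(q + u)]
          mm <- sum(cand != unit)
          if (mm <= max_mismatch) { nxt <- q; sp_used <- sp; mm_used <- mm; break }
        }
        if (is.na(nxt)) break
        starts <- c(starts, nxt)
        spacers <- c(spacers, sp_used)
        mism <- mism + mm_used
        pos <- nxt
      }
      n_cop <- length(starts)
      if (n_cop >= min_copies) {
        # mismatched positions count against the chain so that a clean
        # periodicity beats a longer unit that merely absorbs spacer bases
        val <- n_cop * u - 2L * mism
        if (is.null(best) || val > best$val) {
          best <- list(val = val, u = u, starts = starts, spacers = spacers)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  copies_mat <- vapply(best$starts, function(p) {
    arm_int[(p + 1L):(p + best$u)]
  }, integer(best$u))
  consensus <- intToUtf8(apply(copies_mat, 1, function(r) {
    tb <- table(r)
    as.integer(names(tb)[which.max(tb)])
  }))
  list(unit_len = best$u, unit = consensus, copies = length(best$starts),
       spacers = best$spacers, start = best$starts[1])
}

#' Score the terminal 10-bp palindromic motif
#'
#' Position i (1..5) pairs with position 11-i iff the bases are Watson-Crick
#' complements; the set of unpaired positions is returned with both members
#' of each broken pair listed. Positions holding N are reported unpaired.
#'
#' @param terminal exactly 10 bases.
#' @return sorted integer vector of unpaired positions (possibly empty).
#' @export
score_terminal_palindrome <- function(terminal) {
  if (nchar(terminal) != 10) stop("terminal motif must be exactly 10 bp")
  b <- seq_chars(terminal)
  unpaired <- integer()
  for (i in 1:5) {
    j <- 11L - i
    ok <- b[i] != "N" && b[j] != "N" && complement_base(b[i]) == b[j]
    if (!ok) unpaired <- c(unpaired, i, j)
  }
  sort(unpaired)
}

#' Locate the transposase ORF around the DDE domain
#'
#' Aligns the DDE query against all six frames of the element; the
#' best-scoring frame localizes the domain, and the longest stop-free open
#' reading frame overlapping it is reported. Multi-exon structure is not
#' inferred (single-ORF approximation); a stop codon inside the aligned
#' domain sets the `interrupted` flag.
#'
#' @param element element DNA (>= 300 bp).
#' @param dde_query DDE-domain peptide.
#' @param dde_offsets optional integer vector of the catalytic D, D, E
#'   positions within `dde_query` (1-based); mapped to element coordinates.
#' @param evalue_cutoff minimum significance for a coding call.
#' @return list with `orf_span` (forward-strand element coordinates),
#'   `domain_span`, `strand`, `frame`, `score`, `evalue`, `interrupted`,
#'   `dde_element_offsets`, `approximation = "single-ORF"`; or `NULL` for
#'   noncoding elements.
#' @export
locate_orf_dde <- function(element, dde_query, dde_offsets = NULL,
                           evalue_cutoff = 1e-5) {
  L <- nchar(element)
  if (L < 300) stop("element shorter than 300 bp")
  frames <- six_frame_translate(element)
  submat <- protein_submat()
  best <- NULL
  for (k in seq_len(nrow(frames))) {
    pep <- frames$peptide[k]
    if (!nzchar(pep)) next
    al <- local_align_protein(dde_query, pep, submat)
    if (is.null(best) || al$score > best$al$score) {
      best <- list(al = al, strand = frames$strand[k], frame = frames$frame[k],
                   pep = pep)
    }
  }
  if (is.null(best)) return(NULL)
  n_space <- 2 * floor(L / 3)
  ev <- evalue_surrogate(best$al$score, nchar(dde_query), n_space)
  if (ev > evalue_cutoff) return(NULL)

  al <- best$al
  dom_pep <- al$subject_span                # frame-peptide coords
  interrupted <- grepl("*", al$subject_aln, fixed = TRUE)

  # stop-free stretch of the frame peptide containing (most of) the domain
  pep_chars <- seq_chars(best$pep)
  stops <- c(0L, which(pep_chars == "*"), length(pep_chars) + 1L)
  seg_lo <- max(stops[stops <= dom_pep[1]])          # stop before domain start
  seg_hi <- min(stops[stops > dom_pep[1]])           # first stop at/after domain
  orf_pep <- c(seg_lo, seg_hi - 1L)                  # 0-based half-open

  domain_span <- frame_to_genomic(dom_pep[1], dom_pep[2], best$strand,
                                  best$frame, L)
  orf_span <- frame_to_genomic(orf_pep[1], orf_pep[2], best$strand,
                               best$frame, L)

  dde_elem <- NULL
  if (!is.null(dde_offsets)) {
    qa <- seq_chars(al$query_aln); sa <- seq_chars(al$subject_aln)
    qpos <- al$query_span[1]; spos <- al$subject_span[1]
    dde_elem <- rep(NA_integer_, length(dde_offsets))
    for (col in seq_along(qa)) {
      if (qa[col] != "-") qpos <- qpos + 1L
      if (sa[col] != "-") spos <- spos + 1L
      hitq <- which(dde_offsets == qpos & qa[col] != "-" & sa[col] != "-")
      if (length(hitq)) {
        g <- frame_to_genomic(spos - 1L, spos, best$strand, best$frame, L)
        dde_elem[hitq] <- g[1]
      }
    }
  }

  list(orf_span = orf_span, domain_span = domain_span, strand = best$strand,
       frame = best$frame, score = al$score, evalue = ev,
       interrupted = interrupted, dde_element_offsets = dde_elem,
       approximation = "single-ORF")
}

#' Refine an approximate element span using TSD and terminal evidence
#'
#' Enumerates small shifts of both boundaries and selects the span whose
#' flanks carry a perfect target-site duplication, breaking ties by the
#' longest TSD and then by terminal inverted-repeat agreement. Returns the
#' input span unchanged when no shift produces a perfect TSD.
#'
#' @param genome GenomeSet.
#' @param scaffold scaffold id.
#' @param span approximate 0-based half-open span.
#' @param slop maximum boundary shift in bp.
#' @param len_range TSD length range.
#' @return list with `span`, `tsd` (a [call_tsd()] result or NULL).
#' @export
refine_element_span <- function(genome, scaffold, span, slop = 12L,
                                len_range = c(8L, 10L)) {
  seq <- genome$scaffolds[[scaffold]]
  L <- nchar(seq)
  best <- NULL
  for (ds in -slop:slop) {
    s <- span[1] + ds
    if (s < len_range[2] || s >= span[2]) next
    lf <- subseq0(seq, max(0L, s - 12L), s)
    for (de in -slop:slop) {
      e <- span[2] + de
      if (e > L - len_range[1] || e <= s) next
      rf <- subseq0(seq, e, min(L, e + 12L))
      tsd <- call_tsd(lf, rf, len_range, allow_imperfect = FALSE)
      if (is.null(tsd)) next
      term <- cpp_match_count(subseq0(seq, s, s + 10L),
                              revcomp(subseq0(seq, e - 10L, e)))
      key <- c(tsd$length, term)
      if (is.null(best) || key[1] > best$key[1] ||
          (key[1] == best$key[1] && key[2] > best$key[2])) {
        best <- list(span = c(s, e), tsd = tsd, key = key)
      }
    }
  }
  if (is.null(best)) return(list(span = span, tsd = NULL))
  list(span = best$span, tsd = best$tsd)
}

#' Fully annotate an element at a known span
#'
#' Runs TIR discovery, TSD calling, subterminal-repeat detection, terminal
#' palindrome scoring, and coding-capacity assessment on a genomic span.
#'
#' @param genome GenomeSet.
#' @param scaffold scaffold id.
#' @param span 0-based half-open element span.
#' @param dde_query optional DDE peptide for the coding call.
#' @param dde_offsets optional catalytic-triad offsets within `dde_query`.
#' @param config parameter list, see [default_config()].
#' @return an `AnnotatedElement`: list with `scaffold`, `span`, `tir`,
#'   `tsd`, `subrepeats`, `palindrome` (unpaired positions of the terminal
#'   10-mer), `coding`.
#' @export
annotate_element <- function(genome, scaffold, span, dde_query = NULL,
                             dde_offsets = NULL, config = default_config()) {
  seq <- genome$scaffolds[[scaffold]]
  L <- nchar(seq)
  element <- subseq0(seq, span[1], span[2])
  tir <- find_tir(element, min_len = config$tir_min_len,
                  min_identity = config$tir_min_identity)
  lf <- subseq0(seq, max(0L, span[1] - 12L), span[1])
  rf <- subseq0(seq, span[2], min(L, span[2] + 12L))
  tsd <- call_tsd(lf, rf, config$tsd_len_range)
  sub <- NULL
  pal <- NULL
  if (!is.null(tir)) {
    arm <- subseq0(element, tir$arm5[1], tir$arm5[2])
    sub <- find_subterminal_repeats(arm)
    if (nchar(element) >= 10) {
      pal <- score_terminal_palindrome(substr(element, 1, 10))
    }
  }
  coding <- NULL
  if (!is.null(dde_query) && nchar(element) >= 300) {
    coding <- locate_orf_dde(element, dde_query, dde_offsets)
  }
  structure(list(scaffold = scaffold, span = span, tir = tir, tsd = tsd,
                 subrepeats = sub, palindrome = pal, coding = coding),
            class = "AnnotatedElement")
}

#' @export
print.AnnotatedElement <- function(x, ...) {
  cat(sprintf("AnnotatedElement %s:%d-%d (%d bp)\n", x$scaffold,
              x$span[1], x$span[2], x$span[2] - x$span[1]))
  if (!is.null(x$tir))
    cat(sprintf("  TIR %d bp, %.1f%% arm identity\n", x$tir$length,
                100 * x$tir$identity))
  if (!is.null(x$tsd))
    cat(sprintf("  TSD %d bp %s%s\n", x$tsd$length, x$tsd$left,
                if (x$tsd$perfect) "" else " (imperfect)"))
  if (!is.null(x$subrepeats))
    cat(sprintf("  subterminal repeats: %d x %d bp (%s)\n",
                x$subrepeats$copies, x$subrepeats$unit_len, x$subrepeats$unit))
  if (!is.null(x$palindrome))
    cat(sprintf("  terminal palindrome unpaired: {%s}\n",
                paste(x$palindrome, collapse = ",")))
  if (!is.null(x$coding))
    cat(sprintf("  coding: ORF %d-%d (%s)%s\n", x$coding$orf_span[1],
                x$coding$orf_span[2], x$coding$strand,
                if (x$coding$interrupted) " [interrupted]" else ""))
  invisible(x)
}
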