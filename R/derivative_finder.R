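# Genome-wide discovery of nonautonomous derivatives from the autonomous
# element's 50-bp termini: mismatch-bounded seed-and-extend matching, end
# pairing, TSD verification, and Pack-MULE content classification.

#' Find occurrences of an element terminus genome-wide
#'
#' Seed-and-extend: exact 12-mer seeds of the 50-bp terminus are located
#' with a precompiled dictionary, each seed hit is extended to the full
#' 50-mer placement, and placements with at most `max_mismatches` are
#' reported on both strands.
#'
#' @param genome GenomeSet.
#' @param terminus exactly 50 bp from the element's 5' end.
#' @param max_mismatches maximum mismatches over the 50-mer.
#' @return data.frame: scaffold, start, end (forward-strand 0-based
#'   half-open), orientation (`fwd` = terminus as given: an element 5' end
#'   on +, `rc` = reverse complement: an element 3' end on +), mismatches.
#' @export
terminal_seed_search <- function(genome, terminus, max_mismatches = 5L) {
  if (nchar(terminus) != 50) stop("terminus must be exactly 50 bp")
  check_dna(terminus, "terminus")
  hits <- list()
  for (orient in c("fwd", "rc")) {
    pat <- if (orient == "fwd") terminus else revcomp(terminus)
    seeds <- substring(pat, seq(1, 39, by = 12), seq(12, 50, by = 12))
    seed_offsets <- seq(0, 38, by = 12)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (sc in names(genome$scaffolds)) {
      subject <- Biostrings::DNAString(genome$scaffolds[[sc]])
      L <- length(subject)
      mt <- Biostrings::matchPDict(pd, subject)
      cand <- integer()
      for (si in seq_along(seeds)) {
        st <- Biostrings::startIndex(mt)[[si]]
        if (!is.null(st)) cand <- c(cand, st - 1L - seed_offsets[si])
      }
      cand <- sort(unique(cand[cand >= 0 & cand + 50 <= L]))
      if (!length(cand)) next
      sstr <- genome$scaffolds[[sc]]
      pat_int <- utf8ToInt(pat)
      for (p in cand) {
        window <- substr(sstr, p + 1L, p + 50L)
        mm <- sum(utf8ToInt(window) != pat_int)
        if (mm <= max_mismatches) {
          hits[[length(hits) + 1L]] <- data.frame(
            scaffold = sc, start = p, end = p + 50L, orientation = orient,
            mismatches = mm)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), orientation = character(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$scaffold, out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair oriented end hits into candidate element intervals
#'
#' Greedy convergent pairing with nesting support: scanning each scaffold
#' left to right, `fwd` hits (element 5' ends) are stacked and each `rc`
#' hit (element 3' end) closes the most recent open 5' end whose span fits
#' the limits, like matching parentheses. Each hit is used at most once;
#' nested candidates are both emitted and flagged.
#'
#' @param end_hits output of [terminal_seed_search()].
#' @param min_span,max_span candidate length limits, bp.
#' @return data.frame: scaffold, start, end, left_mismatches,
#'   right_mismatches, nested.
#' @export
pair_ends <- function(end_hits, min_span = 100L, max_span = 20000L) {
  out <- list()
  for (sc in unique(end_hits$scaffold)) {
    h <- end_hits[end_hits$scaffold == sc, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    stack <- integer()                 # row indices of open fwd hits
    for (r in seq_len(nrow(h))) {
      if (h$orientation[r] == "fwd") {
        stack <- c(stack, r)
      } else if (length(stack)) {
        e <- h$end[r]
        spans <- e - h$start[stack]
        fit <- which(spans >= min_span & spans <= max_span)
        if (!length(fit)) next
        k <- stack[max(fit)]           # most recent open end that fits
        stack <- stack[-max(fit)]
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc, start = h$start[k], end = e,
          left_mismatches = h$mismatches[k],
          right_mismatches = h$mismatches[r], nested = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), left_mismatches = integer(),
                      right_mismatches = integer(), nested = logical()))
  }
  res <- do.call(rbind, out)
  # flag both members of any containment relation among candidates
  for (i in seq_len(nrow(res))) {
    other <- res$scaffold == res$scaffold[i] & seq_len(nrow(res)) != i
    contains_i <- other & res$start <= res$start[i] & res$end >= res$end[i]
    inside_i <- other & res$start >= res$start[i] & res$end <= res$end[i]
    if (any(contains_i) || any(inside_i)) res$nested[i] <- TRUE
  }
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Verify candidate derivatives by TSD and annotate structure
#'
#' Retrieves `flank` bp on each side of every candidate (truncated at
#' scaffold edges), calls the TSD, and partitions candidates into
#' TSD-verified and unverified. TIR structure is annotated per candidate.
#'
#' @param candidates output of [pair_ends()].
#' @param genome GenomeSet.
#' @param flank flanking bp retrieved for verification.
#' @param config parameter list.
#' @return list of `DerivativeElement`s: scaffold, span, tsd (or NULL),
#'   verified (perfect-TSD flag), tir, internal_span, nested, pack_hits
#'   (empty until [classify_pack_content()]).
#' @export
verify_and_annotate <- function(candidates, genome, flank = 100L,
                                config = default_config()) {
  lapply(seq_len(nrow(candidates)), function(i) {
    sc <- candidates$scaffold[i]
    span <- c(candidates$start[i], candidates$end[i])
    seq <- genome$scaffolds[[sc]]
    L <- nchar(seq)
    lf <- subseq0(seq, max(0L, span[1] - flank), span[1])
    rf <- subseq0(seq, span[2], min(L, span[2] + flank))
    tsd <- call_tsd(lf, rf, config$tsd_len_range)
    element <- subseq0(seq, span[1], span[2])
    tir <- find_tir(element, min_len = min(config$tir_min_len, 30L),
                    min_identity = config$tir_min_identity)
    internal <- if (!is.null(tir)) span[1] + c(tir$arm5[2], tir$arm3[1])
                else span
    structure(list(scaffold = sc, span = span, tsd = tsd,
                   verified = !is.null(tsd) && isTRUE(tsd$perfect),
                   tir = tir, internal_span = internal,
                   nested = candidates$nested[i], pack_hits = list()),
              class = "DerivativeElement")
  })
}

#' Classify Pack-MULE content of a derivative's internal region
#'
#' Locally aligns the internal region against each host coding sequence and
#' reports hits with at least `min_identity` identity over at least
#' `min_len` bp.
#'
#' @param derivative a `DerivativeElement`.
#' @param genome GenomeSet the derivative lives on.
#' @param host_cds_set named character vector of host coding sequences.
#' @param min_identity,min_len reporting thresholds.
#' @return data.frame of pack hits: source, internal_start, internal_end,
#'   identity, length.
#' @export
classify_pack_content <- function(derivative, genome, host_cds_set,
                                  min_identity = 0.7, min_len = 100L) {
  span <- derivative$internal_span
  if (span[2] - span[1] < 50)
    return(data.frame(source = character(), internal_start = integer(),
                      internal_end = integer(), identity = numeric(),
                      length = integer()))
  internal <- subseq0(genome$scaffolds[[derivative$scaffold]], span[1], span[2])
  rows <- list()
  for (src in names(host_cds_set)) {
    for (strand_seq in c(host_cds_set[[src]], revcomp(host_cds_set[[src]]))) {
      al <- local_align_dna(internal, strand_seq)
      len <- al$query_span[2] - al$query_span[1]
      if (len < min_len) next
      ca <- seq_chars(al$query_aln); cb <- seq_chars(al$subject_aln)
      ident <- sum(ca == cb & ca != "-") / length(ca)
      if (ident >= min_identity) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, internal_start = al$query_span[1],
          internal_end = al$query_span[2], identity = ident, length = len)
        break  # one orientation per source is enough
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(source = character(), internal_start = integer(),
                      internal_end = integer(), identity = numeric(),
                      length = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full derivative discovery pipeline
#'
#' [terminal_seed_search()] with both element termini, [pair_ends()],
#' [verify_and_annotate()].
#'
#' @param genome GenomeSet.
#' @param element autonomous element sequence (>= 50 bp per terminus).
#' @param max_mismatches seed-search mismatch bound.
#' @param exclude_spans optional data.frame (scaffold, start, end) of known
#'   full-length elements to drop from the candidate list, so the census
#'   counts nonautonomous derivatives only (autonomous copies share the
#'   termini and are otherwise recovered too).
#' @param config parameter list.
#' @return list with `hits`, `candidates`, `derivatives` (all candidates),
#'   `verified` (perfect-TSD subset).
#' @export
find_derivatives <- function(genome, element, max_mismatches = 5L,
                             exclude_spans = NULL, config = default_config()) {
  terminus <- substr(element, 1, 50)
  hits <- terminal_seed_search(genome, terminus, max_mismatches)
  cands <- pair_ends(hits)
  if (!is.null(exclude_spans) && nrow(cands)) {
    keep <- !vapply(seq_len(nrow(cands)), function(i) {
      any(exclude_spans$scaffold == cands$scaffold[i] &
            abs(exclude_spans$start - cands$start[i]) <= 5 &
            abs(exclude_spans$end - cands$end[i]) <= 5)
    }, logical(1))
    cands <- cands[keep, , drop = FALSE]
  }
  der <- verify_and_annotate(cands, genome, config = config)
  list(hits = hits, candidates = cands, derivatives = der,
       verified = Filter(function(d) d$verified, der))
}
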