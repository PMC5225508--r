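# Translated homology search for the conserved DDE transposase domain: a
# six-frame Smith-Waterman scan standing in for a TBLASTN discovery stage,
# with a Karlin-Altschul surrogate E-value for filtering.

KA_LAMBDA <- 0.267  # gapped BLOSUM62 (11,1) constants
KA_K <- 0.041

#' Karlin-Altschul surrogate E-value
#'
#' E = K * m * n * exp(-lambda * S) with fixed gapped-BLOSUM62 constants.
#' Used as a monotone surrogate for BLAST E-values so that published cutoffs
#' (1e-3 search, 1e-15 significance filter) keep their filtering semantics.
#'
#' @param score alignment score in substitution-matrix units.
#' @param m query length (residues).
#' @param n effective search-space size (residues scanned).
#' @return numeric E-value (> 0).
#' @export
evalue_surrogate <- function(score, m, n) {
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

# minimal score that still meets an E-value cutoff
score_cutoff <- function(evalue, m, n) {
  (log(KA_K * m * n) - log(evalue)) / KA_LAMBDA
}

#' Six-frame conceptual translation
#'
#' @param seq DNA string (A/C/G/T/N), length >= 3. Stop codons are rendered
#'   `*`; codons containing N translate to `X`.
#' @return data.frame with one row per frame: `strand` (+/-), `frame`
#'   (0,1,2: offset into the strand sequence), `peptide`.
#' @export
six_frame_translate <- function(seq) {
  check_dna(seq, "translation input")
  if (nchar(seq) < 3) stop("sequence shorter than one codon")
  rc <- revcomp(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, frame = f,
        peptide = translate_dna(substr(s, f + 1L, nchar(s))))
    }
  }
  do.call(rbind, rows)
}

#' Map a peptide-coordinate interval back to forward-strand genomic span
#'
#' Inverts the coordinate transform of [six_frame_translate()]: residues
#' `[p_start, p_end)` (0-based half-open) of the frame peptide map to a
#' genomic interval on forward-strand coordinates whose length is divisible
#' by 3.
#'
#' @param p_start,p_end 0-based half-open residue interval.
#' @param strand `+` or `-`.
#' @param frame 0, 1, or 2.
#' @param seq_len length of the source DNA.
#' @return integer c(start, end), 0-based half-open on the forward strand.
#' @export
frame_to_genomic <- function(p_start, p_end, strand, frame, seq_len) {
  s <- frame + 3L * p_start
  e <- frame + 3L * p_end
  if (strand == "+") c(s, e) else c(seq_len - e, seq_len - s)
}

#' Optimal local protein alignment (affine gaps)
#'
#' Full Smith-Waterman with Gotoh affine gaps; a gap of length k costs
#' `gap_open + k * gap_extend`. Traceback is deterministic (ties: diagonal,
#' then up, then left). Residues outside the matrix alphabet are mapped to X
#' and score -4 against everything.
#'
#' @param query,subject peptide strings.
#' @param submat substitution matrix (default [protein_submat()]).
#' @param gap_open,gap_extend positive gap penalties.
#' @return list with `score`, `query_span`, `subject_span` (0-based
#'   half-open), `query_aln`, `subject_aln`.
#' @export
local_align_protein <- function(query, subject, submat = protein_submat(),
                                gap_open = 10, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  ab <- paste(colnames(submat), collapse = "")
  query <- sanitize_peptide(query, ab)
  subject <- sanitize_peptide(subject, ab)
  r <- cpp_affine_align(query, subject, ab, submat, gap_open, gap_extend, TRUE)
  list(score = r$score,
       query_span = c(r$a_start, r$a_end),
       subject_span = c(r$b_start, r$b_end),
       query_aln = r$a_aln, subject_aln = r$b_aln)
}

#' Local nucleotide alignment (affine gaps)
#'
#' @inheritParams local_align_protein
#' @param query,subject DNA strings (A/C/G/T/N); N never matches.
#' @export
local_align_dna <- function(query, subject, submat = nuc_submat(),
                            gap_open = 5, gap_extend = 2) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  r <- cpp_affine_align(query, subject, "ACGTN", submat, gap_open, gap_extend,
                        TRUE)
  list(score = r$score,
       query_span = c(r$a_start, r$a_end),
       subject_span = c(r$b_start, r$b_end),
       query_aln = r$a_aln, subject_aln = r$b_aln)
}

#' Global pairwise alignment (affine gaps)
#'
#' Needleman-Wunsch with the same scoring conventions as the local aligners;
#' used by the multiple-alignment and identity computations.
#'
#' @inheritParams local_align_protein
#' @param type `"protein"` or `"dna"`.
#' @export
global_align <- function(query, subject, type = c("protein", "dna"),
                         submat = NULL, gap_open = 10, gap_extend = 1) {
  type <- match.arg(type)
  if (type == "dna") {
    if (is.null(submat)) submat <- nuc_submat()
    ab <- "ACGTN"
  } else {
    if (is.null(submat)) submat <- protein_submat()
    ab <- paste(colnames(submat), collapse = "")
    query <- sanitize_peptide(query, ab)
    subject <- sanitize_peptide(subject, ab)
  }
  r <- cpp_affine_align(query, subject, ab, submat, gap_open, gap_extend, FALSE)
  list(score = r$score, query_aln = r$a_aln, subject_aln = r$b_aln)
}

#' Translated search of a genome for a protein query
#'
#' Scans every frame of every scaffold with [local_align_protein()], masking
#' each accepted hit and re-scanning so that multiple copies per frame are
#' recovered. Hits are reported with a surrogate E-value computed over the
#' total translated search space and filtered at `evalue_cutoff`.
#'
#' @param genome a GenomeSet.
#' @param query DDE-domain peptide, length >= 30.
#' @param evalue_cutoff retain hits with E <= cutoff (default the permissive
#'   search-stage cutoff; apply [filter_hits()] for the significance filter).
#' @param max_hits_per_frame safety bound on masking iterations.
#' @return data.frame of hits: scaffold, start, end (forward-strand 0-based
#'   half-open), strand, frame, score, evalue, subject_peptide; sorted by
#'   score descending.
#' @export
search_dde <- function(genome, query, evalue_cutoff = 1e-3,
                       max_hits_per_frame = 100L) {
  stopifnot(inherits(genome, "GenomeSet"))
  if (nchar(query) < 30) stop("query shorter than 30 residues")
  submat <- protein_submat()
  ab <- paste(colnames(submat), collapse = "")
  query <- sanitize_peptide(query, ab)
  m <- nchar(query)
  n_space <- sum(pmax(0, floor(genome$lengths / 3)) * 2)
  if (n_space == 0) return(empty_hits())
  s_min <- score_cutoff(evalue_cutoff, m, n_space)

  rows <- list()
  for (sc in names(genome$scaffolds)) {
    seq <- genome$scaffolds[[sc]]
    L <- nchar(seq)
    if (L < 3) next
    frames <- six_frame_translate(seq)
    for (k in seq_len(nrow(frames))) {
      pep <- frames$peptide[k]
      if (nchar(pep) == 0) next
      for (it in seq_len(max_hits_per_frame)) {
        al <- local_align_protein(query, pep, submat)
        if (al$score < s_min || al$score <= 0) break
        span <- frame_to_genomic(al$subject_span[1], al$subject_span[2],
                                 frames$strand[k], frames$frame[k], L)
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold = sc, start = span[1], end = span[2],
          strand = frames$strand[k], frame = frames$frame[k],
          score = al$score,
          evalue = evalue_surrogate(al$score, m, n_space),
          subject_peptide = gsub("-", "", al$subject_aln))
        # mask the matched subject segment and rescan
        w <- al$subject_span
        substr(pep, w[1] + 1L, w[2]) <-
          paste(rep("*", w[2] - w[1]), collapse = "")
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$scaffold, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(scaffold = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), score = numeric(),
             evalue = numeric(), subject_peptide = character())
}

#' Post-filter hits at a stricter significance cutoff
#' @param hits output of [search_dde()].
#' @param evalue_cutoff significance threshold (default 1e-15).
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-15) {
  hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
}

#' Remove duplicate overlapping hits
#'
#' Greedy retention by score: keep the best-scoring hit, drop any
#' lower-scoring hit on the same scaffold and strand whose reciprocal
#' overlap with a kept hit is at least `reciprocal_overlap` of BOTH spans.
#'
#' @param hits data.frame of hits.
#' @param reciprocal_overlap minimum reciprocal overlap fraction.
#' @export
dedup_hits <- function(hits, reciprocal_overlap = 0.5) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(-hits$score, hits$scaffold, hits$start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    drop_i <- FALSE
    if (any(keep)) {
      prev <- which(keep)
      same <- prev[hits$scaffold[prev] == hits$scaffold[i] &
                   hits$strand[prev] == hits$strand[i]]
      for (j in same) {
        ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
        if (ov > 0) {
          li <- hits$end[i] - hits$start[i]
          lj <- hits$end[j] - hits$start[j]
          if (ov / li >= reciprocal_overlap && ov / lj >= reciprocal_overlap) {
            drop_i <- TRUE
            break
          }
        }
      }
    }
    keep[i] <- !drop_i
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
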