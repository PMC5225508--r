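# End-to-end discovery: translated DDE search -> family clustering ->
# boundary detection between family copies -> TSD-guided span refinement ->
# structural annotation.

#' Discover and annotate full-length elements in a genome
#'
#' Runs the translated DDE search, removes duplicate hits, groups hits into
#' families on translated-domain identity, determines element boundaries by
#' comparing each hit with a family partner (including flanking sequence),
#' refines spans on TSD evidence, and annotates structure.
#'
#' @param genome GenomeSet.
#' @param query DDE-domain peptide.
#' @param dde_offsets optional catalytic-triad offsets within the query.
#' @param flank flanking bp used for boundary detection.
#' @param config parameter list; `search_evalue` and `filter_evalue` control
#'   the two-stage E-value filtering.
#' @param partner_identity translated-domain identity for grouping hits into
#'   families for boundary comparison.
#' @return list with `hits` (filtered, deduplicated), `elements` (list of
#'   `AnnotatedElement`), `unresolved` (hits without a usable family
#'   partner or boundary).
#' @export
discover_full_elements <- function(genome, query, dde_offsets = NULL,
                                   flank = 4000L, config = default_config(),
                                   partner_identity = 0.9) {
  hits <- search_dde(genome, query, evalue_cutoff = config$search_evalue)
  hits <- filter_hits(hits, config$filter_evalue)
  hits <- dedup_hits(hits)
  n <- nrow(hits)
  if (n == 0) return(list(hits = hits, elements = list(), unresolved = list()))

  fams <- cluster_families(setNames(hits$subject_peptide,
                                    sprintf("hit%03d", seq_len(n))),
                           identity_threshold = partner_identity,
                           type = "protein")
  assign <- fams$assignments

  window_of <- function(i) {
    sc <- hits$scaffold[i]
    L <- genome$lengths[[sc]]
    s <- max(0L, hits$start[i] - flank)
    e <- min(L, hits$end[i] + flank)
    list(seq = subseq0(genome$scaffolds[[sc]], s, e), offset = s, scaffold = sc)
  }

  elements <- list()
  unresolved <- list()
  seen <- character()
  for (i in seq_len(n)) {
    partners <- which(assign == assign[i] & seq_len(n) != i)
    # prefer a partner at a different locus
    partners <- partners[hits$scaffold[partners] != hits$scaffold[i] |
                         abs(hits$start[partners] - hits$start[i]) > 100]
    if (!length(partners)) {
      unresolved[[length(unresolved) + 1L]] <- hits[i, ]
      next
    }
    wa <- window_of(i)
    span <- NULL
    for (p in partners) {
      wb <- window_of(p)
      b <- tryCatch(detect_boundaries(wa$seq, wb$seq),
                    error = function(e) NULL)
      if (!is.null(b)) { span <- b$a; break }
    }
    if (is.null(span)) {
      unresolved[[length(unresolved) + 1L]] <- hits[i, ]
      next
    }
    rough <- span + wa$offset
    ref <- refine_element_span(genome, wa$scaffold, rough)
    key <- sprintf("%s:%d-%d", wa$scaffold, ref$span[1], ref$span[2])
    if (key %in% seen) next
    seen <- c(seen, key)
    el <- annotate_element(genome, wa$scaffold, ref$span, dde_query = query,
                           dde_offsets = dde_offsets, config = config)
    el$id <- sprintf("element%03d", length(elements) + 1L)
    elements[[length(elements) + 1L]] <- el
  }
  list(hits = hits, elements = elements, unresolved = unresolved)
}
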