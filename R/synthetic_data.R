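# Synthetic genomes, annotations, and assay fixtures with machine-readable
# ground truth. The generator plants structurally faithful MULE-like
# elements (long TIRs with a 10-bp imperfect terminal palindrome and
# subterminal tandem repeats, 8-9 bp TSDs, a DDE-bearing transposase ORF)
# in uniform-ACGT background so that every discovery and annotation
# operation can be validated closed-loop.

#' Element structure template
#'
#' Defaults mirror the active autonomous element characterized in the study
#' system: 3198 bp, 145-bp TIRs carrying a 10-bp imperfect terminal
#' palindrome (positions 5 and 6 unpaired) and 9 copies of a 12-bp
#' subterminal tandem repeat with 3-4 bp spacers, a 2-exon transposase ORF,
#' and 9-bp TSDs.
#'
#' @param total_len element length, bp.
#' @param tir_len TIR length, bp.
#' @param tsd_len TSD length: 8 or 9.
#' @param palindrome_unpaired unpaired positions of the terminal 10-mer;
#'   must come in (i, 11-i) pairs.
#' @param subrepeat_unit_len,subrepeat_copies subterminal repeat geometry.
#' @param spacer_len_range c(min, max) spacer between repeat copies, bp.
#' @param n_exons 1 or 2 (2 inserts a short intron upstream of the DDE
#'   domain).
#' @param family_divergence substitutions applied per additional family
#'   copy.
#' @return an `ElementTemplate` list.
#' @export
element_template <- function(total_len = 3198L, tir_len = 145L, tsd_len = 9L,
                             palindrome_unpaired = c(5L, 6L),
                             subrepeat_unit_len = 12L, subrepeat_copies = 9L,
                             spacer_len_range = c(3L, 4L), n_exons = 2L,
                             family_divergence = 0L) {
  if (!tsd_len %in% c(8L, 9L)) stop("tsd_len must be 8 or 9")
  if (length(palindrome_unpaired)) {
    pu <- sort(unique(as.integer(palindrome_unpaired)))
    if (!setequal(pu, sort(unique(c(pu, 11L - pu)))))
      stop("palindrome_unpaired positions must come in (i, 11-i) pairs")
  } else pu <- integer()
  min_fit <- 10L + subrepeat_copies * subrepeat_unit_len +
    (subrepeat_copies - 1L) * spacer_len_range[1]
  if (min_fit > tir_len)
    stop("palindrome + subterminal repeats do not fit inside tir_len")
  structure(list(total_len = as.integer(total_len),
                 tir_len = as.integer(tir_len), tsd_len = as.integer(tsd_len),
                 palindrome_unpaired = pu,
                 subrepeat_unit_len = as.integer(subrepeat_unit_len),
                 subrepeat_copies = as.integer(subrepeat_copies),
                 spacer_len_range = as.integer(spacer_len_range),
                 n_exons = as.integer(n_exons),
                 family_divergence = as.integer(family_divergence)),
            class = "ElementTemplate")
}

#' Synthetic transposase fixture
#'
#' A fixed synthetic transposase (not any natural gene) whose conceptual
#' translation carries the catalytic D, D, E triad at known offsets; shipped
#' as plain-text FASTA under `extdata`. The DDE-domain segment is the query
#' used by the translated homology search.
#'
#' @return list with `peptide` (full transposase), `cds` (back-translated
#'   coding sequence), `dde_domain` (domain peptide), `dde_offsets`
#'   (triad positions within the domain), `domain_offset` (0-based residue
#'   offset of the domain within the transposase).
#' @export
synthetic_transposase <- function() {
  f_pep <- system.file("extdata", "synthetic_transposase.faa",
                       package = "mulescan", mustWork = TRUE)
  f_cds <- system.file("extdata", "synthetic_transposase_cds.fa",
                       package = "mulescan", mustWork = TRUE)
  pep <- as.character(Biostrings::readAAStringSet(f_pep))[[1]]
  cds <- as.character(Biostrings::readDNAStringSet(f_cds))[[1]]
  domain_offset <- 100L
  domain_len <- 130L
  dde <- c(10L, 60L, 120L)
  list(peptide = pep, cds = cds,
       dde_domain = substr(pep, domain_offset + 1L,
                           domain_offset + domain_len),
       dde_offsets = dde, domain_offset = domain_offset)
}

# --- element construction ---------------------------------------------------

make_palindrome <- function(unpaired) {
  b <- sample(DNA_BASES, 10, replace = TRUE)
  for (i in 1:5) {
    j <- 11L - i
    if (i %in% unpaired) {
      b[j] <- b[i]                      # equal bases never pair
    } else {
      b[j] <- complement_base(b[i])
    }
  }
  paste(b, collapse = "")
}

# distribute a spacer budget among n junctions, each within [lo, hi]
draw_spacers <- function(n, lo, hi, budget) {
  if (budget < n * lo) stop("subterminal repeats do not fit: spacer budget too small")
  budget <- min(budget, n * hi)
  sp <- rep(lo, n)
  extra <- budget - n * lo
  while (extra > 0) {
    open <- which(sp < hi)
    k <- if (length(open) == 1) open else sample(open, 1)
    sp[k] <- sp[k] + 1L
    extra <- extra - 1L
  }
  sp
}

# spacer content: consecutive spacers are forced to differ at >= 2 positions
# so that no longer-period repeat chain can shadow the planted unit
make_spacer_seqs <- function(lens) {
  out <- character(length(lens))
  prev <- ""
  for (i in seq_along(lens)) {
    repeat {
      s <- random_dna(lens[i])
      if (!nzchar(prev)) break
      n <- min(nchar(s), nchar(prev))
      if (n < 2) break
      d <- sum(utf8ToInt(substr(s, 1, n)) != utf8ToInt(substr(prev, 1, n)))
      if (d >= 2) break
    }
    out[i] <- s
    prev <- s
  }
  out
}

build_tir <- function(template) {
  pal <- make_palindrome(template$palindrome_unpaired)
  unit <- random_dna(template$subrepeat_unit_len)
  n_j <- template$subrepeat_copies - 1L
  budget <- template$tir_len - 10L -
    template$subrepeat_copies * template$subrepeat_unit_len
  sp_lens <- draw_spacers(n_j, template$spacer_len_range[1],
                          template$spacer_len_range[2], budget)
  sp_seqs <- make_spacer_seqs(sp_lens)
  arr <- unit
  for (i in seq_len(n_j)) arr <- paste0(arr, sp_seqs[i], unit)
  tir <- paste0(pal, arr)
  if (nchar(tir) > template$tir_len) stop("subterminal repeats overflow tir_len")
  paste0(tir, random_dna(template$tir_len - nchar(tir)))
}

# Force the 10 bases just inside each TIR arm to break the inverted repeat:
# internal position t+j is set equal to internal position L-1-t-j (equal
# bases are never complementary), so TIR alignments end exactly at tir_len.
break_tir_boundary <- function(element, tir_len) {
  ch <- seq_chars(element)
  L <- length(ch)
  for (j in 0:9) {
    ch[tir_len + 1L + j] <- ch[L - tir_len - j]
  }
  paste(ch, collapse = "")
}

#' Build one full-length autonomous element from a template
#'
#' Internal layout: left TIR, filler, transposase CDS (with a short intron
#' when `n_exons == 2`), filler, right TIR (reverse complement of the left).
#' Draws from the current RNG stream.
#'
#' @param template an [element_template()].
#' @param transposase optional [synthetic_transposase()] result (loaded if
#'   NULL).
#' @return list with `seq`, `tir` (left arm), `cds_span` (0-based half-open
#'   span of the planted coding region within the element), `template`.
#' @export
build_full_element <- function(template, transposase = NULL) {
  if (is.null(transposase)) transposase <- synthetic_transposase()
  tir <- build_tir(template)
  cds <- transposase$cds
  if (template$n_exons >= 2L) {
    intron <- paste0("GT", random_dna(56), "AG")
    # intron placed upstream of the DDE domain so the domain stays contiguous
    cut <- 3L * 50L
    cds <- paste0(substr(cds, 1, cut), intron,
                  substr(cds, cut + 1, nchar(cds)))
  }
  internal_len <- template$total_len - 2L * template$tir_len
  if (internal_len < nchar(cds) + 40L)
    stop("transposase does not fit in the internal region")
  pad <- internal_len - nchar(cds)
  pad_left <- as.integer(pad / 2)
  internal <- paste0(random_dna(pad_left), cds, random_dna(pad - pad_left))
  el <- paste0(tir, internal, revcomp(tir))
  el <- break_tir_boundary(el, template$tir_len)
  list(seq = el, tir = tir,
       cds_span = c(template$tir_len + pad_left,
                    template$tir_len + pad_left + nchar(cds)),
       template = template)
}

mutate_seq <- function(seq, n_subs) {
  if (n_subs <= 0) return(seq)
  ch <- seq_chars(seq)
  pos <- sample(length(ch), min(n_subs, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Build a nonautonomous derivative element
#'
#' TIR arms are truncated copies of the parent's arms (terminal side kept;
#' truncation drawn uniformly from 50-100% of the TIR length, independently
#' per side); the internal region is random DNA or, for Pack-MULE style
#' derivatives, carries a mutated host-gene fragment.
#'
#' @param parent_tir the parent element's left TIR arm.
#' @param internal_len internal region length, bp.
#' @param host_fragment optional DNA fragment to embed (Pack-MULE content).
#' @return list with `seq`, `tir_len` c(left, right), `pack_span` (span of
#'   the embedded fragment within the element, or NULL).
#' @export
build_derivative <- function(parent_tir, internal_len = 600L,
                             host_fragment = NULL) {
  tl <- nchar(parent_tir)
  t_left <- as.integer(round(runif(1, 0.5, 1.0) * tl))
  t_right <- as.integer(round(runif(1, 0.5, 1.0) * tl))
  arm_l <- substr(parent_tir, 1, t_left)
  arm_r <- revcomp(substr(parent_tir, 1, t_right))
  pack_span <- NULL
  if (!is.null(host_fragment) && nzchar(host_fragment)) {
    fl <- nchar(host_fragment)
    if (internal_len < fl + 20L) internal_len <- fl + 20L
    pad <- internal_len - fl
    pl <- as.integer(pad / 2)
    internal <- paste0(random_dna(pl), host_fragment,
                       random_dna(pad - pl))
    pack_span <- c(t_left + pl, t_left + pl + fl)
  } else {
    internal <- random_dna(internal_len)
  }
  el <- paste0(arm_l, internal, arm_r)
  el <- break_tir_boundary(el, min(t_left, t_right))
  list(seq = el, tir_len = c(t_left, t_right), pack_span = pack_span)
}

#' Generate a Pack-MULE style derivative from a host gene sequence
#'
#' @param template an [element_template()] (provides the parent TIR).
#' @param host_gene_seq source DNA.
#' @param fragment_len captured fragment length (0 = plain nonautonomous).
#' @param identity fraction identity of the captured copy vs the source, in
#'   (0, 1].
#' @param seed integer seed.
#' @return list with `seq`, `pack` (logical), `fragment_span`, `source_span`
#'   (span sampled from the host gene), `n_mismatches`.
#' @export
generate_pack_derivative <- function(template, host_gene_seq, fragment_len,
                                     identity = 1.0, seed = 1L) {
  if (identity <= 0 || identity > 1) stop("identity must be in (0, 1]")
  if (fragment_len > nchar(host_gene_seq))
    stop("fragment_len exceeds host gene length")
  with_seed(derive_seed(seed, 701L), {
    tir <- build_tir(template)
    if (fragment_len == 0) {
      d <- build_derivative(tir, internal_len = 400L)
      return(list(seq = d$seq, pack = FALSE, fragment_span = NULL,
                  source_span = NULL, n_mismatches = NA_integer_))
    }
    s0 <- sample(0:(nchar(host_gene_seq) - fragment_len), 1)
    frag <- subseq0(host_gene_seq, s0, s0 + fragment_len)
    n_mut <- as.integer(round(fragment_len * (1 - identity)))
    frag_mut <- mutate_seq(frag, n_mut)
    d <- build_derivative(tir, internal_len = fragment_len + 60L,
                          host_fragment = frag_mut)
    list(seq = d$seq, pack = TRUE, fragment_span = d$pack_span,
         source_span = c(s0, s0 + fragment_len), n_mismatches = n_mut)
  })
}

# --- genome assembly --------------------------------------------------------

place_genes <- function(lengths, n_genes, gene_len_range = c(1000L, 3000L),
                        buffer = 500L) {
  genes <- list()
  placed <- lapply(names(lengths), function(x) matrix(0, 0, 2))
  names(placed) <- names(lengths)
  tries <- 0L
  while (length(genes) < n_genes && tries < 5000L) {
    tries <- tries + 1L
    sc <- sample(names(lengths), 1, prob = as.numeric(lengths))
    gl <- sample(gene_len_range[1]:gene_len_range[2], 1)
    if (lengths[[sc]] < gl + 2L * buffer) next
    s <- sample(buffer:(lengths[[sc]] - gl - buffer), 1)
    e <- s + gl
    ex <- placed[[sc]]
    if (nrow(ex) && any(pmin(ex[, 2], e) - pmax(ex[, 1], s) > -buffer)) next
    placed[[sc]] <- rbind(ex, c(s, e))
    genes[[length(genes) + 1L]] <- data.frame(
      id = sprintf("gene%03d", length(genes) + 1L), scaffold = sc,
      start = s, end = e, strand = sample(c("+", "-"), 1))
  }
  if (length(genes) < n_genes) stop("could not place all genes without overlap")
  do.call(rbind, genes)
}

min_gene_dist <- function(pos, sc, genes) {
  g <- genes[genes$scaffold == sc, , drop = FALSE]
  if (!nrow(g)) return(Inf)
  inside <- pos >= g$start & pos < g$end
  if (any(inside)) return(0)
  min(pmin(abs(pos - g$end + 1L), abs(g$start - pos)))
}

# An insertion is only planted where the (flank, TSD, element) decomposition
# is unambiguous: no shifted span within `slop` carries an equal-or-longer
# perfect duplication. Keeps closed-loop span recovery exact.
unambiguous_insertion <- function(bg, pos, k, element, slop = 12L) {
  w <- 30L
  if (pos - w < 0 || pos + k + w > nchar(bg)) return(FALSE)
  ctx <- paste0(subseq0(bg, pos - w, pos + k), element,
                subseq0(bg, pos, pos + k + w))
  L0 <- w + k
  E0 <- L0 + nchar(element)
  for (ds in -slop:slop) {
    s <- L0 + ds
    lf <- substr(ctx, s - 11L, s)
    for (de in -slop:slop) {
      if (ds == 0 && de == 0) next
      e <- E0 + de
      rf <- substr(ctx, e + 1L, e + 12L)
      tsd <- call_tsd(lf, rf, c(8L, 10L), allow_imperfect = FALSE)
      if (!is.null(tsd) && tsd$length >= k) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic genome with planted elements and ground truth
#'
#' Background is i.i.d. uniform ACGT. Full-length autonomous copies are
#' built from `template` (each with an intact DDE-bearing ORF); derivatives
#' carry truncated TIRs and random or host-derived internal sequence. Every
#' insertion duplicates the 8/9 bp at the insertion point into a TSD; a
#' fraction `derivative_tsd_frac` of derivatives keep the duplication
#' perfect, the remainder have one base of the right-hand copy mutated. A
#' fraction `genic_insert_frac` of all planted sites fall inside gene
#' bodies; the rest are placed farther than `window` from any gene.
#'
#' @param template an [element_template()].
#' @param n_scaffolds,scaffold_len genome geometry.
#' @param n_full_copies,n_derivatives,n_genes planted feature counts.
#' @param genic_insert_frac fraction of planted sites in genic regions.
#' @param seed integer; identical seeds give byte-identical output.
#' @param derivative_tsd_frac fraction of derivatives with perfect TSDs.
#' @param derivative_internal_range internal-length range for derivatives.
#' @param window genic-proximity window, bp.
#' @return list with `genome` (GenomeSet), `genes` (GeneSet), `truth`
#'   (data.frame: scaffold, start, end, kind, tsd_seq, tsd_len,
#'   perfect_tsd, tir_len, genic, host_fragment_source, insert_point),
#'   `template`, `element` (the [build_full_element()] result).
#' @export
generate_genome <- function(template = element_template(), n_scaffolds = 4L,
                            scaffold_len = 100000L, n_full_copies = 8L,
                            n_derivatives = 20L, n_genes = 12L,
                            genic_insert_frac = 0.643, seed = 1L,
                            derivative_tsd_frac = 0.57,
                            derivative_internal_range = c(200L, 1500L),
                            window = 5000L) {
  stopifnot(n_full_copies >= 0, n_derivatives >= 0, n_genes >= 0,
            genic_insert_frac >= 0, genic_insert_frac <= 1)
  transposase <- synthetic_transposase()

  bg <- with_seed(derive_seed(seed, 1L), {
    setNames(vapply(seq_len(n_scaffolds), function(i) random_dna(scaffold_len),
                    character(1)),
             sprintf("scaffold_%02d", seq_len(n_scaffolds)))
  })
  lengths <- setNames(nchar(bg), names(bg))

  genes0 <- if (n_genes > 0) {
    with_seed(derive_seed(seed, 2L), place_genes(lengths, n_genes))
  } else {
    data.frame(id = character(), scaffold = character(), start = integer(),
               end = integer(), strand = character())
  }

  n_sites <- n_full_copies + n_derivatives
  element <- with_seed(derive_seed(seed, 3L),
                       build_full_element(template, transposase))

  out <- with_seed(derive_seed(seed, 4L), {
    n_genic <- as.integer(round(genic_insert_frac * n_sites))
    if (n_genes == 0) n_genic <- 0L
    kinds <- c(rep("full", n_full_copies), rep("derivative", n_derivatives))
    n_perfect <- as.integer(round(derivative_tsd_frac * n_derivatives))
    deriv_perfect <- c(rep(TRUE, n_perfect),
                       rep(FALSE, n_derivatives - n_perfect))
    genic_flags <- if (n_sites > 0)
      sample(c(rep(TRUE, n_genic), rep(FALSE, n_sites - n_genic)))
    else logical()

    min_sep <- 150L
    edge_margin <- 300L
    placed <- data.frame(scaffold = character(), pos = integer())
    ok_sep <- function(sc, pos) {
      s <- placed[placed$scaffold == sc, ]
      !nrow(s) || all(abs(s$pos - pos) >= min_sep)
    }
    gb <- genes0[genes0$end - genes0$start > 2L * min_sep, , drop = FALSE]
    draw_pos <- function(genic, seqi, k) {
      for (try in 1:5000) {
        if (genic) {
          g <- gb[sample(nrow(gb), 1), ]
          sc <- g$scaffold
          pos <- sample((g$start + 20L):(g$end - 20L - k), 1)
        } else {
          sc <- sample(names(lengths), 1, prob = as.numeric(lengths))
          if (lengths[[sc]] < 2L * edge_margin + 10L) next
          pos <- sample(edge_margin:(lengths[[sc]] - edge_margin), 1)
          if (min_gene_dist(pos, sc, genes0) <= window + 50L) next
        }
        if (!ok_sep(sc, pos)) next
        if (!unambiguous_insertion(bg[[sc]], pos, k, seqi)) next
        placed[nrow(placed) + 1L, ] <<- list(sc, pos)
        return(list(scaffold = sc, pos = pos))
      }
      stop("could not place ", if (genic) "genic" else "distal",
           " insertion site without overlap/ambiguity")
    }

    ins <- vector("list", n_sites)
    di <- 0L
    for (i in seq_len(n_sites)) {
      kind <- kinds[i]
      if (kind == "full") {
        seqi <- mutate_seq(element$seq, template$family_divergence)
        tirl <- template$tir_len
        perfect <- TRUE
      } else {
        di <- di + 1L
        il <- sample(derivative_internal_range[1]:derivative_internal_range[2], 1)
        d <- build_derivative(element$tir, internal_len = il)
        seqi <- d$seq
        tirl <- min(d$tir_len)
        perfect <- deriv_perfect[di]
      }
      site <- draw_pos(genic_flags[i], seqi, template$tsd_len)
      ins[[i]] <- list(scaffold = site$scaffold, pos = site$pos,
                       seq = seqi, kind = kind, genic = genic_flags[i],
                       tsd_len = template$tsd_len, perfect = perfect,
                       tir_len = tirl)
    }
    ins
  })

  # splice insertions into each scaffold, tracking coordinate shifts
  truth <- list()
  scaffolds <- bg
  genes <- genes0
  for (sc in names(bg)) {
    here <- Filter(function(x) x$scaffold == sc, out)
    if (!length(here)) next
    ord <- order(vapply(here, function(x) x$pos, integer(1)))
    here <- here[ord]
    pieces <- character()
    cursor <- 0L
    offset <- 0L
    adds <- data.frame(pos = integer(), added = integer())
    for (x in here) {
      k <- x$tsd_len
      tsd <- subseq0(bg[[sc]], x$pos, x$pos + k)
      pieces <- c(pieces, subseq0(bg[[sc]], cursor, x$pos + k), x$seq)
      start_final <- x$pos + k + offset
      el_len <- nchar(x$seq)
      truth[[length(truth) + 1L]] <- data.frame(
        scaffold = sc, start = start_final, end = start_final + el_len,
        kind = x$kind, tsd_seq = if (x$perfect) tsd else NA_character_,
        tsd_len = x$tsd_len, perfect_tsd = x$perfect, tir_len = x$tir_len,
        genic = x$genic, host_fragment_source = NA_character_,
        insert_point = x$pos, mutate_tsd = !x$perfect)
      cursor <- x$pos           # right TSD copy re-emitted with next piece
      offset <- offset + el_len + k
      adds <- rbind(adds, data.frame(pos = x$pos, added = el_len + k))
    }
    pieces <- c(pieces, subseq0(bg[[sc]], cursor, lengths[[sc]]))
    scaffolds[[sc]] <- paste(pieces, collapse = "")
    if (nrow(genes)) {
      gi <- genes$scaffold == sc
      if (any(gi)) {
        for (r in which(gi)) {
          genes$start[r] <- genes$start[r] +
            sum(adds$added[adds$pos < genes$start[r]])
          genes$end[r] <- genes$end[r] +
            sum(adds$added[adds$pos < genes$end[r]])
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame()

  # imperfect derivative TSDs: mutate one base of the right-hand copy
  if (nrow(truth)) {
    scv <- scaffolds
    imp <- which(truth$mutate_tsd)
    if (length(imp)) {
      scv_chars <- list()
      for (r in imp) {
        sc <- truth$scaffold[r]
        if (is.null(scv_chars[[sc]])) scv_chars[[sc]] <- seq_chars(scv[[sc]])
        p <- truth$end[r] + as.integer(truth$tsd_len[r] / 2)  # inside right copy
        old <- scv_chars[[sc]][p + 1L]
        scv_chars[[sc]][p + 1L] <- with_seed(derive_seed(seed, 5000L + r),
                                             sample(setdiff(DNA_BASES, old), 1))
      }
      for (sc in names(scv_chars)) scv[[sc]] <- paste(scv_chars[[sc]], collapse = "")
    }
    scaffolds <- scv
    truth$mutate_tsd <- NULL
  }

  list(genome = genome_set(scaffolds),
       genes = gene_set(genes),
       truth = truth, template = template, element = element)
}

# --- assay fixtures ---------------------------------------------------------

default_assay_element <- function() {
  # small artificial reporter-style element: 50-bp TIR arms, short internal
  tir <- random_dna(50)
  el <- paste0(tir, random_dna(150), revcomp(tir))
  break_tir_boundary(el, 50L)
}

#' Generate revertant-junction fixtures for footprint classification
#'
#' Builds a donor locus (element with or without flanking TSD inside a
#' reporter context) and emits one revertant junction per requested class:
#' `precise` (element plus exactly one TSD copy removed; exact restoration
#' when no TSD), `flank_deletion` (1-4 bp lost per side), `insertion` (1-5
#' random extra bp), `tir_remnant` (1-13 terminal bp of the element left).
#' `nonprecise` draws from the imprecise classes in proportions matching the
#' observed footprint spectrum (predominantly small flank deletions).
#'
#' @param class_counts named integer vector/list, e.g.
#'   `c(precise = 4, nonprecise = 34)`.
#' @param tsd donor-site TSD sequence or NULL for the no-TSD construct.
#' @param seed integer seed.
#' @param element element sequence (default: a small artificial element).
#' @param flank_len donor flank length per side.
#' @return list with `donor` (flank_left, flank_right, element, tsd) and
#'   `junctions` (data.frame: id, seq, class, left_lost, right_lost,
#'   remnant_len).
#' @export
generate_assay_fixtures <- function(class_counts, tsd = NULL, seed = 1L,
                                    element = NULL, flank_len = 60L) {
  counts <- unlist(class_counts)
  if (any(counts < 0)) stop("class counts must be >= 0")
  known <- c("precise", "flank_deletion", "insertion", "tir_remnant",
             "nonprecise")
  if (!all(names(counts) %in% known))
    stop("unknown footprint class: ",
         paste(setdiff(names(counts), known), collapse = ", "))
  with_seed(derive_seed(seed, 11L), {
    if (is.null(element)) element <- default_assay_element()
    fl <- random_dna(flank_len)
    fr <- random_dna(flank_len)
    tsd_s <- if (is.null(tsd)) "" else toupper(tsd)
    ref <- paste0(fl, tsd_s, fr)     # reconstructed empty donor site
    L_el <- nchar(element)
    term5 <- substr(element, 1, 13)
    term3 <- substr(element, L_el - 12, L_el)

    classes <- unlist(lapply(names(counts), function(k) {
      if (k == "nonprecise") {
        sample(c("flank_deletion", "insertion", "tir_remnant"), counts[[k]],
               replace = TRUE, prob = c(0.8, 0.1, 0.1))
      } else rep(k, counts[[k]])
    }))
    rows <- lapply(seq_along(classes), function(i) {
      cl <- classes[i]
      left_lost <- 0L; right_lost <- 0L; remnant <- 0L
      if (cl == "precise") {
        seq <- ref
      } else if (cl == "flank_deletion") {
        repeat {
          dl <- sample(0:4, 1); dr <- sample(0:4, 1)
          if (dl + dr >= 1) break
        }
        leftpart <- substr(ref, 1, flank_len + nchar(tsd_s) - dl)
        rightpart <- substr(ref, flank_len + nchar(tsd_s) + dr + 1, nchar(ref))
        seq <- paste0(leftpart, rightpart)
        left_lost <- dl; right_lost <- dr
      } else if (cl == "insertion") {
        repeat {
          ins <- random_dna(sample(2:5, 1))
          seq <- paste0(substr(ref, 1, flank_len + nchar(tsd_s)), ins,
                        substr(ref, flank_len + nchar(tsd_s) + 1, nchar(ref)))
          cand <- insertion_candidates(seq, ref)
          if (length(cand) &&
              !any(vapply(cand, function(s) {
                s == substr(term5, 1, nchar(s)) ||
                  s == substr(term3, 14 - nchar(s), 13)
              }, logical(1)))) break
        }
      } else {                       # tir_remnant
        repeat {
          remnant <- sample(1:13, 1)
          side <- sample(c("5p", "3p"), 1)
          rem <- if (side == "5p") substr(element, 1, remnant)
                 else substr(element, L_el - remnant + 1, L_el)
          seq <- paste0(substr(ref, 1, flank_len + nchar(tsd_s)), rem,
                        substr(ref, flank_len + nchar(tsd_s) + 1, nchar(ref)))
          cand <- insertion_candidates(seq, ref)
          ok <- any(vapply(cand, function(s) {
            s == substr(term5, 1, nchar(s)) ||
              s == substr(term3, 14 - nchar(s), 13)
          }, logical(1)))
          if (ok) break
        }
      }
      data.frame(id = sprintf("rev%03d", i), seq = seq, class = cl,
                 left_lost = left_lost, right_lost = right_lost,
                 remnant_len = remnant)
    })
    list(donor = list(flank_left = fl, flank_right = fr, element = element,
                      tsd = if (is.null(tsd)) NULL else tsd_s),
         junctions = do.call(rbind, rows))
  })
}

#' Generate reinsertion-site fixtures with planted TSDs
#'
#' Picks insertion points in a genome, records the junction flanks an
#' insertion with an 8- or 9-bp TSD would produce, and builds
#' transposon-display style reads (20 bp of element terminus followed by
#' the flank). Sites whose surroundings would make the TSD length ambiguous
#' under the longest-match rule, or whose flanks are not unique in the
#' genome, are resampled.
#'
#' @param n8,n9 numbers of 8-bp and 9-bp TSD events.
#' @param genome GenomeSet (e.g. a synthetic stand-in for the host genome).
#' @param seed integer seed.
#' @param flank_len recorded flank length per side.
#' @param terminus element terminal sequence used in the display reads
#'   (>= 20 bp; default a fixed synthetic terminus).
#' @return data.frame: id, scaffold, pos, tsd_len, left_flank, right_flank,
#'   left_read, right_read.
#' @export
generate_reinsertion_flanks <- function(n8, n9, genome, seed = 1L,
                                        flank_len = 40L, terminus = NULL) {
  stopifnot(n8 >= 0, n9 >= 0)
  with_seed(derive_seed(seed, 21L), {
    if (is.null(terminus)) terminus <- random_dna(20)
    tt <- substr(terminus, 1, 20)
    lens <- genome$lengths
    ks <- c(rep(8L, n8), rep(9L, n9))
    rows <- list()
    for (i in seq_along(ks)) {
      k <- ks[i]
      ok <- FALSE
      for (try in 1:5000) {
        sc <- sample(names(lens), 1, prob = as.numeric(lens))
        L <- lens[[sc]]
        if (L < 2L * flank_len + 30L) next
        pos <- sample((flank_len + 2L):(L - flank_len - k - 2L), 1)
        seq <- genome$scaffolds[[sc]]
        lf <- subseq0(seq, pos + k - flank_len, pos + k)
        rf <- subseq0(seq, pos, pos + flank_len)
        # reject coincidental longest-match extensions (k+1, k+2 calls)
        ext <- FALSE
        for (kk in (k + 1L):10L) {
          l2 <- subseq0(seq, pos + k - kk, pos + k)
          r2 <- subseq0(seq, pos, pos + kk)
          if (l2 == r2) { ext <- TRUE; break }
        }
        if (ext) next
        # flanks must map uniquely for display-read mapping
        if (count_occurrences(genome, substr(rf, 1, 30)) != 1) next
        if (count_occurrences(genome, substr(lf, flank_len - 29, flank_len)) != 1) next
        rows[[i]] <- data.frame(
          id = sprintf("site%03d", i), scaffold = sc, pos = pos, tsd_len = k,
          left_flank = lf, right_flank = rf,
          left_read = paste0(tt, revcomp(lf)),
          right_read = paste0(tt, rf))
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place reinsertion site ", i)
    }
    do.call(rbind, rows)
  })
}

# occurrences of a pattern in a genome, both strands
count_occurrences <- function(genome, pattern) {
  n <- 0L
  rc <- revcomp(pattern)
  for (sc in names(genome$scaffolds)) {
    s <- genome$scaffolds[[sc]]
    n <- n + length(gregexpr(pattern, s, fixed = TRUE)[[1]][
      gregexpr(pattern, s, fixed = TRUE)[[1]] > 0])
    n <- n + length(gregexpr(rc, s, fixed = TRUE)[[1]][
      gregexpr(rc, s, fixed = TRUE)[[1]] > 0])
  }
  n
}

#' Plant site coordinates with a fixed genic/distal composition
#'
#' Pure coordinate sampling (no sequence editing): `n_nondistal` sites are
#' placed in gene bodies or within `window` of a gene edge, the remainder
#' farther than `window` from any gene.
#'
#' @param genome GenomeSet.
#' @param genes GeneSet.
#' @param n_total,n_nondistal site counts.
#' @param window proximity window, bp.
#' @param seed integer seed.
#' @return data.frame: scaffold, pos, planted_category.
#' @export
generate_proximity_sites <- function(genome, genes, n_total, n_nondistal,
                                     window = 1000L, seed = 1L) {
  stopifnot(n_nondistal <= n_total)
  with_seed(derive_seed(seed, 31L), {
    lens <- genome$lengths
    n_body <- as.integer(n_nondistal / 2)
    n_win <- n_nondistal - n_body
    rows <- list()
    add <- function(cat) {
      for (try in 1:10000) {
        sc <- sample(names(lens), 1, prob = as.numeric(lens))
        pos <- sample(5L:(lens[[sc]] - 5L), 1)
        d <- min_gene_dist(pos, sc, genes)
        ok <- switch(cat,
                     gene_body = d == 0,
                     within_window = d > 0 && d <= window,
                     distal = d > window)
        if (ok) {
          rows[[length(rows) + 1L]] <<- data.frame(
            scaffold = sc, pos = pos, planted_category = cat)
          return(invisible(NULL))
        }
      }
      stop("could not place site of category ", cat)
    }
    for (i in seq_len(n_body)) add("gene_body")
    for (i in seq_len(n_win)) add("within_window")
    for (i in seq_len(n_total - n_nondistal)) add("distal")
    do.call(rbind, rows)
  })
}
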