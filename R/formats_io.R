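# Readers/writers for the standard formats the pipeline touches. Disk
# formats are 1-based inclusive (FASTA headers are free text, GFF3 1-based);
# everything in memory is 0-based half-open.

#' Construct a GenomeSet from named sequences
#'
#' @param scaffolds named character vector of DNA sequences (A/C/G/T/N;
#'   lowercase accepted and uppercased).
#' @return a `GenomeSet`: list with `scaffolds` (named uppercase character
#'   vector) and `lengths` (named integer vector).
#' @export
genome_set <- function(scaffolds) {
  if (is.null(names(scaffolds)) || any(names(scaffolds) == ""))
    stop("all scaffolds must be named")
  if (anyDuplicated(names(scaffolds)))
    stop("duplicate scaffold id: ",
         names(scaffolds)[duplicated(names(scaffolds))][1])
  scaffolds <- toupper(scaffolds)
  for (i in seq_along(scaffolds))
    check_dna(scaffolds[[i]], paste0("scaffold '", names(scaffolds)[i], "'"))
  structure(list(scaffolds = scaffolds,
                 lengths = setNames(nchar(scaffolds), names(scaffolds))),
            class = "GenomeSet")
}

#' @export
print.GenomeSet <- function(x, ...) {
  cat(sprintf("GenomeSet: %d scaffold(s), %s bp total\n",
              length(x$scaffolds), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Load a genome FASTA file
#'
#' @param path FASTA file path.
#' @return a [genome_set()] with uppercased sequences; scaffold ids are the
#'   first whitespace-delimited token of each header.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("malformed FASTA '", path, "': duplicate record id '",
         ids[duplicated(ids)][1], "'")
  seqs <- setNames(toupper(as.character(ss)), ids)
  # collapse IUPAC ambiguity beyond N is rejected by genome_set
  genome_set(seqs)
}

#' Write a GenomeSet to FASTA
#' @param genome a GenomeSet.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$scaffolds)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a GeneSet
#'
#' @param genes data.frame with columns `id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`).
#' @param genome optional GenomeSet for coordinate validation.
#' @return a `GeneSet` data.frame.
#' @export
gene_set <- function(genes, genome = NULL) {
  need <- c("id", "scaffold", "start", "end", "strand")
  if (nrow(genes) == 0) {
    genes <- data.frame(id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character())
  }
  if (!all(need %in% names(genes))) stop("GeneSet needs columns: ",
                                         paste(need, collapse = ", "))
  genes <- genes[, need]
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (!is.null(genome)) {
    bad <- !genes$scaffold %in% names(genome$scaffolds)
    if (any(bad)) stop("gene '", genes$id[bad][1], "' on unknown scaffold '",
                       genes$scaffold[bad][1], "'")
    over <- genes$end > genome$lengths[genes$scaffold]
    if (any(over)) stop("gene '", genes$id[over][1],
                        "' extends beyond its scaffold")
  }
  class(genes) <- c("GeneSet", "data.frame")
  genes
}

#' Load gene annotations from GFF3
#'
#' Coordinates on disk are 1-based inclusive and converted to the internal
#' 0-based half-open convention. Only features of type `gene` are kept; if
#' the file contains no `gene` features, all features are used.
#'
#' @param path GFF3 file.
#' @param genome GenomeSet the annotation refers to.
#' @return a [gene_set()].
#' @export
load_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) && "type" %in% names(S4Vectors::mcols(gr))) {
    g <- gr[S4Vectors::mcols(gr)$type == "gene"]
    if (length(g)) gr <- g
  }
  ids <- if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
    else paste0("gene", seq_along(gr))
  } else character()
  df <- data.frame(
    id = ids,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"))
  gene_set(df, genome)
}

#' Write a GeneSet to GFF3
#' @param genes a GeneSet.
#' @param path output path.
#' @export
write_annotation <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    lines <- sprintf("%s\tmulescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$scaffold, genes$start + 1L, genes$end,
                     genes$strand, genes$id)
    writeLines(lines, con)
  }
  invisible(path)
}

# element table --------------------------------------------------------------

# Normalize a list of AnnotatedElement / DerivativeElement objects (or an
# already-flat data.frame) into the flat table used by the exporters.
elements_table <- function(elements) {
  if (is.data.frame(elements)) return(elements)
  rows <- lapply(seq_along(elements), function(i) {
    e <- elements[[i]]
    data.frame(
      id = if (!is.null(e$id)) e$id else paste0("element", i),
      scaffold = e$scaffold,
      start = e$span[1], end = e$span[2],
      strand = if (!is.null(e$strand)) e$strand else "+",
      type = if (inherits(e, "DerivativeElement")) "derivative" else "full",
      tir_len = if (!is.null(e$tir)) e$tir$length else NA_integer_,
      tsd_len = if (!is.null(e$tsd)) e$tsd$length else NA_integer_,
      tsd_seq = if (!is.null(e$tsd)) e$tsd$left else NA_character_)
  })
  do.call(rbind, rows)
}

#' Export elements to GFF3 or BED
#'
#' GFF3 is written 1-based inclusive, BED 0-based half-open. TIR and TSD
#' annotations are carried as GFF3 attributes (`tir_len`, `TSD`, `tsd_seq`)
#' or extra BED columns.
#'
#' @param elements list of annotated/derivative elements or a flat
#'   data.frame with columns `id, scaffold, start, end, strand` and optional
#'   `type, tir_len, tsd_len, tsd_seq`.
#' @param path output file.
#' @param dialect `"gff3"` or `"bed"`.
#' @export
export_elements <- function(elements, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  tab <- elements_table(elements)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gff3") {
    writeLines("##gff-version 3", con)
    if (nrow(tab)) {
      attrs <- sprintf("ID=%s", tab$id)
      if ("type" %in% names(tab))
        attrs <- paste0(attrs, ";element_type=", tab$type)
      if ("tir_len" %in% names(tab))
        attrs <- ifelse(is.na(tab$tir_len), attrs,
                        sprintf("%s;tir_len=%d", attrs, tab$tir_len))
      if ("tsd_len" %in% names(tab))
        attrs <- ifelse(is.na(tab$tsd_len), attrs,
                        sprintf("%s;TSD=%d;tsd_seq=%s", attrs, tab$tsd_len,
                                tab$tsd_seq))
      writeLines(sprintf("%s\tmulescan\ttransposable_element\t%d\t%d\t.\t%s\t.\t%s",
                         tab$scaffold, tab$start + 1L, tab$end,
                         ifelse(tab$strand %in% c("+", "-"), tab$strand, "+"),
                         attrs), con)
    }
  } else {
    writeLines('track name="mulescan_elements"', con)
    if (nrow(tab)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", tab$scaffold, tab$start, tab$end,
                         tab$id), con)
    }
  }
  invisible(path)
}

#' Re-import an exported element file
#'
#' Inverse of [export_elements()]; used for round-trip checks and for
#' feeding externally curated element sets back into the pipeline.
#'
#' @param path file written by [export_elements()].
#' @param dialect `"gff3"` or `"bed"`.
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
import_elements <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    data.frame(
      id = as.character(mc$ID),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
      type = if ("element_type" %in% names(mc)) as.character(mc$element_type)
             else NA_character_,
      tir_len = if ("tir_len" %in% names(mc))
        as.integer(as.character(mc$tir_len)) else NA_integer_,
      tsd_len = if ("TSD" %in% names(mc))
        as.integer(as.character(mc$TSD)) else NA_integer_,
      tsd_seq = if ("tsd_seq" %in% names(mc)) as.character(mc$tsd_seq)
                else NA_character_)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(
      id = as.character(S4Vectors::mcols(gr)$name),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr))
  }
}

# config ----------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Central registry of tunable thresholds. Values can be overridden from a
#' YAML file via [load_config()].
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    search_evalue = 1e-3,       # permissive translated-search cutoff
    filter_evalue = 1e-15,      # post-filter for significant DDE hits
    derivative_evalue = 1e-10,  # terminal-match significance for derivatives
    family_identity = 0.95,     # within-family similarity threshold
    tir_min_len = 50L,
    tir_min_identity = 0.8,
    tsd_len_range = c(8L, 10L),
    boundary_window = 20L,      # bp, boundary similarity window
    boundary_min_identity = 0.8,
    pack_min_identity = 0.7,
    pack_min_len = 100L,
    proximity_window = 5000L,   # bp, genic-proximity window (genome scale)
    null_replicates = 1000L
  )
}

#' Load configuration from YAML, merged over defaults
#' @param path YAML file; keys override [default_config()].
#' @return named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    usr <- yaml::read_yaml(path)
    for (k in names(usr)) cfg[[k]] <- usr[[k]]
  }
  cfg
}

# logging ---------------------------------------------------------------------

mulescan_log_level <- new.env(parent = emptyenv())

#' Set verbosity of pipeline messages
#' @param level one of `"quiet"`, `"info"`, `"debug"`.
#' @export
set_log_level <- function(level = c("info", "quiet", "debug")) {
  mulescan_log_level$level <- match.arg(level)
  invisible(mulescan_log_level$level)
}

log_msg <- function(..., level = "info") {
  cur <- if (is.null(mulescan_log_level$level)) "info" else mulescan_log_level$level
  rank <- c(quiet = 0, info = 1, debug = 2)
  if (rank[[level]] <= rank[[cur]] && cur != "quiet")
    message("[mulescan] ", sprintf(...))
  invisible(NULL)
}
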