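# Genic-proximity classification of insertion sites, randomized-null
# enrichment, and insertion-site position-frequency matrices.

#' Classify a site by proximity to annotated genes
#'
#' `gene_body` when the position falls inside a gene span; `within_window`
#' when the distance to the nearest gene edge is at most `window` bp
#' (inclusive, strand-ignored); otherwise `distal`. Ties resolve toward the
#' more genic category.
#'
#' @param site list/vector with `scaffold` and `pos` (0-based), or a
#'   data.frame of such sites.
#' @param genes GeneSet.
#' @param window proximity window in bp.
#' @param genome optional GenomeSet for scaffold validation.
#' @return character vector of categories.
#' @export
classify_proximity <- function(site, genes, window = 5000L, genome = NULL) {
  sites <- if (is.data.frame(site)) site
           else data.frame(scaffold = site$scaffold, pos = site$pos)
  if (!is.null(genome)) {
    bad <- !sites$scaffold %in% names(genome$scaffolds)
    if (any(bad)) stop("site on unknown scaffold '", sites$scaffold[bad][1], "'")
  }
  vapply(seq_len(nrow(sites)), function(i) {
    g <- genes[genes$scaffold == sites$scaffold[i], , drop = FALSE]
    if (!nrow(g)) return("distal")
    pos <- sites$pos[i]
    if (any(pos >= g$start & pos < g$end)) return("gene_body")
    d <- min(pmin(abs(pos - (g$end - 1L)), abs(g$start - pos)))
    if (d <= window) "within_window" else "distal"
  }, character(1))
}

# Interval-based bulk classification equivalent to classify_proximity():
# per scaffold, gene bodies and window-extended zones are reduced to
# disjoint interval sets and sites are classified by overlap.
classify_bulk <- function(sites, genes, window, lengths) {
  out <- rep("distal", nrow(sites))
  for (sc in unique(sites$scaffold)) {
    si <- which(sites$scaffold == sc)
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (!nrow(g)) next
    L <- lengths[[sc]]
    body <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    winz <- IRanges::reduce(IRanges::IRanges(pmax(1L, g$start + 1L - window),
                                             pmin(L, g$end + window)))
    p <- IRanges::IRanges(sites$pos[si] + 1L, sites$pos[si] + 1L)
    in_body <- IRanges::overlapsAny(p, body)
    in_win <- IRanges::overlapsAny(p, winz)
    out[si][in_win] <- "within_window"
    out[si][in_body] <- "gene_body"
  }
  out
}

#' Randomized null distribution of genic-proximity counts
#'
#' Each replicate draws `n_sites` positions uniformly over the total genome
#' length (scaffolds weighted by length), classifies them, and accumulates
#' per-category counts; the null mean and SD across replicates are
#' returned.
#'
#' @param genome GenomeSet.
#' @param genes GeneSet.
#' @param n_sites sites per replicate (>= 1).
#' @param window proximity window, bp.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return list with `mean`, `sd` (named per category), `n_sites`,
#'   `n_replicates`, `window`, `seed`, `replicates` (matrix of counts).
#' @export
random_null <- function(genome, genes, n_sites, window = 5000L,
                        n_replicates = 1000L, seed = 1L) {
  stopifnot(n_sites >= 1, n_replicates >= 1)
  cats <- c("gene_body", "within_window", "distal")
  lens <- as.numeric(genome$lengths)
  total <- sum(lens)
  cum <- cumsum(lens)
  scn <- names(genome$lengths)
  n_draw <- n_sites * n_replicates
  df <- with_seed(seed, {
    u <- floor(runif(n_draw) * total)
    idx <- findInterval(u, cum) + 1L
    data.frame(scaffold = scn[idx], pos = as.integer(u - c(0, cum)[idx]),
               rep = rep(seq_len(n_replicates), each = n_sites))
  })
  cl <- classify_bulk(df, genes, window, genome$lengths)
  counts <- matrix(0L, n_replicates, 3, dimnames = list(NULL, cats))
  for (k in seq_along(cats)) {
    t <- tabulate(df$rep[cl == cats[k]], nbins = n_replicates)
    counts[, k] <- t
  }
  list(mean = colMeans(counts),
       sd = apply(counts, 2, sd),
       n_sites = n_sites, n_replicates = n_replicates, window = window,
       seed = seed, replicates = counts)
}

#' Enrichment z-scores of observed counts against the randomized null
#'
#' z = (observed - null mean) / null SD per category. A zero-SD category
#' with observed == mean scores 0; zero SD with a discrepant observation is
#' flagged infinite.
#'
#' @param observed named counts per category (gene_body, within_window,
#'   distal).
#' @param null a [random_null()] result.
#' @return an `EnrichmentResult`: list with `observed`, `null_mean`,
#'   `null_sd`, `z`, `infinite` (logical per category), plus the null's
#'   metadata.
#' @export
enrichment <- function(observed, null) {
  cats <- names(null$mean)
  obs <- setNames(numeric(length(cats)), cats)
  obs[names(observed)] <- as.numeric(observed)
  z <- setNames(numeric(length(cats)), cats)
  inf <- setNames(logical(length(cats)), cats)
  for (k in cats) {
    if (null$sd[[k]] > 0) {
      z[[k]] <- (obs[[k]] - null$mean[[k]]) / null$sd[[k]]
    } else if (obs[[k]] == null$mean[[k]]) {
      z[[k]] <- 0
    } else {
      z[[k]] <- ifelse(obs[[k]] > null$mean[[k]], Inf, -Inf)
      inf[[k]] <- TRUE
    }
  }
  structure(list(observed = obs, null_mean = null$mean, null_sd = null$sd,
                 z = z, infinite = inf, n_sites = null$n_sites,
                 n_replicates = null$n_replicates, window = null$window,
                 seed = null$seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult (%d sites vs %d randomized replicates, window %d bp)\n",
              x$n_sites, x$n_replicates, x$window))
  for (k in names(x$observed)) {
    cat(sprintf("  %-14s obs %5.0f  null %7.2f +/- %5.2f  z %6.2f\n", k,
                x$observed[[k]], x$null_mean[[k]], x$null_sd[[k]], x$z[[k]]))
  }
  invisible(x)
}

#' Position frequency matrix of insertion-site windows
#'
#' Per-position base counts over equal-length windows centered on the
#' insertion point, with per-position information content under a uniform
#' background: IC_j = 2 + sum_b f_bj log2 f_bj.
#'
#' @param site_sequences character vector of equal-length DNA windows.
#' @return a `PositionFrequencyMatrix`: list with `counts` (4 x width),
#'   `ic` (bits per position), `n`, `width`.
#' @export
build_pfm <- function(site_sequences) {
  if (!length(site_sequences)) stop("no sequences")
  w <- unique(nchar(site_sequences))
  if (length(w) != 1) stop("windows differ in length")
  m <- do.call(rbind, strsplit(site_sequences, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
      G = sum(m[, j] == "G"), T = sum(m[, j] == "T"))
  }, numeric(4))
  ic <- vapply(seq_len(w), function(j) {
    f <- counts[, j] / sum(counts[, j])
    f <- f[f > 0]
    max(0, min(2, 2 + sum(f * log2(f))))
  }, numeric(1))
  structure(list(counts = counts, ic = ic, n = length(site_sequences),
                 width = w),
            class = "PositionFrequencyMatrix")
}

#' @export
print.PositionFrequencyMatrix <- function(x, ...) {
  cat(sprintf("PositionFrequencyMatrix: %d sequences x %d positions, mean IC %.3f bits\n",
              x$n, x$width, mean(x$ic)))
  invisible(x)
}
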