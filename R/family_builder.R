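# Family clustering of DDE hits and the bootstrap neighbor-joining
# phylogeny of the translated catalytic domains.

#' Center-star progressive multiple alignment
#'
#' Picks the sequence with the highest summed pairwise global-alignment
#' score as the center, aligns every other sequence to it, and merges the
#' pairwise alignments under the once-a-gap-always-a-gap rule. Intended for
#' closely related domain sequences where topology-level downstream results
#' (distances, trees) matter more than individual columns.
#'
#' @param seqs character vector (>= 2) of peptide or DNA sequences;
#'   names are preserved.
#' @param type `"protein"` or `"dna"`.
#' @return named character vector of aligned rows (equal length; removing
#'   `-` recovers the inputs).
#' @export
align_peptides <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 2) {
    al <- global_align(seqs[[1]], seqs[[2]], type = type)
    out <- c(al$query_aln, al$subject_aln)
    names(out) <- names(seqs)
    return(out)
  }
  score <- matrix(0, n, n)
  alns <- vector("list", n * n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(seqs[[i]], seqs[[j]], type = type)
      score[i, j] <- score[j, i] <- al$score
      alns[[(i - 1) * n + j]] <- al
    }
  }
  center <- which.max(rowSums(score))
  lc <- nchar(seqs[[center]])
  # per-sequence gap counts between center residues (slot 0..lc)
  gaps <- matrix(0L, n, lc + 1)
  parsed <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == center) next
    al <- if (i > center) alns[[(center - 1) * n + i]]
          else {
            a <- alns[[(i - 1) * n + center]]
            list(query_aln = a$subject_aln, subject_aln = a$query_aln)
          }
    ca <- seq_chars(al$query_aln)    # center row
    sa <- seq_chars(al$subject_aln)
    slot <- 0L
    ins <- vector("list", lc + 1)
    for (s in seq_len(lc + 1)) ins[[s]] <- character()
    onto <- character(lc)            # subject char aligned to center residue
    for (col in seq_along(ca)) {
      if (ca[col] == "-") {
        ins[[slot + 1L]] <- c(ins[[slot + 1L]], sa[col])
      } else {
        slot <- slot + 1L
        onto[slot] <- sa[col]
      }
    }
    gaps[i, ] <- vapply(ins, length, integer(1))
    parsed[[i]] <- list(ins = ins, onto = onto)
  }
  g <- apply(gaps, 2, max)
  rows <- character(n)
  # center row
  parts <- character()
  cc <- seq_chars(seqs[[center]])
  for (s in 0:lc) {
    parts <- c(parts, strrep("-", g[s + 1]))
    if (s < lc) parts <- c(parts, cc[s + 1])
  }
  rows[center] <- paste(parts, collapse = "")
  for (i in seq_len(n)) {
    if (i == center) next
    p <- parsed[[i]]
    parts <- character()
    for (s in 0:lc) {
      own <- paste(p$ins[[s + 1]], collapse = "")
      parts <- c(parts, own, strrep("-", g[s + 1] - nchar(own)))
      if (s < lc) parts <- c(parts, p$onto[s + 1])
    }
    rows[i] <- paste(parts, collapse = "")
  }
  names(rows) <- names(seqs)
  rows
}

#' Proportion-distance matrix from a multiple alignment
#'
#' d(i, j) = mismatches / compared sites, ignoring columns where either row
#' carries a gap.
#'
#' @param alignment named character vector of equal-length rows.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 3) stop("need at least 3 rows for a distance matrix")
  if (length(unique(nchar(alignment))) != 1) stop("rows differ in length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("rows ", i, " and ", j, " share no comparable sites")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Deterministic agglomeration: ties on the minimum Q criterion are broken
#' by the smallest (i, j) index pair; negative branch lengths are clamped
#' to zero. The result is the standard unrooted NJ topology.
#'
#' @param dist square symmetric distance matrix with row/column names,
#'   n >= 3.
#' @return a `PhyloTree`: list with `newick`, `leaves`, `splits` (canonical
#'   internal bipartitions as `|`-joined sorted leaf names on the side not
#'   containing the first leaf), and `support` (NULL until
#'   [bootstrap_support()] is run).
#' @export
neighbor_joining <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("distance matrix must be square")
  if (max(abs(dist - t(dist))) > 1e-9) stop("distance matrix must be symmetric")
  n0 <- nrow(dist)
  if (n0 < 3) stop("need at least 3 taxa")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  d <- dist
  nodes <- lapply(labels, function(x) list(nwk = x, leaves = x))
  splits <- character()
  all_leaves <- labels

  canonical_split <- function(leaves) {
    side <- if (all_leaves[1] %in% leaves) setdiff(all_leaves, leaves) else leaves
    if (length(side) < 2 || length(side) > length(all_leaves) - 2) return(NULL)
    paste(sort(side), collapse = "|")
  }

  while (length(nodes) > 3) {
    n <- length(nodes)
    r <- rowSums(d)
    best <- NULL
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- list(
      nwk = sprintf("(%s:%.10g,%s:%.10g)", nodes[[i]]$nwk, li,
                    nodes[[j]]$nwk, lj),
      leaves = c(nodes[[i]]$leaves, nodes[[j]]$leaves))
    sp <- canonical_split(new_node$leaves)
    if (!is.null(sp)) splits <- c(splits, sp)
    keep <- setdiff(seq_len(n), c(i, j))
    dk <- 0.5 * (d[i, keep] + d[j, keep] - d[i, j])
    d2 <- matrix(0, n - 1, n - 1)
    d2[1:(n - 2), 1:(n - 2)] <- d[keep, keep, drop = FALSE]
    d2[n - 1, 1:(n - 2)] <- dk
    d2[1:(n - 2), n - 1] <- dk
    d <- d2
    nodes <- c(nodes[keep], list(new_node))
  }
  # resolve the final three nodes with the three-point formulas
  l1 <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  l2 <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  l3 <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  ls <- pmax(c(l1, l2, l3), 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[[1]]$nwk, ls[1],
                    nodes[[2]]$nwk, ls[2], nodes[[3]]$nwk, ls[3])
  structure(list(newick = newick, leaves = all_leaves,
                 splits = unique(splits), support = NULL),
            class = "PhyloTree")
}

#' @export
print.PhyloTree <- function(x, ...) {
  cat(sprintf("PhyloTree: %d leaves, %d internal splits\n", length(x$leaves),
              length(x$splits)))
  cat(" ", x$newick, "\n")
  if (!is.null(x$support)) {
    cat("  bootstrap support:",
        paste(sprintf("%.0f", x$support), collapse = " "), "\n")
  }
  invisible(x)
}

#' Bootstrap support for the internal bipartitions of the NJ tree
#'
#' Alignment columns are resampled with replacement; each replicate tree is
#' rebuilt with [neighbor_joining()] on p-distances, and support is the
#' percentage of replicates containing each internal bipartition of the
#' full-data tree.
#'
#' @param alignment named character vector of aligned rows (>= 4).
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return the full-data `PhyloTree` with `support` filled in (named
#'   percentages in `[0, 100]`, one per internal split).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  if (length(alignment) < 4) stop("need >= 4 rows for bootstrap supports")
  if (n_reps < 1) stop("n_reps must be >= 1")
  d <- p_distance_matrix(alignment)
  if (all(d == 0))
    stop("degenerate distances: all sequences identical, no tree is defined")
  full <- neighbor_joining(d)
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  ncol_a <- ncol(m)
  counts <- setNames(numeric(length(full$splits)), full$splits)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
      rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      db <- tryCatch(p_distance_matrix(rows), error = function(e) NULL)
      if (is.null(db)) next
      tb <- neighbor_joining(db)
      hit <- full$splits %in% tb$splits
      counts[hit] <- counts[hit] + 1
    }
  })
  full$support <- 100 * counts / n_reps
  full
}

#' Cluster element sequences into families by pairwise identity
#'
#' Single-linkage: two sequences are linked when their global-alignment
#' identity exceeds `identity_threshold`, and families are the connected
#' components. Matches the notion that all members of a family share high
#' similarity transitively.
#'
#' @param seqs named character vector of sequences (nucleotide elements by
#'   default; translated domains also work with `type = "protein"`).
#' @param identity_threshold linkage threshold (exclusive).
#' @param type `"dna"` or `"protein"`.
#' @return a `FamilySet`: list with `assignments` (named integer vector),
#'   `families` (list of `id`, `members`, `min_identity`), `n_families`.
#' @export
cluster_families <- function(seqs, identity_threshold = 0.95,
                             type = c("dna", "protein")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 0) {
    return(structure(list(assignments = integer(), families = list(),
                          n_families = 0L), class = "FamilySet"))
  }
  ident <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ident[i, j] <- ident[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]],
                                                        type = type)
      }
    }
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (ident[i, j] > identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fam_ids <- match(roots, unique(roots))
  families <- lapply(seq_along(unique(roots)), function(f) {
    members <- names(seqs)[fam_ids == f]
    idx <- which(fam_ids == f)
    mi <- if (length(idx) > 1) min(ident[idx, idx][upper.tri(diag(length(idx)))])
          else 1
    list(id = sprintf("family%02d", f), members = members, min_identity = mi)
  })
  structure(list(assignments = setNames(fam_ids, names(seqs)),
                 families = families, n_families = length(families)),
            class = "FamilySet")
}

#' Global-alignment identity of two sequences
#'
#' Matching columns divided by total alignment columns.
#'
#' @param a,b sequences.
#' @param type `"dna"` or `"protein"`.
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (a == b) return(1)
  al <- global_align(a, b, type = type)
  ca <- seq_chars(al$query_aln)
  cb <- seq_chars(al$subject_aln)
  sum(ca == cb & ca != "-") / length(ca)
}
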