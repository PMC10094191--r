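#' Read a protein alignment from FASTA
#'
#' @param path Path to an aligned amino-acid FASTA file (equal-length rows;
#'   `-` for gaps).
#' @return A tibble with columns `taxon` and `sequence` (uppercase).
#' @export
read_protein_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(taxon = sub("\\s.*$", "", names(set)),
                 sequence = toupper(unname(as.character(set))))
}

# alignment tibble -> taxa x sites character matrix, validated
.aln_matrix <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("taxon", "sequence") %in% names(aln)))
  len <- nchar(aln$sequence)
  if (length(unique(len)) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(aln$sequence), ""))
  rownames(m) <- aln$taxon
  m
}

#' Poisson-corrected amino-acid distances
#'
#' Complete deletion first: every column containing a gap (`-`), `?` or `X`
#' in any taxon is dropped. For each pair, p is the proportion of retained
#' columns at which the two sequences differ and the distance is the
#' Poisson correction d = -ln(1 - p), which accounts for multiple
#' substitutions at a site under uniform rates.
#'
#' @param aln An alignment tibble from [read_protein_alignment()].
#' @return A symmetric matrix of distances with taxon dimnames and zero
#'   diagonal.
#' @export
poisson_distance <- function(aln) {
  m <- .aln_matrix(aln)
  keep <- colSums(m == "-" | m == "?" | m == "X") == 0L
  if (!any(keep))
    stop("complete deletion removed every column", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- mean(m[i, ] != m[j, ])
    if (p >= 1)
      stop("saturated pair (p = 1): ", rownames(m)[i], " vs ",
           rownames(m)[j], "; Poisson distance infinite", call. = FALSE)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the given distances. Taxa are ordered
#' lexicographically before joining so ties resolve by label, independent
#' of input order. Negative branch lengths are clamped to zero; the total
#' clamped amount is attached as attribute `"clamped"`.
#'
#' @param dm A symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (is.null(rownames(dm)))
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (nrow(dm) < 3L) stop("need at least 3 taxa", call. = FALSE)
  ord <- order(rownames(dm))
  tr <- ape::nj(dm[ord, ord])
  clamped <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

# nj on a site matrix, with saturation guarded for bootstrap resamples
.nj_from_sites <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    p <- min(mean(m[i, ] != m[j, ]), 1 - 1e-9)
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  neighbor_joining(d)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from Poisson-corrected distances on the
#' complete-deletion alignment, then resamples alignment columns with
#' replacement `replicates` times, rebuilds the tree each time, and reports
#' for each internal edge of the full-data tree the percentage of
#' replicates recovering its bipartition. Reproducible given `seed`; only
#' column indices are drawn, so supports do not depend on taxon order.
#'
#' @param aln An alignment tibble from [read_protein_alignment()].
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for column resampling.
#' @return The full-data `phylo` tree with `node.label` holding supports
#'   in percent (root label empty).
#' @export
bootstrap_supports <- function(aln, replicates = 1000, seed = 1L) {
  stopifnot(replicates >= 1)
  m <- .aln_matrix(aln)
  keep <- colSums(m == "-" | m == "?" | m == "X") == 0L
  if (!any(keep))
    stop("complete deletion removed every column", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  full <- .nj_from_sites(m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- replicate(replicates, sample.int(ncol(m), replace = TRUE),
                   simplify = FALSE)
  boots <- lapply(idx, function(i) .nj_from_sites(m[, i, drop = FALSE]))
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""   # root of the unrooted representation
  attr(full, "replicates") <- replicates
  attr(full, "seed") <- seed
  full
}

# save/restore the global RNG state so seeded helpers don't perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object; internal node labels (e.g. bootstrap
#'   supports) are preserved.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
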