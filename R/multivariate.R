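# widen an RSCU table and impute undefined cells with the codon column mean
.rscu_matrix <- function(x) {
  if (!is.data.frame(x)) stop("expected a data frame", call. = FALSE)
  wide <- if ("rscu" %in% names(x) && "codon" %in% names(x))
    codon_wide(x, "rscu") else x
  m <- as.matrix(wide[, setdiff(names(wide), "gene_id")])
  rownames(m) <- wide$gene_id
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
  }
  attr(m, "n_imputed") <- n_imputed
  m
}

#' Correspondence analysis of an RSCU matrix
#'
#' Classical (chi-square metric) correspondence analysis of the gene-by-
#' codon RSCU table: the table is scaled to proportions, standardized
#' residuals from the independence model are formed and decomposed by SVD,
#' and genes and codons are returned in principal coordinates. The inertia
#' fraction of axis a is its squared singular value over the total. Each
#' axis's sign is fixed by making the codon with the largest absolute
#' coordinate positive. Undefined RSCU cells (a family absent from a gene)
#' are imputed with the codon's column mean before analysis; the number of
#' imputed cells is reported.
#'
#' @param x An RSCU tibble from [rscu()] (two or more genes) or a wide
#'   gene-by-codon data frame with a `gene_id` column.
#' @param k Number of axes to retain; defaults to all non-trivial axes,
#'   min(genes, codons) - 1, truncated to the numerical rank.
#' @return An object of class `codon_ca` with elements `gene_coords` and
#'   `codon_coords` (tibbles, one coordinate column per axis), `inertia`
#'   (tibble with `axis`, `singular_value`, `inertia`, `fraction`), `k`,
#'   `total_inertia` and `n_imputed`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
correspondence_analysis <- function(x, k = NULL) {
  m <- .rscu_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0))
    stop("zero row margin for gene(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  if (any(cs == 0))
    stop("zero column margin for codon(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  attr(S, "n_imputed") <- NULL
  sv <- svd(S)
  kmax <- min(nrow(m), ncol(m)) - 1L
  keep <- which(sv$d > max(sv$d[1], 0) * 1e-10 & sv$d > 1e-12)
  keep <- keep[keep <= kmax]
  if (!is.null(k)) keep <- keep[seq_len(min(k, length(keep)))]
  total_inertia <- sum(sv$d[seq_len(kmax)]^2)
  if (length(keep) == 0L || total_inertia < 1e-12) {
    res <- structure(list(
      gene_coords = tibble::tibble(gene_id = rownames(m)),
      codon_coords = tibble::tibble(codon = colnames(m)),
      inertia = tibble::tibble(axis = integer(), singular_value = numeric(),
                               inertia = numeric(), fraction = numeric()),
      k = 0L, total_inertia = 0,
      n_imputed = attr(m, "n_imputed"), residuals = S,
      row_mass = r, col_mass = cc), class = "codon_ca")
    return(res)
  }
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: dominant codon loading positive on every axis
  for (a in seq_along(keep)) {
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) { V[, a] <- -V[, a]; U[, a] <- -U[, a] }
  }
  gene_pc <- sweep(U, 1, sqrt(r), "/") %*% diag(d, length(d))
  codon_pc <- sweep(V, 1, sqrt(cc), "/") %*% diag(d, length(d))
  axes <- paste0("axis", seq_along(keep))
  colnames(gene_pc) <- axes; colnames(codon_pc) <- axes
  structure(list(
    gene_coords = dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(gene_pc)),
    codon_coords = dplyr::bind_cols(
      tibble::tibble(codon = colnames(m)), tibble::as_tibble(codon_pc)),
    inertia = tibble::tibble(axis = seq_along(keep), singular_value = d,
                             inertia = d^2, fraction = d^2 / total_inertia),
    k = length(keep), total_inertia = total_inertia,
    n_imputed = attr(m, "n_imputed"), residuals = S,
    row_mass = r, col_mass = cc), class = "codon_ca")
}

#' @export
print.codon_ca <- function(x, ...) {
  cat("Correspondence analysis of codon usage\n")
  cat("  genes:", nrow(x$gene_coords), " codons:", nrow(x$codon_coords),
      " axes retained:", x$k, "\n")
  if (x$k == 0L) {
    cat("  degenerate: no variation in the table\n")
  } else {
    f <- utils::head(x$inertia$fraction, 2)
    cat(sprintf("  inertia: axis 1 %.1f%%%s of total %.4g\n", 100 * f[1],
                if (length(f) > 1) sprintf(", axis 2 %.1f%%", 100 * f[2])
                else "", x$total_inertia))
  }
  if (x$n_imputed > 0)
    cat("  imputed", x$n_imputed, "undefined RSCU cell(s) with column means\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correspondence-analysis result
#'
#' @param x A `codon_ca` object.
#' @param type `"coords"` (default; gene and codon coordinates long, with a
#'   `point` column saying which) or `"inertia"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy codon_ca
#' @export
tidy.codon_ca <- function(x, type = c("coords", "inertia"), ...) {
  type <- match.arg(type)
  if (type == "inertia") return(x$inertia)
  dplyr::bind_rows(
    x$gene_coords |> dplyr::rename(label = "gene_id") |>
      dplyr::mutate(point = "gene", .before = 1),
    x$codon_coords |> dplyr::rename(label = "codon") |>
      dplyr::mutate(point = "codon", .before = 1))
}

#' One-row summary of a correspondence-analysis result
#'
#' @param x A `codon_ca` object.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_codons`, `k`, `total_inertia`,
#'   `fraction_axis1`, `fraction_axis2`, `n_imputed`.
#' @method glance codon_ca
#' @export
glance.codon_ca <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$gene_coords), n_codons = nrow(x$codon_coords),
    k = x$k, total_inertia = x$total_inertia,
    fraction_axis1 = if (x$k >= 1) x$inertia$fraction[1] else NA_real_,
    fraction_axis2 = if (x$k >= 2) x$inertia$fraction[2] else NA_real_,
    n_imputed = x$n_imputed)
}

#' Hierarchical clustering of RSCU profiles
#'
#' Agglomerates genes by the chosen linkage on Euclidean distances between
#' their 59-dimensional RSCU vectors. Genes are ordered lexicographically
#' by id before clustering so the result does not depend on input order;
#' undefined RSCU cells are imputed with codon column means as in
#' [correspondence_analysis()].
#'
#' @param x An RSCU tibble or wide gene-by-codon data frame.
#' @param metric Distance metric; only `"euclidean"`.
#' @param linkage `"average"` (default), `"ward"` (Ward.D2) or
#'   `"complete"`.
#' @return An `hclust` object (subclass `codon_hclust`) with attributes
#'   `metric` and `linkage`; use [stats::cutree()] for flat clusters and
#'   [write_newick_dendrogram()] to export.
#' @export
cluster_rscu <- function(x, metric = "euclidean",
                         linkage = c("average", "ward", "complete")) {
  metric <- match.arg(metric, "euclidean")
  linkage <- match.arg(linkage)
  m <- .rscu_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 genes", call. = FALSE)
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- stats::dist(m, method = metric)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  h <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  h$call <- NULL
  attr(h, "metric") <- metric
  attr(h, "linkage") <- linkage
  class(h) <- c("codon_hclust", "hclust")
  h
}

#' Write a dendrogram as Newick
#'
#' Branch lengths derive from merge heights.
#'
#' @param h An `hclust` object, e.g. from [cluster_rscu()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_dendrogram <- function(h, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(h)), file = path)
  invisible(path)
}

#' Pairwise Pearson correlation panel
#'
#' All unordered pairs of the chosen numeric variables, with two-sided p
#' from the t distribution and pairwise-complete observations. A
#' zero-variance variable gives `NA` correlations for its pairs with a
#' warning, not an error.
#'
#' @param data A data frame, e.g. an index table from
#'   [codon_usage_indices()], optionally joined with CA axis coordinates.
#' @param vars Variables to correlate; default all numeric columns.
#' @param include_self Include the trivial diagonal pairs (default FALSE).
#' @return A tibble with `var1`, `var2`, `r`, `p`, `n`.
#' @export
correlation_panel <- function(data, vars = NULL, include_self = FALSE) {
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2L) stop("need at least two variables", call. = FALSE)
  pairs <- utils::combn(vars, 2L)
  if (include_self) pairs <- cbind(pairs, rbind(vars, vars))
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ok <- stats::complete.cases(data[[v1]], data[[v2]])
    n <- sum(ok)
    x <- data[[v1]][ok]; y <- data[[v2]][ok]
    if (v1 == v2)
      return(tibble::tibble(var1 = v1, var2 = v2, r = 1, p = NA_real_,
                            n = n))
    if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("correlation undefined for ", v1, " vs ", v2, call. = FALSE)
      return(tibble::tibble(var1 = v1, var2 = v2, r = NA_real_,
                            p = NA_real_, n = n))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(var1 = v1, var2 = v2, r = unname(ct$estimate),
                   p = ct$p.value, n = n)
  })
}
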