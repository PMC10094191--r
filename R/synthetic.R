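# Default amino-acid composition of generated genes: family totals of the
# pooled XET study set (4500 synonymous codons over 18 families), so
# synthetic genes exercise the same family-size structure as the real data.
.default_aa_weights <- c(
  F = 326, L = 288, I = 207, V = 278, S = 322, P = 239, T = 263, A = 308,
  Y = 255, H = 102, Q = 217, N = 198, K = 245, D = 336, E = 174, C = 79,
  R = 298, G = 365)

#' Within-family codon sampling probabilities of the generator
#'
#' Each synonymous codon gets unnormalized weight (b * t)^concentration,
#' where b = `gc3_bias` if the codon ends in G or C and 1 - `gc3_bias`
#' otherwise, and t = 1 + 0.001 * (family_size - rank) is a tiny
#' deterministic tie-break (alphabetical rank within the family) so that a
#' degenerate concentration selects a single codon per family. Weights are
#' normalized within each family; `concentration = 0` gives uniform use,
#' larger values concentrate mass on the favored third-position bases, and
#' `concentration = Inf` is fully degenerate.
#'
#' @param gc3_bias Probability mass steered to G/C-ending synonyms, in
#'   [0, 1]; 0.5 is neutral.
#' @param concentration Within-family skew exponent, >= 0 (default 1).
#' @return A tibble with `codon`, `aa`, `third` and `prob` (probabilities
#'   summing to 1 within each family) over the 59 synonymous codons.
#' @export
codon_probabilities <- function(gc3_bias = 0.5, concentration = 1) {
  stopifnot(gc3_bias >= 0, gc3_bias <= 1, concentration >= 0)
  code <- .code_table()
  syn <- code[code$synonymous, c("codon", "aa", "family_size", "third")]
  syn |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(
      b = ifelse(.data$third %in% c("G", "C"), gc3_bias, 1 - gc3_bias),
      base = .data$b * (1 + 1e-3 * (dplyr::n() - dplyr::row_number())),
      w = if (is.infinite(concentration))
        as.numeric(.data$base == max(.data$base))
      else .data$base^concentration,
      w = if (sum(.data$w) > 0) .data$w else rep(1, dplyr::n()),
      prob = .data$w / sum(.data$w)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "aa", "third", "prob")
}

#' Expected GC3s of generated genes
#'
#' Closed-form expectation of the synonymous G/C-ending fraction implied by
#' the generator's amino-acid composition and within-family probabilities,
#' for checking that simulated data match their own specification.
#'
#' @inheritParams codon_probabilities
#' @param aa_weights Named amino-acid composition (relative weights over
#'   the 18 synonymous families); default mirrors the packaged study set.
#' @return Expected GC3s in percent.
#' @export
expected_gc3s <- function(gc3_bias = 0.5, concentration = 1,
                          aa_weights = NULL) {
  if (is.null(aa_weights)) aa_weights <- .default_aa_weights
  p <- codon_probabilities(gc3_bias, concentration)
  p <- p[p$aa %in% names(aa_weights), ]
  wa <- aa_weights[p$aa] / sum(aa_weights)
  100 * sum(wa * p$prob * (p$third %in% c("G", "C")))
}

#' Generate synthetic coding sequences with controlled codon usage
#'
#' Each gene draws `codons_per_gene` amino acids from a fixed composition,
#' samples a codon for each from the family probabilities of
#' [codon_probabilities()], prepends the AUG start and appends a UAA stop.
#' `gc3_bias` and `concentration` may be single values or one per gene
#' (recycled per group label if `group` is given), so two-group designs
#' with opposing third-position bias are one call. Identical arguments and
#' seed give byte-identical output.
#'
#' @param n_genes Number of genes (default 20).
#' @param codons_per_gene Synonymous-family codons per gene, excluding
#'   start and stop (default 225, matching the study's 4500 codons over 20
#'   genes).
#' @param gc3_bias Scalar or length-`n_genes` vector in [0, 1].
#' @param concentration Scalar or length-`n_genes` vector, >= 0.
#' @param group Optional group labels (length `n_genes` or recycled).
#' @param aa_weights Named amino-acid composition; see [expected_gc3s()].
#' @param seed Integer seed (default 1).
#' @return A tibble with `gene_id`, `group`, `gc3_bias`, `concentration`
#'   and `sequence` (RNA), ready for [count_codons()].
#' @export
codon_generate <- function(n_genes = 20, codons_per_gene = 225,
                           gc3_bias = 0.5, concentration = 1,
                           group = NULL, aa_weights = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, codons_per_gene >= 1)
  if (is.null(aa_weights)) aa_weights <- .default_aa_weights
  gc3_bias <- rep_len(gc3_bias, n_genes)
  concentration <- rep_len(concentration, n_genes)
  group <- if (is.null(group)) rep("all", n_genes) else
    as.character(rep_len(group, n_genes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  aas <- names(aa_weights)
  pa <- aa_weights / sum(aa_weights)
  seqs <- vapply(seq_len(n_genes), function(g) {
    probs <- codon_probabilities(gc3_bias[g], concentration[g])
    fam <- split(probs[, c("codon", "prob")], probs$aa)
    aa_draw <- sample(aas, codons_per_gene, replace = TRUE, prob = pa)
    codons <- vapply(aa_draw, function(a) {
      f <- fam[[a]]
      f$codon[sample.int(nrow(f), 1L, prob = f$prob)]
    }, character(1))
    paste0("AUG", paste(codons, collapse = ""), "UAA")
  }, character(1))
  tibble::tibble(
    gene_id = sprintf("synth%02d", seq_len(n_genes)),
    group = group, gc3_bias = gc3_bias, concentration = concentration,
    sequence = seqs)
}

#' Write coding sequences as FASTA
#'
#' @param cds A data frame with `gene_id` and `sequence`; a `description`
#'   column, if present, is appended to the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  desc <- if ("description" %in% names(cds) &&
              any(nzchar(cds$description)))
    paste0(" ", cds$description) else ""
  lines <- paste0(">", cds$gene_id, desc, "\n", cds$sequence)
  writeLines(lines, path)
  invisible(path)
}
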