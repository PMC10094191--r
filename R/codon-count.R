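#' Read coding sequences from a FASTA file
#'
#' Accepts DNA or RNA FASTA (multi-record, wrapped lines, any case). The
#' sequence is stored internally in the RNA alphabet (T converted to U) so
#' codons read the way they are usually reported.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `gene_id` (first whitespace-delimited token
#'   of the header), `sequence` (uppercase RNA) and `description` (the rest
#'   of the header line, possibly empty).
#' @export
read_cds <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  gene_id <- sub("\\s.*$", "", headers)
  description <- sub("^\\S+\\s*", "", headers)
  seqs <- toupper(chartr("T", "U", as.character(set)))
  tibble::tibble(gene_id = gene_id, sequence = unname(seqs),
                 description = description)
}

#' @keywords internal
#' @noRd
validate_cds <- function(sequence, gene_id = "<sequence>") {
  if (is.na(sequence) || nchar(sequence) == 0L)
    stop("empty sequence for gene '", gene_id, "'", call. = FALSE)
  s <- toupper(sequence)
  if (grepl("T", s, fixed = TRUE) && grepl("U", s, fixed = TRUE))
    stop("mixed DNA/RNA alphabet in gene '", gene_id, "'", call. = FALSE)
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0L)
    stop("invalid character '", substr(s, bad, bad), "' at position ", bad,
         " in gene '", gene_id, "'", call. = FALSE)
  chartr("T", "U", s)
}

#' Count codons in coding sequences
#'
#' Counts every consecutive non-overlapping triplet from position 1 of each
#' sequence. The result is a long tibble with one row per gene and codon
#' over all 64 codons, so downstream verbs can group and join freely.
#'
#' @param cds A data frame with columns `gene_id` and `sequence` (DNA or
#'   RNA), e.g. from [read_cds()] or [codon_generate()]. A bare character
#'   vector of sequences is also accepted (gene ids are made up).
#' @param frame_policy `"strict"` (default) rejects sequences whose length
#'   is not a multiple of 3; `"trim_tail"` silently drops the trailing 1-2
#'   nucleotides.
#' @return A tibble with columns `gene_id`, `codon` (RNA, alphabetical
#'   order) and `count`; 64 rows per gene.
#' @examples
#' count_codons(tibble::tibble(gene_id = "g", sequence = "AUGUGA"))
#' @export
count_codons <- function(cds, frame_policy = c("strict", "trim_tail")) {
  frame_policy <- match.arg(frame_policy)
  if (is.character(cds))
    cds <- tibble::tibble(gene_id = paste0("seq", seq_along(cds)),
                          sequence = cds)
  stopifnot(is.data.frame(cds), all(c("gene_id", "sequence") %in% names(cds)))
  codons <- codon_order()
  purrr::map2_dfr(cds$gene_id, cds$sequence, function(id, s) {
    s <- validate_cds(s, id)
    n <- nchar(s)
    if (n %% 3L != 0L) {
      if (frame_policy == "strict")
        stop("length of gene '", id, "' (", n,
             ") is not a multiple of 3; use frame_policy = \"trim_tail\" ",
             "to drop the remainder", call. = FALSE)
      s <- substr(s, 1L, n - n %% 3L)
    }
    cnt <- Biostrings::trinucleotideFrequency(Biostrings::RNAString(s),
                                              step = 3L)
    names(cnt) <- chartr("T", "U", names(cnt))
    tibble::tibble(gene_id = id, codon = codons,
                   count = as.integer(cnt[codons]))
  })
}

#' Per-gene codon totals
#'
#' @param counts A long codon-count tibble from [count_codons()].
#' @return A tibble with one row per gene: `total_codons` (all 64 codons)
#'   and `synonymous_total` (the 59 synonymous codons, i.e. excluding Met,
#'   Trp and stops).
#' @export
codon_totals <- function(counts) {
  syn <- synonymous_codons()
  counts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      total_codons = sum(.data$count),
      synonymous_total = sum(.data$count[.data$codon %in% syn]),
      .groups = "drop")
}

#' Pool codon counts over genes
#'
#' Element-wise sum of counts over all genes in the table, e.g. to compute
#' the usage of a whole gene set.
#'
#' @param counts A long codon-count tibble.
#' @param gene_id Label for the pooled pseudo-gene.
#' @return A codon-count tibble with a single gene.
#' @export
pool_counts <- function(counts, gene_id = "pooled") {
  if (nrow(counts) == 0L) stop("no count tables to pool", call. = FALSE)
  counts |>
    dplyr::group_by(.data$codon) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(gene_id = gene_id) |>
    dplyr::arrange(.data$codon) |>
    dplyr::select("gene_id", "codon", "count")
}

#' Relative synonymous codon usage
#'
#' For codon i of an amino acid with synonymous-family total T and family
#' size N, RSCU = count_i * N / T: the ratio of observed usage to the usage
#' expected were all synonyms used equally. Values average 1 within each
#' family. Only the 59 synonymous codons are scored; AUG, UGG and stops are
#' excluded. A family entirely absent from a gene (T = 0) yields `NA` for
#' all its codons -- "undefined", which is a different fact from an RSCU of
#' 0 (codon unused while its synonyms are used).
#'
#' @param counts A long codon-count tibble from [count_codons()],
#'   [pool_counts()] or a fixture.
#' @return A tibble with columns `gene_id`, `codon`, `aa`, `family_size`,
#'   `count`, `rscu`; 59 rows per gene.
#' @examples
#' counts <- count_codons(tibble::tibble(gene_id = "g",
#'   sequence = "AUGUUUUUCUUC"))
#' rscu(counts)
#' @export
rscu <- function(counts) {
  code <- .code_table()[.code_table()$synonymous,
                        c("codon", "aa", "family_size")]
  counts |>
    dplyr::inner_join(code, by = "codon") |>
    dplyr::group_by(.data$gene_id, .data$aa) |>
    dplyr::mutate(family_total = sum(.data$count),
                  rscu = ifelse(.data$family_total > 0,
                                .data$count * .data$family_size /
                                  .data$family_total,
                                NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id, .data$codon) |>
    dplyr::select("gene_id", "codon", "aa", "family_size", "count", "rscu")
}

#' Spread a long per-gene codon table to the wide matrix form
#'
#' @param x A long tibble with `gene_id`, `codon` and one value column.
#' @param value Name of the value column (default `"rscu"` if present,
#'   otherwise `"count"`).
#' @return A tibble with one row per gene and one column per codon in the
#'   fixed alphabetical RNA order.
#' @export
codon_wide <- function(x, value = NULL) {
  if (is.null(value)) value <- if ("rscu" %in% names(x)) "rscu" else "count"
  wide <- x |>
    dplyr::select("gene_id", "codon", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "codon", values_from = dplyr::all_of(value))
  ord <- intersect(codon_order(), names(wide))
  wide[, c("gene_id", ord)]
}

#' Write a wide per-gene codon table as TSV
#'
#' One row per gene, one column per codon in the fixed alphabetical RNA
#' order stated in the header comment.
#'
#' @param x A long codon-count or RSCU tibble.
#' @param path Output path.
#' @param value Value column to spread; see [codon_wide()].
#' @return `path`, invisibly.
#' @export
write_codon_tsv <- function(x, path, value = NULL) {
  wide <- codon_wide(x, value)
  writeLines("# codon columns in alphabetical RNA order", path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
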