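#' Classify codons by usage frequency
#'
#' Bins each codon's RSCU into high (> 1.5, strictly), mid ([1.0, 1.5]) and
#' low (< 1.0); undefined RSCU (absent family) stays undefined. The
#' boundaries themselves belong to the middle bin, so a codon at exactly
#' 1.50 is mid, not high.
#'
#' @param profile An RSCU tibble from [rscu()] (one or more genes).
#' @param high,low Bin boundaries (defaults 1.5 and 1.0).
#' @return The input with an added `class` factor
#'   (`high`/`mid`/`low`/`undefined`).
#' @export
classify_frequency <- function(profile, high = 1.5, low = 1.0) {
  stopifnot(low < high)
  profile |>
    dplyr::mutate(class = factor(
      dplyr::case_when(
        is.na(.data$rscu) ~ "undefined",
        .data$rscu > high ~ "high",
        .data$rscu < low ~ "low",
        TRUE ~ "mid"),
      levels = c("high", "mid", "low", "undefined")))
}

#' Preferred codons from a delta-RSCU contrast
#'
#' Contrasts mean RSCU between a high-bias and a low-bias gene group:
#' delta-RSCU(codon) = mean RSCU in the high-bias group minus mean RSCU in
#' the low-bias group. Codons with delta-RSCU above the threshold (default
#' 0.08) are the preferred codons of the set. By default the groups are the
#' ENc quantiles -- the lowest-ENc `fraction` of genes (strong bias) versus
#' the highest-ENc `fraction` (weak bias) -- with ENc computed from the
#' profile's own counts; explicit gene-id groups can be supplied instead.
#'
#' @param profiles An RSCU tibble from [rscu()] covering several genes.
#' @param grouping `"enc_quantile"` (default) or `"explicit"`.
#' @param fraction Fraction of genes in each ENc-quantile group
#'   (default 0.25).
#' @param threshold delta-RSCU cutoff for membership (default 0.08).
#' @param high_group,low_group Gene ids for `grouping = "explicit"`.
#' @return A tibble with columns `codon`, `delta_rscu` and `preferred`,
#'   with the two gene groups and threshold attached as attributes
#'   `"high_group"`, `"low_group"`, `"threshold"`.
#' @export
preferred_codons <- function(profiles, grouping = c("enc_quantile",
                                                    "explicit"),
                             fraction = 0.25, threshold = 0.08,
                             high_group = NULL, low_group = NULL) {
  grouping <- match.arg(grouping)
  genes <- unique(profiles$gene_id)
  if (grouping == "enc_quantile") {
    e <- enc(profiles[, c("gene_id", "codon", "count")])
    e <- e[order(e$enc, e$gene_id), ]
    k <- max(2L, ceiling(fraction * nrow(e)))
    high_group <- e$gene_id[seq_len(k)]                 # strongest bias
    low_group <- rev(e$gene_id)[seq_len(k)]             # weakest bias
  }
  if (length(high_group) < 2L || length(low_group) < 2L)
    stop("each contrast group needs at least 2 genes", call. = FALSE)
  if (length(intersect(high_group, low_group)))
    stop("contrast groups overlap: ",
         paste(intersect(high_group, low_group), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c(high_group, low_group), genes)
  if (length(missing))
    stop("genes not in profiles: ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- profiles |>
    dplyr::filter(.data$gene_id %in% c(high_group, low_group)) |>
    dplyr::group_by(.data$codon) |>
    dplyr::summarise(
      delta_rscu =
        mean(.data$rscu[.data$gene_id %in% high_group], na.rm = TRUE) -
        mean(.data$rscu[.data$gene_id %in% low_group], na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(preferred = !is.na(.data$delta_rscu) &
                    .data$delta_rscu > threshold)
  attr(out, "high_group") <- high_group
  attr(out, "low_group") <- low_group
  attr(out, "threshold") <- threshold
  out
}

#' Optimal codons of a focal gene
#'
#' A codon is optimal when it is both high-frequency in the focal gene
#' (RSCU strictly above 1.5) and preferred across the gene set
#' (delta-RSCU above threshold), i.e. the intersection of the two screens.
#'
#' @param profile A single-gene RSCU tibble.
#' @param preferred A tibble with `codon` and logical `preferred` (from
#'   [preferred_codons()] or a fixture), or a character vector of codons.
#' @param high RSCU cutoff for the high-frequency screen (default 1.5,
#'   strict).
#' @return Sorted character vector of optimal codons.
#' @export
optimal_codons <- function(profile, preferred, high = 1.5) {
  if (length(unique(profile$gene_id)) != 1L)
    stop("`profile` must contain exactly one gene", call. = FALSE)
  if (is.data.frame(preferred))
    preferred <- preferred$codon[preferred$preferred]
  hi <- profile$codon[!is.na(profile$rscu) & profile$rscu > high]
  sort(intersect(hi, preferred))
}

#' Similarity of two codon-usage patterns
#'
#' Two genes use a codon similarly when both RSCU values fall in the same
#' bin of {< 1.0, [1.0, 1.5], > 1.5}. The summary is the fraction of
#' similar codons among codons defined in both profiles, attached as
#' attribute `"fraction"`.
#'
#' @param p1,p2 Single-gene RSCU tibbles on the same codon set.
#' @param high,low Bin boundaries (defaults 1.5 and 1.0).
#' @return A tibble with per-codon columns `codon`, `rscu_1`, `rscu_2`,
#'   `bin_1`, `bin_2`, `similar`; attribute `"fraction"` holds the summary.
#' @export
pattern_similarity <- function(p1, p2, high = 1.5, low = 1.0) {
  bin <- function(x) dplyr::case_when(is.na(x) ~ NA_character_,
                                      x > high ~ "high",
                                      x < low ~ "low",
                                      TRUE ~ "mid")
  m <- dplyr::inner_join(
    dplyr::select(p1, "codon", rscu_1 = "rscu"),
    dplyr::select(p2, "codon", rscu_2 = "rscu"), by = "codon")
  if (nrow(m) == 0L)
    stop("profiles share no codons", call. = FALSE)
  m <- m |>
    dplyr::mutate(bin_1 = bin(.data$rscu_1), bin_2 = bin(.data$rscu_2),
                  similar = .data$bin_1 == .data$bin_2)
  defined <- !is.na(m$similar)
  if (!any(defined))
    stop("no codon is defined in both profiles; similarity undefined",
         call. = FALSE)
  attr(m, "fraction") <- mean(m$similar[defined])
  m
}
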