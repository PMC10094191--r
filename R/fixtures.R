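# name -> (file, md5) registry for the packaged study tables
.fixture_registry <- list(
  citxet_counts = list(file = "citxet_codon_counts.tsv",
                       md5 = "839920b77b0563c8a0209bbb9dcbe501"),
  xet20_counts = list(file = "xet20_codon_counts.tsv",
                      md5 = "4dbe9e3a2984d12acdf0be653cefb248"),
  table1_indices = list(file = "xet_index_table.tsv",
                        md5 = "1f489055ffeb655b5f35b19ebab60689"))

#' Packaged codon-usage tables from the XET study
#'
#' Three plain-text fixtures ship with the package, transcribed from the
#' printed tables of a study of 20 plant xyloglucan endotransglycosylase
#' (XET) coding sequences:
#'
#' * `"citxet_counts"` -- codon counts of the CitXET gene over the 59
#'   synonymous codons (300 codons in total), with the RSCU values as
#'   printed and the star annotations marking preferred codons. The
#'   printed Gly RSCU row is internally inconsistent with its own counts;
#'   the counts are authoritative, the printed values are carried verbatim.
#' * `"xet20_counts"` -- pooled codon counts of the 20 genes (4500
#'   synonymous codons), printed RSCU and preferred-codon stars.
#' * `"table1_indices"` -- the per-gene index matrix (U3s, C3s, A3s, G3s,
#'   GC3s, GC, CAI, CBI, Fop, ENc, GRAVY, aromaticity) for the 20 genes
#'   with their GenBank accessions.
#'
#' Loading validates a checksum and the documented totals (300 / 4500 /
#' 20 rows).
#'
#' @param name One of `"citxet_counts"`, `"xet20_counts"`,
#'   `"table1_indices"`.
#' @return A tibble. Count fixtures have columns `gene_id`, `codon`, `aa`,
#'   `count`, `rscu_printed`, `preferred` and work anywhere a codon-count
#'   tibble does.
#' @examples
#' cit <- xet_fixture("citxet_counts")
#' sum(cit$count) # 300
#' @export
xet_fixture <- function(name) {
  entry <- .fixture_registry[[name]]
  if (is.null(entry))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_registry), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", entry$file, package = "codonbias",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), entry$md5))
    stop("fixture '", name, "' failed its integrity checksum", call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (name == "citxet_counts") {
    stopifnot(sum(tbl$count) == 300L, nrow(tbl) == 59L)
    tbl <- dplyr::mutate(tbl, gene_id = "CitXET", .before = 1)
  } else if (name == "xet20_counts") {
    stopifnot(sum(tbl$count) == 4500L, nrow(tbl) == 59L)
    tbl <- dplyr::mutate(tbl, gene_id = "XET20", .before = 1)
  } else {
    stopifnot(nrow(tbl) == 20L)
  }
  tbl
}
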