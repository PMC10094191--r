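#' The standard genetic code as a tidy codon table
#'
#' Returns one row per codon (RNA alphabet, alphabetical order) with the
#' encoded amino acid, synonymous-family size and degeneracy class. The 59
#' synonymous codons are the sense codons excluding AUG (Met) and UGG (Trp),
#' whose families have a single member, and the three stop codons. The 18
#' synonymous families partition into degeneracy classes: nine 2-fold, one
#' 3-fold (Ile), five 4-fold and three 6-fold (Leu, Ser, Arg).
#'
#' @return A tibble with columns `codon`, `aa` (one-letter code, `*` for
#'   stop), `family_size` (number of synonymous codons for the amino acid),
#'   `degeneracy` (2, 3, 4 or 6; `NA` for Met, Trp and stops),
#'   `synonymous` (logical, `TRUE` for the 59 codons used in synonymous
#'   statistics) and `third` (third-position base).
#' @examples
#' gc <- genetic_code()
#' sum(gc$synonymous) # 59
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  codon <- chartr("T", "U", names(code))
  ord <- order(codon)
  tbl <- tibble::tibble(codon = codon[ord], aa = unname(code)[ord])
  fam <- table(tbl$aa)
  tbl$family_size <- as.integer(fam[tbl$aa])
  tbl$synonymous <- tbl$aa != "*" & tbl$family_size > 1L
  tbl$degeneracy <- ifelse(tbl$synonymous, tbl$family_size, NA_integer_)
  tbl$third <- substr(tbl$codon, 3L, 3L)
  tbl[, c("codon", "aa", "family_size", "degeneracy", "synonymous", "third")]
}

# cached copy; the code table never changes
.gc_env <- new.env(parent = emptyenv())

.code_table <- function() {
  if (is.null(.gc_env$tbl)) .gc_env$tbl <- genetic_code()
  .gc_env$tbl
}

#' All 64 codons in the fixed reporting order
#'
#' Alphabetical RNA order; every wide table written by the package uses this
#' column order.
#'
#' @return Character vector of length 64.
#' @export
codon_order <- function() .code_table()$codon

#' The 59 synonymous codons
#'
#' @return Character vector of length 59 (alphabetical RNA order).
#' @export
synonymous_codons <- function() {
  tbl <- .code_table()
  tbl$codon[tbl$synonymous]
}
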