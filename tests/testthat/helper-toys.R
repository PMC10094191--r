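# build a long codon-count tibble from a named codon -> count vector,
# filling the remaining codons with zero
make_counts <- function(counts, gene = "g") {
  all <- setNames(rep(0L, 64L), codon_order())
  counts <- counts[order(names(counts))]
  all[names(counts)] <- as.integer(counts)
  tibble::tibble(gene_id = gene, codon = names(all), count = unname(all))
}

# independent genetic-code map used by test oracles: straight from
# Biostrings, never through the package's own table
oracle_code <- local({
  code <- Biostrings::GENETIC_CODE
  names(code) <- chartr("T", "U", names(code))
  code
})

# brute-force RSCU by direct enumeration over a codon list
oracle_rscu <- function(codon_vec) {
  fam_size <- table(oracle_code)
  out <- list()
  for (cd in unique(codon_vec)) {
    aa <- oracle_code[[cd]]
    if (aa %in% c("*", "M", "W")) next
    syns <- names(oracle_code)[oracle_code == aa]
    tot <- sum(codon_vec %in% syns)
    out[[cd]] <- sum(codon_vec == cd) * length(syns) / tot
  }
  out
}

# CitXET counts from the packaged fixture, as a plain count tibble
citxet_counts <- function() {
  fx <- xet_fixture("citxet_counts")
  fx[, c("gene_id", "codon", "count")]
}
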