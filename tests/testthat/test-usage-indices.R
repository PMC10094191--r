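test_that("third-position composition uses the could-have denominators", {
  cit <- citxet_counts()
  comp <- third_position_composition(cit)
  # independent enumeration of numerators and denominators from the raw
  # genetic code: a codon enters the X denominator iff its family offers
  # an X-ending synonym
  syn_codons <- names(oracle_code)[
    !oracle_code %in% c("*", "M", "W")]
  cnt <- setNames(cit$count, cit$codon)[syn_codons]
  for (b in c(U = "U", C = "C", A = "A", G = "G")) {
    enders <- syn_codons[substr(syn_codons, 3, 3) == b]
    capable_aa <- unique(oracle_code[enders])
    denom <- sum(cnt[oracle_code[syn_codons] %in% capable_aa])
    num <- sum(cnt[enders])
    got <- comp[[paste0(tolower(b), "3s")]]
    expect_equal(got, 100 * num / denom, tolerance = 1e-12)
  }
  # the four derived denominators for this gene
  expect_equal(round(comp$a3s, 2), 36.54)   # 76 / 208
  expect_equal(round(comp$u3s, 2), 43.70)   # 111 / 254
  expect_equal(round(comp$c3s, 2), 27.56)   # 70 / 254
  expect_equal(round(comp$g3s, 2), 22.51)   # 43 / 191
  expect_equal(round(comp$gc3s, 1), 37.7)   # 113 / 300
})

test_that("composition saturates and rejects empty genes", {
  # only A-ending codons, all within A-capable families
  sat <- third_position_composition(
    make_counts(c(GCA = 5, CCA = 3, AAA = 2)))
  expect_equal(sat$a3s, 100)
  expect_equal(sat$gc3s, 0)
  only_met <- make_counts(c(AUG = 10))
  expect_error(third_position_composition(only_met), "undefined|no synonymous")
})

test_that("gc_content covers trivial and fixture cases", {
  gc <- gc_content(tibble::tibble(gene_id = c("a", "b"),
                                  sequence = c("GCGC", "AUAU")))
  expect_equal(gc$gc, c(100, 0))
})

test_that("ENc hits its theoretical bounds", {
  # one codon per family, large counts -> 20
  code <- genetic_code()
  one_per_fam <- code |>
    dplyr::filter(synonymous) |>
    dplyr::group_by(aa) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  low <- make_counts(setNames(rep(1000L, 18L), one_per_fam$codon))
  expect_equal(enc(low)$enc, 20)
  # uniform within every family, large counts -> near 61
  syn <- code[code$synonymous, ]
  hi <- make_counts(setNames(rep(200L, 59L), syn$codon))
  expect_equal(enc(hi)$enc, 61, tolerance = 0.5 / 61)
  # sampled uniform usage at 10,000 codons also lands near the cap
  cds <- codon_generate(n_genes = 1, codons_per_gene = 10000,
                        gc3_bias = 0.5, concentration = 0, seed = 21)
  expect_gt(enc(count_codons(cds))$enc, 60.5)
})

test_that("ENc matches the study value on the CitXET counts", {
  expect_equal(enc(citxet_counts())$enc, 47.39, tolerance = 0.5 / 47.39)
})

test_that("ENc is invariant to codon-label permutation within families", {
  cit <- citxet_counts()
  base <- enc(cit)$enc
  # swap the counts of UUU/UUC (same family): homozygosity is unchanged
  swapped <- cit
  i <- match(c("UUU", "UUC"), swapped$codon)
  swapped$count[i] <- swapped$count[rev(i)]
  expect_equal(enc(swapped)$enc, base)
  # gene order does not matter
  two <- dplyr::bind_rows(cit, dplyr::mutate(swapped, gene_id = "other"))
  expect_equal(sort(enc(two)$enc), sort(enc(two[sample(nrow(two)), ])$enc))
})

test_that("stronger within-family concentration lowers ENc", {
  means <- sapply(c(0.5, 2, 6), function(k) {
    cds <- codon_generate(n_genes = 5, codons_per_gene = 300,
                          gc3_bias = 0.8, concentration = k, seed = 17)
    mean(enc(count_codons(cds))$enc)
  })
  expect_true(all(diff(means) < 0))
})

test_that("ENc warns and returns NA when a degeneracy class is missing", {
  # only two-fold families present: 4- and 6-fold classes not computable
  expect_warning(out <- enc(make_counts(c(UUU = 5, UUC = 5, AAA = 3,
                                          AAG = 2))),
                 "not computable")
  expect_true(is.na(out$enc))
})

test_that("CAI follows its geometric-mean definition", {
  w1 <- tibble::tibble(codon = synonymous_codons(), weight = 1)
  gene <- make_counts(c(UUU = 10, AAA = 5, GGC = 5))
  expect_equal(cai(gene, w1)$cai, 1)
  # two occurrences with weights 0.25 and 1 -> sqrt(0.25 * 1) = 0.5
  w2 <- dplyr::mutate(w1, weight = ifelse(codon == "UUU", 0.25, 1))
  pair <- make_counts(c(UUU = 1, UUC = 1))
  expect_equal(cai(pair, w2)$cai, 0.5)
  # duplication invariance: concatenating a gene with itself
  cds <- codon_generate(n_genes = 1, codons_per_gene = 120, seed = 4)
  ref <- cai_weights(count_codons(
    codon_generate(n_genes = 5, codons_per_gene = 400, gc3_bias = 0.8,
                   seed = 40)))
  single <- cai(count_codons(cds), ref)$cai
  doubled <- cai(count_codons(tibble::tibble(
    gene_id = "dup", sequence = paste0(cds$sequence, cds$sequence))), ref)$cai
  expect_equal(single, doubled)
})

test_that("a gene built from the reference's best codons has CAI 1", {
  ref_counts <- count_codons(
    codon_generate(n_genes = 5, codons_per_gene = 400, gc3_bias = 0.9,
                   concentration = 2, seed = 8))
  w <- cai_weights(ref_counts)
  code <- genetic_code()
  best <- dplyr::inner_join(w, code[, c("codon", "aa")], by = "codon") |>
    dplyr::group_by(aa) |>
    dplyr::slice_max(weight, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  gene <- make_counts(setNames(rep(17L, nrow(best)), best$codon))
  expect_equal(cai(gene, w)$cai, 1)
})

test_that("CBI and Fop match direct arithmetic", {
  gene <- make_counts(c(UUU = 3, UUC = 1, AAA = 2, AAG = 4))
  # all used codons optimal
  all_opt <- cbi_fop(gene, c("UUU", "UUC", "AAA", "AAG"))
  expect_equal(all_opt$fop, 1)
  expect_equal(all_opt$cbi, 1)
  # hand-computed toy: Nopt 3, Nrand 2, Nsyn 10
  toy <- cbi_fop(gene, "UUU")
  expect_equal(toy$fop, 0.3)
  expect_equal(toy$cbi, (3 - 2) / (10 - 2))
  # exactly uniform usage within families -> CBI 0
  uni <- cbi_fop(make_counts(c(UUU = 5, UUC = 5, AAA = 7, AAG = 7)),
                 c("UUU", "AAA"))
  expect_equal(uni$cbi, 0)
  expect_error(cbi_fop(gene, character()), "empty")
  expect_error(cbi_fop(gene, "AUG"), "not synonymous")
})

test_that("GRAVY and aromaticity follow the hydropathy scale", {
  ala <- tibble::tibble(gene_id = "a",
                        sequence = strrep("GCU", 10))
  expect_equal(gravy_aromo(ala)$gravy, 1.8)
  expect_equal(gravy_aromo(ala)$aromo, 0)
  phe <- tibble::tibble(gene_id = "f", sequence = strrep("UUU", 8))
  expect_equal(gravy_aromo(phe)$aromo, 1)
  # residue-wise oracle on a random CDS via an independent translation
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  cds <- codon_generate(n_genes = 1, codons_per_gene = 100, seed = 31)
  res <- gravy_aromo(cds)
  codons <- substring(cds$sequence, seq(1, nchar(cds$sequence), 3),
                      seq(3, nchar(cds$sequence), 3))
  aa <- oracle_code[codons]
  aa <- aa[aa != "*"]
  expect_equal(res$gravy, mean(kd[aa]))
  expect_equal(res$aromo, mean(aa %in% c("F", "Y", "W")))
  # internal stop is rejected with its codon position
  expect_error(gravy_aromo(tibble::tibble(gene_id = "s",
                                          sequence = "AUGUAAUUU")),
               "position 2")
})

test_that("the index table covers every gene with sane values", {
  cds <- codon_generate(n_genes = 20, codons_per_gene = 225,
                        gc3_bias = runif(20, 0.2, 0.9), seed = 12)
  ref <- cai_weights(count_codons(cds))
  idx <- codon_usage_indices(cds, cai_ref = ref, optimal = c("AGA", "GCU"))
  expect_equal(nrow(idx), 20L)
  expect_equal(idx$gene_id, cds$gene_id)   # input order preserved
  for (v in c("u3s", "c3s", "a3s", "g3s", "gc3s", "gc"))
    expect_true(all(idx[[v]] >= 0 & idx[[v]] <= 100))
  expect_true(all(idx$enc >= 20 & idx$enc <= 61))
  expect_true(all(idx$cai > 0 & idx$cai <= 1))
  expect_true(all(idx$fop >= 0 & idx$fop <= 1))
  expect_true(all(idx$aromo >= 0 & idx$aromo <= 1))
  # TSV round-trip is an identity
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(idx, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(idx), tolerance = 1e-12)
})

test_that("a failing gene yields NA fields, not a batch failure", {
  cds <- tibble::tibble(
    gene_id = c("ok", "stops"),
    sequence = c(strrep("GCU", 30), paste0("AUGUAA", strrep("GCU", 28))))
  expect_warning(idx <- codon_usage_indices(cds), "internal stop")
  expect_equal(nrow(idx), 2L)
  expect_false(is.na(idx$gravy[1]))
  expect_true(is.na(idx$gravy[2]))
  expect_false(is.na(idx$gc[2]))   # sequence-level indices still computed
})
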