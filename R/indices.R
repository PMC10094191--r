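# Kyte-Doolittle hydropathy scale (standard values)
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Synonymous third-position base composition (codonW convention)
#'
#' X3s (X in U, C, A, G) is the percentage of synonymous codons ending in X
#' among synonymous codons whose family offers X as a third-position
#' synonym -- the "could-have" denominator used by codonW. A lysine codon,
#' for example, never enters the U3s denominator because neither AAA nor
#' AAG ends in U. GC3s is the percentage of all synonymous codons ending in
#' G or C.
#'
#' @param counts A long codon-count tibble.
#' @return A tibble with one row per gene: `u3s`, `c3s`, `a3s`, `g3s`,
#'   `gc3s`, all percentages.
#' @export
third_position_composition <- function(counts) {
  code <- .code_table()
  syn <- code[code$synonymous, ]
  # families offering each third base as a synonymous ending
  capable <- lapply(c(U = "U", C = "C", A = "A", G = "G"), function(b)
    unique(syn$aa[syn$third == b]))
  x <- dplyr::inner_join(counts, syn[, c("codon", "aa", "third")],
                         by = "codon")
  x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      tot <- sum(d$count)
      if (tot == 0L)
        stop("gene '", key$gene_id, "' has no synonymous codons; ",
             "composition undefined", call. = FALSE)
      one <- function(b) {
        den <- sum(d$count[d$aa %in% capable[[b]]])
        100 * sum(d$count[d$third == b]) / den
      }
      tibble::tibble(u3s = one("U"), c3s = one("C"), a3s = one("A"),
                     g3s = one("G"),
                     gc3s = 100 * sum(d$count[d$third %in% c("G", "C")]) / tot)
    }) |>
    dplyr::ungroup()
}

#' Overall G+C content of coding sequences
#'
#' @param cds A data frame with `gene_id` and `sequence`.
#' @return A tibble with one row per gene and column `gc` (percent over the
#'   full CDS, all three codon positions).
#' @export
gc_content <- function(cds) {
  tibble::tibble(
    gene_id = cds$gene_id,
    gc = purrr::map2_dbl(cds$sequence, cds$gene_id, function(s, id) {
      s <- validate_cds(s, id)
      100 * stringr::str_count(s, "[GC]") / nchar(s)
    }))
}

# Wright's homozygosity for one family's counts
.f_hat <- function(cnt) {
  n <- sum(cnt)
  if (n <= 1L) return(NA_real_)
  p <- cnt / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Effective number of codons (Wright's ENc)
#'
#' Summarises how far synonymous codon usage departs from uniform use: 20
#' when exactly one codon is used per family, 61 when all synonyms are used
#' equally. Per family with total count n > 1 the codon homozygosity is
#' F = (n * sum(p_i^2) - 1) / (n - 1); F values are averaged within
#' degeneracy classes (2-, 3-, 4- and 6-fold) and
#' ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. Families with total count <= 1 or
#' F <= 0 are excluded from their class mean; an entirely missing 3-fold
#' class (Ile absent) is imputed as the mean of the 2- and 4-fold class
#' means; the result is capped at 61. If the 2-, 4- or 6-fold class has no
#' computable family the gene's ENc is `NA` with a warning.
#'
#' @param counts A long codon-count tibble.
#' @return A tibble with one row per gene and column `enc`.
#' @export
enc <- function(counts) {
  code <- .code_table()
  syn <- code[code$synonymous, c("codon", "aa", "degeneracy")]
  dplyr::inner_join(counts, syn, by = "codon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      fam <- d |>
        dplyr::group_by(.data$aa, .data$degeneracy) |>
        dplyr::summarise(f = .f_hat(.data$count), .groups = "drop") |>
        dplyr::filter(!is.na(.data$f), .data$f > 0)
      fbar <- vapply(c(2, 3, 4, 6), function(k) {
        v <- fam$f[fam$degeneracy == k]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      names(fbar) <- c("F2", "F3", "F4", "F6")
      if (is.na(fbar["F3"]) && !is.na(fbar["F2"]) && !is.na(fbar["F4"]))
        fbar["F3"] <- mean(fbar[c("F2", "F4")])
      if (anyNA(fbar)) {
        warning("ENc undefined for gene '", key$gene_id,
                "': degeneracy class(es) ",
                paste(names(fbar)[is.na(fbar)], collapse = ", "),
                " not computable", call. = FALSE)
        return(tibble::tibble(enc = NA_real_))
      }
      val <- 2 + 9 / fbar["F2"] + 1 / fbar["F3"] + 5 / fbar["F4"] +
        3 / fbar["F6"]
      tibble::tibble(enc = min(unname(val), 61))
    }) |>
    dplyr::ungroup()
}

#' Relative adaptiveness weights from a reference gene set
#'
#' Builds CAI weights from the codon counts of a reference set (typically
#' highly expressed genes, pooled): within each synonymous family,
#' w = count / max(count). Zero reference counts are replaced by a 0.5
#' pseudo-count first, the usual convention, so every weight is positive.
#'
#' @param ref_counts A long codon-count tibble (one or more genes; counts
#'   are pooled).
#' @return A tibble with columns `codon` and `weight` covering the 59
#'   synonymous codons; the maximum weight in each family is 1.
#' @export
cai_weights <- function(ref_counts) {
  pool_counts(ref_counts, "ref") |>
    rscu() |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(adj = pmax(.data$count, 0.5),
                  weight = .data$adj / max(.data$adj)) |>
    dplyr::ungroup() |>
    dplyr::select("codon", "weight")
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness w of every synonymous codon
#' occurrence in a gene (Met, Trp and stops excluded). Codons without a
#' weight in the reference are skipped; the number skipped is attached as
#' attribute `"skipped"`.
#'
#' @param counts A long codon-count tibble.
#' @param weights A tibble with columns `codon` and `weight`, e.g. from
#'   [cai_weights()] or read from a two-column TSV.
#' @return A tibble with one row per gene and column `cai`.
#' @export
cai <- function(counts, weights) {
  stopifnot(all(c("codon", "weight") %in% names(weights)))
  syn <- synonymous_codons()
  skipped <- 0L
  out <- counts |>
    dplyr::filter(.data$codon %in% syn) |>
    dplyr::left_join(weights, by = "codon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      use <- !is.na(d$weight) & d$count > 0
      skipped <<- skipped + sum(d$count[is.na(d$weight)])
      n <- sum(d$count[use])
      if (n == 0L)
        stop("no overlap between codons of gene '", key$gene_id,
             "' and the reference weights", call. = FALSE)
      tibble::tibble(cai = exp(sum(d$count[use] * log(d$weight[use])) / n))
    }) |>
    dplyr::ungroup()
  attr(out, "skipped") <- skipped
  out
}

#' Codon bias index and frequency of optimal codons
#'
#' Fop is the fraction of a gene's synonymous codons drawn from a designated
#' optimal set. CBI rescales it against the count expected under uniform
#' within-family usage: CBI = (Nopt - Nrand) / (Nsyn - Nrand), so 0 means
#' no bias toward the optimal set and 1 means exclusive use.
#'
#' @param counts A long codon-count tibble.
#' @param optimal Character vector of optimal codons (RNA), all synonymous.
#' @return A tibble with one row per gene: `cbi`, `fop`.
#' @export
cbi_fop <- function(counts, optimal) {
  optimal <- toupper(chartr("T", "U", optimal))
  if (length(optimal) == 0L) stop("optimal set is empty", call. = FALSE)
  bad <- setdiff(optimal, synonymous_codons())
  if (length(bad))
    stop("not synonymous codons: ", paste(bad, collapse = ", "),
         call. = FALSE)
  code <- .code_table()
  syn <- code[code$synonymous, c("codon", "aa", "family_size")]
  dplyr::inner_join(counts, syn, by = "codon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      n_syn <- sum(d$count)
      if (n_syn == 0L)
        return(tibble::tibble(cbi = NA_real_, fop = NA_real_))
      n_opt <- sum(d$count[d$codon %in% optimal])
      opt_per_fam <- d |>
        dplyr::group_by(.data$aa) |>
        dplyr::summarise(
          e = sum(.data$count) *
            sum(.data$codon %in% optimal) / dplyr::first(.data$family_size),
          .groups = "drop")
      n_rand <- sum(opt_per_fam$e)
      # when the optimal set saturates every family the rescaling is 0/0;
      # exclusive optimal use is maximal bias by definition
      cbi <- if (n_syn == n_rand) {
        if (n_opt == n_syn) 1 else NA_real_
      } else (n_opt - n_rand) / (n_syn - n_rand)
      tibble::tibble(cbi = cbi, fop = n_opt / n_syn)
    }) |>
    dplyr::ungroup()
}

#' Translate a coding sequence
#'
#' Standard-code translation; a trailing stop codon is dropped. An internal
#' stop is an error naming the offending codon position.
#'
#' @param cds A data frame with `gene_id` and `sequence` (length a multiple
#'   of 3).
#' @return A tibble with `gene_id` and `protein` (one-letter residues).
#' @export
translate_cds <- function(cds) {
  prot <- purrr::map2_chr(cds$sequence, cds$gene_id, function(s, id) {
    s <- validate_cds(s, id)
    if (nchar(s) %% 3L != 0L)
      stop("length of gene '", id, "' is not a multiple of 3", call. = FALSE)
    aa <- as.character(Biostrings::translate(Biostrings::RNAString(s)))
    n <- nchar(aa)
    if (substr(aa, n, n) == "*") aa <- substr(aa, 1L, n - 1L)
    star <- regexpr("*", aa, fixed = TRUE)
    if (star > 0L)
      stop("internal stop codon at codon position ", star, " in gene '",
           id, "'", call. = FALSE)
    aa
  })
  tibble::tibble(gene_id = cds$gene_id, protein = prot)
}

#' GRAVY and aromaticity of the encoded protein
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy over all residues of the
#' translated protein (terminal stop excluded); aromaticity is the fraction
#' of Phe, Tyr and Trp residues.
#'
#' @param cds A data frame with `gene_id` and `sequence`.
#' @return A tibble with one row per gene: `gravy`, `aromo`.
#' @export
gravy_aromo <- function(cds) {
  prot <- translate_cds(cds)
  tibble::tibble(
    gene_id = prot$gene_id,
    gravy = purrr::map_dbl(prot$protein, function(p)
      mean(.kd_scale[strsplit(p, "")[[1]]])),
    aromo = purrr::map_dbl(prot$protein, function(p)
      stringr::str_count(p, "[FYW]") / nchar(p)))
}

#' Per-gene codon-usage index table
#'
#' Assembles the standard per-gene record: synonymous third-position
#' composition (U3s/C3s/A3s/G3s/GC3s), overall GC, CAI (if reference
#' weights are given), CBI and Fop (if an optimal-codon set is given), ENc,
#' GRAVY and aromaticity. Genes are reported in input order; a failure in
#' one gene yields `NA` fields for that gene with a warning, not an error.
#'
#' @param cds A data frame with `gene_id` and `sequence`.
#' @param cai_ref Optional weights tibble for [cai()].
#' @param optimal Optional optimal-codon set for [cbi_fop()].
#' @param frame_policy Passed to [count_codons()].
#' @return A tibble with one row per gene and columns `gene_id`, `u3s`,
#'   `c3s`, `a3s`, `g3s`, `gc3s`, `gc`, `cai`, `cbi`, `fop`, `enc`,
#'   `gravy`, `aromo` (index columns absent when their inputs are absent
#'   are `NA`).
#' @export
codon_usage_indices <- function(cds, cai_ref = NULL, optimal = NULL,
                                frame_policy = "strict") {
  cols <- c("u3s", "c3s", "a3s", "g3s", "gc3s", "gc", "cai", "cbi", "fop",
            "enc", "gravy", "aromo")
  # each index family runs per gene so one bad gene yields NA fields in
  # its own record instead of failing the batch
  safe <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  rows <- purrr::map(seq_len(nrow(cds)), function(i) {
    g <- cds[i, , drop = FALSE]
    rec <- as.list(setNames(rep(NA_real_, length(cols)), cols))
    counts <- safe(count_codons(g, frame_policy))
    if (!is.null(counts)) {
      comp <- safe(third_position_composition(counts))
      if (!is.null(comp)) rec[c("u3s", "c3s", "a3s", "g3s", "gc3s")] <-
          comp[c("u3s", "c3s", "a3s", "g3s", "gc3s")]
      e <- safe(enc(counts))
      if (!is.null(e)) rec$enc <- e$enc
      if (!is.null(cai_ref)) {
        v <- safe(cai(counts, cai_ref))
        if (!is.null(v)) rec$cai <- v$cai
      }
      if (!is.null(optimal)) {
        v <- safe(cbi_fop(counts, optimal))
        if (!is.null(v)) { rec$cbi <- v$cbi; rec$fop <- v$fop }
      }
    }
    gcv <- safe(gc_content(g))
    if (!is.null(gcv)) rec$gc <- gcv$gc
    ga <- safe(gravy_aromo(g))
    if (!is.null(ga)) { rec$gravy <- ga$gravy; rec$aromo <- ga$aromo }
    tibble::as_tibble(rec)
  })
  dplyr::bind_cols(tibble::tibble(gene_id = cds$gene_id),
                   dplyr::bind_rows(rows))
}
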