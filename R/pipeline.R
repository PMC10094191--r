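#' Assemble a pipeline configuration
#'
#' Validates inputs up front so a misconfigured run fails before any
#' computation: thresholds must be positive with `rscu_low < rscu_high`,
#' and the `tree` stage requires an alignment.
#'
#' @param out_dir Output directory (created if missing).
#' @param fasta Optional CDS FASTA path. When `NULL` the pipeline runs in
#'   fixture-only mode on the packaged study tables.
#' @param alignment Optional aligned protein FASTA for the `tree` stage.
#' @param stages Stages to run, a subset of the default vector; they
#'   execute in dependency order regardless of the order given.
#' @param cai_ref Optional CAI reference: a weights tibble or a two-column
#'   TSV path (`codon`, `weight`).
#' @param optimal Optional optimal-codon set: character vector or
#'   one-column text file.
#' @param rscu_high,rscu_low High/low-frequency RSCU bin boundaries.
#' @param delta_rscu Preferred-codon threshold.
#' @param enc_strong_bias ENc cutoff below which a gene is flagged as
#'   strongly biased.
#' @param group_fraction ENc-quantile fraction for the preference contrast.
#' @param replicates Bootstrap replicates for the tree stage.
#' @param seed Integer seed used everywhere randomness exists.
#' @return A list of class `codon_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, fasta = NULL, alignment = NULL,
                            stages = c("counts", "rscu", "indices",
                                       "preference", "ca", "cluster",
                                       "correlation", "tree"),
                            cai_ref = NULL, optimal = NULL,
                            rscu_high = 1.5, rscu_low = 1.0,
                            delta_rscu = 0.08, enc_strong_bias = 35,
                            group_fraction = 0.25, replicates = 100,
                            seed = 1L) {
  stages_requested <- !missing(stages)
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(rscu_high > 0, rscu_low > 0, delta_rscu > 0,
            enc_strong_bias > 0)
  if (rscu_low >= rscu_high)
    stop("rscu_low must be below rscu_high", call. = FALSE)
  if (!is.null(fasta) && !file.exists(fasta))
    stop("FASTA not found: ", fasta, call. = FALSE)
  if (!is.null(alignment) && !file.exists(alignment))
    stop("alignment not found: ", alignment, call. = FALSE)
  # an explicitly requested tree stage with nothing to build it from is a
  # configuration error, caught before any computation
  if (stages_requested && "tree" %in% stages && is.null(alignment))
    stop("the tree stage needs an alignment; supply `alignment` or drop ",
         "\"tree\" from `stages`", call. = FALSE)
  if (is.character(cai_ref) && length(cai_ref) == 1L && file.exists(cai_ref))
    cai_ref <- readr::read_tsv(cai_ref, show_col_types = FALSE)
  if (is.character(optimal) && length(optimal) == 1L && file.exists(optimal))
    optimal <- readLines(optimal)
  structure(list(out_dir = out_dir, fasta = fasta, alignment = alignment,
                 stages = stages, cai_ref = cai_ref, optimal = optimal,
                 rscu_high = rscu_high, rscu_low = rscu_low,
                 delta_rscu = delta_rscu,
                 enc_strong_bias = enc_strong_bias,
                 group_fraction = group_fraction,
                 replicates = replicates, seed = as.integer(seed)),
            class = "codon_pipeline_config")
}

#' Flag genes with strong codon bias by ENc
#'
#' An ENc below the cutoff (35 by convention) marks a gene as strongly
#' biased; above it the deviation from uniform synonym use is considered
#' low.
#'
#' @param records An index tibble with columns `enc` and a gene label
#'   column.
#' @param cutoff ENc cutoff (default 35).
#' @return The input with an added logical `strong_bias` column.
#' @export
flag_strong_bias <- function(records, cutoff = 35) {
  stopifnot("enc" %in% names(records))
  dplyr::mutate(records, strong_bias = !is.na(.data$enc) &
                  .data$enc < cutoff)
}

#' Run the codon-usage analysis pipeline
#'
#' Executes the enabled stages in dependency order (counts, RSCU, indices,
#' preference screening, correspondence analysis, clustering, correlation
#' panel, and the tree if an alignment is given), writing each result as
#' TSV or Newick under `config$out_dir` plus a JSON manifest recording
#' every output together with the parameters and package version. With no
#' FASTA the pipeline runs on the packaged study fixtures instead. Reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config A configuration from [pipeline_config()].
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_codon_pipeline <- function(config) {
  stopifnot(inherits(config, "codon_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(stage, file) {
    outputs[[length(outputs) + 1L]] <<- list(stage = stage, file = file)
    file.path(config$out_dir, file)
  }
  stages <- config$stages

  if (is.null(config$fasta)) {
    # fixture-only mode: reproduce the study-table summaries
    cit <- xet_fixture("citxet_counts")
    idx <- xet_fixture("table1_indices")
    prof <- rscu(cit[, c("gene_id", "codon", "count")])
    readr::write_tsv(classify_frequency(prof, config$rscu_high,
                                        config$rscu_low),
                     emit("rscu", "citxet_rscu.tsv"))
    stars <- xet_fixture("xet20_counts")[, c("codon", "preferred")]
    opt <- optimal_codons(prof, stars, high = config$rscu_high)
    writeLines(opt, emit("preference", "citxet_optimal_codons.txt"))
    readr::write_tsv(flag_strong_bias(idx, config$enc_strong_bias),
                     emit("indices", "index_table.tsv"))
    readr::write_tsv(correlation_panel(idx),
                     emit("correlation", "correlation_panel.tsv"))
  } else {
    cds <- read_cds(config$fasta)
    counts <- count_codons(cds)
    if ("counts" %in% stages)
      write_codon_tsv(counts, emit("counts", "codon_counts.tsv"), "count")
    prof <- rscu(counts)
    if ("rscu" %in% stages)
      write_codon_tsv(prof, emit("rscu", "rscu.tsv"), "rscu")
    idx <- codon_usage_indices(cds, cai_ref = config$cai_ref,
                               optimal = config$optimal)
    if ("indices" %in% stages)
      readr::write_tsv(flag_strong_bias(idx, config$enc_strong_bias),
                       emit("indices", "index_table.tsv"))
    if ("preference" %in% stages) {
      if (length(unique(prof$gene_id)) < 4L) {
        warning("preference stage skipped: fewer than 4 genes",
                call. = FALSE)
      } else {
        pref <- preferred_codons(prof, fraction = config$group_fraction,
                                 threshold = config$delta_rscu)
        readr::write_tsv(pref, emit("preference", "preferred_codons.tsv"))
      }
    }
    ca_fit <- NULL
    if ("ca" %in% stages) {
      ca_fit <- correspondence_analysis(prof)
      readr::write_tsv(tidy(ca_fit), emit("ca", "ca_coordinates.tsv"))
      readr::write_tsv(ca_fit$inertia, emit("ca", "ca_inertia.tsv"))
    }
    if ("cluster" %in% stages)
      write_newick_dendrogram(cluster_rscu(prof),
                              emit("cluster", "rscu_dendrogram.nwk"))
    if ("correlation" %in% stages) {
      cp_data <- idx
      if (!is.null(ca_fit) && ca_fit$k >= 1) {
        axes <- ca_fit$gene_coords[, c("gene_id",
                                       paste0("axis",
                                              seq_len(min(2, ca_fit$k))))]
        cp_data <- dplyr::left_join(idx, axes, by = "gene_id")
      }
      keep <- vapply(cp_data, function(v)
        is.numeric(v) && sum(!is.na(v)) >= 3, logical(1))
      readr::write_tsv(correlation_panel(cp_data, vars = names(cp_data)[keep]),
                       emit("correlation", "correlation_panel.tsv"))
    }
    if ("tree" %in% stages && !is.null(config$alignment)) {
      aln <- read_protein_alignment(config$alignment)
      tr <- bootstrap_supports(aln, replicates = config$replicates,
                               seed = config$seed)
      write_newick_tree(tr, emit("tree", "nj_tree.nwk"))
    }
  }

  manifest <- list(
    package = "codonbias",
    version = as.character(utils::packageVersion("codonbias")),
    parameters = config[setdiff(names(config),
                                c("out_dir", "cai_ref", "optimal"))],
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
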