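#' Run the full motif-discovery pipeline
#'
#' Chains the analysis stages: background filtering, the two-segment
#' rank-intensity fit, strong-probe selection, k-mer decomposition,
#' G/C-run filtering, ranking, greedy motif clustering with PWM and
#' consensus, mutation-scan and greedy extension of the top seed,
#' rank-based enrichment statistics for the top consensus, and the putative
#' target-gene scan.
#'
#' @param design a `pbm_design`, or its `probes` data.frame (needs
#'   `probe_id` and `core_seq`).
#' @param intensities data.frame `probe_id`, `intensity` and either a
#'   `background` column or the `background` argument.
#' @param config a [pbm_config()].
#' @param background optional scalar background.
#' @param out_dir optional directory; when given, every stage's outputs are
#'   written there (TSV/JSON/MEME) along with `summary.json`.
#' @return object of class `pbm_run`: list with `fit`, `strong`, `kmers`
#'   (ranked table), `clusters`, `top_cluster`, `mutation`, `extension`,
#'   `enrichment`, `gene_hits`, `summary` (plain list), `config`.
#' @export
run_pbm_pipeline <- function(design, intensities, config = pbm_config(),
                             background = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pbm_config"))
  probes <- if (inherits(design, "pbm_design")) design$probes else design
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "core_seq") %in% names(probes)))

  above <- filter_background(intensities, background = background)
  fit <- fit_rank_segments(above, keep_data = FALSE)
  strong <- select_strong_probes(above, fit)
  strong_seq <- merge(strong, probes[, c("probe_id", "core_seq")],
                      by = "probe_id", sort = FALSE)
  if (nrow(strong_seq) < nrow(strong)) {
    stop("pipeline stage 'kmers' failed: some strong probes are missing from the design",
         call. = FALSE)
  }
  kt <- kmer_decompose(strong_seq, k = config$k)
  kt <- gc_run_filter(kt, min_run = config$min_run)
  ranked <- rank_kmers(kt, mode = config$sort_mode,
                       min_occurrence = config$min_occurrence)
  ranked_head <- utils::head(ranked, config$max_rank)
  clusters <- cluster_all(ranked_head, max_mismatch = config$max_mismatch,
                          core_len = config$core_len,
                          max_clusters = config$max_clusters,
                          trim_support = config$trim_support)
  top <- clusters[[1]]
  mut <- mutation_scan(top$seed, kt)
  ext <- extend_motif(top$seed, kt)
  above_seq <- merge(above, probes[, c("probe_id", "core_seq")],
                     by = "probe_id", sort = FALSE)
  enr <- enrichment_summary(above_seq, fit, top$consensus)
  hits <- scan_probes(strong_seq, top$consensus, include_rc = config$include_rc)

  summary <- list(
    n_above_background = nrow(above),
    cutoff = fit$cutoff,
    breakpoint_rank = fit$breakpoint_rank,
    n_strong = nrow(strong),
    k = config$k,
    n_distinct_kmers = nrow(kt),
    n_gc_discarded = attr(kt, "n_discarded"),
    top_kmer = ranked$kmer[1],
    top_intensity_ave = ranked$intensity_ave[1],
    n_clusters = length(clusters),
    cluster_sizes = vapply(clusters, `[[`, integer(1), "n_members"),
    consensus = top$consensus,
    extended_motif = ext$final_motif,
    mwu_p = if (!is.null(enr$mwu)) enr$mwu$p_value else NA_real_,
    n_motif_probes = hits$n_probes,
    n_putative_genes = hits$n_genes,
    seed = config$seed
  )

  run <- structure(
    list(fit = fit, strong = strong, kmers = ranked, clusters = clusters,
         top_cluster = top, mutation = mut, extension = ext,
         enrichment = enr, gene_hits = hits, summary = summary,
         config = config),
    class = "pbm_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fit_json(fit, file.path(out_dir, "fit.json"))
    write_intensity_tsv(strong, file.path(out_dir, "strong_probes.tsv"))
    write_kmer_tsv(ranked, file.path(out_dir, "kmers.tsv"))
    write_meme_motif(top, name = top$consensus,
                     path = file.path(out_dir, "top_motif.meme"))
    data.table::fwrite(hits$hits, file.path(out_dir, "gene_hits.tsv"),
                       sep = "\t")
    writeLines(hits$genes, file.path(out_dir, "putative_genes.txt"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_pbm_config(config, file.path(out_dir, "config.json"))
  }
  run
}

#' @export
print.pbm_run <- function(x, ...) {
  s <- x$summary
  cat("PBM motif-discovery run\n")
  cat(sprintf("  %d probes above background; cutoff %.4g -> %d strong probes\n",
              s$n_above_background, s$cutoff, s$n_strong))
  cat(sprintf("  %d distinct %d-mers (%d G/C-run k-mers discarded)\n",
              s$n_distinct_kmers, s$k, s$n_gc_discarded))
  cat(sprintf("  top k-mer %s (mean pseudo-intensity %.1f)\n",
              s$top_kmer, s$top_intensity_ave))
  cat(sprintf("  %d cluster(s), sizes: %s\n", s$n_clusters,
              paste(s$cluster_sizes, collapse = ", ")))
  cat(sprintf("  consensus %s, extended %s\n", s$consensus, s$extended_motif))
  if (!is.na(s$mwu_p)) cat(sprintf("  enrichment p-value %.3g\n", s$mwu_p))
  cat(sprintf("  %d motif-bearing strong probes -> %d putative target gene(s)\n",
              s$n_motif_probes, s$n_putative_genes))
  invisible(x)
}

#' @export
summary.pbm_run <- function(object, ...) object$summary
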