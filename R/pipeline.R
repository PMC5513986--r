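#' Run the full domestication scan
#'
#' Orchestrates the pipeline end to end: read the input bundle, compute
#' gene-level and per-SNP statistics, annotate SNPs against the genetic code,
#' calibrate the neutral RoD baseline, apply the three-criterion selection
#' test, classify seed-preferential expression and test enrichment, and build
#' haplotype networks for genes under selection. All tabular outputs are
#' written as TSV (infinities serialized as \code{"Inf"}, undefined values as
#' \code{"NA"}), plus a machine-readable summary JSON.
#'
#' @param config Named list (see \code{\link{read_run_config}}) with entries
#'   \code{fasta, vcf, groups, annotation, expression, tissues} (input paths;
#'   \code{expression}/\code{tissues} optional), \code{outdir}, and
#'   optionally \code{wild_label} (default \code{"wild_weedy"}),
#'   \code{landrace_label} (default \code{"landrace"}), \code{fold}
#'   (expression fold threshold, default 2).
#' @return Invisibly, a list with the computed tables and the summary.
#' @export
run_pipeline <- function(config) {
  wild_label <- config$wild_label %||% "wild_weedy"
  landrace_label <- config$landrace_label %||% "landrace"
  fold <- config$fold %||% 2
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  inputs <- read_inputs(config$fasta, config$vcf, config$groups,
                        config$annotation)
  wild <- group_samples(inputs$groups, wild_label)
  landrace <- group_samples(inputs$groups, landrace_label)
  if (!length(wild) || !length(landrace))
    stop("contrast groups absent from groups file")

  gstats <- do.call(rbind, lapply(inputs$matrices, gene_stats,
                                  wild = wild, landrace = landrace))
  gstats$is_neutral <- inputs$genes$is_neutral[match(gstats$gene_id,
                                                     inputs$genes$gene_id)]
  sstats <- do.call(rbind, lapply(inputs$matrices, per_site_stats,
                                  wild = wild, landrace = landrace))
  rownames(gstats) <- rownames(sstats) <- NULL
  sstats <- annotate_sites(sstats, inputs$genes)

  baseline <- neutral_baseline(gstats[gstats$is_neutral, , drop = FALSE])
  calls <- gene_selection_calls(sstats, baseline)
  snps_sel <- selected_snps(sstats, baseline)

  .write_tsv(gstats, file.path(outdir, "gene_stats.tsv"))
  .write_tsv(sstats, file.path(outdir, "site_stats.tsv"))
  .write_tsv(calls, file.path(outdir, "selection_calls.tsv"))
  .write_tsv(snps_sel, file.path(outdir, "selected_snps.tsv"))

  enrich <- NULL
  if (!is.null(config$expression) && !is.null(config$tissues)) {
    profiles <- expression_profiles(config$expression, config$tissues,
                                    fold = fold)
    .write_tsv(profiles, file.path(outdir, "expression_classes.tsv"))
    enrich <- enrichment_report(calls, profiles)
    jsonlite::write_json(
      list(table = enrich$table,
           pct_selected_seed_pref = enrich$pct_selected_seed_pref,
           pct_selected_other = enrich$pct_selected_other,
           chi2 = enrich$chi2, p_value = enrich$p_value),
      file.path(outdir, "enrichment_report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  ## haplotype networks for genes under selection
  sel_genes <- calls$gene_id[calls$under_selection]
  hap_rows <- list(); edge_rows <- list()
  for (g in sel_genes) {
    hs <- build_network(enumerate_haplotypes(inputs$matrices[[g]],
                                             inputs$groups))
    hap_rows[[g]] <- data.frame(
      gene_id = g, haplotype = rownames(hs$counts), allele_string =
        hs$haplotypes, hs$counts, check.names = FALSE,
      stringsAsFactors = FALSE)
    if (nrow(hs$edges))
      edge_rows[[g]] <- data.frame(gene_id = g, hs$edges,
                                   stringsAsFactors = FALSE)
  }
  haps_tab <- if (length(hap_rows)) do.call(rbind, hap_rows) else NULL
  edges_tab <- if (length(edge_rows)) do.call(rbind, edge_rows) else NULL
  if (!is.null(haps_tab)) .write_tsv(haps_tab,
                                     file.path(outdir, "haplotypes.tsv"))
  if (!is.null(edges_tab)) .write_tsv(edges_tab,
                                      file.path(outdir, "hapnet_edges.tsv"))

  summary <- list(
    n_genes = nrow(gstats),
    n_neutral_genes = sum(gstats$is_neutral),
    n_snps_total = nrow(sstats),
    n_snps_synonymous = sum(sstats$functional_class %in% "synonymous"),
    n_snps_nonsynonymous = sum(sstats$functional_class %in% "nonsynonymous"),
    baseline_mean_rod = baseline$mean_rod,
    baseline_n_loci_used = baseline$n_loci_used,
    baseline_n_excluded_nonfinite = baseline$n_loci_excluded_nonfinite,
    n_snps_selected = nrow(snps_sel),
    n_genes_under_selection = sum(calls$under_selection),
    n_genes_nonsyn_selected = sum(calls$has_nonsyn_selected %in% TRUE),
    enrichment = if (is.null(enrich)) NULL else list(
      table = enrich$table,
      pct_selected_seed_pref = enrich$pct_selected_seed_pref,
      pct_selected_other = enrich$pct_selected_other,
      chi2 = enrich$chi2, p_value = enrich$p_value)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  message("domesticscan: ", summary$n_genes_under_selection,
          " genes under selection (baseline mean RoD = ",
          signif(baseline$mean_rod, 4), ")")

  invisible(list(gene_stats = gstats, site_stats = sstats,
                 baseline = baseline, selection_calls = calls,
                 selected_snps = snps_sel, enrichment = enrich,
                 haplotypes = haps_tab, hapnet_edges = edges_tab,
                 summary = summary))
}

#' Simulate a dataset and run the scan on it
#'
#' Convenience wrapper: \code{\link{generate_dataset}} into \code{dir}, then
#' \code{\link{run_pipeline}} with the generated paths.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param dir Working directory for inputs and outputs.
#' @return The \code{\link{run_pipeline}} result, with the generator's
#'   \code{truth} table attached.
#' @export
run_synthetic_pipeline <- function(cfg, dir = tempfile("domesticscan")) {
  ds <- generate_dataset(cfg, dir)
  res <- run_pipeline(list(fasta = ds$fasta, vcf = ds$vcf,
                           groups = ds$groups, annotation = ds$annotation,
                           expression = ds$expression, tissues = ds$tissues,
                           outdir = file.path(dir, "scan")))
  res$truth <- ds$truth
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
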