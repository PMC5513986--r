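#' Neutral-locus RoD baseline
#'
#' Arithmetic mean of the finite gene-level RoD values of the neutral loci.
#' Infinite or undefined RoD values (landrace or both groups invariant) are
#' excluded from the mean and counted for transparency.
#'
#' @param gene_stats \code{data.frame} from \code{\link{gene_stats}} rows,
#'   restricted to neutral genes, with a \code{rod} column.
#' @return List with \code{mean_rod}, \code{n_loci_used},
#'   \code{n_loci_excluded_nonfinite}.
#' @export
neutral_baseline <- function(gene_stats) {
  r <- gene_stats$rod
  usable <- is.finite(r)
  if (!any(usable)) stop("calibration error: no neutral locus with finite RoD")
  list(mean_rod = mean(r[usable]),
       n_loci_used = sum(usable),
       n_loci_excluded_nonfinite = sum(!usable))
}

#' Per-SNP purifying-selection test
#'
#' A SNP is flagged as carrying a purifying-selection signature when all
#' three criteria hold: (1) its per-site RoD exceeds the neutral baseline,
#' evaluated in the cross-multiplied form \code{pi_wild > mean_rod *
#' pi_landrace} so that infinite per-site RoD needs no division; (2) the
#' per-site Fst is strictly positive; and (3) Tajima's D of the landrace
#' group at the site is defined and strictly negative. Sites where the
#' landrace group is monomorphic have undefined site D and therefore never
#' pass, even though their RoD is infinite.
#'
#' @param site_stats \code{data.frame} from \code{\link{per_site_stats}}.
#' @param baseline List from \code{\link{neutral_baseline}}.
#' @return Logical vector, one flag per row of \code{site_stats}.
#' @export
snp_selection_test <- function(site_stats, baseline) {
  c1 <- !is.na(site_stats$pi_wild) & !is.na(site_stats$pi_landrace) &
    site_stats$pi_wild > baseline$mean_rod * site_stats$pi_landrace
  c2 <- !is.na(site_stats$fst_site) & site_stats$fst_site > 0
  c3 <- !is.na(site_stats$tajima_d_site_landrace) &
    site_stats$tajima_d_site_landrace < 0
  c1 & c2 & c3
}

#' Aggregate per-SNP selection flags to gene-level calls
#'
#' @param site_stats Annotated per-site table (ideally with a
#'   \code{functional_class} column from \code{\link{annotate_sites}}).
#' @param baseline List from \code{\link{neutral_baseline}}.
#' @return \code{data.frame} with one row per gene present in
#'   \code{site_stats}: \code{gene_id, n_snps_total, n_snps_selected,
#'   under_selection, has_nonsyn_selected}.
#' @export
gene_selection_calls <- function(site_stats, baseline) {
  flag <- snp_selection_test(site_stats, baseline)
  gene_ids <- unique(site_stats$gene_id)
  has_fc <- "functional_class" %in% names(site_stats)
  out <- lapply(gene_ids, function(g) {
    rows <- site_stats$gene_id == g
    sel <- flag & rows
    data.frame(
      gene_id = g,
      n_snps_total = sum(rows),
      n_snps_selected = sum(sel),
      under_selection = sum(sel) >= 1L,
      has_nonsyn_selected = if (has_fc) {
        any(sel & site_stats$functional_class %in% "nonsynonymous")
      } else NA,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the table of selected SNPs
#'
#' @inheritParams gene_selection_calls
#' @return The rows of \code{site_stats} passing the three-criterion test.
#' @export
selected_snps <- function(site_stats, baseline) {
  site_stats[snp_selection_test(site_stats, baseline), , drop = FALSE]
}
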