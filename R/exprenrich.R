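#' Classify seed-preferential expression
#'
#' A gene is seed-preferential when its maximum FPKM over seed-tissue samples
#' exceeds twice its maximum over non-seed samples (strict inequality). The
#' non-seed maximum is floored at 1 FPKM so that genes silent outside the
#' seed are classified positive without an infinite fold change.
#'
#' @param fpkm Named numeric vector of FPKM values over expression samples.
#' @param tissue_class Character vector parallel to \code{fpkm}, values
#'   \code{"seed"} or \code{"non_seed"}; both classes must be present.
#' @param fold Fold-change threshold (default 2).
#' @param floor Minimum non-seed FPKM used in the comparison (default 1).
#' @return Logical flag.
#' @export
classify_seed_preferential <- function(fpkm, tissue_class, fold = 2,
                                       floor = 1) {
  if (any(fpkm < 0)) stop("domain error: negative FPKM")
  if (!all(c("seed", "non_seed") %in% tissue_class))
    stop("both tissue classes must be present")
  max_seed <- max(fpkm[tissue_class == "seed"])
  max_nonseed <- max(fpkm[tissue_class == "non_seed"])
  max_seed > fold * max(max_nonseed, floor)
}

#' Build expression profiles from an FPKM table
#'
#' @param expression_path TSV with a \code{gene_id} column and one column per
#'   expression sample.
#' @param tissues_path Two-column TSV \code{sample_label, tissue_class}.
#' @param fold,floor Passed to \code{\link{classify_seed_preferential}}.
#' @return \code{data.frame} with \code{gene_id, max_seed, max_nonseed,
#'   seed_preferential}.
#' @export
expression_profiles <- function(expression_path, tissues_path, fold = 2,
                                floor = 1) {
  ex <- utils::read.delim(expression_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ti <- utils::read.delim(tissues_path, stringsAsFactors = FALSE)
  samples <- setdiff(names(ex), "gene_id")
  cls <- ti$tissue_class[match(samples, ti$sample_label)]
  if (anyNA(cls)) stop("expression sample missing from tissue table")
  mat <- as.matrix(ex[, samples, drop = FALSE])
  data.frame(
    gene_id = ex$gene_id,
    max_seed = apply(mat[, cls == "seed", drop = FALSE], 1L, max),
    max_nonseed = apply(mat[, cls == "non_seed", drop = FALSE], 1L, max),
    seed_preferential = apply(mat, 1L, classify_seed_preferential,
                              tissue_class = cls, fold = fold, floor = floor),
    stringsAsFactors = FALSE)
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' Computed from the textbook formula sum((O - E)^2 / E) with expected counts
#' from the row and column margins, without continuity correction. The
#' p-value uses the chi-square survival function with one degree of freedom.
#'
#' @param a,b,c,d Cell counts; rows are seed-preferential yes/no, columns
#'   under-selection yes/no.
#' @return List with \code{statistic}, \code{df = 1}, \code{p_value}.
#' @export
pearson_chi2_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(o < 0)) stop("domain error: negative count")
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  if (any(e == 0)) return(list(statistic = NA_real_, df = 1L,
                               p_value = NA_real_))
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Enrichment of selection among seed-preferential genes
#'
#' Crosses gene-level selection calls with seed-preferential expression
#' classes over the genes present in both inputs, reports the 2x2 table, the
#' percentage of genes under selection within each expression class (rounded
#' to the nearest integer), and the uncorrected Pearson chi-square.
#'
#' @param selection_calls \code{data.frame} from
#'   \code{\link{gene_selection_calls}}.
#' @param profiles \code{data.frame} from \code{\link{expression_profiles}}.
#' @return List with \code{table} (2x2 matrix), \code{pct_selected_seed_pref},
#'   \code{pct_selected_other}, \code{chi2}, \code{p_value}, \code{n_genes}.
#' @export
enrichment_report <- function(selection_calls, profiles) {
  common <- intersect(selection_calls$gene_id, profiles$gene_id)
  if (!length(common)) stop("input error: no gene present in both inputs")
  sel <- selection_calls$under_selection[match(common, selection_calls$gene_id)]
  pref <- profiles$seed_preferential[match(common, profiles$gene_id)]
  a <- sum(pref & sel); b <- sum(pref & !sel)
  c_ <- sum(!pref & sel); d <- sum(!pref & !sel)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(seed_preferential = c("yes", "no"),
                                under_selection = c("yes", "no")))
  chi <- pearson_chi2_2x2(a, b, c_, d)
  list(table = tab,
       pct_selected_seed_pref = round(100 * a / (a + b)),
       pct_selected_other = round(100 * c_ / (c_ + d)),
       chi2 = chi$statistic, p_value = chi$p_value,
       n_genes = length(common))
}
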