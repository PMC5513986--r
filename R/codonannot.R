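#' Classify a CDS SNP as synonymous or non-synonymous
#'
#' Substitutes the alternate allele into the reference codon containing the
#' site and translates both codons with the standard nuclear genetic code.
#' Identical amino acids give \code{"synonymous"}; anything else, including
#' stop gain or loss, gives \code{"nonsynonymous"}. Each SNP is evaluated in
#' the reference codon context only (no haplotype-aware multi-SNP codons).
#'
#' @param reference_cds Reference CDS string; length a multiple of 3.
#' @param cds_position 0-based position of the SNP within the CDS.
#' @param ref_allele,alt_allele Single bases; \code{ref_allele} must match the
#'   reference at \code{cds_position}.
#' @return \code{"synonymous"} or \code{"nonsynonymous"}.
#' @export
classify_snp <- function(reference_cds, cds_position, ref_allele, alt_allele) {
  L <- nchar(reference_cds)
  if (L %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (cds_position < 0 || cds_position >= L)
    stop("position outside CDS")
  bases <- c("A", "C", "G", "T")
  if (!(ref_allele %in% bases) || !(alt_allele %in% bases))
    stop("domain error: ambiguous or invalid base")
  if (substr(reference_cds, cds_position + 1L, cds_position + 1L) != ref_allele)
    stop("consistency error: ref allele does not match reference CDS")
  codon_start <- (cds_position %/% 3L) * 3L + 1L
  codon <- substr(reference_cds, codon_start, codon_start + 2L)
  if (grepl("[^ACGT]", codon)) stop("domain error: ambiguous base in codon")
  offset <- cds_position %% 3L + 1L
  alt_codon <- codon
  substr(alt_codon, offset, offset) <- alt_allele
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Annotate per-SNP statistics with functional class
#'
#' Adds a \code{functional_class} column to a per-site statistics table (see
#' \code{\link{per_site_stats}}) by classifying each SNP against its gene's
#' reference CDS. Genes whose CDS length is not a multiple of 3 are skipped
#' with a warning and receive \code{NA}.
#'
#' @param site_stats \code{data.frame} with \code{gene_id, cds_position, ref,
#'   alt} columns.
#' @param genes \code{data.frame} with \code{gene_id, reference_cds}.
#' @return \code{site_stats} with a \code{functional_class} column.
#' @export
annotate_sites <- function(site_stats, genes) {
  ref_by_gene <- stats::setNames(genes$reference_cds, genes$gene_id)
  fc <- rep(NA_character_, nrow(site_stats))
  bad <- character(0)
  for (i in seq_len(nrow(site_stats))) {
    cds <- ref_by_gene[[site_stats$gene_id[i]]]
    if (is.null(cds)) next
    if (nchar(cds) %% 3L != 0L) {
      bad <- union(bad, site_stats$gene_id[i])
      next
    }
    fc[i] <- classify_snp(cds, site_stats$cds_position[i],
                          site_stats$ref[i], site_stats$alt[i])
  }
  if (length(bad))
    warning("CDS length not a multiple of 3; codon annotation skipped for: ",
            paste(bad, collapse = ", "))
  site_stats$functional_class <- fc
  site_stats
}
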