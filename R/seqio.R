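#' Per-gene alignment matrix
#'
#' Container for the biallelic SNPs of one gene's CDS across the panel:
#' ordered sample ids, strictly increasing 0-based CDS positions, the
#' reference and alternate allele per site, and a samples x sites genotype
#' matrix coded 0 (reference), 1 (alternate), \code{NA} (missing).
#'
#' @param gene_id Gene identifier.
#' @param sample_ids Character vector of sample ids (rows of \code{geno}).
#' @param pos Integer vector of 0-based CDS positions, strictly increasing.
#' @param ref,alt Single-character allele vectors parallel to \code{pos}.
#' @param geno Integer matrix, \code{length(sample_ids)} rows and
#'   \code{length(pos)} columns, values in \{0, 1, NA\}.
#' @param cds_length CDS length in bp.
#' @return Object of class \code{aln_matrix}.
#' @export
aln_matrix <- function(gene_id, sample_ids, pos, ref, alt, geno, cds_length) {
  pos <- as.integer(pos)
  geno <- matrix(as.integer(geno), nrow = length(sample_ids),
                 ncol = length(pos))
  rownames(geno) <- sample_ids
  if (length(pos) && any(diff(pos) <= 0))
    stop("positions must be strictly increasing")
  if (length(pos) && (min(pos) < 0 || max(pos) >= cds_length))
    stop("consistency error: site position outside CDS")
  if (length(ref) != length(pos) || length(alt) != length(pos))
    stop("ref/alt must be parallel to pos")
  structure(list(gene_id = gene_id, sample_ids = sample_ids, pos = pos,
                 ref = ref, alt = alt, geno = geno,
                 cds_length = as.integer(cds_length)),
            class = "aln_matrix")
}

#' @export
print.aln_matrix <- function(x, ...) {
  cat("aln_matrix:", x$gene_id, "-", length(x$sample_ids), "samples,",
      length(x$pos), "SNPs,", x$cds_length, "bp CDS\n")
  invisible(x)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

## Parse one VCF GT string (haploid or diploid separators) into 0/1/NA.
## Heterozygous or half-missing diploid calls become NA (inbred-line rule).
.parse_gt <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    g <- sub(":.*$", "", g)
    al <- strsplit(g, "[/|]")[[1L]]
    al <- al[al != ""]
    if (!length(al) || any(al == ".")) return(NA_integer_)
    u <- unique(al)
    if (length(u) != 1L) return(NA_integer_)   # heterozygous -> missing
    as.integer(u)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read the pipeline's input bundle
#'
#' Reads the per-gene reference FASTA, the haploid CDS VCF, the
#' sample-to-group TSV and the gene annotation TSV, checks their mutual
#' consistency, and assembles one \code{\link{aln_matrix}} per annotated gene.
#' VCF positions (1-based within the CDS) are converted to internal 0-based
#' coordinates; multi-allelic or indel records are dropped with a warning;
#' heterozygous or partially missing genotype calls become missing;
#' minus-strand genes are reverse-complemented into coding orientation.
#'
#' @param fasta_path Multi-FASTA, one record per gene, record id = gene id.
#' @param vcf_path VCF v4.2 with CHROM = gene id and POS relative to the CDS.
#' @param groups_path Two-column TSV \code{sample_id, group_label}.
#' @param annotation_path TSV \code{gene_id, cds_length, strand, is_neutral}.
#' @return List with \code{genes} (annotation \code{data.frame} plus
#'   \code{reference_cds}), \code{groups} (\code{data.frame}) and
#'   \code{matrices} (named list of \code{aln_matrix}).
#' @export
read_inputs <- function(fasta_path, vcf_path, groups_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  genes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  groups <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (anyDuplicated(groups$sample_id))
    stop("consistency error: duplicated sample ids in groups file")
  if (!all(genes$gene_id %in% names(seqs)))
    stop("consistency error: annotated gene missing from FASTA")
  ref_seq <- as.character(seqs)[genes$gene_id]
  if (any(nchar(ref_seq) != genes$cds_length))
    stop("consistency error: FASTA length != annotated cds_length")
  genes$reference_cds <- unname(ref_seq)

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(v)
  if (is.null(dim(fix_raw)))   # single-record VCFs come back as a vector
    fix_raw <- matrix(fix_raw, nrow = 1L,
                      dimnames = list(NULL, names(fix_raw)))
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(gt_raw)
  if (!all(vcf_samples %in% groups$sample_id))
    stop("consistency error: VCF sample(s) absent from groups file: ",
         paste(setdiff(vcf_samples, groups$sample_id), collapse = ", "))

  keep <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (any(!keep))
    warning(sum(!keep), " multi-allelic or indel VCF record(s) dropped")
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  matrices <- vector("list", nrow(genes))
  names(matrices) <- genes$gene_id
  pos_all <- as.integer(fix$POS)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    L <- genes$cds_length[i]
    rows <- which(fix$CHROM == gid)
    pos <- pos_all[rows] - 1L            # 1-based VCF -> 0-based CDS
    if (length(pos) && (min(pos) < 0 || max(pos) >= L))
      stop("consistency error: VCF POS outside CDS for gene ", gid)
    ref <- fix$REF[rows]; alt <- fix$ALT[rows]
    geno <- if (length(rows)) {
      t(apply(gt_raw[rows, , drop = FALSE], 1L, .parse_gt))
    } else matrix(integer(0), nrow = 0, ncol = length(vcf_samples))
    geno <- t(matrix(geno, nrow = length(rows), ncol = length(vcf_samples)))
    if (identical(genes$strand[i], "-")) {
      pos <- L - 1L - pos
      ref <- unname(.complement[ref])
      alt <- unname(.complement[alt])
    }
    o <- order(pos)
    matrices[[gid]] <- aln_matrix(
      gene_id = gid, sample_ids = vcf_samples, pos = pos[o],
      ref = ref[o], alt = alt[o], geno = geno[, o, drop = FALSE],
      cds_length = L)
  }
  list(genes = genes, groups = groups, matrices = matrices)
}

#' Sample ids belonging to one group label
#'
#' @param groups \code{data.frame} with \code{sample_id, group_label}.
#' @param label Group label, e.g. \code{"wild_weedy"} or \code{"landrace"}.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(groups, label) {
  groups$sample_id[groups$group_label == label]
}

#' Read a flat key-value run configuration file
#'
#' YAML-style \code{key: value} pairs; used by the command-line wrapper to
#' locate inputs and set the contrast groups and thresholds.
#'
#' @param path Configuration file path.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
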