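#' Simulation configuration for the two-population domestication scenario
#'
#' Bundles and validates the parameters of the synthetic wild/weedy versus
#' landrace panel: sample sizes, per-site scaled mutation rate theta = 4*N*mu,
#' split time in coalescent units of 2N generations, the post-split landrace
#' bottleneck, and the per-gene diversity loss applied to genes simulated as
#' selected.
#'
#' Defaults describe a 25-genotype panel (12 wild/weedy + 13 landrace inbred
#' lines coded as one haplotype each), 114 candidate and 159 neutral genes of
#' 1404 bp CDS, theta = 0.005 per site (theta*L about 7), a split 0.15
#' coalescent units ago with the landrace lineage at 30 percent of the wild
#' effective size, and a 10-fold extra diversity loss at half of the candidate
#' genes.
#'
#' @param n_wild,n_landrace Haploid sample counts per group (each \code{>= 2}).
#' @param n_candidate_genes,n_neutral_genes Gene counts.
#' @param cds_length CDS length in bp, a multiple of 3.
#' @param theta Population-scaled mutation rate per site (\code{> 0}).
#' @param t_split Split time, coalescent units of 2N generations.
#' @param bottleneck_factor Ratio in (0, 1] of landrace to wild effective size
#'   after the split.
#' @param selection_rod Multiplicative extra diversity reduction (\code{>= 1})
#'   applied to selected candidate genes.
#' @param frac_selected Proportion of candidate genes simulated as selected.
#' @param p_seed_pref_selected,p_seed_pref_unselected Probability that a
#'   selected / unselected candidate gene is given seed-preferential
#'   expression in the synthetic FPKM table.
#' @param n_seed_samples,n_nonseed_samples Expression sample counts per
#'   tissue class (\code{>= 2} and \code{>= 5}).
#' @param rng_seed Integer seed driving all randomness.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_wild = 12L, n_landrace = 13L,
                       n_candidate_genes = 114L, n_neutral_genes = 159L,
                       cds_length = 1404L, theta = 0.005,
                       t_split = 0.15, bottleneck_factor = 0.3,
                       selection_rod = 10, frac_selected = 0.5,
                       p_seed_pref_selected = 0.27,
                       p_seed_pref_unselected = 0.10,
                       n_seed_samples = 4L, n_nonseed_samples = 5L,
                       rng_seed = 42L) {
  cfg <- list(n_wild = as.integer(n_wild), n_landrace = as.integer(n_landrace),
              n_candidate_genes = as.integer(n_candidate_genes),
              n_neutral_genes = as.integer(n_neutral_genes),
              cds_length = as.integer(cds_length), theta = theta,
              t_split = t_split, bottleneck_factor = bottleneck_factor,
              selection_rod = selection_rod, frac_selected = frac_selected,
              p_seed_pref_selected = p_seed_pref_selected,
              p_seed_pref_unselected = p_seed_pref_unselected,
              n_seed_samples = as.integer(n_seed_samples),
              n_nonseed_samples = as.integer(n_nonseed_samples),
              rng_seed = as.integer(rng_seed))
  if (cfg$n_wild < 2 || cfg$n_landrace < 2)
    stop("configuration error: need at least 2 samples per group")
  if (cfg$cds_length %% 3L != 0L)
    stop("configuration error: cds_length must be a multiple of 3")
  if (cfg$theta < 0) stop("configuration error: theta must be >= 0")
  if (cfg$bottleneck_factor <= 0 || cfg$bottleneck_factor > 1)
    stop("configuration error: bottleneck_factor must be in (0, 1]")
  if (cfg$selection_rod < 1)
    stop("configuration error: selection_rod must be >= 1")
  if (cfg$frac_selected < 0 || cfg$frac_selected > 1)
    stop("configuration error: frac_selected must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

## Simulate the genealogy of n_wild + n_landrace haploid lineages under a
## split model: one panmictic ancestor (relative size 1), split at t_split,
## landrace deme at relative size `bottleneck_factor` afterwards (forward in
## time). For a selected gene the landrace deme carries a partial sweep:
## each landrace lineage escapes with probability 1/selection_rod; swept
## lineages coalesce among themselves in a deme shrunk a further
## 1/selection_rod, escaped lineages at the neutral landrace rate, and the
## two backgrounds do not coalesce with each other before the split.
## Returns a list of branch segments (members = sample indices below the
## branch, len = branch length in units of 2N generations).
.simulate_genealogy <- function(cfg, selected) {
  n <- cfg$n_wild + cfg$n_landrace
  ## lineage bookkeeping: members (list of integer vectors), class, blen
  members <- lapply(seq_len(n), identity)
  cls <- c(rep("W", cfg$n_wild), rep("L", cfg$n_landrace))
  if (selected && cfg$selection_rod > 1) {
    esc <- stats::runif(cfg$n_landrace) < 1 / cfg$selection_rod
    cls[cfg$n_wild + which(esc)] <- "E"
    ## swept lineages sit in a deme shrunk by the sweep
    b_swept <- cfg$bottleneck_factor / cfg$selection_rod
  } else {
    b_swept <- cfg$bottleneck_factor
  }
  blen <- numeric(n)
  segments <- vector("list", 2L * n)
  nseg <- 0L
  push_segment <- function(mem, len) {
    nseg <<- nseg + 1L
    segments[[nseg]] <<- list(members = mem, len = len)
  }
  size_of <- c(W = 1, L = cfg$bottleneck_factor, E = cfg$bottleneck_factor,
               A = 1)
  size_of["L"] <- if (selected) b_swept else cfg$bottleneck_factor
  t <- 0
  repeat {
    k <- length(members)
    if (k == 1L) break
    classes <- unique(cls)
    rates <- vapply(classes, function(cl) {
      m <- sum(cls == cl)
      m * (m - 1) / 2 / size_of[[cl]]
    }, numeric(1))
    total <- sum(rates)
    in_split_phase <- t < cfg$t_split && any(cls != "A")
    if (total <= 0) {
      if (!in_split_phase) stop("internal: no coalescence possible")
      dt <- cfg$t_split - t
    } else {
      dt <- stats::rexp(1, total)
    }
    if (in_split_phase && t + dt >= cfg$t_split) {
      dt <- cfg$t_split - t
      blen <- blen + dt
      t <- cfg$t_split
      cls[] <- "A"   # merge demes into the ancestral pool
      next
    }
    blen <- blen + dt
    t <- t + dt
    cl <- sample(classes, 1L, prob = rates)
    idx <- which(cls == cl)
    pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
    i <- pair[1L]; j <- pair[2L]
    push_segment(members[[i]], blen[i])
    push_segment(members[[j]], blen[j])
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    blen[i] <- 0
    members[[j]] <- NULL
    cls <- cls[-j]
    blen <- blen[-j]
  }
  segments[seq_len(nseg)]
}

#' Simulate one gene's alignment matrix
#'
#' Draws a genealogy under the two-population split/bottleneck coalescent and
#' places infinite-sites mutations on its branches as Poisson events with rate
#' theta/2 per site per unit of 2N generations. A mutation landing on an
#' already-mutated site is re-placed, so every polymorphic site is biallelic.
#' For \code{selected = TRUE} the landrace lineage carries a partial sweep
#' that shrinks landrace-private branch lengths (see \code{\link{sim_config}}),
#' emulating the extra reduction of diversity at genes targeted during
#' domestication.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param selected Logical; simulate this gene as under selection.
#' @param gene_id Gene identifier for the returned matrix.
#' @param reference_cds Optional reference CDS string; randomly drawn when
#'   \code{NULL}.
#' @return An \code{\link{aln_matrix}} with attribute \code{reference_cds}.
#' @export
simulate_gene <- function(cfg, selected = FALSE, gene_id = "gene1",
                          reference_cds = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_wild + cfg$n_landrace
  L <- cfg$cds_length
  if (is.null(reference_cds)) {
    reference_cds <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = "")
  }
  sample_ids <- c(sprintf("wild_%02d", seq_len(cfg$n_wild)),
                  sprintf("landrace_%02d", seq_len(cfg$n_landrace)))
  segs <- .simulate_genealogy(cfg, selected)
  lens <- vapply(segs, `[[`, numeric(1), "len")
  if (selected && cfg$selection_rod > 1) {
    ## landrace-private branches carry 1/selection_rod the mutation load
    landrace_idx <- cfg$n_wild + seq_len(cfg$n_landrace)
    private <- vapply(segs, function(s) all(s$members %in% landrace_idx),
                      logical(1))
    lens[private] <- lens[private] / cfg$selection_rod
  }
  total_len <- sum(lens)
  n_mut <- if (cfg$theta > 0) stats::rpois(1L, cfg$theta / 2 * L * total_len) else 0L
  n_mut <- min(n_mut, L)  # infinite-sites cap: at most one mutation per site
  geno <- matrix(0L, nrow = n, ncol = 0L)
  pos <- integer(0); ref <- character(0); alt <- character(0)
  if (n_mut > 0) {
    seg_idx <- sample.int(length(segs), n_mut, replace = TRUE, prob = lens)
    used <- logical(L)
    refchars <- strsplit(reference_cds, "", fixed = TRUE)[[1L]]
    bases <- c("A", "C", "G", "T")
    pos <- integer(n_mut); ref <- character(n_mut); alt <- character(n_mut)
    geno <- matrix(0L, nrow = n, ncol = n_mut)
    for (m in seq_len(n_mut)) {
      repeat {   # resample occupied positions to keep sites biallelic
        p <- sample.int(L, 1L)
        if (!used[p]) break
      }
      used[p] <- TRUE
      pos[m] <- p - 1L                 # 0-based CDS coordinate
      ref[m] <- refchars[p]
      alt[m] <- sample(setdiff(bases, ref[m]), 1L)
      geno[segs[[seg_idx[m]]]$members, m] <- 1L
    }
    ## drop mutations above the whole sample (root-adjacent full segments)
    poly <- colSums(geno) < n & colSums(geno) > 0
    geno <- geno[, poly, drop = FALSE]
    pos <- pos[poly]; ref <- ref[poly]; alt <- alt[poly]
    o <- order(pos)
    geno <- geno[, o, drop = FALSE]
    pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  }
  out <- aln_matrix(gene_id = gene_id, sample_ids = sample_ids,
                    pos = pos, ref = ref, alt = alt, geno = geno,
                    cds_length = L)
  attr(out, "reference_cds") <- reference_cds
  out
}

#' Generate a complete synthetic input bundle
#'
#' Simulates candidate and neutral genes under \code{\link{sim_config}} and
#' writes every file the pipeline consumes: a multi-FASTA of per-gene
#' reference CDS, a haploid VCF v4.2 over CDS coordinates, a sample-to-group
#' TSV, a gene annotation TSV, an FPKM expression matrix with a tissue-class
#' TSV, and a ground-truth table recording which genes were simulated as
#' neutral/selected together with their realized RoD. Output is byte-stable
#' for a fixed \code{rng_seed}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with file paths (\code{fasta, vcf, groups,
#'   annotation, expression, tissues, truth}), the in-memory
#'   \code{matrices} (list of \code{aln_matrix}) and the \code{truth}
#'   \code{data.frame}.
#' @export
generate_dataset <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$rng_seed)

  n_cand <- cfg$n_candidate_genes
  n_neut <- cfg$n_neutral_genes
  gene_ids <- c(sprintf("cand%03d", seq_len(n_cand)),
                sprintf("neut%03d", seq_len(n_neut)))
  is_neutral <- c(rep(FALSE, n_cand), rep(TRUE, n_neut))
  n_sel <- round(cfg$frac_selected * n_cand)
  is_selected <- c(rep(c(TRUE, FALSE), c(n_sel, n_cand - n_sel)),
                   rep(FALSE, n_neut))

  matrices <- vector("list", length(gene_ids))
  names(matrices) <- gene_ids
  realized <- numeric(length(gene_ids))
  wild_ids <- sprintf("wild_%02d", seq_len(cfg$n_wild))
  land_ids <- sprintf("landrace_%02d", seq_len(cfg$n_landrace))
  for (i in seq_along(gene_ids)) {
    m <- simulate_gene(cfg, selected = is_selected[i], gene_id = gene_ids[i])
    matrices[[i]] <- m
    realized[i] <- rod(theta_pi(m, wild_ids), theta_pi(m, land_ids))
  }

  ## --- reference FASTA
  fasta <- file.path(outdir, "reference.fasta")
  seqs <- Biostrings::DNAStringSet(vapply(matrices, attr, character(1),
                                          "reference_cds"))
  names(seqs) <- gene_ids
  Biostrings::writeXStringSet(seqs, fasta, width = 70L)

  ## --- VCF (haploid GT, POS 1-based within the gene CDS)
  vcf <- file.path(outdir, "variants.vcf")
  sample_ids <- c(wild_ids, land_ids)
  .write_vcf(vcf, matrices, sample_ids)

  ## --- groups TSV
  groups <- file.path(outdir, "groups.tsv")
  utils::write.table(
    data.frame(sample_id = sample_ids,
               group_label = rep(c("wild_weedy", "landrace"),
                                 c(cfg$n_wild, cfg$n_landrace))),
    groups, sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- annotation TSV
  annotation <- file.path(outdir, "annotation.tsv")
  utils::write.table(
    data.frame(gene_id = gene_ids, cds_length = cfg$cds_length,
               strand = "+", is_neutral = is_neutral),
    annotation, sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- expression (candidate genes only; seed-preference enriched in
  ##     selected genes so the enrichment stage has signal)
  p_pref <- ifelse(is_selected[seq_len(n_cand)],
                   cfg$p_seed_pref_selected, cfg$p_seed_pref_unselected)
  seed_pref <- stats::runif(n_cand) < p_pref
  expr_samples <- c(sprintf("seed_s%d", seq_len(cfg$n_seed_samples)),
                    sprintf("nonseed_s%d", seq_len(cfg$n_nonseed_samples)))
  tissue_class <- rep(c("seed", "non_seed"),
                      c(cfg$n_seed_samples, cfg$n_nonseed_samples))
  fpkm <- matrix(0, nrow = n_cand, ncol = length(expr_samples),
                 dimnames = list(gene_ids[seq_len(n_cand)], expr_samples))
  for (i in seq_len(n_cand)) {
    baseline <- stats::rlnorm(1, meanlog = 2, sdlog = 1)
    fold <- if (seed_pref[i]) {
      max(2.5, stats::rlnorm(1, meanlog = log(6), sdlog = 0.4))
    } else 1
    fpkm[i, tissue_class == "seed"] <-
      baseline * fold * stats::rlnorm(cfg$n_seed_samples, 0, 0.3)
    fpkm[i, tissue_class == "non_seed"] <-
      baseline * stats::rlnorm(cfg$n_nonseed_samples, 0, 0.3)
  }
  fpkm <- round(fpkm, 4)
  expression <- file.path(outdir, "expression.tsv")
  utils::write.table(data.frame(gene_id = rownames(fpkm), fpkm,
                                check.names = FALSE),
                     expression, sep = "\t", quote = FALSE, row.names = FALSE)
  tissues <- file.path(outdir, "tissues.tsv")
  utils::write.table(data.frame(sample_label = expr_samples,
                                tissue_class = tissue_class),
                     tissues, sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- truth table
  truth <- data.frame(gene_id = gene_ids, is_neutral = is_neutral,
                      is_selected = is_selected, realized_rod = realized,
                      stringsAsFactors = FALSE)
  truth$seed_preferential <- c(seed_pref, rep(NA, n_neut))
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(fasta = fasta, vcf = vcf, groups = groups,
                 annotation = annotation, expression = expression,
                 tissues = tissues, truth_path = truth_path,
                 matrices = matrices, truth = truth))
}

## Minimal deterministic VCF v4.2 writer for haploid per-gene CDS variants.
.write_vcf <- function(path, matrices, sample_ids) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=domesticscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")), con)
  for (m in matrices) {
    if (length(m$pos) == 0L) next
    idx <- match(sample_ids, m$sample_ids)
    for (j in seq_along(m$pos)) {
      gt <- m$geno[idx, j]
      gt_str <- ifelse(is.na(gt), ".", as.character(gt))
      writeLines(paste(c(m$gene_id, m$pos[j] + 1L, ".", m$ref[j], m$alt[j],
                         ".", "PASS", ".", "GT", gt_str), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}
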