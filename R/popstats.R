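#' Tajima (1989) normalizing constants
#'
#' Computes the harmonic-number based constants used by Watterson's theta and
#' Tajima's D for a sample of \code{n} sequences.
#'
#' @param n Sample size (number of sequences), \code{n >= 2}.
#' @return Named list with \code{a1, a2, b1, b2, c1, c2, e1, e2}.
#' @export
tajima_constants <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

## Per-site heterozygosity-style pi on the count scale:
## probability that two sequences drawn without replacement differ at the site.
## x is a 0/1/NA genotype vector at one site.
.site_pi <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(NA_real_)
  n1 <- sum(x == 1L)
  2 * n1 * (n - n1) / (n * (n - 1))
}

.subset_geno <- function(mat, samples) {
  if (is.null(samples)) return(mat$geno)
  idx <- match(samples, mat$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  mat$geno[idx, , drop = FALSE]
}

#' Nucleotide diversity (theta-pi) of a sample subset
#'
#' Average pairwise difference per site (Nei-Li estimator): the per-site
#' mismatch probabilities among non-missing alleles are summed over all sites
#' and divided by the full CDS length, so monomorphic sites contribute zero.
#'
#' @param mat An \code{aln_matrix} (see \code{\link{aln_matrix}}).
#' @param samples Character vector of sample ids, or \code{NULL} for all.
#' @return Per-site diversity (non-negative), 0 for a matrix with no
#'   polymorphic site, or \code{NA} when fewer than two samples carry data at
#'   every site.
#' @export
theta_pi <- function(mat, samples = NULL) {
  g <- .subset_geno(mat, samples)
  if (nrow(g) < 2) return(NA_real_)
  if (ncol(g) == 0L) return(0)
  pis <- apply(g, 2L, .site_pi)
  if (all(is.na(pis))) return(NA_real_)
  sum(pis, na.rm = TRUE) / mat$cds_length
}

#' Watterson's theta of a sample subset
#'
#' Segregating sites within the subset scaled by the harmonic number of the
#' subset size, per site of CDS.
#'
#' @inheritParams theta_pi
#' @return Per-site estimate, or \code{NA} for fewer than two samples.
#' @export
theta_w <- function(mat, samples = NULL) {
  g <- .subset_geno(mat, samples)
  n <- nrow(g)
  if (n < 2) return(NA_real_)
  S <- .count_segregating(g)
  S / (tajima_constants(n)$a1 * mat$cds_length)
}

## number of sites polymorphic within the genotype matrix (complete-case)
.count_segregating <- function(g) {
  if (ncol(g) == 0L) return(0L)
  seg <- apply(g, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && any(x == 1L) && any(x == 0L)
  })
  sum(seg)
}

#' Tajima's D of a sample subset
#'
#' Normalized difference between the mean pairwise difference count and the
#' segregating-sites estimate of the scaled mutation rate
#' (D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))). The mean pairwise difference
#' k is the sum over sites of complete-case mismatch probabilities, i.e. a
#' count, not a per-site rate. Undefined (\code{NA}) when the subset has no
#' segregating site or fewer than four sequences.
#'
#' @inheritParams theta_pi
#' @return Tajima's D, or \code{NA} when undefined.
#' @export
tajima_d <- function(mat, samples = NULL) {
  g <- .subset_geno(mat, samples)
  n <- nrow(g)
  if (n < 4) return(NA_real_)
  S <- .count_segregating(g)
  if (S < 1) return(NA_real_)
  pis <- if (ncol(g)) apply(g, 2L, .site_pi) else numeric(0)
  kbar <- sum(pis, na.rm = TRUE)
  cst <- tajima_constants(n)
  (kbar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

## Hudson-style within/between pairwise difference rates at one site.
## xa, xb: 0/1/NA vectors for the two groups. Returns c(hw, hb) or NAs.
.site_hw_hb <- function(xa, xb) {
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  na <- length(xa); nb <- length(xb)
  if (na < 2 || nb < 2) return(c(NA_real_, NA_real_))
  pa <- mean(xa); pb <- mean(xb)
  ha <- 2 * sum(xa) * (na - sum(xa)) / (na * (na - 1))
  hb_within <- 2 * sum(xb) * (nb - sum(xb)) / (nb * (nb - 1))
  hw <- (ha + hb_within) / 2              # unweighted two-group mean
  hb <- pa * (1 - pb) + pb * (1 - pa)     # between-group mismatch rate
  c(hw, hb)
}

#' Hudson's Fst between two sample subsets
#'
#' Fst = 1 - Hw/Hb with Hw the unweighted mean of the two within-group mean
#' pairwise difference rates and Hb the mean between-group pairwise difference
#' rate. At the gene level the per-site Hw and Hb are aggregated as a ratio of
#' sums over polymorphic sites (the standard multi-site Hudson estimator); the
#' value may be negative. Undefined (\code{NA}) when Hb sums to zero or either
#' group has fewer than two usable samples everywhere.
#'
#' @param mat An \code{aln_matrix}.
#' @param group_a,group_b Character vectors of sample ids.
#' @return Fst (\code{<= 1}), possibly negative, or \code{NA} when undefined.
#' @export
hudson_fst <- function(mat, group_a, group_b) {
  ga <- .subset_geno(mat, group_a)
  gb <- .subset_geno(mat, group_b)
  if (ncol(ga) == 0L) return(NA_real_)
  hwb <- vapply(seq_len(ncol(ga)),
                function(j) .site_hw_hb(ga[, j], gb[, j]), numeric(2))
  hw <- sum(hwb[1L, ], na.rm = TRUE)
  hb <- sum(hwb[2L, ], na.rm = TRUE)
  if (!is.finite(hb) || hb <= 0) return(NA_real_)
  1 - hw / hb
}

#' Reduction of diversity (RoD)
#'
#' Fold decrease of diversity in the landrace group relative to the wild/weedy
#' group: \code{pi_wild / pi_landrace}.
#'
#' @param pi_wild,pi_landrace Non-negative diversity values.
#' @return The ratio; \code{Inf} when the landrace value is zero but the wild
#'   value is positive; \code{NA} when both are zero.
#' @export
rod <- function(pi_wild, pi_landrace) {
  if (any(c(pi_wild, pi_landrace) < 0, na.rm = TRUE))
    stop("diversity values must be non-negative")
  ifelse(is.na(pi_wild) | is.na(pi_landrace), NA_real_,
         ifelse(pi_landrace > 0, pi_wild / pi_landrace,
                ifelse(pi_wild > 0, Inf, NA_real_)))
}

#' Gene-level summary statistics
#'
#' Computes, for one gene, the counts and estimators entering the
#' domestication scan: segregating sites, per-group theta-pi, Watterson's
#' theta and Tajima's D, Hudson's Fst between the two contrast groups, and the
#' RoD ratio.
#'
#' @param mat An \code{aln_matrix}.
#' @param wild,landrace Character vectors of sample ids for the two groups.
#' @return One-row \code{data.frame} with columns \code{gene_id, n_sites_polymorphic,
#'   theta_pi_wild, theta_pi_landrace, theta_w_wild, theta_w_landrace,
#'   tajima_d_wild, tajima_d_landrace, fst, rod}.
#' @export
gene_stats <- function(mat, wild, landrace) {
  pw <- theta_pi(mat, wild)
  pl <- theta_pi(mat, landrace)
  data.frame(
    gene_id = mat$gene_id,
    n_sites_polymorphic = .count_segregating(.subset_geno(mat, NULL)),
    theta_pi_wild = pw,
    theta_pi_landrace = pl,
    theta_w_wild = theta_w(mat, wild),
    theta_w_landrace = theta_w(mat, landrace),
    tajima_d_wild = tajima_d(mat, wild),
    tajima_d_landrace = tajima_d(mat, landrace),
    fst = hudson_fst(mat, wild, landrace),
    rod = rod(pw, pl),
    stringsAsFactors = FALSE
  )
}

#' Per-SNP statistics (1-bp sliding window)
#'
#' Single-nucleotide resolution statistics for every polymorphic site of a
#' gene: per-group site diversity (count scale), Hudson's Fst restricted to
#' the site, Tajima's D of the landrace group at the site (S = 1), and the
#' per-site RoD ratio. Sites where the landrace group is monomorphic have
#' undefined site D (reported \code{NA}); such sites cannot satisfy the
#' negative-D selection criterion.
#'
#' @param mat An \code{aln_matrix}.
#' @param wild,landrace Character vectors of sample ids.
#' @return \code{data.frame} with one row per site in the matrix, columns
#'   \code{gene_id, cds_position, ref, alt, pi_wild, pi_landrace, fst_site,
#'   tajima_d_site_landrace, rod_site}.
#' @export
per_site_stats <- function(mat, wild, landrace) {
  gw <- .subset_geno(mat, wild)
  gl <- .subset_geno(mat, landrace)
  nsite <- length(mat$pos)
  pi_w <- numeric(nsite); pi_l <- numeric(nsite)
  fst_s <- numeric(nsite); d_l <- numeric(nsite); rod_s <- numeric(nsite)
  for (j in seq_len(nsite)) {
    pi_w[j] <- .site_pi(gw[, j])
    pi_l[j] <- .site_pi(gl[, j])
    hwb <- .site_hw_hb(gw[, j], gl[, j])
    fst_s[j] <- if (is.na(hwb[2L]) || hwb[2L] <= 0) NA_real_ else 1 - hwb[1L] / hwb[2L]
    xl <- gl[, j][!is.na(gl[, j])]
    nl <- length(xl)
    if (nl >= 4 && !is.na(pi_l[j]) && pi_l[j] > 0) {
      cst <- tajima_constants(nl)
      d_l[j] <- (pi_l[j] - 1 / cst$a1) / sqrt(cst$e1)
    } else {
      d_l[j] <- NA_real_
    }
    rod_s[j] <- rod(pi_w[j], pi_l[j])
  }
  data.frame(
    gene_id = rep(mat$gene_id, nsite),
    cds_position = mat$pos,
    ref = mat$ref,
    alt = mat$alt,
    pi_wild = pi_w,
    pi_landrace = pi_l,
    fst_site = fst_s,
    tajima_d_site_landrace = d_l,
    rod_site = rod_s,
    stringsAsFactors = FALSE
  )
}
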