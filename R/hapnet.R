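#' Enumerate CDS haplotypes with per-group counts
#'
#' Collapses each sample's allele string over the gene's polymorphic sites
#' into distinct haplotypes and tabulates carrier counts per group. Samples
#' with any missing allele at a polymorphic site are excluded and counted
#' (complete-case haplotypes). With zero polymorphic sites all samples form a
#' single haplotype.
#'
#' @param mat An \code{\link{aln_matrix}}.
#' @param groups \code{data.frame} with \code{sample_id, group_label}.
#' @return List of class \code{haplotype_set}: \code{gene_id},
#'   \code{haplotypes} (character vector of allele strings over the sites),
#'   \code{counts} (haplotype x group matrix), \code{n_excluded_missing},
#'   \code{edges} (\code{NULL} until \code{\link{build_network}}).
#' @export
enumerate_haplotypes <- function(mat, groups) {
  g <- mat$geno
  labels <- groups$group_label[match(mat$sample_ids, groups$sample_id)]
  if (anyNA(labels)) stop("consistency error: sample without group label")
  complete <- if (ncol(g)) !apply(g, 1L, anyNA) else rep(TRUE, nrow(g))
  gc <- g[complete, , drop = FALSE]
  labc <- labels[complete]
  hap_str <- if (ncol(gc)) {
    apply(gc, 1L, function(x)
      paste(ifelse(x == 1L, mat$alt, mat$ref), collapse = ""))
  } else rep("", nrow(gc))
  haps <- unique(hap_str)
  grp_levels <- unique(groups$group_label)
  counts <- matrix(0L, nrow = length(haps), ncol = length(grp_levels),
                   dimnames = list(paste0("hap", seq_along(haps)), grp_levels))
  for (i in seq_along(hap_str)) {
    counts[match(hap_str[i], haps), labc[i]] <-
      counts[match(hap_str[i], haps), labc[i]] + 1L
  }
  structure(list(gene_id = mat$gene_id, haplotypes = haps, counts = counts,
                 n_excluded_missing = sum(!complete), edges = NULL),
            class = "haplotype_set")
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

#' Build a minimum-spanning-tree haplotype network
#'
#' Computes pairwise Hamming distances between haplotypes and connects them
#' with a minimum spanning tree (Kruskal's algorithm). Ties are broken
#' deterministically by smaller distance, then by the smaller haplotype index
#' pair, so identical inputs always yield the identical network. Branch
#' lengths are the genetic distances between haplotypes.
#'
#' @param haps A \code{haplotype_set} from \code{\link{enumerate_haplotypes}}.
#' @return The \code{haplotype_set} with \code{edges}: \code{data.frame}
#'   (\code{hap_i, hap_j, distance}) with \code{n_haplotypes - 1} rows.
#' @export
build_network <- function(haps) {
  n <- length(haps$haplotypes)
  if (n <= 1L) {
    haps$edges <- data.frame(hap_i = integer(0), hap_j = integer(0),
                             distance = integer(0))
    return(haps)
  }
  cand <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    data.frame(hap_i = i, hap_j = (i + 1L):n,
               distance = vapply((i + 1L):n, function(j)
                 .hamming(haps$haplotypes[i], haps$haplotypes[j]),
                 numeric(1)))
  }))
  cand <- cand[order(cand$distance, cand$hap_i, cand$hap_j), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- cand[0, , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    ri <- find(cand$hap_i[r]); rj <- find(cand$hap_j[r])
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, cand[r, , drop = FALSE])
      if (nrow(edges) == n - 1L) break
    }
  }
  rownames(edges) <- NULL
  haps$edges <- edges
  haps
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", x$gene_id, "-", length(x$haplotypes), "haplotypes,",
      sum(x$counts), "samples (", x$n_excluded_missing, "excluded ),",
      if (is.null(x$edges)) "no network" else
        paste(nrow(x$edges), "MST edges"), "\n")
  invisible(x)
}

#' Plot a haplotype network
#'
#' Simple force-free layout of the MST with circle areas proportional to
#' carrier counts and pie-like group coloring (dominant group color per
#' haplotype; legend lists all groups).
#'
#' @param x A \code{haplotype_set} with edges.
#' @param ... Passed to \code{plot}.
#' @export
plot.haplotype_set <- function(x, ...) {
  if (is.null(x$edges)) x <- build_network(x)
  n <- length(x$haplotypes)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  xy <- cbind(cos(ang), sin(ang))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 main = x$gene_id, ...)
  if (nrow(x$edges)) {
    graphics::segments(xy[x$edges$hap_i, 1], xy[x$edges$hap_i, 2],
             xy[x$edges$hap_j, 1], xy[x$edges$hap_j, 2], col = "grey50")
  }
  tot <- rowSums(x$counts)
  cols <- grDevices::hcl.colors(ncol(x$counts), "Dark 3")
  dom <- apply(x$counts, 1L, which.max)
  graphics::symbols(xy[, 1], xy[, 2], circles = 0.08 * sqrt(tot / max(tot)),
                    inches = FALSE, add = TRUE, bg = cols[dom])
  graphics::legend("topright", legend = colnames(x$counts), pt.bg = cols,
                   pch = 21, bty = "n", cex = 0.8)
  invisible(x)
}
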