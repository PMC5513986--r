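# Independent brute-force oracles used to cross-check the package's
# estimators. These deliberately use naive O(n^2 L) pair loops (or external
# packages) and share no code with the implementation under test.

# build an aln_matrix from a plain genotype matrix (rows = samples)
make_aln <- function(geno, cds_length = ncol(geno), pos = NULL,
                     ref = NULL, alt = NULL, gene_id = "g") {
  n <- nrow(geno); s <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(s) - 1L
  if (is.null(ref)) ref <- rep("A", s)
  if (is.null(alt)) alt <- rep("T", s)
  aln_matrix(gene_id = gene_id,
             sample_ids = sprintf("s%02d", seq_len(n)),
             pos = pos, ref = ref, alt = alt, geno = geno,
             cds_length = cds_length)
}

random_aln <- function(n = 8, s = 20, cds_length = 30, miss = 0) {
  geno <- matrix(sample(0:1, n * s, replace = TRUE), nrow = n)
  if (miss > 0) geno[sample(length(geno), round(miss * length(geno)))] <- NA
  make_aln(geno, cds_length = cds_length)
}

# --- theta-pi: all-pairs Hamming differences with per-site complete cases
oracle_theta_pi <- function(geno, L) {
  n <- nrow(geno)
  total <- 0
  for (j in seq_len(ncol(geno))) {
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      x <- geno[a, j]; y <- geno[b, j]
      if (!is.na(x) && !is.na(y)) {
        pairs <- pairs + 1
        if (x != y) diffs <- diffs + 1
      }
    }
    if (pairs > 0) total <- total + diffs / pairs
  }
  total / L
}

oracle_site_pi <- function(x) {
  x <- unname(x[!is.na(x)])
  n <- length(x)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    diffs <- diffs + (x[a] != x[b])
  diffs / choose(n, 2)
}

# --- Tajima's D with constants recomputed from the published 1989 formulas
oracle_tajima_d <- function(geno) {
  n <- nrow(geno)
  keep <- apply(geno, 2, function(x) sum(!is.na(x)) >= 2)
  g <- geno[, keep, drop = FALSE]
  S <- sum(apply(g, 2, function(x) {
    x <- x[!is.na(x)]; any(x == 1) && any(x == 0)
  }))
  if (S < 1 || n < 4) return(NA_real_)
  kbar <- sum(vapply(seq_len(ncol(g)), function(j) {
    v <- oracle_site_pi(g[, j]); if (is.na(v)) 0 else v
  }, numeric(1)))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Hudson Fst by explicit pair loops (ratio of sums over sites)
oracle_hudson_fst <- function(geno_a, geno_b) {
  hw_sum <- 0; hb_sum <- 0; any_site <- FALSE
  rate_within <- function(x) {
    x <- unname(x[!is.na(x)])
    if (length(x) < 2) return(NA_real_)
    d <- 0; p <- 0
    for (a in seq_len(length(x) - 1)) for (b in (a + 1):length(x)) {
      p <- p + 1; d <- d + (x[a] != x[b])
    }
    d / p
  }
  for (j in seq_len(ncol(geno_a))) {
    xa <- geno_a[, j]; xb <- geno_b[, j]
    ha <- rate_within(xa); hb_w <- rate_within(xb)
    if (is.na(ha) || is.na(hb_w)) next
    xa2 <- unname(xa[!is.na(xa)]); xb2 <- unname(xb[!is.na(xb)])
    d <- 0; p <- 0
    for (a in seq_along(xa2)) for (b in seq_along(xb2)) {
      p <- p + 1; d <- d + (xa2[a] != xb2[b])
    }
    hw_sum <- hw_sum + (ha + hb_w) / 2
    hb_sum <- hb_sum + d / p
    any_site <- TRUE
  }
  if (!any_site || hb_sum <= 0) return(NA_real_)
  1 - hw_sum / hb_sum
}

# --- chi-square from the definition, cellwise
oracle_chi2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  rs <- c(a + b, a + b, c + d, c + d)
  cs <- c(a + c, b + d, a + c, b + d)
  e <- rs * cs / n
  sum((o - e)^2 / e)
}

# --- codon classification via seqinr's translation table
oracle_classify <- function(codon, alt_codon) {
  aa1 <- seqinr::translate(strsplit(codon, "")[[1]])
  aa2 <- seqinr::translate(strsplit(alt_codon, "")[[1]])
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}

# --- independent neutral coalescent oracle for a single constant-size
#     population: genealogy from ape::rcoal (standard coalescent times),
#     Poisson mutations on edges, statistics from derived-allele counts.
oracle_coalescent_stats <- function(n, thetaL) {
  tr <- ape::rcoal(n)
  tips_below <- function(tree, node) {
    if (node <= n) return(1L)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sum(vapply(kids, function(k) tips_below(tree, k), integer(1)))
  }
  counts <- integer(0)
  for (e in seq_len(nrow(tr$edge))) {
    nm <- stats::rpois(1, thetaL / 2 * tr$edge.length[e])
    if (nm > 0) {
      c_e <- tips_below(tr, tr$edge[e, 2])
      if (c_e < n) counts <- c(counts, rep(c_e, nm))
    }
  }
  S <- length(counts)
  kbar <- if (S) sum(2 * counts * (n - counts) / (n * (n - 1))) else 0
  D <- if (S >= 1) {
    a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  } else NA_real_
  list(S = S, kbar = kbar, D = D)
}

# --- exhaustive minimum-spanning-tree weight via Prufer enumeration (n <= 6)
oracle_mst_weight <- function(dist_mat) {
  n <- nrow(dist_mat)
  if (n == 1) return(0)
  if (n == 2) return(dist_mat[1, 2])
  tree_weight <- function(pruefer) {
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    seq_nodes <- pruefer
    leafset <- which(degree == 1L)
    for (v in seq_nodes) {
      leaf <- min(leafset)
      w <- w + dist_mat[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
      leafset <- setdiff(leafset, leaf)
      if (degree[v] == 1L) leafset <- sort(c(leafset, v))
    }
    uv <- which(degree == 1L)
    w + dist_mat[uv[1], uv[2]]
  }
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  min(apply(combos, 1, tree_weight))
}

# --- BBH by brute-force double loop over query sets
oracle_bbh <- function(hits_ab, hits_ba) {
  best <- function(hits, q) {
    h <- hits[hits$query == q, , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, h$subject), , drop = FALSE]
    h$subject[1]
  }
  pairs <- character(0)
  for (q in unique(hits_ab$query)) {
    s <- best(hits_ab, q)
    if (s %in% hits_ba$query && best(hits_ba, s) == q)
      pairs <- c(pairs, paste(q, s))
  }
  sort(pairs)
}
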