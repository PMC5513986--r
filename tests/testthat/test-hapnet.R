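two_group_df <- function(ids) {
  data.frame(sample_id = ids,
             group_label = rep(c("wild_weedy", "landrace"),
                               length.out = length(ids)))
}

test_that("haplotype enumeration collapses identical allele strings", {
  m <- make_aln(matrix(0L, nrow = 4, ncol = 2), cds_length = 6)
  hs <- enumerate_haplotypes(m, two_group_df(m$sample_ids))
  expect_equal(length(hs$haplotypes), 1L)
  expect_equal(sum(hs$counts), 4)
  # {AA, AT, AT, TT} over 2 sites -> 3 haplotypes, counts 1/2/1
  g <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 1L), c(1L, 1L))
  hs2 <- enumerate_haplotypes(make_aln(g, cds_length = 6),
                              two_group_df(sprintf("s%02d", 1:4)))
  expect_equal(length(hs2$haplotypes), 3L)
  expect_equal(sort(unname(rowSums(hs2$counts))), c(1, 1, 2))
  # missing data -> complete-case exclusion, counted
  g[2, 1] <- NA
  hs3 <- enumerate_haplotypes(make_aln(g, cds_length = 6),
                              two_group_df(sprintf("s%02d", 1:4)))
  expect_equal(hs3$n_excluded_missing, 1L)
  expect_equal(sum(hs3$counts), 3)
})

test_that("haplotype counts equal a string-dedup oracle and ignore sample order", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_aln(n = 10, s = sample(2:8, 1), cds_length = 12)
    grp <- two_group_df(m$sample_ids)
    hs <- enumerate_haplotypes(m, grp)
    strings <- apply(m$geno, 1, paste, collapse = "")
    expect_equal(length(hs$haplotypes), length(unique(strings)))
    expect_equal(sort(rowSums(hs$counts)), sort(as.integer(table(strings))),
                 ignore_attr = TRUE)
    perm <- sample(10)
    m2 <- make_aln(m$geno[perm, ], cds_length = 12)
    hs2 <- enumerate_haplotypes(m2, two_group_df(m2$sample_ids))
    expect_equal(sort(unname(rowSums(hs2$counts))),
                 sort(unname(rowSums(hs$counts))))
  }
})

test_that("network edges form a minimum spanning tree", {
  # single haplotype -> no edges
  m <- make_aln(matrix(0L, nrow = 3, ncol = 1), cds_length = 3)
  hs <- build_network(enumerate_haplotypes(m, two_group_df(m$sample_ids)))
  expect_equal(nrow(hs$edges), 0L)
  # three haplotypes at mutual distances 1,1,2 -> weight 2
  g <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  hs2 <- build_network(enumerate_haplotypes(make_aln(g, cds_length = 6),
                                            two_group_df(sprintf("s%02d", 1:3))))
  expect_equal(nrow(hs2$edges), 2L)
  expect_equal(sum(hs2$edges$distance), 2)
})

test_that("MST weight matches exhaustive spanning-tree enumeration", {
  set.seed(12)
  for (rep in 1:15) {
    nh <- sample(3:6, 1)
    geno <- unique(matrix(sample(0:1, nh * 6, replace = TRUE), ncol = 6))
    nh <- nrow(geno)
    if (nh < 2) next
    m <- make_aln(geno, cds_length = 18)
    hs <- build_network(enumerate_haplotypes(m, two_group_df(m$sample_ids)))
    dmat <- as.matrix(dist(geno, method = "manhattan"))
    expect_equal(nrow(hs$edges), nh - 1L)
    expect_equal(sum(hs$edges$distance), oracle_mst_weight(dmat))
  }
})

test_that("MST agrees with igraph on larger haplotype sets and is deterministic", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:10) {
    geno <- unique(matrix(sample(0:1, 12 * 10, replace = TRUE), ncol = 10))
    m <- make_aln(geno, cds_length = 30)
    hs <- build_network(enumerate_haplotypes(m, two_group_df(m$sample_ids)))
    dmat <- as.matrix(dist(geno, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(dmat, weighted = TRUE,
                                             mode = "undirected")
    mst <- igraph::mst(g)
    expect_equal(sum(hs$edges$distance),
                 sum(igraph::E(mst)$weight))
    hs2 <- build_network(enumerate_haplotypes(m, two_group_df(m$sample_ids)))
    expect_identical(hs$edges, hs2$edges)
  }
})
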