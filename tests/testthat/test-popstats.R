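test_that("theta_pi matches hand-computed and trivial cases", {
  # all samples identical -> 0
  m <- make_aln(matrix(0L, nrow = 4, ncol = 3), cds_length = 12)
  expect_equal(theta_pi(m), 0)
  # 4 samples, one 2/2 site, CDS length 10: 4 differing pairs of 6
  m2 <- make_aln(matrix(c(0L, 0L, 1L, 1L), ncol = 1), cds_length = 10)
  expect_equal(theta_pi(m2), (4 / 6) / 10)
  # matrix without sites -> 0, single sample -> undefined
  m3 <- make_aln(matrix(integer(0), nrow = 3, ncol = 0), cds_length = 9)
  expect_equal(theta_pi(m3), 0)
  expect_true(is.na(theta_pi(m2, samples = "s01")))
})

test_that("theta_pi and per-site pi equal the all-pairs oracle on random matrices", {
  set.seed(101)
  for (rep in 1:40) {
    m <- random_aln(n = sample(4:8, 1), s = sample(5:50, 1),
                    cds_length = 60, miss = sample(c(0, 0.1), 1))
    expect_equal(theta_pi(m), oracle_theta_pi(m$geno, 60), tolerance = 1e-12)
    ss <- per_site_stats(m, wild = m$sample_ids[1:2],
                         landrace = m$sample_ids[-(1:2)])
    for (j in seq_along(m$pos)) {
      expect_equal(ss$pi_landrace[j],
                   oracle_site_pi(m$geno[-(1:2), j]), tolerance = 1e-12)
    }
  }
})

test_that("Tajima's D reproduces independently recomputed constants", {
  # n = 4, S = 1, derived allele count 2: kbar = 2/3, D = (2/3 - 6/11)/sqrt(e1)
  m <- make_aln(matrix(c(0L, 0L, 1L, 1L), ncol = 1), cds_length = 10)
  a1 <- 1 + 1 / 2 + 1 / 3
  b1 <- 5 / 9; b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  a2 <- 1 + 1 / 4 + 1 / 9
  c1 <- b1 - 1 / a1; c2 <- b2 - 6 / (4 * a1) + a2 / a1^2
  e1 <- (c1 / a1)
  expect_equal(tajima_d(m), (2 / 3 - 1 / a1) / sqrt(e1), tolerance = 1e-12)
  # S = 0 is undefined, not zero
  m0 <- make_aln(matrix(1L, nrow = 5, ncol = 2), cds_length = 6)
  expect_true(is.na(tajima_d(m0)))
})

test_that("Tajima's D equals the brute-force oracle on random matrices", {
  set.seed(202)
  for (rep in 1:40) {
    m <- random_aln(n = sample(4:9, 1), s = sample(2:40, 1), cds_length = 50)
    expect_equal(tajima_d(m), oracle_tajima_d(m$geno), tolerance = 1e-12)
  }
})

test_that("Hudson Fst: fixed difference gives 1, label swap is symmetric, oracle agrees", {
  m <- make_aln(matrix(c(0L, 0L, 0L, 1L, 1L, 1L), ncol = 1), cds_length = 3)
  a <- m$sample_ids[1:3]; b <- m$sample_ids[4:6]
  expect_equal(hudson_fst(m, a, b), 1)
  set.seed(303)
  for (rep in 1:40) {
    m <- random_aln(n = 9, s = sample(3:30, 1), cds_length = 40,
                    miss = sample(c(0, 0.1), 1))
    a <- m$sample_ids[1:4]; b <- m$sample_ids[5:9]
    f1 <- hudson_fst(m, a, b)
    expect_equal(f1, hudson_fst(m, b, a), tolerance = 1e-12)
    expect_equal(f1, oracle_hudson_fst(m$geno[1:4, , drop = FALSE],
                                       m$geno[5:9, , drop = FALSE]),
                 tolerance = 1e-12)
    if (!is.na(f1)) expect_lte(f1, 1)
  }
})

test_that("estimators are invariant to sample order and allele relabeling", {
  set.seed(404)
  m <- random_aln(n = 8, s = 25, cds_length = 30)
  perm <- sample(8)
  mp <- make_aln(m$geno[perm, ], cds_length = 30)
  expect_equal(theta_pi(m), theta_pi(mp))
  flip <- make_aln(1L - m$geno, cds_length = 30)
  expect_equal(theta_pi(m), theta_pi(flip))
  a <- m$sample_ids[1:4]; b <- m$sample_ids[5:8]
  expect_equal(hudson_fst(m, a, b), hudson_fst(flip, a, b))
})

test_that("RoD handles fixation and degenerate inputs per the contract", {
  expect_equal(rod(0.0058, 0.0001), 58)
  expect_equal(rod(0.004, 0.004), 1)
  expect_identical(rod(0.004, 0), Inf)
  expect_true(is.na(rod(0, 0)))
  expect_error(rod(-0.1, 0.2), "non-negative")
})

test_that("per-site stats: divergent monomorphic site and landrace-fixed site", {
  # both groups monomorphic, fixed for different alleles
  m <- make_aln(matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), ncol = 1),
                cds_length = 3)
  ss <- per_site_stats(m, m$sample_ids[1:4], m$sample_ids[5:8])
  expect_equal(ss$pi_wild, 0)
  expect_equal(ss$pi_landrace, 0)
  expect_equal(ss$fst_site, 1)
  # wild 50/50, landrace fixed: infinite RoD but undefined site D
  m2 <- make_aln(matrix(c(0L, 0L, 1L, 1L, rep(0L, 4)), ncol = 1),
                 cds_length = 3)
  ss2 <- per_site_stats(m2, m2$sample_ids[1:4], m2$sample_ids[5:8])
  expect_identical(ss2$rod_site, Inf)
  expect_true(is.na(ss2$tajima_d_site_landrace))
})

test_that("gene theta_pi is internally consistent with per-site pi values", {
  set.seed(505)
  m <- random_aln(n = 10, s = 30, cds_length = 45)
  ss <- per_site_stats(m, m$sample_ids[1:5], m$sample_ids[6:10])
  pis <- apply(m$geno, 2, oracle_site_pi)
  expect_equal(theta_pi(m), sum(pis) / m$cds_length, tolerance = 1e-12)
  expect_gte(theta_w(m), 0)
})
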