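write_mini_inputs <- function(dir, vcf_body, strand = "+", cds = "ATGGCTAAA",
                              samples = c("w1", "w2", "l1", "l2"),
                              labels = c("wild_weedy", "wild_weedy",
                                         "landrace", "landrace")) {
  dir.create(dir, showWarnings = FALSE)
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(">g1", cds), fasta)
  vcf <- file.path(dir, "v.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               vcf_body), vcf)
  groups <- file.path(dir, "groups.tsv")
  writeLines(c("sample_id\tgroup_label",
               paste(samples, labels, sep = "\t")), groups)
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("gene_id\tcds_length\tstrand\tis_neutral",
               paste("g1", nchar(cds), strand, "FALSE", sep = "\t")), ann)
  list(fasta = fasta, vcf = vcf, groups = groups, annotation = ann)
}

test_that("VCF 1-based POS becomes 0-based CDS coordinate; zero records allowed", {
  p <- write_mini_inputs(tempfile(),
    "g1\t3\t.\tG\tC\t.\tPASS\t.\tGT\t0\t0\t1\t1")
  inp <- read_inputs(p$fasta, p$vcf, p$groups, p$annotation)
  m <- inp$matrices[["g1"]]
  expect_equal(m$pos, 2L)
  expect_equal(unname(m$geno[, 1]), c(0L, 0L, 1L, 1L))
  # zero records for a gene -> matrix with zero sites
  p0 <- write_mini_inputs(tempfile(), character(0))
  m0 <- read_inputs(p0$fasta, p0$vcf, p0$groups, p0$annotation)$matrices[["g1"]]
  expect_equal(length(m0$pos), 0L)
})

test_that("heterozygous and half-missing diploid calls become missing", {
  p <- write_mini_inputs(tempfile(),
    "g1\t2\t.\tT\tA\t.\tPASS\t.\tGT\t0/1\t./1\t1/1\t.")
  m <- read_inputs(p$fasta, p$vcf, p$groups, p$annotation)$matrices[["g1"]]
  expect_equal(unname(m$geno[, 1]), c(NA, NA, 1L, NA))
})

test_that("multi-allelic and indel records are dropped with a warning", {
  body <- c("g1\t2\t.\tT\tA,C\t.\tPASS\t.\tGT\t0\t1\t2\t0",
            "g1\t4\t.\tG\tGTT\t.\tPASS\t.\tGT\t0\t1\t1\t0",
            "g1\t6\t.\tT\tG\t.\tPASS\t.\tGT\t0\t1\t1\t0")
  p <- write_mini_inputs(tempfile(), body)
  expect_warning(inp <- read_inputs(p$fasta, p$vcf, p$groups, p$annotation),
                 "multi-allelic or indel")
  expect_equal(inp$matrices[["g1"]]$pos, 5L)
})

test_that("minus-strand genes are flipped into coding orientation", {
  p <- write_mini_inputs(tempfile(),
    "g1\t1\t.\tA\tG\t.\tPASS\t.\tGT\t0\t0\t1\t1", strand = "-",
    cds = "ATGGCTAAA")
  m <- read_inputs(p$fasta, p$vcf, p$groups, p$annotation)$matrices[["g1"]]
  expect_equal(m$pos, 8L)        # L-1-0
  expect_equal(m$ref, "T")
  expect_equal(m$alt, "C")
})

test_that("inconsistent inputs are rejected", {
  p <- write_mini_inputs(tempfile(),
    "g1\t2\t.\tT\tA\t.\tPASS\t.\tGT\t0\t0\t1\t1",
    labels = c("wild_weedy", "wild_weedy", "landrace", "landrace"))
  groups_bad <- file.path(tempfile(fileext = ".tsv"))
  writeLines(c("sample_id\tgroup_label", "w1\twild_weedy"), groups_bad)
  expect_error(read_inputs(p$fasta, p$vcf, groups_bad, p$annotation),
               "absent from groups")
  p2 <- write_mini_inputs(tempfile(),
    "g1\t99\t.\tT\tA\t.\tPASS\t.\tGT\t0\t0\t1\t1")
  expect_error(read_inputs(p2$fasta, p2$vcf, p2$groups, p2$annotation),
               "outside CDS")
})

test_that("synthetic round trip preserves alleles exactly and order does not matter", {
  cfg <- sim_config(n_candidate_genes = 3L, n_neutral_genes = 3L,
                    cds_length = 600L, rng_seed = 12L)
  ds <- generate_dataset(cfg, tempfile())
  inp <- read_inputs(ds$fasta, ds$vcf, ds$groups, ds$annotation)
  for (g in names(ds$matrices)) {
    expect_identical(unname(inp$matrices[[g]]$geno),
                     unname(ds$matrices[[g]]$geno))
    expect_identical(inp$matrices[[g]]$pos, ds$matrices[[g]]$pos)
    expect_identical(inp$matrices[[g]]$ref, ds$matrices[[g]]$ref)
  }
  # shuffle the VCF body: matrices identical after internal sorting
  lines <- readLines(ds$vcf)
  hdr <- grepl("^#", lines)
  set.seed(5)
  shuffled <- c(lines[hdr], sample(lines[!hdr]))
  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(shuffled, vcf2)
  inp2 <- read_inputs(ds$fasta, vcf2, ds$groups, ds$annotation)
  for (g in names(ds$matrices))
    expect_identical(unname(inp2$matrices[[g]]$geno),
                     unname(inp$matrices[[g]]$geno))
})
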