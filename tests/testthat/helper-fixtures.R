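# Reusable fixtures built in code.

# Ortholog evidence sets with a prescribed Venn structure per species:
# n_bbh / n_syn pairs of which n_both appear in both sets, one source gene
# per target gene, plus `shared` targets re-used across species pairs.
make_evidence <- function(species, n_bbh, n_syn, n_both, prefix) {
  n_union <- n_bbh + n_syn - n_both
  targets <- sprintf("Sb.%s%03d", prefix, seq_len(n_union))
  sources <- sprintf("%s_src%03d", species, seq_len(n_union))
  # first n_both pairs in both sets, next (n_bbh - n_both) BBH-only,
  # remainder synteny-only
  bbh <- data.frame(source_gene = sources[seq_len(n_bbh)],
                    target_gene = targets[seq_len(n_bbh)])
  syn_idx <- c(seq_len(n_both), (n_bbh + 1):n_union)
  syn <- data.frame(source_gene = sources[syn_idx],
                    target_gene = targets[syn_idx])
  list(bbh = bbh, syn = syn, targets = targets)
}

# The three-species ortholog evidence bundle mirroring the published counts:
# rice 55 BBH / 47 synteny / 30 both (72 unique), maize 20/12/9 (23),
# arabidopsis 25 unique (per-method split unpublished; 17/13/5 used here),
# 9 targets shared by exactly two species -> 111 overall.
venn_evidence <- function() {
  rice <- make_evidence("rice", 55, 47, 30, "R")
  maize <- make_evidence("maize", 20, 12, 9, "M")
  at <- make_evidence("arabidopsis", 17, 13, 5, "A")
  # overlay 9 cross-species duplicates: 5 maize and 4 arabidopsis targets
  # renamed to rice targets (each shared by exactly two species)
  maize$bbh$target_gene[1:5] <- rice$targets[1:5]
  maize$syn$target_gene[1:5] <- rice$targets[1:5]
  at$bbh$target_gene[1:4] <- rice$targets[6:9]
  at$syn$target_gene[1:4] <- rice$targets[6:9]
  rbind(merge_evidence(rice$bbh, rice$syn, "rice"),
        merge_evidence(maize$bbh, maize$syn, "maize"),
        merge_evidence(at$bbh, at$syn, "arabidopsis"))
}

# random 12-column hit tables for BBH stress tests
random_hits <- function(queries, subjects, n = 60) {
  data.frame(query = sample(queries, n, replace = TRUE),
             subject = sample(subjects, n, replace = TRUE),
             pident = runif(n, 50, 100), length = sample(50:500, n, TRUE),
             mismatch = sample(0:50, n, TRUE), gapopen = sample(0:5, n, TRUE),
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = 10^-runif(n, 2, 50),
             bitscore = round(runif(n, 50, 900), 1))
}
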