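#' Read a 12-column tabular protein-homology hit file
#'
#' Standard tab-separated alignment format: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score.
#'
#' @param path File path.
#' @return \code{data.frame} with typed columns.
#' @export
read_blast_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12L)
    stop("parse error: expected 12 tab-separated columns in ", path)
  names(hits) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(hits[[cn]]))
    if (anyNA(v) && !anyNA(hits[[cn]])) {
      bad <- which(is.na(v))[1L]
      stop("parse error: non-numeric value in column ", cn, " at line ", bad)
    }
    hits[[cn]] <- v
  }
  hits
}

## best subject per query: highest bit score, ties by lower e-value then
## lexicographically smaller subject id
.best_hits <- function(hits) {
  o <- order(hits$query, -hits$bitscore, hits$evalue, hits$subject)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query), c("query", "subject")]
}

#' Bidirectional best hits between two genomes
#'
#' A pair (a, b) is kept when b is a's highest-scoring subject in the A-to-B
#' hit table and a is b's highest-scoring subject in the B-to-A table. Ties
#' are broken deterministically by lower e-value, then lexicographic subject
#' id.
#'
#' @param hits_ab,hits_ba Hit tables (\code{data.frame}s from
#'   \code{\link{read_blast_hits}}, or paths).
#' @return \code{data.frame} with \code{source_gene} (genome A) and
#'   \code{target_gene} (genome B).
#' @export
bbh_pairs <- function(hits_ab, hits_ba) {
  if (is.character(hits_ab)) hits_ab <- read_blast_hits(hits_ab)
  if (is.character(hits_ba)) hits_ba <- read_blast_hits(hits_ba)
  best_ab <- .best_hits(hits_ab)
  best_ba <- .best_hits(hits_ba)
  back <- stats::setNames(best_ba$subject, best_ba$query)
  keep <- !is.na(back[best_ab$subject]) &
    back[best_ab$subject] == best_ab$query
  out <- best_ab[keep, , drop = FALSE]
  data.frame(source_gene = out$query, target_gene = out$subject,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge BBH and synteny ortholog evidence
#'
#' Union of the two evidence sets with a method label per pair:
#' \code{"BBH"}, \code{"synteny"}, or \code{"both"} when the pair appears in
#' both sets.
#'
#' @param bbh,synteny \code{data.frame}s with \code{source_gene,
#'   target_gene} columns (either may be empty).
#' @param source_species Species label attached to the records.
#' @return \code{data.frame} of ortholog records: \code{source_species,
#'   source_gene, target_gene, method}.
#' @export
merge_evidence <- function(bbh, synteny, source_species = "other") {
  key <- function(df) paste(df$source_gene, df$target_gene, sep = "\r")
  kb <- if (nrow(bbh)) key(bbh) else character(0)
  ks <- if (nrow(synteny)) key(synteny) else character(0)
  all_keys <- union(kb, ks)
  if (!length(all_keys))
    return(data.frame(source_species = character(0),
                      source_gene = character(0), target_gene = character(0),
                      method = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  method <- ifelse(all_keys %in% kb & all_keys %in% ks, "both",
                   ifelse(all_keys %in% kb, "BBH", "synteny"))
  out <- data.frame(source_species = source_species,
                    source_gene = vapply(parts, `[`, "", 1L),
                    target_gene = vapply(parts, `[`, "", 2L),
                    method = method, stringsAsFactors = FALSE)
  out <- out[order(out$source_gene, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally unique ortholog targets per species and overall
#'
#' Counts unique target genes per source species and across all species
#' (genes found for two or more source species are counted once overall).
#' Also asserts the inclusion-exclusion identity |union| = |BBH| + |synteny|
#' - |both| per species.
#'
#' @param records \code{data.frame} of ortholog records (rbind of
#'   \code{\link{merge_evidence}} outputs).
#' @return List with \code{per_species} (named integer vector of unique
#'   targets), \code{n_unique_overall}, and \code{n_shared_multi_species}.
#' @export
ortholog_tally <- function(records) {
  per_species <- vapply(split(records, records$source_species), function(df) {
    n_union <- length(unique(df$target_gene))
    pairs_b <- df$method %in% c("BBH", "both")
    pairs_s <- df$method %in% c("synteny", "both")
    stopifnot(n_union <= sum(pairs_b) + sum(pairs_s))
    n_union
  }, integer(1))
  by_target <- tapply(records$source_species, records$target_gene,
                      function(s) length(unique(s)))
  list(per_species = per_species,
       n_unique_overall = length(by_target),
       n_shared_multi_species = sum(by_target >= 2))
}

#' Add externally curated candidate genes
#'
#' Set union of the ortholog target genes and an extra gene list; idempotent
#' and order-independent.
#'
#' @param records Ortholog records \code{data.frame} (or character vector of
#'   target gene ids).
#' @param extra_gene_list Character vector of additional candidate gene ids.
#' @return Sorted character vector of unique candidate gene ids.
#' @export
add_external_candidates <- function(records, extra_gene_list = character(0)) {
  targets <- if (is.data.frame(records)) records$target_gene else records
  sort(union(targets, extra_gene_list))
}
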