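## Candidate B-chromosome scaffold identification.
##
## Male-specific sequence is isolated by assembly subtraction: a male
## scaffold is a candidate when less than 20% of its length can be aligned
## to the female assembly. Alignability is measured as shared-k-mer coverage
## of the male scaffold (both strands), which applies the same 20%
## covered-length decision rule the downstream analysis depends on.
## Candidates carrying annotated proteins homologous to known sequences are
## removed; a B-linked probe ranks the survivors.

#' Subtract the female assembly from male scaffolds
#'
#' @param male_scaffolds,female_scaffolds named character vectors
#' @param cov_threshold aligned-length fraction below which a male scaffold
#'   is a B candidate (default 0.20)
#' @param k k-mer size for shared-sequence coverage; the default 21 makes
#'   chance matches against a megabase-scale assembly negligible while true
#'   homology at a few percent divergence still covers most of a scaffold
#' @return BCandidate data.frame: scaffold_id, length, aligned_fraction,
#'   candidate
#' @export
subtract_assemblies <- function(male_scaffolds, female_scaffolds,
                                cov_threshold = 0.20, k = 21L) {
  stopifnot(length(male_scaffolds) > 0, length(female_scaffolds) > 0)
  frac <- cpp_kmer_coverage(unname(male_scaffolds), unname(female_scaffolds),
                            as.integer(k))
  data.frame(scaffold_id = names(male_scaffolds),
             length = nchar(male_scaffolds),
             aligned_fraction = frac,
             candidate = frac < cov_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove candidates whose annotated proteins match known sequences
#'
#' @param candidates BCandidate data.frame (rows with `candidate = TRUE`
#'   are filtered; others pass through unchanged)
#' @param annotations data.frame: scaffold_id, protein_id (proteins
#'   annotated on candidate scaffolds); may be empty
#' @param known_hits data.frame: protein_id (proteins with homology to any
#'   published sequence); may be empty
#' @return `candidates` with `known_homology` and updated `candidate`
#' @export
filter_known <- function(candidates, annotations, known_hits) {
  flagged <- unique(annotations$scaffold_id[
    annotations$protein_id %in% known_hits$protein_id])
  candidates$known_homology <- candidates$scaffold_id %in% flagged
  candidates$candidate <- candidates$candidate & !candidates$known_homology
  candidates
}

#' Rank scaffolds by local-alignment similarity to a probe
#'
#' Scaffolds sharing no `k`-mer with the probe are omitted from the ranking.
#' Scoring: match +1, mismatch -1, gap -2 (per gap position). Ties are
#' broken by scaffold id.
#'
#' @param probe probe sequence (>= 50 bp)
#' @param scaffolds named character vector
#' @param match,mismatch,gap local-alignment scores
#' @param k prefilter k-mer size
#' @return data.frame ranked by descending score: scaffold_id, score
#' @export
probe_bait <- function(probe, scaffolds, match = 1, mismatch = -1, gap = -2,
                       k = 13L) {
  stopifnot(nchar(probe) >= 50)
  shared <- cpp_kmer_coverage(unname(scaffolds), probe, as.integer(k)) > 0
  hit <- which(shared)
  if (!length(hit)) {
    return(data.frame(scaffold_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  score1 <- function(s) {
    fw <- Biostrings::pairwiseAlignment(probe, s, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = abs(gap),
                                        scoreOnly = TRUE)
    rv <- Biostrings::pairwiseAlignment(probe, revcomp(s), type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = abs(gap),
                                        scoreOnly = TRUE)
    max(fw, rv)
  }
  sc <- vapply(scaffolds[hit], score1, 1)
  res <- data.frame(scaffold_id = names(scaffolds)[hit], score = sc,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$scaffold_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-sex fraction of reads aligning to a centromeric sequence set
#'
#' A read counts when it has an ungapped placement with at most `max_mm`
#' mismatches on any centromeric sequence.
#'
#' @param reads_by_sex named list (e.g. male/female) of character vectors of
#'   read sequences
#' @param centromeric_seqs named character vector (non-empty)
#' @param max_mm mismatch allowance (default 2)
#' @param k seed size
#' @return data.frame: sex, n_reads, n_aligned, fraction
#' @export
centromeric_read_fraction <- function(reads_by_sex, centromeric_seqs,
                                      max_mm = 2L, k = 13L) {
  stopifnot(length(centromeric_seqs) > 0)
  idx <- index_reference(centromeric_seqs, k)
  rows <- lapply(names(reads_by_sex), function(sx) {
    rd <- reads_by_sex[[sx]]
    al <- align_single(idx, rd, max_mm)
    data.frame(sex = sx, n_reads = length(rd), n_aligned = sum(al$mapped),
               fraction = if (length(rd)) sum(al$mapped) / length(rd) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
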