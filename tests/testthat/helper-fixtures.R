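## Shared fixtures: everything is generated in code at test time.

## a small four-chromosome genome plan (fast; same karyotype as the default)
small_plan <- function(seed = 7L, gene_counts = c(6L, 2L, 4L, 8L)) {
  genome_plan(chrom_specs = data.frame(
    label = c("chr2", "chr4", "chrX", "neo"),
    muller = c("B+E", "F", "A", "C+D"),
    length = c(60000L, 20000L, 40000L, 80000L),
    gene_count = as.integer(gene_counts),
    stringsAsFactors = FALSE), seed = seed)
}

## a quiet divergence plan: everything off unless switched on
quiet_divergence <- function(...) {
  args <- list(snp_rate = 0, indel_rate = 0, pseudogene_fraction = 0,
               ancestral_fraction = 0, female_het = 0,
               female_indel_rate = 0, male_het = 0, male_poly_rate = 0,
               tandem_dup_count = 0L, neoY_tandem_dup_count = 0L,
               large_del_count = 0L, large_ins_count = 0L,
               b_slice_len = 0L, b_unique_len = 0L, b_snp_count = 0L)
  do.call(divergence_plan, utils::modifyList(args, list(...)))
}

## deterministic random DNA helper for constructed cases
rand_seq <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## independent exhaustive hypergeometric two-sided Fisher p-value
## (enumerates all 2x2 tables with the observed margins)
fisher_enum <- function(a, b, c, d) {
  ## margins: row1 = a+b, row2 = c+d, col1 = a+c
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 1)
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## build a pileup object directly from fabricated per-chromosome 8 x len
## count matrices (rows A,C,G,T forward then A,C,G,T reverse)
fake_pileup <- function(genome, mats) {
  structure(list(counts = mats, depth = lapply(mats, colSums),
                 lengths = stats::setNames(nchar(genome), names(genome))),
            class = "pileup")
}

zero_mat <- function(len) matrix(0L, nrow = 8L, ncol = len)

## a cached small end-to-end pipeline run shared by several test files
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config(
        seed = 42L,
        genome = genome_plan(chrom_specs = data.frame(
          label = c("chr2", "chr4", "chrX", "neo"),
          muller = c("B+E", "F", "A", "C+D"),
          length = c(90000L, 30000L, 60000L, 150000L),
          gene_count = c(8L, 3L, 6L, 14L),
          stringsAsFactors = FALSE)),
        divergence = divergence_plan(neoY_tandem_dup_count = 6L,
                                     b_unique_len = 45000L),
        coverage_female = 22, coverage_male = 26)
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})
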