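test_that("generated genes are valid ORFs (independent codon-table re-scan)", {
  g <- simulate_genome(small_plan(seed = 3L))
  expect_equal(nrow(g$genes), 20L)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(g$genes))) {
    gr <- g$genes[i, ]
    cds <- substr(g$seqs[[gr$chrom]], gr$cds_start, gr$cds_end)
    if (gr$strand == "-") cds <- rc(cds)
    ## standalone scan: split into codons and translate one by one
    n <- nchar(cds) %/% 3L
    cods <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
    aa <- unname(code[cods])
    expect_identical(cods[1L], "ATG")
    expect_identical(aa[n], "*")
    expect_false(any(aa[-n] == "*"))
  }
  ## genes do not overlap each other
  for (ch in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    gg <- gg[order(gg$cds_start), ]
    if (nrow(gg) > 1L) {
      expect_true(all(gg$cds_start[-1L] > gg$cds_end[-nrow(gg)]))
    }
  }
})

test_that("gene_count 0 gives a genome with an empty GFF3", {
  plan <- genome_plan(chrom_specs = data.frame(
    label = "chr2", muller = "B+E", length = 30000L, gene_count = 0L,
    stringsAsFactors = FALSE), seed = 1L)
  g <- simulate_genome(plan)
  expect_equal(nrow(g$genes), 0L)
  f <- tempfile(fileext = ".gff3")
  write_gff3(g$genes, f)
  back <- read_gff3(f)
  expect_equal(nrow(back), 0L)
})

test_that("identical plan and seed give byte-identical FASTA output", {
  g1 <- simulate_genome(small_plan(seed = 11L))
  g2 <- simulate_genome(small_plan(seed = 11L))
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(g1$seqs, f1); write_fasta(g2$seqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g3 <- simulate_genome(small_plan(seed = 12L))
  expect_false(identical(g1$seqs, g3$seqs))
})

test_that("infeasible gene packing fails naming the chromosome", {
  expect_error(genome_plan(chrom_specs = data.frame(
    label = "chrX", muller = "A", length = 5000L, gene_count = 10L,
    stringsAsFactors = FALSE)), "chrom_specs")
})

test_that("zero divergence gives haplotypes identical to the seed genome", {
  g <- simulate_genome(small_plan(seed = 5L))
  hap <- derive_haplotypes(g, quiet_divergence(), seed = 2L)
  expect_identical(hap$female$hapA, g$seqs)
  expect_identical(hap$female$hapB, g$seqs)
  expect_identical(hap$male$hapA, g$seqs)
  expect_identical(hap$male$hapB, g$seqs[setdiff(names(g$seqs), "chrX")])
  expect_null(hap$b_fragment)
  expect_equal(nrow(hap$truth$snps), 0L)
  expect_equal(nrow(hap$truth$disruptions), 0L)
})

test_that("pseudogene_fraction yields the exact planned disruption count", {
  g <- simulate_genome(small_plan(seed = 5L, gene_counts = c(0L, 0L, 0L, 20L)))
  hap <- derive_haplotypes(g, quiet_divergence(pseudogene_fraction = 0.2),
                           seed = 9L)
  d <- hap$truth$disruptions
  expect_equal(sum(d$scope == "neoY"), 4L) # 0.2 * 20
  expect_true(all(d$kind %in% c("premature_stop", "frameshift")))
})

test_that("pseudogene_fraction > 0 with no neo genes fails loudly", {
  g <- simulate_genome(small_plan(seed = 5L, gene_counts = c(2L, 2L, 2L, 0L)))
  expect_error(
    derive_haplotypes(g, quiet_divergence(pseudogene_fraction = 0.5), seed = 1L),
    "no genes")
})

test_that("planted neo-Y SNP counts are binomial at the planned rate", {
  ## neo-only genome so each replicate is cheap; rate 1e-3 over 1 Mb
  plan <- genome_plan(chrom_specs = data.frame(
    label = c("chrX", "neo"), muller = c("A", "C+D"),
    length = c(20000L, 1000000L), gene_count = c(0L, 0L),
    stringsAsFactors = FALSE), seed = 1L)
  g <- simulate_genome(plan)
  dp <- quiet_divergence(snp_rate = 1e-3)
  counts <- vapply(1:10, function(s) {
    hap <- derive_haplotypes(g, dp, seed = s)
    sum(hap$truth$snps$carrier == "neoY")
  }, 1L)
  expected <- 1e-3 * 1e6
  sd3 <- 3 * sqrt(1e6 * 1e-3 * (1 - 1e-3))
  expect_true(all(abs(counts - expected) < sd3))
  ## and the counts vary between seeds (they are draws, not a constant)
  expect_gt(length(unique(counts)), 1L)
})

test_that("every planted event is physically present in its haplotype", {
  g <- simulate_genome(small_plan(seed = 13L))
  dp <- quiet_divergence(snp_rate = 2e-3, indel_rate = 3e-4,
                         pseudogene_fraction = 0.25,
                         neoY_tandem_dup_count = 2L,
                         tandem_dup_count = 1L)
  hap <- derive_haplotypes(g, dp, seed = 4L)
  tr <- hap$truth
  ## no duplicate events
  expect_false(anyDuplicated(paste(tr$snps$chrom, tr$snps$pos, tr$snps$haplotype)) > 0)
  ## neo-Y SNPs: alt base visible in the male hapB at a position recoverable
  ## by local string inspection around the site
  ysnp <- tr$snps[tr$snps$carrier == "neoY", ]
  yseq <- hap$male$hapB[["neo"]]
  ref <- g$seqs[["neo"]]
  ## restrict the string probe to sites isolated from other planted events
  allpos <- sort(c(tr$snps$pos[tr$snps$chrom == "neo"],
                   tr$indels$pos[tr$indels$chrom == "neo"]))
  isolated <- vapply(ysnp$pos, function(p)
    sum(abs(allpos - p) <= 10L) == 1L, TRUE)
  ysnp <- ysnp[isolated, , drop = FALSE]
  for (i in seq_len(min(25L, nrow(ysnp)))) {
    p <- ysnp$pos[i] + 1L # truth is 0-based
    ## context probe: 21-mer centred on the site with the alt base must occur
    ## in the haplotype, and with the ref base it must occur in the reference
    ctx_ref <- substr(ref, p - 10L, p + 10L)
    ctx_alt <- ctx_ref
    substr(ctx_alt, 11L, 11L) <- ysnp$alt[i]
    expect_identical(substr(ctx_ref, 11L, 11L), ysnp$ref[i])
    expect_true(grepl(ctx_alt, yseq, fixed = TRUE))
  }
  ## tandem duplications: the duplicated unit occurs twice in tandem
  td <- tr$svs[tr$svs$type == "tandem_dup" & tr$svs$haplotype == "male_hapB" &
               tr$svs$chrom == "neo", ]
  for (i in seq_len(nrow(td))) {
    unit <- substr(ref, td$start[i] + 1L, td$end[i])
    expect_true(grepl(paste0(substr(unit, nchar(unit) - 30L, nchar(unit)),
                             substr(unit, 1L, 30L)), yseq, fixed = TRUE))
  }
  ## the female sample carries no neo-Y or B sequence
  expect_false(any(tr$snps$carrier %in% c("neoY", "B") &
                   grepl("female", tr$snps$haplotype)))
})

test_that("read simulation: pair counts, exactness at zero error, insert moments", {
  g <- simulate_genome(genome_plan(chrom_specs = data.frame(
    label = "chr2", muller = "B+E", length = 100000L, gene_count = 0L,
    stringsAsFactors = FALSE), seed = 1L))
  ins <- insert_spec(mean = 500, sd = 50, read_len = 100L)
  rd <- simulate_reads(list(hapA = g$seqs), ins, coverage = 10, err_rate = 0,
                       seed = 2L)
  ## coverage arithmetic: round(C * G / (2L)) pairs
  expect_equal(length(rd$reads1), round(10 * 100000 / (2 * 100)))
  ## zero error: every mate is an exact substring of the source
  expect_true(all(vapply(rd$reads1[1:200], grepl, TRUE, x = g$seqs[[1L]],
                         fixed = TRUE)))
  r2f <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rd$reads2[1:200])))
  expect_true(all(vapply(r2f, grepl, TRUE, x = g$seqs[[1L]], fixed = TRUE)))
  ## insert sampling: mean within 3 * sd / sqrt(n) of the spec
  m <- mean(rd$meta$insert)
  expect_lt(abs(m - 500), 3 * 50 / sqrt(nrow(rd$meta)) + 1) # +1 for rounding
  ## orientation: mates face inward (mate1 forward is upstream of mate2 site)
  expect_true(all(rd$meta$insert >= 2 * 100))
})

test_that("reads longer than the chromosome are rejected", {
  ins <- insert_spec(mean = 300, sd = 10, read_len = 100L)
  expect_error(simulate_reads(list(hapA = c(tiny = rand_seq(50))), ins,
                              coverage = 5, seed = 1L), "read length")
})

test_that("FASTQ round-trips reads and truth tables round-trip as TSV", {
  g <- simulate_genome(small_plan(seed = 2L))
  hap <- derive_haplotypes(g, divergence_plan(b_unique_len = 2000L), seed = 3L)
  ins <- insert_spec()
  rd <- simulate_reads(hap$female, ins, coverage = 1, err_rate = 0.001, seed = 4L)
  f <- tempfile(fileext = ".fastq")
  write_fastq(rd$reads1, f)
  back <- read_fastq(f)
  expect_identical(unname(back), unname(rd$reads1))
  tsv <- tempfile(fileext = ".tsv")
  write_tsv(hap$truth$snps, tsv)
  back2 <- read_tsv(tsv)
  expect_equal(back2$pos, hap$truth$snps$pos)
  expect_equal(back2$alt, hap$truth$snps$alt)
})
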