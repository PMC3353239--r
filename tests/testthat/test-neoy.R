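## small constructed gene systems for allele reconstruction
mk_gene_system <- function(seed = 111L, strand = "+") {
  set.seed(seed)
  ncod <- 60L
  orf <- paste0("ATG", paste(sample(setdiff(
    as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                    c("A","C","G","T"), paste0)),
    c("TAA", "TAG", "TGA")), ncod - 2L, replace = TRUE), collapse = ""), "TAA")
  left <- rand_seq(300, seed + 1L)
  right <- rand_seq(300, seed + 2L)
  ins <- if (strand == "-") rc(orf) else orf
  genome <- c(chrA = paste0(left, ins, right))
  genes <- data.frame(gene_id = "g1", chrom = "chrA", cds_start = 301L,
                      cds_end = 300L + nchar(orf), gene_start = 101L,
                      gene_end = 500L + nchar(orf), strand = strand,
                      stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, orf = orf)
}

empty_calls <- function() data.frame(
  kind = character(0), chrom = character(0), pos = integer(0),
  ref = character(0), alt = character(0), male_ref = integer(0),
  male_alt = integer(0), female_ref = integer(0), female_alt = integer(0),
  alt_fwd = integer(0), alt_rev = integer(0), partition = character(0),
  alt_ratio_male = numeric(0), stringsAsFactors = FALSE)

snp_call <- function(pos, ref, alt, partition = "male_only", ratio = 0.5) {
  data.frame(kind = "snp", chrom = "chrA", pos = pos, ref = ref, alt = alt,
             male_ref = 10L, male_alt = 10L, female_ref = 20L, female_alt = 0L,
             alt_fwd = 5L, alt_rev = 5L, partition = partition,
             alt_ratio_male = ratio, stringsAsFactors = FALSE)
}

test_that("with no variants both alleles equal the reference CDS", {
  sys <- mk_gene_system()
  ap <- reconstruct_alleles(sys$genes, sys$genome, empty_calls(), empty_calls())
  expect_identical(ap$neoX_cds, sys$orf)
  expect_identical(ap$neoY_cds, sys$orf)
  expect_true(ap$ok)
})

test_that("a male-only stop substitution appears only in the neo-Y allele", {
  sys <- mk_gene_system()
  ## force codon 20 to AAA so a single K -> * substitution creates TAA
  cod20_start <- 301L + 3L * 19L
  substr(sys$genome, cod20_start, cod20_start + 2L) <- "AAA"
  substr(sys$orf, 3L * 19L + 1L, 3L * 19L + 3L) <- "AAA"
  p <- cod20_start # first base of the codon: AAA -> TAA
  mc <- snp_call(p - 1L, "A", "T")
  ap <- reconstruct_alleles(sys$genes, sys$genome, empty_calls(), mc)
  expect_identical(ap$neoX_cds, sys$orf)
  expect_equal(sum(strsplit(ap$neoY_cds, "")[[1L]] !=
                   strsplit(sys$orf, "")[[1L]]), 1L)
  flags <- scan_disruptions(ap$neoY_cds, nchar(sys$orf), "g1")
  expect_identical(flags$kind, "premature_stop")
  expect_equal(flags$cds_offset, 3L * 19L)
})

test_that("reconstruction is strand-aware (minus-strand genes)", {
  sys <- mk_gene_system(seed = 117L, strand = "-")
  ap <- reconstruct_alleles(sys$genes, sys$genome, empty_calls(), empty_calls())
  expect_identical(ap$neoX_cds, sys$orf)
  ## a male SNP inside the CDS appears reverse-complemented in the allele
  p <- sys$genes$cds_start + 30L
  ref <- substr(sys$genome, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
  ap2 <- reconstruct_alleles(sys$genes, sys$genome, empty_calls(),
                             snp_call(p - 1L, ref, alt))
  d <- which(strsplit(ap2$neoY_cds, "")[[1L]] != strsplit(sys$orf, "")[[1L]])
  expect_equal(length(d), 1L)
  expect_identical(substr(ap2$neoY_cds, d, d), rc(alt))
})

test_that("reconstructed alleles equal direct extraction from the donor haplotype", {
  ## full-pipeline consistency on the cached small run: for genes whose
  ## neo-Y variants were all recovered, the reconstructed neo-Y allele must
  ## equal the CDS cut straight from the simulated male hapB sequence
  res <- small_run()
  tr <- res$hap$truth
  neo_genes <- res$genome$genes[res$genome$genes$chrom == "neo", ]
  ## restrict to genes with no planted indels or SVs inside the CDS and all
  ## planted SNP events inside the CDS recovered as calls
  donor <- res$hap$male$hapB[["neo"]]
  shift_events <- rbind(
    data.frame(pos = tr$indels$pos[tr$indels$chrom == "neo"],
               len = tr$indels$len[tr$indels$chrom == "neo"],
               type = tr$indels$type[tr$indels$chrom == "neo"]),
    data.frame(pos = tr$svs$start[tr$svs$chrom == "neo" &
                                  tr$svs$haplotype == "male_hapB"],
               len = tr$svs$end[tr$svs$chrom == "neo" &
                                tr$svs$haplotype == "male_hapB"] -
                     tr$svs$start[tr$svs$chrom == "neo" &
                                  tr$svs$haplotype == "male_hapB"],
               type = tr$svs$type[tr$svs$chrom == "neo" &
                                  tr$svs$haplotype == "male_hapB"]))
  checked <- 0L
  for (i in seq_len(nrow(neo_genes))) {
    g <- neo_genes[i, ]
    ## offset of the CDS in the donor = planted net indel/SV length upstream;
    ## insertions of unrecorded length block the computation
    ev_up <- shift_events[shift_events$pos < g$cds_start - 1L, , drop = FALSE]
    if (any(ev_up$pos + ev_up$len >= g$cds_start - 1L)) next
    if (any(ev_up$type == "large_ins")) next
    shift <- sum(ifelse(ev_up$type %in% c("del", "large_del"), -ev_up$len,
                 ifelse(ev_up$type == "ins", ev_up$len,
                 ifelse(ev_up$type == "tandem_dup", ev_up$len, 0L))))
    ## skip genes with indels inside the CDS (coordinates shift within)
    ind_in <- tr$indels$chrom == "neo" &
      tr$indels$pos >= g$cds_start - 1L & tr$indels$pos < g$cds_end
    sv_in <- tr$svs$chrom == "neo" & tr$svs$haplotype == "male_hapB" &
      tr$svs$start < g$cds_end & tr$svs$end > g$cds_start
    if (any(ind_in) || any(sv_in)) next
    truth_cds <- substr(donor, g$cds_start + shift, g$cds_end + shift)
    if (g$strand == "-") truth_cds <- rc(truth_cds)
    got <- res$alleles$neoY_cds[res$alleles$gene_id == g$gene_id]
    ## compare only when every planted CDS SNP of this gene was called male-only
    planted <- tr$snps[tr$snps$chrom == "neo" & tr$snps$carrier == "neoY" &
                       tr$snps$pos >= g$cds_start - 1L &
                       tr$snps$pos < g$cds_end, , drop = FALSE]
    called <- res$calls[res$calls$chrom == "neo" &
                        res$calls$partition == "male_only", ]
    if (!all(planted$pos %in% called$pos)) next
    if (nchar(got) != nchar(truth_cds)) next
    mmr <- mean(strsplit(got, "")[[1L]] != strsplit(truth_cds, "")[[1L]])
    expect_lte(mmr, 0.02)
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("disruption scanning flags stops, frameshifts and start loss", {
  sys <- mk_gene_system(seed = 119L)
  orf <- sys$orf
  ## identity: no flags
  expect_equal(nrow(scan_disruptions(orf, nchar(orf), "g")), 0L)
  ## premature stop at codon 50 of a 200-codon CDS sits at offset 147
  long_orf <- paste0("ATG", strrep("GGT", 198L), "TAA")
  mut <- long_orf
  substr(mut, 148L, 150L) <- "TAA"
  fl <- scan_disruptions(mut, nchar(long_orf), "g")
  expect_identical(fl$kind, "premature_stop")
  expect_equal(fl$cds_offset, 147L)
  ## 4 bp deletion: frameshift
  fs <- paste0(substr(orf, 1L, 30L), substring(orf, 35L))
  fl2 <- scan_disruptions(fs, nchar(orf), "g")
  expect_true("frameshift" %in% fl2$kind)
  ## damaged ATG: start loss
  sl <- orf
  substr(sl, 1L, 1L) <- "C"
  fl3 <- scan_disruptions(sl, nchar(orf), "g")
  expect_true("start_loss" %in% fl3$kind)
  ## too-short CDS is skipped with a warning
  expect_warning(out <- scan_disruptions("ATG", 3L, "tiny"), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("ancestral pseudogenes are excluded from the neo-Y set", {
  flags <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    chrom = "neo",
    allele = c("neoX", "neoY", "neoY", "neoX"),
    kind = c("premature_stop", "premature_stop", "frameshift", "frameshift"),
    cds_offset = c(10L, 10L, NA, NA), stringsAsFactors = FALSE)
  out <- filter_ancestral(flags)
  ## g1 disrupted on both alleles: ancestral, excluded; g2 only neo-Y: kept
  expect_identical(out$neoY$gene_id, "g2")
  expect_setequal(out$ancestral$gene_id, c("g1", "g3"))
  ## no gene is in both sets
  expect_equal(length(intersect(out$neoY$gene_id, out$ancestral$gene_id)), 0L)
})

test_that("Fisher enrichment matches exhaustive enumeration and the printed counts", {
  ## identical proportions: p = 1
  counts <- data.frame(chrom = c("neo", "chr2"), pseudogenes = c(10L, 10L),
                       total = c(1000L, 1000L), stringsAsFactors = FALSE)
  out <- pseudogene_enrichment(counts)
  expect_equal(out$p_vs_neo[2L], 1)
  ## small-margin tables: exact agreement with the enumeration oracle
  grid <- expand.grid(a = c(0L, 1L, 3L, 5L), c = c(0L, 1L, 4L),
                      n1 = c(8L, 10L), n2 = c(10L, 15L))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; c_ <- grid$c[i]; n1 <- grid$n1[i]; n2 <- grid$n2[i]
    if (a > n1 || c_ > n2) next
    cnt <- data.frame(chrom = c("neo", "other"), pseudogenes = c(a, c_),
                      total = c(n1, n2), stringsAsFactors = FALSE)
    got <- pseudogene_enrichment(cnt)$p_vs_neo[2L]
    want <- fisher_enum(a, n1 - a, c_, n2 - c_)
    expect_equal(got, want, tolerance = 1e-9)
  }
  ## (3 of 10) vs (1 of 10)
  cnt <- data.frame(chrom = c("neo", "o"), pseudogenes = c(3L, 1L),
                    total = c(10L, 10L), stringsAsFactors = FALSE)
  expect_equal(pseudogene_enrichment(cnt)$p_vs_neo[2L],
               fisher_enum(3L, 7L, 1L, 9L), tolerance = 1e-9)
})

test_that("Nei-Gojobori counting matches hand-enumerated values", {
  ## identical alleles
  k0 <- kaks("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(k0$Ka, 0)
  expect_equal(k0$Ks, 0)
  ## single synonymous third-position change: TTT -> TTC (Phe)
  k1 <- kaks("ATGTTTGCTGCAGCG", "ATGTTCGCTGCAGCG")
  expect_equal(k1$Ns, 1)
  expect_equal(k1$Na, 0)
  expect_gt(k1$Ks, 0)
  expect_equal(k1$Ka, 0)
  ## single nonsynonymous change: GCT (Ala) -> GGT (Gly)
  k2 <- kaks("ATGGCTTTT", "ATGGGTTTT")
  expect_equal(k2$Na, 1)
  expect_equal(k2$Ns, 0)
  ## hand-enumerated site counts for a toy 6-codon pair:
  ## ATG CCA TTT AAA GGG CAT. Fractional synonymous sites per codon under
  ## the averaged single-change rule (stop-producing changes excluded from
  ## the synonymous numerator):
  ##   ATG 0; CCA 1; TTT 1/3; AAA 1/3; GGG 1/3 + 1/3 = ... enumerated below
  s <- "ATGCCATTTAAAGGGCAT"
  enum_syn <- function(codon) {
    code <- Biostrings::GENETIC_CODE
    tot <- 0
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, p, p))) {
      nc <- codon; substr(nc, p, p) <- b
      if (code[[nc]] == "*") next
      if (code[[nc]] == code[[codon]]) tot <- tot + 1 / 3
    }
    tot
  }
  cods <- substring(s, 3 * (1:6) - 2, 3 * (1:6))
  want_Ss <- sum(vapply(cods, enum_syn, 1))
  k3 <- kaks(s, s)
  expect_equal(k3$Ss, want_Ss, tolerance = 1e-9)
  expect_equal(k3$Sa, 3 * 6 - want_Ss, tolerance = 1e-9)
})

test_that("kaks is symmetric and invariant under codon rotation", {
  set.seed(131)
  a <- paste(sample(c("GCT", "AAA", "TTT", "CCA", "GGG", "CAT", "GAA", "TGC"),
                    40L, replace = TRUE), collapse = "")
  b <- a
  for (i in sample(40L, 6L)) {
    p <- 3L * (i - 1L) + sample(3L, 1L)
    cur <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  k_ab <- kaks(a, b)
  k_ba <- kaks(b, a)
  expect_equal(k_ab$Ka, k_ba$Ka, tolerance = 1e-12)
  expect_equal(k_ab$Ks, k_ba$Ks, tolerance = 1e-12)
  ## rotating both sequences by whole codons changes nothing
  rot <- function(x) paste0(substring(x, 16L), substr(x, 1L, 15L))
  k_rot <- kaks(rot(a), rot(b))
  expect_equal(k_ab$Ka, k_rot$Ka, tolerance = 1e-12)
  expect_equal(k_ab$Ks, k_rot$Ks, tolerance = 1e-12)
  ## unequal lengths are an error
  expect_error(kaks("ATGAAA", "ATGAAATTT"), "length")
})

test_that("ENC hits its formula limits and matches an independent recomputation", {
  ## one codon per family: ENC = 20
  one_per_family <- paste(rep(c("GCT", "AAA", "TTT", "CCC", "GGA", "CAT",
                                "GAA", "TGT", "ATT", "CTA", "AGA", "TCT",
                                "ACA", "GTT", "TAT", "CAA", "AAT", "GAT",
                                "ATG", "TGG"), each = 30L), collapse = "")
  expect_equal(enc(one_per_family), 20, tolerance = 1e-6)
  ## uniform usage approaches the 61 ceiling
  fams <- split(names(Biostrings::GENETIC_CODE),
                unname(as.character(Biostrings::GENETIC_CODE)))
  fams <- fams[!names(fams) %in% "*"]
  uni <- paste(rep(unlist(fams), times = 60L), collapse = "")
  expect_gt(enc(uni), 59.5)
  expect_lte(enc(uni), 61)
  ## random sequence: independent re-implementation of Wright's formula
  set.seed(133)
  cods <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), 1000L, replace = TRUE)
  s <- paste(cods, collapse = "")
  oracle <- local({
    code <- Biostrings::GENETIC_CODE
    tab <- table(factor(cods, levels = names(code)))
    fam <- split(names(code), unname(as.character(code)))
    fam <- fam[!names(fam) %in% "*"]
    Fk <- list()
    for (aa in names(fam)) {
      k <- length(fam[[aa]])
      if (k < 2L) next
      n <- sum(tab[fam[[aa]]])
      if (n < 2) next
      p <- as.numeric(tab[fam[[aa]]]) / n
      Fk[[aa]] <- c(k = k, f = (n * sum(p^2) - 1) / (n - 1))
    }
    m <- do.call(rbind, Fk)
    av <- function(k) mean(m[m[, "k"] == k, "f"])
    2 + 9 / av(2) + 1 / av(3) + 5 / av(4) + 3 / av(6)
  })
  expect_equal(enc(s), oracle, tolerance = 1e-9)
})

test_that("codon-bias indices stay in their theoretical ranges", {
  set.seed(135)
  seqs <- vapply(1:20, function(i) {
    paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), 300L, replace = TRUE),
          collapse = "")
  }, "")
  names(seqs) <- sprintf("g%d", 1:20)
  cb <- codon_bias(seqs, ref_expression = runif(20))
  expect_true(all(cb$ENC >= 20 & cb$ENC <= 61))
  expect_true(all(cb$CAI > 0 & cb$CAI <= 1))
  expect_true(all(cb$FOP >= 0 & cb$FOP <= 1))
  expect_true(all(is.finite(cb$CBI)))
  ## a sequence made only of reference-optimal codons maximizes FOP
  opt_seq <- paste(rep("GCC", 200L), collapse = "")
  cb2 <- codon_bias(c(ref = opt_seq, test = opt_seq))
  expect_equal(cb2$FOP, c(1, 1))
  expect_equal(cb2$CAI, c(1, 1))
})
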