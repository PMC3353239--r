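test_that("a single error-free read gives reference-base columns of count 1", {
  genome <- c(chrA = rand_seq(500, seed = 81L))
  rd <- substr(genome, 101L, 200L)
  pu <- build_pileup(genome, "chrA", 100L, "+", rd)
  m <- pu$counts$chrA
  expect_true(all(pu$depth$chrA[101:200] == 1L))
  expect_true(all(pu$depth$chrA[-(101:200)] == 0L))
  refrow <- match(strsplit(substr(genome, 101, 200), "")[[1L]], c("A", "C", "G", "T"))
  expect_true(all(m[cbind(refrow, 101:200)] == 1L))
})

test_that("two overlapping disagreeing reads give two non-zero base counts", {
  genome <- c(chrA = rand_seq(400, seed = 82L))
  r1 <- substr(genome, 51L, 150L)
  r2 <- r1
  cur <- substr(r2, 50L, 50L)
  substr(r2, 50L, 50L) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  pu <- build_pileup(genome, c("chrA", "chrA"), c(50L, 50L), c("+", "-"),
                     c(r1, rc(r2)))
  col <- pu$counts$chrA[, 100L]
  tot <- col[1:4] + col[5:8]
  expect_equal(sum(tot > 0), 2L)
  expect_equal(sum(tot), 2L)
})

test_that("pileup depth equals an independent interval-stabbing count", {
  genome <- c(chrA = rand_seq(3000, seed = 83L), chrB = rand_seq(2000, seed = 84L))
  set.seed(85)
  n <- 800L
  chrom <- sample(names(genome), n, replace = TRUE)
  pos <- vapply(chrom, function(ch) sample.int(nchar(genome[[ch]]) - 100L, 1L), 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome[chrom], pos + 1L, pos + 100L)
  seqs <- ifelse(strand == "-", as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs))), seqs)
  pu <- build_pileup(genome, chrom, pos, strand, seqs)
  for (ch in names(genome)) {
    iv <- IRanges::IRanges(pos[chrom == ch] + 1L, pos[chrom == ch] + 100L)
    oracle <- as.integer(IRanges::coverage(iv, width = nchar(genome[[ch]])))
    expect_equal(unname(pu$depth[[ch]]), oracle)
  }
})

test_that("unknown reference names in alignments fail loudly", {
  genome <- c(chrA = rand_seq(200, seed = 86L))
  expect_error(build_pileup(genome, "chrZ", 10L, "+", "ACGT"), "chrZ")
})

test_that("SNP calling thresholds, partitions and the 1:1 male ratio", {
  genome <- c(chrA = paste(rep("A", 50), collapse = ""))
  len <- 50L
  ## fabricate counts: site 10 = male 12 ref / 11 alt (C), female 20 ref / 0
  mm <- zero_mat(len); mf <- zero_mat(len)
  mm[1L, ] <- 6L; mm[5L, ] <- 6L   # male background depth 12, all ref (A)
  mf[1L, ] <- 10L; mf[5L, ] <- 10L # female background depth 20
  mm[1L, 10L] <- 6L; mm[5L, 10L] <- 6L
  mm[2L, 10L] <- 6L; mm[6L, 10L] <- 5L # alt C: 11 reads
  mm[1L, 10L] <- 6L; mm[5L, 10L] <- 6L # ref A: 12 reads
  ## a female-only site at 20: alt T 8 of 20
  mf[4L, 20L] <- 4L; mf[8L, 20L] <- 4L
  mf[1L, 20L] <- 6L; mf[5L, 20L] <- 6L
  ## depth-1 site at 30 must not be called anywhere
  mm[2L, 30L] <- 1L
  pu_m <- fake_pileup(genome, list(chrA = mm))
  pu_f <- fake_pileup(genome, list(chrA = mf))
  calls <- call_snps(pu_m, pu_f, genome, caller_params())
  expect_true(all(calls$pos %in% c(9L, 19L)))
  s10 <- calls[calls$pos == 9L, ]
  expect_identical(s10$partition, "male_only")
  expect_identical(s10$alt, "C")
  expect_equal(s10$male_alt, 11L)
  expect_equal(s10$male_ref, 12L)
  expect_equal(s10$alt_ratio_male, 11 / 23, tolerance = 1e-12)
  s20 <- calls[calls$pos == 19L, ]
  expect_identical(s20$partition, "female_segregating")
  expect_identical(s20$alt, "T")
})

test_that("indel retention requires support from both strands", {
  gp <- function(strand, n, pos = 100L) data.frame(
    name = sprintf("r%d", seq_len(n)), mapped = TRUE, chrom = "chrA",
    pos = pos - 50L, strand = strand, mm = 0L, gap_type = "del",
    gap_len = 4L, gap_pos = pos, gap_seq = "ACGT",
    stringsAsFactors = FALSE)
  ## 3 forward-only supporting reads: rejected
  m1 <- do.call(rbind, list(gp("+", 3L)))
  none <- call_indels(m1, m1[0, ])
  expect_equal(nrow(none), 0L)
  ## 1 forward + 1 reverse: retained
  m2 <- rbind(gp("+", 1L), gp("-", 1L))
  one <- call_indels(m2, m2[0, ])
  expect_equal(nrow(one), 1L)
  expect_identical(one$kind, "del")
  expect_identical(one$partition, "male_only")
  expect_equal(one$pos, 100L)
  ## same event in both sexes: shared
  both <- call_indels(m2, m2)
  expect_identical(both$partition, "shared")
})

test_that("planted deletions are recovered at the left-aligned coordinate", {
  ## end-to-end on a tiny system: one chromosome, one 4 bp deletion
  genome <- c(chrA = rand_seq(20000, seed = 91L))
  donor <- paste0(substr(genome, 1L, 5000L), substr(genome, 5005L, 20000L))
  rd <- simulate_reads(list(hapA = c(chrA = donor)), insert_spec(),
                       coverage = 20, err_rate = 0, seed = 92L)
  idx <- index_reference(genome)
  mp <- map_reads(idx, rd)
  pu <- pileup_from_mapping(genome, mp, rd)
  calls <- call_indels(mp$gapped, mp$gapped[0, ], pu, pu)
  dels <- calls[calls$kind == "del", ]
  expect_equal(nrow(dels), 1L)
  ## left-aligned truth coordinate computed independently
  p <- 5001L
  while (p > 1L && substr(genome, p - 1L, p - 1L) == substr(genome, p + 3L, p + 3L)) {
    p <- p - 1L
  }
  expect_equal(dels$pos, p - 1L)
  expect_equal(nchar(dels$ref), 4L)
})

test_that("window densities match a naive per-window recount", {
  lens <- c(chrA = 2500000)
  params <- caller_params(window = 1e6, step = 1e5)
  ## 10 calls uniformly inside the first 1 Mb window -> 0.01 sites/kb
  calls <- data.frame(chrom = "chrA", pos = as.integer(seq(50000, 950000,
                                                           length.out = 10)))
  tr <- window_density(calls, lens, params)
  expect_equal(tr$density[tr$start == 0], 10 / 1e6 * 1000)
  ## zero calls -> all-zero track
  tr0 <- window_density(calls[0, ], lens, params)
  expect_true(all(tr0$density == 0))
  ## random calls vs naive recount
  set.seed(93)
  calls2 <- data.frame(chrom = "chrA", pos = sort(sample.int(2500000, 400)) - 1L)
  tr2 <- window_density(calls2, lens, params)
  for (i in sample(nrow(tr2), 25)) {
    naive <- sum(calls2$pos >= tr2$start[i] & calls2$pos < tr2$end[i])
    expect_equal(tr2$n[i], naive)
  }
  ## trailing partial window uses its true length
  last <- tr2[nrow(tr2), ]
  expect_lt(last$end - last$start, params$window)
  expect_equal(last$density, last$n / (last$end - last$start) * 1000)
})

test_that("density ratios print in the published table style", {
  r <- ratio_of_densities(2.04, 1.01)
  expect_identical(r$printed, "2.02")
  expect_identical(ratio_of_densities(4.61, 0.97)$printed, "4.75")
  expect_identical(ratio_of_densities(0.18, 0.01)$printed, "18")
  expect_identical(ratio_of_densities(1, 1)$printed, "1.00")
  expect_identical(ratio_of_densities(1, 0)$printed, "NA")
})

test_that("allele-ratio spectrum separates fixed-like from low-frequency calls", {
  genome <- c(chrA = paste(rep("A", 100), collapse = ""))
  mk_call <- function(pos, alt, ref) data.frame(
    kind = "snp", chrom = "chrA", pos = pos, ref = "A", alt = "C",
    male_ref = ref, male_alt = alt, female_ref = 0L, female_alt = 0L,
    alt_fwd = alt, alt_rev = 0L, partition = "male_only",
    alt_ratio_male = alt / (alt + ref), stringsAsFactors = FALSE)
  calls <- rbind(mk_call(10L, 10L, 10L),  # ratio 1:1 -> in bin
                 mk_call(20L, 2L, 18L))   # ratio 0.1 -> out of bin
  m <- zero_mat(100L); m[1L, ] <- 20L
  pu <- fake_pileup(genome, list(chrA = m))
  sp <- allele_ratio_spectrum(calls, pu)
  expect_equal(sp$summary$frac_in_bin, 0.5)
  expect_equal(sum(sp$spectrum$fraction), 1)
  expect_equal(sp$summary$density_in_bin, 1 / 100 * 1000)
})

test_that("VCF output is well-formed and positions are 1-based", {
  genome <- c(chrA = rand_seq(100, seed = 95L))
  calls <- data.frame(kind = c("snp", "del"), chrom = "chrA",
                      pos = c(9L, 49L),
                      ref = c(substr(genome, 10L, 10L), substr(genome, 50L, 52L)),
                      alt = c("T", ""), male_ref = 5L, male_alt = 5L,
                      female_ref = 5L, female_alt = 0L, alt_fwd = 3L,
                      alt_rev = 2L, partition = "male_only",
                      alt_ratio_male = 0.5, stringsAsFactors = FALSE)
  calls$alt[1L] <- setdiff(c("A", "C", "G", "T"), calls$ref[1L])[1L]
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, genome, f)
  ln <- readLines(f)
  body <- ln[!startsWith(ln, "#")]
  expect_equal(length(body), 2L)
  fields <- strsplit(body, "\t")
  expect_equal(as.integer(fields[[1L]][2]), 10L)     # snp: 1-based
  expect_equal(as.integer(fields[[2L]][2]), 49L)     # del: anchor base
  expect_equal(nchar(fields[[2L]][4]), 4L)           # anchor + 3 deleted
  expect_match(fields[[1L]][8], "PARTITION=male_only")
})
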