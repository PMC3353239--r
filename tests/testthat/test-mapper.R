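test_that("k-mer lookups agree with a naive string scan", {
  ref <- c(chrA = rand_seq(10000, seed = 21L))
  idx <- index_reference(ref, k = 13L)
  set.seed(22)
  starts <- sample.int(10000 - 13, 100)
  for (s in starts[1:40]) {
    km <- substr(ref, s, s + 12L)
    hits <- lookup_kmer(idx, km)
    ## naive oracle: every occurrence by sliding-window comparison
    naive <- which(vapply(1:(10000 - 12), function(p)
      substr(ref, p, p + 12L) == km, TRUE)) - 1L
    expect_setequal(hits$pos, naive)
  }
})

test_that("sequences shorter than k are skipped with a warning", {
  expect_warning(idx <- index_reference(c(a = "ACGT", b = rand_seq(100, 2L)),
                                        k = 13L), "shorter")
  expect_identical(idx$names, "b")
})

test_that("verbatim mates at the insert distance align FR with zero mismatches", {
  ref <- c(chrA = rand_seq(5000, seed = 31L))
  ins <- insert_spec(mean = 500, sd = 50, read_len = 100L)
  s <- 1000L
  r1 <- substr(ref, s, s + 99L)
  r2 <- rc(substr(ref, s + 400L, s + 499L))
  idx <- index_reference(ref)
  pa <- align_pairs(idx, r1, r2)
  expect_true(pa$mapped)
  expect_equal(pa$pos1, s - 1L)
  expect_equal(c(pa$mm1, pa$mm2), c(0L, 0L))
  expect_identical(pa$orientation_class, "FR")
  expect_equal(pa$span, 500L)
})

test_that("a mate with three mismatches everywhere is unmapped", {
  ref <- c(chrA = rand_seq(4000, seed = 33L))
  r <- substr(ref, 501L, 600L)
  for (p in c(10L, 50L, 90L)) {
    cur <- substr(r, p, p)
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  idx <- index_reference(ref)
  al2 <- align_single(idx, substr(ref, 501L, 600L))
  expect_true(al2$mapped)
  al3 <- align_single(idx, r)
  expect_false(al3$mapped)
  ## and the pair is reported unmapped with a reason
  pa <- align_pairs(idx, r, rc(substr(ref, 901L, 1000L)))
  expect_false(pa$mapped)
  expect_identical(pa$reason, "no_placement")
})

test_that("alignment position matches the Biostrings mismatch-scan oracle", {
  ref <- c(chrA = rand_seq(15000, seed = 35L))
  idx <- index_reference(ref)
  set.seed(36)
  for (i in 1:40) {
    s <- sample.int(14900, 1)
    r <- substr(ref, s, s + 99L)
    nmm <- sample(0:2, 1)
    if (nmm > 0) for (p in sample(100, nmm)) {
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1L]
    }
    al <- align_single(idx, r)
    ## independent oracle: all placements with <= 2 mismatches on both strands
    fw <- Biostrings::matchPattern(r, ref[[1L]], max.mismatch = 2)
    rv <- Biostrings::matchPattern(rc(r), ref[[1L]], max.mismatch = 2)
    n_pl <- length(fw) + length(rv)
    if (n_pl == 1L) {
      expect_true(al$mapped && al$unique)
      if (length(fw)) {
        expect_equal(al$pos, Biostrings::start(fw)[1L] - 1L)
        expect_identical(al$strand, "+")
      } else {
        expect_equal(al$pos, Biostrings::start(rv)[1L] - 1L)
        expect_identical(al$strand, "-")
      }
    }
  }
})

test_that("all simulated error-free pairs align back to their origin", {
  g <- simulate_genome(small_plan(seed = 41L, gene_counts = c(0L, 0L, 0L, 0L)))
  rd <- simulate_reads(list(hapA = g$seqs), insert_spec(), coverage = 2,
                       err_rate = 0, seed = 5L)
  idx <- index_reference(g$seqs)
  pa <- align_pairs(idx, rd$reads1, rd$reads2)
  expect_true(all(pa$mapped))
  expect_equal(pa$chrom1, rd$meta$chrom)
  expect_equal(pa$pos1, rd$meta$start - 1L)
  expect_true(all(pa$orientation_class == "FR"))
  expect_true(all(pa$mm1 == 0L & pa$mm2 == 0L))
})

test_that("gapped rescue recovers constructed indels and rejects 7 bp gaps", {
  ref <- c(chrA = rand_seq(6000, seed = 51L))
  idx <- index_reference(ref)
  ## read with a 3 bp deletion relative to the reference
  r_del <- paste0(substr(ref, 2001L, 2050L), substr(ref, 2054L, 2103L))
  g <- realign_unmapped(idx, r_del)
  expect_true(g$mapped)
  expect_identical(g$gap_type, "del")
  expect_equal(g$gap_len, 3L)
  ## left-aligned coordinate: shifting the reported gap left must change sequence
  expect_true(g$gap_pos <= 2050L)
  del_seq <- substr(ref, g$gap_pos + 1L, g$gap_pos + 3L)
  expect_identical(g$gap_seq, unname(del_seq))
  ## reconstructing the read from the gapped placement reproduces it
  rebuilt <- paste0(substr(ref, g$pos + 1L, g$gap_pos),
                    substr(ref, g$gap_pos + 4L, g$pos + 103L))
  expect_identical(rebuilt, unname(r_del))
  ## a 7 bp gap is beyond the rescue contract
  r7 <- paste0(substr(ref, 3001L, 3050L), substr(ref, 3058L, 3107L))
  g7 <- realign_unmapped(idx, r7)
  expect_false(g7$mapped)
  ## insertion: 4 extra bases in the read
  r_ins <- paste0(substr(ref, 4001L, 4050L), "TTTT", substr(ref, 4051L, 4096L))
  gi <- realign_unmapped(idx, r_ins)
  expect_true(gi$mapped)
  expect_identical(gi$gap_type, "ins")
  expect_equal(gi$gap_len, 4L)
})

test_that("gapped placements match an exhaustive dynamic scan oracle", {
  ref_str <- rand_seq(1500, seed = 61L)
  ref <- c(chrA = ref_str)
  idx <- index_reference(ref)
  refv <- strsplit(ref_str, "")[[1L]]
  ## oracle: best single-gap placement by brute force over all starts,
  ## gap types, lengths and split points
  oracle <- function(read) {
    rv <- strsplit(read, "")[[1L]]
    L <- length(rv)
    best <- NULL
    for (strand in c("+", "-")) {
      rr <- if (strand == "+") rv else rev(c(A = "T", C = "G", G = "C", T = "A")[rv])
      for (p in 1:(1500 - L - 6)) {
        for (g in 1:6) {
          ## deletion: read skips g reference bases after split i
          pre <- cumsum(rr != refv[p:(p + L - 1L)])
          suf <- rev(cumsum(rev(rr != refv[(p + g):(p + g + L - 1L)])))
          for (i in 1:(L - 1L)) {
            mm <- (if (i > 0) pre[i] else 0L) + (if (i < L) suf[i + 1L] else 0L)
            if (mm <= 2L && (is.null(best) || mm < best$mm)) {
              best <- list(mm = mm, pos = p - 1L, type = "del", len = g,
                           strand = strand)
            }
          }
          ## insertion: g read bases unmatched after split i
          if (L - g >= 2L) {
            pre2 <- cumsum(rr != refv[p:(p + L - 1L)])
            sufv <- rr[(g + 1L):L] != refv[p:(p + L - g - 1L)]
            suf2 <- rev(cumsum(rev(sufv)))
            for (i in 1:(L - g - 1L)) {
              mm <- pre2[i] + suf2[i + 1L]
              if (mm <= 2L && (is.null(best) || mm < best$mm)) {
                best <- list(mm = mm, pos = p - 1L, type = "ins", len = g,
                             strand = strand)
              }
            }
          }
        }
      }
    }
    best
  }
  set.seed(62)
  for (rep in 1:15) {
    s <- sample(200:1300, 1)
    g <- sample(1:6, 1)
    if (runif(1) < 0.5) {
      read <- paste0(substr(ref_str, s, s + 49L),
                     substr(ref_str, s + 50L + g, s + 99L + g))
    } else {
      read <- paste0(substr(ref_str, s, s + 49L),
                     rand_seq(g, seed = rep + 100L),
                     substr(ref_str, s + 50L, s + 99L - g))
    }
    got <- realign_unmapped(idx, read)
    want <- oracle(read)
    expect_true(got$mapped)
    expect_equal(got$mm, want$mm)
    expect_equal(got$gap_len, want$len)
    expect_identical(got$gap_type, want$type)
  }
})

test_that("SAM output parses and round-trips the placements", {
  g <- simulate_genome(small_plan(seed = 71L, gene_counts = c(0L, 0L, 0L, 0L)))
  rd <- simulate_reads(list(hapA = g$seqs["chr2"]), insert_spec(), coverage = 0.5,
                       err_rate = 0, seed = 6L)
  idx <- index_reference(g$seqs)
  pa <- align_pairs(idx, rd$reads1, rd$reads2)
  f <- tempfile(fileext = ".sam")
  write_sam(pa, rd, idx, f)
  back <- read_sam(f)
  expect_equal(nrow(back), 2L * nrow(pa))
  m1 <- back[back$mate == 1L, ]
  m1 <- m1[match(pa$name, m1$name), ]
  expect_equal(m1$pos[pa$mapped], pa$pos1[pa$mapped])
  expect_identical(m1$strand[pa$mapped], pa$strand1[pa$mapped])
  ## header declares every reference
  hdr <- grep("^@SQ", readLines(f), value = TRUE)
  expect_equal(length(hdr), length(idx$names))
})
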