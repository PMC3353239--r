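## Minimal paired-end seed-and-extend aligner.
##
## Mapping contract: at most 2 mismatches per mate in ungapped mode;
## orientation and span are recorded but never used to reject a placement
## (anomalies are the structural-variant evidence); reads failing ungapped
## alignment are rescued in single-end mode with exactly one 1-6 bp gap.
## Ties are broken to the left-most placement (chromosome name order, then
## position) and reported non-unique; non-unique pairs are excluded from
## variant and SV evidence.

#' Build a k-mer seed index over a reference
#'
#' @param genome named character vector of reference sequences; chromosomes
#'   are indexed in lexicographic name order so tie-breaking is deterministic
#' @param k seed length (>= 11; default 13 guarantees an exact seed for a
#'   36-100 bp read carrying at most 2 mismatches)
#' @return object of class `seed_index`
#' @export
index_reference <- function(genome, k = 13L) {
  stopifnot(k >= 11L)
  genome <- genome[order(names(genome))]
  short <- nchar(genome) < k
  if (any(short)) {
    warning("skipping sequences shorter than k: ",
            paste(names(genome)[short], collapse = ", "))
    genome <- genome[!short]
  }
  xp <- cpp_build_index(unname(genome), names(genome), as.integer(k))
  structure(list(xp = xp, k = as.integer(k), names = names(genome),
                 lengths = setNames(nchar(genome), names(genome)),
                 genome = genome),
            class = "seed_index")
}

#' Look up all occurrences of one k-length substring
#' @param index a [index_reference()] result
#' @param kmer string of length `k`
#' @return data.frame with chrom, pos (0-based), strand ("+")
#' @export
lookup_kmer <- function(index, kmer) {
  hits <- cpp_lookup_kmer(index$xp, kmer)
  data.frame(chrom = index$names[hits$chrom_id], pos = hits$pos,
             strand = if (nrow(hits)) "+" else character(0),
             stringsAsFactors = FALSE)
}

## orientation class from per-mate placements (vectorized)
orientation_class <- function(chrom1, pos1, fwd1, chrom2, pos2, fwd2, read_len) {
  inter <- chrom1 != chrom2
  ## identify the left-most mate
  m1_left <- pos1 <= pos2
  up_fwd <- ifelse(m1_left, fwd1, fwd2)
  dn_fwd <- ifelse(m1_left, fwd2, fwd1)
  cls <- ifelse(inter, "interlocus",
         ifelse(up_fwd & !dn_fwd, "FR",
         ifelse(!up_fwd & dn_fwd, "RF", "FF")))
  cls
}

#' Align read pairs against a seed index
#'
#' Each mate is placed at its minimum-mismatch position (<= `max_mm`
#' mismatches); pairs in which either mate has a tied-score alternative
#' placement are reported unmapped-ambiguous (`mapped = FALSE`,
#' `reason = "ambiguous"`). Orientation class and outer span are recorded for
#' downstream SV classification but never cause rejection.
#'
#' @param index a [index_reference()] result
#' @param reads1,reads2 named character vectors of mate sequences (mate 2 as
#'   sequenced, i.e. reverse-complement strand)
#' @param max_mm maximum mismatches per mate (default 2)
#' @return PairAlignment data.frame: name, mapped, unique, reason, chrom1,
#'   pos1 (0-based), strand1, mm1, chrom2, pos2, strand2, mm2, span (outer
#'   distance when co-located, NA otherwise), orientation_class
#' @export
align_pairs <- function(index, reads1, reads2, max_mm = 2L) {
  stopifnot(inherits(index, "seed_index"), length(reads1) == length(reads2))
  res <- cpp_align_pe(index$xp, unname(reads1), unname(reads2),
                      as.integer(max_mm))
  L1 <- nchar(reads1); L2 <- nchar(reads2)
  ok <- res$mapped & res$unique
  chrom1 <- ifelse(res$mapped, index$names[res$chrom1], NA_character_)
  chrom2 <- ifelse(res$mapped, index$names[res$chrom2], NA_character_)
  same <- res$mapped & chrom1 == chrom2
  outer_left <- pmin(res$pos1, res$pos2)
  outer_right <- pmax(res$pos1 + L1, res$pos2 + L2)
  span <- ifelse(same, outer_right - outer_left, NA_integer_)
  cls <- rep(NA_character_, nrow(res))
  cls[res$mapped] <- orientation_class(chrom1[res$mapped], res$pos1[res$mapped],
                                       res$fwd1[res$mapped], chrom2[res$mapped],
                                       res$pos2[res$mapped], res$fwd2[res$mapped],
                                       L1[res$mapped])
  data.frame(
    name = if (!is.null(names(reads1))) names(reads1) else
      sprintf("pair%d", seq_along(reads1)),
    mapped = ok,
    unique = res$unique,
    reason = ifelse(ok, "", ifelse(res$mapped, "ambiguous", "no_placement")),
    chrom1 = chrom1, pos1 = res$pos1,
    strand1 = ifelse(res$fwd1, "+", "-"), mm1 = res$mm1,
    chrom2 = chrom2, pos2 = res$pos2,
    strand2 = ifelse(res$fwd2, "+", "-"), mm2 = res$mm2,
    span = span, orientation_class = cls,
    stringsAsFactors = FALSE)
}

#' Align single reads (best ungapped placement)
#'
#' @inheritParams align_pairs
#' @param reads named character vector
#' @return data.frame: name, mapped, unique, chrom, pos (0-based), strand, mm
#' @export
align_single <- function(index, reads, max_mm = 2L) {
  res <- cpp_align_se(index$xp, unname(reads), as.integer(max_mm))
  data.frame(
    name = if (!is.null(names(reads))) names(reads) else
      sprintf("read%d", seq_along(reads)),
    mapped = res$mapped, unique = res$mapped & res$nties == 1L,
    chrom = ifelse(res$mapped, index$names[res$chrom], NA_character_),
    pos = res$pos, strand = ifelse(res$fwd, "+", "-"), mm = res$mm,
    stringsAsFactors = FALSE)
}

#' Gapped rescue alignment of previously unmapped reads
#'
#' Finds the best placement with at most `max_mm` mismatches plus exactly one
#' contiguous gap of 1..`max_indel` bp in read or reference. The gap is
#' left-aligned against the reference (canonical normalization). Tied
#' placements at distinct loci are reported unmapped.
#'
#' @inheritParams align_pairs
#' @param reads named character vector of reads that failed paired alignment
#' @param max_indel maximum gap length, bp (default 6)
#' @return data.frame: name, mapped, chrom, pos (0-based alignment start),
#'   strand, mm, gap_type ("del" = reference bases absent from the read,
#'   "ins" = extra read bases), gap_len, gap_pos (0-based, left-aligned),
#'   gap_seq
#' @export
realign_unmapped <- function(index, reads, max_mm = 2L, max_indel = 6L) {
  res <- cpp_realign_gapped(index$xp, unname(reads), as.integer(max_mm),
                            as.integer(max_indel))
  data.frame(
    name = if (!is.null(names(reads))) names(reads) else
      sprintf("read%d", seq_along(reads)),
    mapped = res$mapped,
    chrom = ifelse(res$mapped, index$names[res$chrom_id], NA_character_),
    pos = res$pos, strand = ifelse(res$fwd, "+", "-"), mm = res$mm,
    gap_type = c("del", "ins")[res$gap_type], gap_len = res$gap_len,
    gap_pos = res$gap_pos, gap_seq = res$gap_seq,
    stringsAsFactors = FALSE)
}

#' Map one sex's read set: paired mode plus single-end gapped rescue
#'
#' The mapping protocol of the pipeline: reads are first aligned in paired
#' mode; pairs in which at least one mate found no ungapped placement are
#' re-aligned mate-by-mate in single-end mode allowing one 1-6 bp indel.
#'
#' @param index a [index_reference()] result
#' @param reads list with `reads1`, `reads2` (as from [simulate_reads()])
#' @param max_mm maximum mismatches per mate
#' @param max_indel maximum rescue-gap length
#' @return list with `pairs` (PairAlignment data.frame), `singles` (unique
#'   ungapped single-end placements of mates whose pair failed — typically
#'   because the other mate was unmappable; they contribute pileup evidence)
#'   and `gapped` (single-gap rescue alignments with a `mate` column)
#' @export
map_reads <- function(index, reads, max_mm = 2L, max_indel = 6L) {
  pa <- align_pairs(index, reads$reads1, reads$reads2, max_mm)
  ## single-end rescue: mates of pairs without a full paired placement are
  ## re-aligned individually, first ungapped, then with one 1-6 bp gap
  resc <- which(!pa$mapped & pa$reason == "no_placement")
  gapped <- NULL
  singles <- NULL
  if (length(resc)) {
    for (mate in 1:2) {
      r <- if (mate == 1L) reads$reads1[resc] else reads$reads2[resc]
      se <- align_single(index, r, max_mm)
      ok <- se$mapped & se$unique
      if (any(ok)) {
        s <- se[ok, , drop = FALSE]
        s$mate <- mate
        s$seq <- unname(r[ok])
        singles <- rbind(singles, s)
      }
      g <- realign_unmapped(index, r[!ok], max_mm, max_indel)
      g$mate <- mate
      gapped <- rbind(gapped, g[g$mapped, , drop = FALSE])
    }
  }
  if (is.null(gapped)) {
    gapped <- data.frame(name = character(0), mapped = logical(0),
                         chrom = character(0), pos = integer(0),
                         strand = character(0), mm = integer(0),
                         gap_type = character(0), gap_len = integer(0),
                         gap_pos = integer(0), gap_seq = character(0),
                         mate = integer(0), stringsAsFactors = FALSE)
  }
  if (is.null(singles)) {
    singles <- data.frame(name = character(0), mapped = logical(0),
                          unique = logical(0), chrom = character(0),
                          pos = integer(0), strand = character(0),
                          mm = integer(0), mate = integer(0),
                          seq = character(0), stringsAsFactors = FALSE)
  }
  list(pairs = pa, singles = singles, gapped = gapped)
}

## ---- SAM emission / ingestion -------------------------------------------

#' Write pair alignments as SAM
#'
#' Emits a minimal valid SAM: @HD/@SQ header, FLAG encoding pairing and
#' strand, simple `<len>M` CIGARs. Unmapped and ambiguous pairs get FLAG 4.
#'
#' @param pairs PairAlignment data.frame from [align_pairs()]
#' @param reads list with `reads1`, `reads2`
#' @param index the [index_reference()] used
#' @param path output file
#' @return the path, invisibly
#' @export
write_sam <- function(pairs, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", index$names, index$lengths)), con)
  orient <- function(seq, strand) ifelse(strand == "-", revcomp(seq), seq)
  for (mate in 1:2) {
    mapped <- pairs$mapped
    flag <- 1L + ifelse(mate == 1L, 64L, 128L)
    st <- if (mate == 1L) pairs$strand1 else pairs$strand2
    ot <- if (mate == 1L) pairs$strand2 else pairs$strand1
    flag <- flag + ifelse(mapped & st == "-", 16L, 0L) +
      ifelse(mapped & ot == "-", 32L, 0L) + ifelse(mapped, 0L, 4L)
    chrom <- if (mate == 1L) pairs$chrom1 else pairs$chrom2
    pos <- if (mate == 1L) pairs$pos1 else pairs$pos2
    sq <- if (mate == 1L) reads$reads1 else reads$reads2
    sq_out <- ifelse(mapped, orient(unname(sq), st), unname(sq))
    ln <- paste(pairs$name, flag,
                ifelse(mapped, chrom, "*"), ifelse(mapped, pos + 1L, 0L),
                ifelse(mapped, 60L, 0L),
                ifelse(mapped, paste0(nchar(sq), "M"), "*"),
                "*", 0L, 0L, sq_out, strrep("?", nchar(sq)), sep = "\t")
    writeLines(ln, con)
  }
  invisible(path)
}

#' Read a SAM file into the pipeline's alignment representation
#'
#' Alternative entry point for externally produced alignments. Only the
#' fields the pipeline uses are parsed: name, FLAG (strand, mate, unmapped),
#' chrom, 1-based position, CIGAR (M/I/D) and sequence.
#'
#' @param path SAM file
#' @return data.frame: name, mate, mapped, chrom, pos (0-based), strand, seq
#'   (reference-strand orientation), cigar
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) {
    return(data.frame(name = character(0), mate = integer(0),
                      mapped = logical(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      seq = character(0), cigar = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(getf(2))
  data.frame(name = getf(1),
             mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
             mapped = bitwAnd(flag, 4L) == 0L,
             chrom = getf(3),
             pos = as.integer(getf(4)) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             seq = getf(10), cigar = getf(6),
             stringsAsFactors = FALSE)
}
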