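## Pileup-based SNP / short-indel calling per sex and sex-partition
## classification.
##
## The caller is a count-threshold caller: a site is called in a sex when
## depth >= min_depth, alternative-base count >= min_alt_reads and the
## alternative fraction >= f_min. Fixed neo-X/neo-Y differences surface in
## the male read pool at a roughly 1:1 allele ratio, which is what the
## partition label and the allele-ratio spectrum exploit.

#' Caller and density parameters
#'
#' @param min_depth minimum depth for a site to be callable in a sex
#' @param min_alt_reads minimum alternative-base reads
#' @param f_min minimum alternative-base fraction
#' @param window,step sliding-window size and step for density tracks, bp
#' @param ratio_bin allele-ratio interval treated as "around 1:1"
#' @return object of class `caller_params`
#' @export
caller_params <- function(min_depth = 8L, min_alt_reads = 3L, f_min = 0.2,
                          window = 1e6, step = 1e5, ratio_bin = c(0.4, 0.6)) {
  stopifnot(min_depth >= 2L, step <= window)
  structure(list(min_depth = as.integer(min_depth),
                 min_alt_reads = as.integer(min_alt_reads), f_min = f_min,
                 window = window, step = step, ratio_bin = ratio_bin),
            class = "caller_params")
}

#' Build a stranded base pileup from ungapped alignments
#'
#' One column per reference position with per-strand A/C/G/T counts. Only
#' uniquely mapped reads should be supplied (the pipeline's [map_reads()]
#' wrapper enforces this).
#'
#' @param genome named character vector of reference sequences
#' @param chrom,pos,strand,seqs parallel vectors describing ungapped read
#'   placements: chromosome name, 0-based start, "+"/"-", read sequence as
#'   sequenced (minus-strand reads are reverse-complemented internally)
#' @return object of class `pileup`: list with `counts` (per chromosome an
#'   8 x length integer matrix, rows A,C,G,T forward then A,C,G,T reverse)
#'   and `depth` (per chromosome an integer vector)
#' @export
build_pileup <- function(genome, chrom, pos, strand, seqs) {
  missing <- setdiff(unique(chrom[!is.na(chrom)]), names(genome))
  if (length(missing)) {
    stop("alignment reference names absent from genome: ",
         paste(missing, collapse = ", "))
  }
  cid <- match(chrom, names(genome))
  mats <- cpp_pileup(unname(genome), cid, as.integer(pos), strand == "+",
                     unname(seqs))
  names(mats) <- names(genome)
  depth <- lapply(mats, colSums)
  structure(list(counts = mats, depth = depth,
                 lengths = setNames(nchar(genome), names(genome))),
            class = "pileup")
}

## helper: pileup from the pipeline's mapper output for one sex (paired
## placements plus single-end rescued mates)
pileup_from_mapping <- function(genome, mapping, reads) {
  pa <- mapping$pairs
  keep <- which(pa$mapped)
  chrom <- c(pa$chrom1[keep], pa$chrom2[keep])
  pos <- c(pa$pos1[keep], pa$pos2[keep])
  strand <- c(pa$strand1[keep], pa$strand2[keep])
  sq <- c(unname(reads$reads1[keep]), unname(reads$reads2[keep]))
  s <- mapping$singles
  if (!is.null(s) && nrow(s)) {
    chrom <- c(chrom, s$chrom)
    pos <- c(pos, s$pos)
    strand <- c(strand, s$strand)
    sq <- c(sq, s$seq)
  }
  build_pileup(genome, chrom, pos, strand, sq)
}

BASE_ROW <- c(A = 1L, C = 2L, G = 3L, T = 4L)

#' Call SNPs in both sexes and classify their sex partition
#'
#' The alternative base at a site is the most frequent non-reference base in
#' the pooled (male + female) counts (ties broken in A<C<G<T order). A site
#' enters the call set when it is called in at least one sex; the partition
#' is `shared` (called in both, or called in males with above-threshold
#' female support), `male_only` (called in males, female alternative count
#' below `min_alt_reads`) or `female_segregating` (called in females only).
#'
#' @param male_pileup,female_pileup [build_pileup()] results on the same
#'   reference
#' @param genome named character vector of reference sequences
#' @param params a [caller_params()]
#' @return VariantCall data.frame: kind ("snp"), chrom, pos (0-based), ref,
#'   alt, male_ref, male_alt, female_ref, female_alt, alt_fwd, alt_rev,
#'   partition, alt_ratio_male
#' @export
call_snps <- function(male_pileup, female_pileup, genome, params = caller_params()) {
  out <- list()
  for (ch in names(genome)) {
    m <- male_pileup$counts[[ch]]
    f <- female_pileup$counts[[ch]]
    len <- nchar(genome[[ch]])
    totm <- m[1:4, , drop = FALSE] + m[5:8, , drop = FALSE]
    totf <- f[1:4, , drop = FALSE] + f[5:8, , drop = FALSE]
    pool <- totm + totf
    refrow <- BASE_ROW[strsplit(genome[[ch]], "", fixed = TRUE)[[1L]]]
    ok_ref <- !is.na(refrow)
    ridx <- cbind(refrow[ok_ref], which(ok_ref))
    poolA <- pool
    poolA[ridx] <- -1L
    altrow <- max.col(t(poolA), ties.method = "first")
    aidx <- cbind(altrow, seq_len(len))
    alt_m <- totm[aidx]; alt_f <- totf[aidx]
    ref_m <- integer(len); ref_f <- integer(len)
    ref_m[ok_ref] <- totm[ridx]; ref_f[ok_ref] <- totf[ridx]
    dep_m <- male_pileup$depth[[ch]]; dep_f <- female_pileup$depth[[ch]]
    called_m <- ok_ref & dep_m >= params$min_depth &
      alt_m >= params$min_alt_reads & alt_m >= params$f_min * dep_m
    called_f <- ok_ref & dep_f >= params$min_depth &
      alt_f >= params$min_alt_reads & alt_f >= params$f_min * dep_f
    site <- which(called_m | called_f)
    if (!length(site)) next
    partition <- ifelse(called_m[site] & called_f[site], "shared",
                 ifelse(called_m[site],
                        ifelse(alt_f[site] < params$min_alt_reads,
                               "male_only", "shared"),
                        "female_segregating"))
    out[[ch]] <- data.frame(
      kind = "snp", chrom = ch, pos = site - 1L,
      ref = names(BASE_ROW)[refrow[site]], alt = names(BASE_ROW)[altrow[site]],
      male_ref = ref_m[site], male_alt = alt_m[site],
      female_ref = ref_f[site], female_alt = alt_f[site],
      alt_fwd = m[aidx[site, 1L, drop = TRUE] + 0L +
                  (aidx[site, 2L, drop = TRUE] - 1L) * 8L] +
                f[aidx[site, 1L, drop = TRUE] + 0L +
                  (aidx[site, 2L, drop = TRUE] - 1L) * 8L],
      alt_rev = m[aidx[site, 1L, drop = TRUE] + 4L +
                  (aidx[site, 2L, drop = TRUE] - 1L) * 8L] +
                f[aidx[site, 1L, drop = TRUE] + 4L +
                  (aidx[site, 2L, drop = TRUE] - 1L) * 8L],
      partition = partition,
      alt_ratio_male = ifelse(ref_m[site] + alt_m[site] > 0,
                              alt_m[site] / (ref_m[site] + alt_m[site]), NA),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    kind = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), male_ref = integer(0),
    male_alt = integer(0), female_ref = integer(0), female_alt = integer(0),
    alt_fwd = integer(0), alt_rev = integer(0), partition = character(0),
    alt_ratio_male = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call short indels from gapped rescue alignments
#'
#' An indel is retained in a sex when it has at least one supporting read on
#' each strand and its length is within 1-6 bp. Reference counts are taken
#' from the ungapped pileup depth at the gap position.
#'
#' @param male_gapped,female_gapped gapped-alignment data.frames from
#'   [realign_unmapped()] / [map_reads()]
#' @param male_pileup,female_pileup [build_pileup()] results (for depth)
#' @param params a [caller_params()]
#' @return VariantCall data.frame (kind "ins"/"del"; ref/alt hold the
#'   deleted/inserted bases)
#' @export
call_indels <- function(male_gapped, female_gapped,
                        male_pileup = NULL, female_pileup = NULL,
                        params = caller_params()) {
  tab <- function(g) {
    g <- g[g$mapped & g$gap_len >= 1L & g$gap_len <= 6L, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    key <- paste(g$chrom, g$gap_pos, g$gap_type, g$gap_len, g$gap_seq, sep = "\r")
    fwd <- tapply(g$strand == "+", key, sum)
    rev_ <- tapply(g$strand == "-", key, sum)
    parts <- do.call(rbind, strsplit(names(fwd), "\r", fixed = TRUE))
    data.frame(chrom = parts[, 1L], gap_pos = as.integer(parts[, 2L]),
               gap_type = parts[, 3L], gap_len = as.integer(parts[, 4L]),
               gap_seq = parts[, 5L], fwd = as.integer(fwd),
               rev = as.integer(rev_), stringsAsFactors = FALSE)
  }
  tm <- tab(male_gapped); tf <- tab(female_gapped)
  keym <- if (!is.null(tm)) paste(tm$chrom, tm$gap_pos, tm$gap_type,
                                  tm$gap_len, tm$gap_seq) else character(0)
  keyf <- if (!is.null(tf)) paste(tf$chrom, tf$gap_pos, tf$gap_type,
                                  tf$gap_len, tf$gap_seq) else character(0)
  pass_m <- if (!is.null(tm)) tm$fwd >= 1L & tm$rev >= 1L else logical(0)
  pass_f <- if (!is.null(tf)) tf$fwd >= 1L & tf$rev >= 1L else logical(0)
  keys <- union(keym[pass_m], keyf[pass_f])
  if (!length(keys)) {
    return(data.frame(kind = character(0), chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      male_ref = integer(0), male_alt = integer(0),
                      female_ref = integer(0), female_alt = integer(0),
                      alt_fwd = integer(0), alt_rev = integer(0),
                      partition = character(0), alt_ratio_male = numeric(0),
                      stringsAsFactors = FALSE))
  }
  im <- match(keys, keym); ifm <- match(keys, keyf)
  getcol <- function(t, i, col, default = 0L) {
    ifelse(is.na(i), default, t[[col]][i])
  }
  chrom <- ifelse(is.na(im), tf$chrom[ifm], tm$chrom[im])
  gpos <- ifelse(is.na(im), tf$gap_pos[ifm], tm$gap_pos[im])
  gtyp <- ifelse(is.na(im), tf$gap_type[ifm], tm$gap_type[im])
  gseq <- ifelse(is.na(im), tf$gap_seq[ifm], tm$gap_seq[im])
  m_sup <- getcol(tm, im, "fwd") + getcol(tm, im, "rev")
  f_sup <- getcol(tf, ifm, "fwd") + getcol(tf, ifm, "rev")
  dep <- function(pu, chrom, pos) {
    if (is.null(pu)) return(rep(NA_integer_, length(pos)))
    vapply(seq_along(pos), function(i) {
      d <- pu$depth[[chrom[i]]]
      p <- pos[i] + 1L
      if (!is.null(d) && p >= 1L && p <= length(d)) as.integer(d[p]) else 0L
    }, 1L)
  }
  dm <- dep(male_pileup, chrom, gpos); df_ <- dep(female_pileup, chrom, gpos)
  male_ref <- pmax(0L, ifelse(is.na(dm), 0L, dm))
  female_ref <- pmax(0L, ifelse(is.na(df_), 0L, df_))
  called_m <- !is.na(im) & pass_m[pmax(1L, im)] & !is.na(im)
  called_m[is.na(im)] <- FALSE
  called_f <- !is.na(ifm)
  called_f[!is.na(ifm)] <- pass_f[ifm[!is.na(ifm)]]
  partition <- ifelse(called_m & called_f, "shared",
               ifelse(called_m, ifelse(f_sup == 0L, "male_only", "shared"),
                      "female_segregating"))
  res <- data.frame(
    kind = ifelse(gtyp == "del", "del", "ins"),
    chrom = chrom, pos = gpos,
    ref = ifelse(gtyp == "del", gseq, ""),
    alt = ifelse(gtyp == "del", "", gseq),
    male_ref = male_ref, male_alt = m_sup,
    female_ref = female_ref, female_alt = f_sup,
    alt_fwd = getcol(tm, im, "fwd") + getcol(tf, ifm, "fwd"),
    alt_rev = getcol(tm, im, "rev") + getcol(tf, ifm, "rev"),
    partition = partition,
    alt_ratio_male = ifelse(m_sup + male_ref > 0, m_sup / (m_sup + male_ref), NA),
    stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Sliding-window variant-density track
#'
#' @param calls VariantCall data.frame (sorted or not)
#' @param chrom_lengths named vector of chromosome lengths
#' @param params a [caller_params()] (window/step)
#' @return data.frame: chrom, start, end (0-based half-open), n, density
#'   (sites/kb; the trailing partial window uses its true length)
#' @export
window_density <- function(calls, chrom_lengths, params = caller_params()) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = params$step)
    ends <- pmin(starts + params$window, len)
    pos <- sort(calls$pos[calls$chrom == ch])
    n <- findInterval(ends, pos) - findInterval(starts, pos)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends, n = n,
                            density = n / (ends - starts) * 1000,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Table-2-style ratio formatting: two decimals, integer when >= 10
format_ratio <- function(x) {
  ifelse(!is.finite(x), "NA",
         ifelse(round(x, 2) >= 10, as.character(round(x)),
                sprintf("%.2f", round(x, 2))))
}

#' Male/female density ratio in Table-2 print style
#'
#' @param male,female densities (sites/kb)
#' @return list with `ratio` (numeric, male/female rounded to 2 decimals)
#'   and `printed` (character: 2 decimals, integer once the ratio reaches 10,
#'   "Inf" marker suppressed to "NA" when the female density is 0)
#' @export
ratio_of_densities <- function(male, female) {
  r <- ifelse(female > 0, male / female, Inf)
  list(ratio = ifelse(is.finite(r), round(r, 2), Inf), printed = format_ratio(r))
}

## callable (depth >= min_depth) bp of an IRanges region set on one chromosome
callable_bp <- function(pileup, chrom, regions, min_depth) {
  d <- pileup$depth[[chrom]]
  if (is.null(d)) return(0)
  sel <- unique(unlist(lapply(seq_along(regions), function(i) {
    seq(IRanges::start(regions)[i], IRanges::end(regions)[i])
  })))
  sel <- sel[sel >= 1 & sel <= length(d)]
  sum(d[sel] >= min_depth)
}

#' Per-chromosome exonic/intronic density table with male/female ratios
#'
#' Exonic = within CDS; intronic = within the gene span but outside the CDS
#' (the simulated genes carry a non-coding genic flank for this purpose).
#' Densities are calls per callable kb, where callable means depth >=
#' `min_depth` in that sex; this avoids coverage confounding between sexes.
#'
#' @param male_calls,female_calls VariantCall data.frames (calls observed in
#'   the respective sex: for males, partitions male_only and shared; for
#'   females, female_segregating and shared)
#' @param genes gene-model data.frame
#' @param male_pileup,female_pileup [build_pileup()] results
#' @param params a [caller_params()]
#' @return data.frame with per-chromosome exonic/intronic densities per sex,
#'   numeric ratios and Table-2-style printed ratios
#' @export
density_ratio_table <- function(male_calls, female_calls, genes,
                                male_pileup, female_pileup,
                                params = caller_params()) {
  chroms <- names(male_pileup$counts)
  rows <- list()
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    cds <- IRanges::reduce(IRanges::IRanges(g$cds_start, g$cds_end))
    genic <- IRanges::reduce(IRanges::IRanges(g$gene_start, g$gene_end))
    intr <- IRanges::setdiff(genic, cds)
    dens <- function(calls, pu, regions) {
      bp <- callable_bp(pu, ch, regions, params$min_depth)
      if (bp == 0) return(NA_real_)
      pos1 <- calls$pos[calls$chrom == ch] + 1L
      n <- sum(IRanges::overlapsAny(IRanges::IRanges(pos1, pos1), regions))
      n / bp * 1000
    }
    ex_m <- dens(male_calls, male_pileup, cds)
    ex_f <- dens(female_calls, female_pileup, cds)
    in_m <- dens(male_calls, male_pileup, intr)
    in_f <- dens(female_calls, female_pileup, intr)
    rex <- ratio_of_densities(ex_m, ex_f)
    rin <- ratio_of_densities(in_m, in_f)
    rows[[ch]] <- data.frame(
      chrom = ch, exonic_male = ex_m, exonic_female = ex_f,
      exonic_ratio = rex$ratio, exonic_printed = rex$printed,
      intronic_male = in_m, intronic_female = in_f,
      intronic_ratio = rin$ratio, intronic_printed = rin$printed,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Allele-ratio spectrum of male calls
#'
#' Fixed neo-X/neo-Y differences sit at a roughly 1:1 alternative-allele
#' ratio in the male read pool; segregating variation is spread over other
#' frequencies. Reports, per chromosome, the full ratio histogram and the
#' fraction and per-kb density of calls in the "around 1:1" bin.
#'
#' @param male_calls VariantCall data.frame of male-observed calls
#' @param male_pileup [build_pileup()] result (callable denominator)
#' @param params a [caller_params()] (`ratio_bin` defines the 1:1 bin)
#' @param breaks histogram breaks on the alt-ratio axis
#' @return list with `spectrum` (chrom, bin_lo, bin_hi, n, fraction; the
#'   fractions sum to 1 per chromosome) and `summary` (chrom, n_calls,
#'   frac_in_bin, density_in_bin sites/kb)
#' @export
allele_ratio_spectrum <- function(male_calls, male_pileup,
                                  params = caller_params(),
                                  breaks = seq(0, 1, by = 0.1)) {
  chroms <- names(male_pileup$counts)
  spec <- list(); summ <- list()
  for (ch in chroms) {
    r <- male_calls$alt_ratio_male[male_calls$chrom == ch]
    r <- r[!is.na(r)]
    h <- if (length(r)) {
      hist(pmin(pmax(r, 0), 1 - 1e-12), breaks = breaks, plot = FALSE)$counts
    } else rep(0L, length(breaks) - 1L)
    spec[[ch]] <- data.frame(chrom = ch, bin_lo = head(breaks, -1L),
                             bin_hi = tail(breaks, -1L), n = h,
                             fraction = if (sum(h)) h / sum(h) else 0,
                             stringsAsFactors = FALSE)
    inb <- r >= params$ratio_bin[1L] & r <= params$ratio_bin[2L]
    bp <- sum(male_pileup$depth[[ch]] >= params$min_depth)
    summ[[ch]] <- data.frame(chrom = ch, n_calls = length(r),
                             frac_in_bin = if (length(r)) mean(inb) else NA_real_,
                             density_in_bin = if (bp) sum(inb) / bp * 1000 else NA_real_,
                             stringsAsFactors = FALSE)
  }
  list(spectrum = do.call(rbind, spec), summary = do.call(rbind, summ))
}

#' @importFrom graphics hist
NULL
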