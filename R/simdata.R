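## Synthetic sexed-genome generator.
##
## Emulates a male/female re-sequencing design on a species with a very young
## neo-sex chromosome system: the female carries two near-identical neo-X
## copies, the male one neo-X and one diverged neo-Y haplotype (fixed
## differences sampled at a ~1:1 read ratio), planted neo-Y coding
## disruptions and tandem duplications, and a male-only B-chromosome scaffold
## mosaicked from subcentromeric ancestral-X / neo sequence plus B-private
## sequence. Every planted event is recorded in a truth table.

#' Plan a synthetic ancestral genome
#'
#' @param chrom_specs data.frame with columns label, muller, length, gene_count.
#'   The default models a four-chromosome karyotype (ancestral X; the fused
#'   neo element; a large autosome; the dot chromosome) totalling 2 Mb.
#' @param gc_content genomic GC fraction
#' @param mean_cds,sd_cds mean and sd of CDS length in bp (rounded to codons)
#' @param flank non-coding genic flank on each side of a CDS, bp; this is the
#'   "intronic" partition used by density reports
#' @param seed integer RNG seed; the same plan and seed give byte-identical
#'   output
#' @return object of class `genome_plan`
#' @export
genome_plan <- function(chrom_specs = NULL, gc_content = 0.42,
                        mean_cds = 900, sd_cds = 150, flank = 200, seed = 1L) {
  if (is.null(chrom_specs)) {
    chrom_specs <- data.frame(
      label = c("chr2", "chr4", "chrX", "neo"),
      muller = c("B+E", "F", "A", "C+D"),
      length = c(600000L, 200000L, 400000L, 800000L),
      gene_count = c(40L, 8L, 25L, 50L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(chrom_specs$length > 0),
            gc_content > 0, gc_content < 1,
            all(chrom_specs$gene_count * (mean_cds + 2 * flank) < chrom_specs$length))
  structure(list(chrom_specs = chrom_specs, gc_content = gc_content,
                 mean_cds = mean_cds, sd_cds = sd_cds, flank = flank,
                 seed = as.integer(seed)),
            class = "genome_plan")
}

#' Generate the ancestral (reference) genome and its gene models
#'
#' Each chromosome is random sequence at the planned GC content carrying
#' non-overlapping single-exon genes. Every gene is a valid ORF: it starts
#' with ATG, ends with exactly one stop codon and has no internal stop.
#'
#' @param plan a [genome_plan()]
#' @return list with `seqs` (named character vector), `genes` (gene-model
#'   data.frame with 1-based inclusive cds/gene coordinates, strand and an
#'   `expression` label used as the codon-bias reference weight), and `info`
#'   (the chromosome table)
#' @export
simulate_genome <- function(plan) {
  stopifnot(inherits(plan, "genome_plan"))
  set.seed(plan$seed)
  cs <- plan$chrom_specs[order(plan$chrom_specs$label), , drop = FALSE]
  seqs <- character(0)
  genes <- list()
  for (i in seq_len(nrow(cs))) {
    lab <- cs$label[i]; len <- cs$length[i]; ng <- cs$gene_count[i]
    seq <- random_dna(len, plan$gc_content)
    if (ng > 0) {
      ncod <- pmax(60L, round(rnorm(ng, plan$mean_cds / 3, plan$sd_cds / 3)))
      cds_len <- 3L * ncod
      slot <- len %/% ng
      need <- cds_len + 2L * plan$flank
      if (any(need + 2L > slot)) {
        stop("cannot pack ", ng, " genes of planned size onto ", lab)
      }
      off <- floor(runif(ng, 0, slot - need))
      cds_start <- (seq_len(ng) - 1L) * slot + plan$flank + off + 1L
      cds_end <- cds_start + cds_len - 1L
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      orfs <- vapply(ncod, function(n) {
        paste0("ATG", paste(sample(SENSE_CODONS, n - 2L, replace = TRUE),
                            collapse = ""), sample(STOP_CODONS, 1L))
      }, "")
      ins <- ifelse(strand == "+", orfs, revcomp(orfs))
      for (g in seq_len(ng)) {
        substr(seq, cds_start[g], cds_end[g]) <- ins[g]
      }
      genes[[lab]] <- data.frame(
        gene_id = sprintf("%s_g%03d", lab, seq_len(ng)),
        chrom = lab, cds_start = cds_start, cds_end = cds_end,
        gene_start = pmax(1L, cds_start - plan$flank),
        gene_end = pmin(len, cds_end + plan$flank),
        strand = strand, expression = rlnorm(ng, 0, 1),
        stringsAsFactors = FALSE)
    }
    seqs[lab] <- seq
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), chrom = character(0),
               cds_start = integer(0), cds_end = integer(0),
               gene_start = integer(0), gene_end = integer(0),
               strand = character(0), expression = numeric(0))
  rownames(genes) <- NULL
  list(seqs = seqs, genes = genes, info = cs)
}

#' Plan the male/female divergence structure
#'
#' Rates are per bp; counts are per chromosome per haplotype unless noted.
#'
#' @param snp_rate fixed neo-X/neo-Y substitution rate on the neo element
#' @param indel_rate neo-Y 1-6 bp indel rate (planted outside CDS)
#' @param indel_len_range small-indel length range, bp
#' @param pseudogene_fraction fraction of neo genes given a neo-Y-private
#'   coding disruption (premature stop or frameshift)
#' @param ancestral_fraction fraction of genes per chromosome disrupted on
#'   every haplotype of both sexes (ancestral pseudogenes)
#' @param female_het residual female heterozygosity (SNPs/bp between the two
#'   female haplotypes); free parameter of the design, default 3e-4
#' @param female_indel_rate female heterozygous small-indel rate
#' @param male_het male autosomal heterozygosity (applied to the Y-bearing
#'   haplotype copies of the autosomes)
#' @param male_poly_rate density of pooled-male segregating sites emulated at
#'   read level (sites/bp); `poly_freq_range` is the per-site minor-allele
#'   frequency range
#' @param poly_freq_range numeric length 2
#' @param tandem_dup_count baseline tandem duplications per chromosome per
#'   haplotype
#' @param neoY_tandem_dup_count tandem duplications planted on the neo-Y
#' @param tandem_dup_len_range duplication unit length range, bp
#' @param large_del_count,large_del_len_range planted large deletions
#' @param large_ins_count,large_ins_len_range planted large novel insertions
#' @param b_slice_len length of each subcentromeric slice mosaicked into the
#'   B fragment, bp
#' @param b_unique_len length of B-private sequence, bp
#' @param b_snp_count diagnostic SNPs planted on the mosaic part of the B
#' @param plant_known_gene_on_b if TRUE the B-private region carries a copy
#'   of a reference gene (used to exercise the homology filter)
#' @return object of class `divergence_plan`
#' @export
divergence_plan <- function(snp_rate = 2e-3, indel_rate = 2e-4,
                            indel_len_range = c(1L, 6L),
                            pseudogene_fraction = 0.2,
                            ancestral_fraction = 0.1,
                            female_het = 3e-4, female_indel_rate = 3e-5,
                            male_het = 1e-3,
                            male_poly_rate = 5e-4,
                            poly_freq_range = c(0.05, 0.5),
                            tandem_dup_count = 3L,
                            neoY_tandem_dup_count = 10L,
                            tandem_dup_len_range = c(500L, 2000L),
                            large_del_count = 2L,
                            large_del_len_range = c(200L, 800L),
                            large_ins_count = 1L,
                            large_ins_len_range = c(160L, 280L),
                            b_slice_len = 5000L, b_unique_len = 50000L,
                            b_snp_count = 25L,
                            plant_known_gene_on_b = FALSE) {
  dp <- list(snp_rate = snp_rate, indel_rate = indel_rate,
             indel_len_range = as.integer(indel_len_range),
             pseudogene_fraction = pseudogene_fraction,
             ancestral_fraction = ancestral_fraction,
             female_het = female_het, female_indel_rate = female_indel_rate,
             male_het = male_het, male_poly_rate = male_poly_rate,
             poly_freq_range = poly_freq_range,
             tandem_dup_count = as.integer(tandem_dup_count),
             neoY_tandem_dup_count = as.integer(neoY_tandem_dup_count),
             tandem_dup_len_range = as.integer(tandem_dup_len_range),
             large_del_count = as.integer(large_del_count),
             large_del_len_range = as.integer(large_del_len_range),
             large_ins_count = as.integer(large_ins_count),
             large_ins_len_range = as.integer(large_ins_len_range),
             b_slice_len = as.integer(b_slice_len),
             b_unique_len = as.integer(b_unique_len),
             b_snp_count = as.integer(b_snp_count),
             plant_known_gene_on_b = isTRUE(plant_known_gene_on_b))
  stopifnot(all(unlist(dp[c("snp_rate", "indel_rate", "female_het",
                            "male_het", "male_poly_rate")]) >= 0),
            dp$pseudogene_fraction >= 0, dp$pseudogene_fraction <= 1,
            dp$ancestral_fraction >= 0, dp$ancestral_fraction <= 1)
  structure(dp, class = "divergence_plan")
}

## ---- internal planting machinery ----------------------------------------

empty_snps <- function() data.frame(
  chrom = character(0), pos = integer(0), ref = character(0),
  alt = character(0), carrier = character(0), haplotype = character(0),
  freq = numeric(0), stringsAsFactors = FALSE)

empty_indels <- function() data.frame(
  chrom = character(0), pos = integer(0), type = character(0),
  len = integer(0), seq = character(0), carrier = character(0),
  haplotype = character(0), stringsAsFactors = FALSE)

empty_svs <- function() data.frame(
  chrom = character(0), start = integer(0), end = integer(0),
  type = character(0), haplotype = character(0), sex = character(0),
  stringsAsFactors = FALSE)

## alt base for a SNP that, when inside a CDS, never creates or destroys a
## stop codon or the start codon; returns NA when no safe alt exists
safe_alt <- function(seq, pos, gene_row) {
  ref <- substr(seq, pos, pos)
  alts <- setdiff(BASES, ref)
  if (is.null(gene_row)) return(sample(alts, 1L))
  cs <- gene_row$cds_start; ce <- gene_row$cds_end
  if (pos < cs + 3L && gene_row$strand == "+") return(NA_character_)
  if (pos > ce - 3L && gene_row$strand == "-") return(NA_character_)
  if (pos > ce - 3L && gene_row$strand == "+") return(NA_character_)
  if (pos < cs + 3L && gene_row$strand == "-") return(NA_character_)
  ## codon containing pos, on the coding strand
  off <- if (gene_row$strand == "+") pos - cs else ce - pos
  cod_i <- off %/% 3L
  if (gene_row$strand == "+") {
    a <- cs + 3L * cod_i
    codon <- substr(seq, a, a + 2L)
    within <- pos - a + 1L
    for (alt in sample(alts)) {
      nc <- codon
      substr(nc, within, within) <- alt
      if (!nc %in% STOP_CODONS) return(alt)
    }
  } else {
    b <- ce - 3L * cod_i
    codon <- revcomp(substr(seq, b - 2L, b))
    within <- b - pos + 1L
    for (alt in sample(alts)) {
      nc <- codon
      substr(nc, within, within) <- revcomp(alt)
      if (!nc %in% STOP_CODONS) return(alt)
    }
  }
  NA_character_
}

## gene covering a position (or NULL); genes is the per-chromosome subset
gene_at <- function(genes, pos) {
  hit <- which(genes$cds_start <= pos & genes$cds_end >= pos)
  if (length(hit)) genes[hit[1L], ] else NULL
}

## sample n distinct positions on [1, len] avoiding masked IRanges
sample_positions <- function(n, len, mask) {
  if (n <= 0L) return(integer(0))
  pos <- unique(ceiling(runif(3L * n + 20L, 0, len)))
  if (length(mask)) {
    bad <- IRanges::overlapsAny(IRanges::IRanges(pos, pos), mask)
    pos <- pos[!bad]
  }
  head(pos, n)
}

## sample k non-overlapping intervals of lengths in rng avoiding mask;
## returns IRanges (may return fewer than k if space is tight)
sample_intervals <- function(k, len, rng, mask) {
  out <- IRanges::IRanges()
  tries <- 0L
  while (length(out) < k && tries < 50L * max(1L, k)) {
    tries <- tries + 1L
    w <- sample(rng[1L]:rng[2L], 1L)
    if (w + 1L >= len) next
    s <- sample.int(len - w, 1L)
    cand <- IRanges::IRanges(s, s + w - 1L)
    if (length(mask) && any(IRanges::overlapsAny(cand, mask))) next
    if (length(out) && any(IRanges::overlapsAny(cand, out))) next
    out <- c(out, cand)
  }
  out
}

## apply SNP/indel edits and SV events (all in reference coordinates, pos
## 1-based) to one sequence; events must be non-overlapping
apply_edits <- function(seq, snps = NULL, indels = NULL, svs = NULL) {
  ev <- list()
  if (!is.null(snps) && nrow(snps)) {
    ev[[length(ev) + 1L]] <- data.frame(pos = snps$pos, kind = "snp",
      len = 1L, payload = snps$alt, end = snps$pos, stringsAsFactors = FALSE)
  }
  if (!is.null(indels) && nrow(indels)) {
    ev[[length(ev) + 1L]] <- data.frame(pos = indels$pos, kind = indels$type,
      len = indels$len, payload = indels$seq,
      end = ifelse(indels$type == "del", indels$pos + indels$len - 1L, indels$pos),
      stringsAsFactors = FALSE)
  }
  if (!is.null(svs) && nrow(svs)) {
    ev[[length(ev) + 1L]] <- data.frame(pos = svs$start, kind = svs$type,
      len = svs$end - svs$start + 1L, payload = svs$seq,
      end = svs$end, stringsAsFactors = FALSE)
  }
  if (!length(ev)) return(seq)
  ev <- do.call(rbind, ev)
  ## substitutions first, in one raw-vector pass (they do not shift coordinates)
  is_snp <- ev$kind == "snp"
  if (any(is_snp)) {
    r <- charToRaw(seq)
    r[ev$pos[is_snp]] <- as.raw(vapply(ev$payload[is_snp], utf8ToInt, 1L,
                                       USE.NAMES = FALSE))
    seq <- rawToChar(r)
    ev <- ev[!is_snp, , drop = FALSE]
    if (!nrow(ev)) return(seq)
  }
  ev <- ev[order(-ev$pos), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]
    seq <- switch(ev$kind[i],
      snp = { substr(seq, p, p) <- ev$payload[i]; seq },
      ins = paste0(substr(seq, 1L, p), ev$payload[i],
                   substring(seq, p + 1L)),
      del = paste0(substr(seq, 1L, p - 1L), substring(seq, p + ev$len[i])),
      large_del = paste0(substr(seq, 1L, p - 1L), substring(seq, ev$end[i] + 1L)),
      large_ins = paste0(substr(seq, 1L, p - 1L), ev$payload[i], substring(seq, p)),
      tandem_dup = paste0(substr(seq, 1L, ev$end[i]),
                          substr(seq, p, ev$end[i]), substring(seq, ev$end[i] + 1L)),
      stop("unknown edit kind ", ev$kind[i]))
  }
  seq
}

## plant one coding disruption in a gene; returns list(snps=, indels=, kind=)
plant_disruption <- function(seq, gene_row) {
  ncod <- (gene_row$cds_end - gene_row$cds_start + 1L) %/% 3L
  kind <- sample(c("premature_stop", "frameshift"), 1L)
  if (kind == "premature_stop") {
    ## find a codon in the middle of the CDS one substitution away from TAA/TAG/TGA
    lo <- max(2L, floor(0.2 * ncod)); hi <- min(ncod - 2L, ceiling(0.8 * ncod))
    for (ci in sample(lo:hi)) {
      if (gene_row$strand == "+") {
        a <- gene_row$cds_start + 3L * (ci - 1L)
        codon <- substr(seq, a, a + 2L)
        for (w in sample(1:3)) for (b in sample(BASES)) {
          nc <- codon; substr(nc, w, w) <- b
          if (nc %in% STOP_CODONS && b != substr(codon, w, w)) {
            return(list(kind = kind, snps = data.frame(
              chrom = gene_row$chrom, pos = a + w - 1L,
              ref = substr(codon, w, w), alt = b, stringsAsFactors = FALSE),
              indels = NULL))
          }
        }
      } else {
        bnd <- gene_row$cds_end - 3L * (ci - 1L)
        codon <- revcomp(substr(seq, bnd - 2L, bnd))
        for (w in sample(1:3)) for (b in sample(BASES)) {
          nc <- codon; substr(nc, w, w) <- b
          if (nc %in% STOP_CODONS && b != substr(codon, w, w)) {
            pos <- bnd - w + 1L
            return(list(kind = kind, snps = data.frame(
              chrom = gene_row$chrom, pos = pos,
              ref = substr(seq, pos, pos), alt = revcomp(b),
              stringsAsFactors = FALSE), indels = NULL))
          }
        }
      }
    }
    kind <- "frameshift" # fall through if no single-base stop was reachable
  }
  ## frameshift: one indel with length not divisible by 3 inside the CDS
  len <- sample(c(1L, 2L, 4L, 5L), 1L)
  lo <- gene_row$cds_start + 6L; hi <- gene_row$cds_end - 6L - len
  p <- sample(lo:hi, 1L)
  type <- if (runif(1) < 0.5) "del" else "ins"
  payload <- if (type == "del") substr(seq, p, p + len - 1L) else random_dna(len)
  la <- left_align_indel(seq, p, type, len, payload)
  ind <- data.frame(chrom = gene_row$chrom, pos = la$pos, type = type,
                    len = len, seq = la$seq, stringsAsFactors = FALSE)
  list(kind = "frameshift", snps = NULL, indels = ind)
}

## plant substitution load on one chromosome copy (rate per bp), avoiding
## stop creation inside CDS; returns SNP data.frame
plant_snps <- function(seq, chrom, rate, genes, mask) {
  len <- nchar(seq)
  n <- rbinom(1L, len, rate)
  pos <- sample_positions(n, len, mask)
  if (!length(pos)) return(empty_snps()[, c("chrom", "pos", "ref", "alt")])
  gsub_ <- genes[genes$chrom == chrom, , drop = FALSE]
  alt <- character(length(pos))
  for (i in seq_along(pos)) {
    alt[i] <- safe_alt(seq, pos[i], gene_at(gsub_, pos[i]))
  }
  keep <- !is.na(alt)
  data.frame(chrom = chrom, pos = pos[keep],
             ref = substring(seq, pos[keep], pos[keep]), alt = alt[keep],
             stringsAsFactors = FALSE)
}

## left-align one planted indel against the reference; returns list(pos, seq).
## del: deletes ref[pos .. pos+len-1]; ins: inserts seq after ref position pos.
left_align_indel <- function(ref, pos, type, len, payload) {
  if (type == "del") {
    while (pos > 1L && substr(ref, pos - 1L, pos - 1L) ==
           substr(ref, pos + len - 1L, pos + len - 1L)) {
      pos <- pos - 1L
    }
    list(pos = pos, seq = substr(ref, pos, pos + len - 1L))
  } else {
    while (pos >= 1L && substr(ref, pos, pos) == substr(payload, len, len)) {
      payload <- paste0(substr(payload, len, len), substr(payload, 1L, len - 1L))
      pos <- pos - 1L
    }
    list(pos = pos, seq = payload)
  }
}

## plant small indels outside CDS; returns indel data.frame (left-aligned)
plant_small_indels <- function(seq, chrom, rate, len_range, genes, mask) {
  len <- nchar(seq)
  n <- rbinom(1L, len, rate)
  gsub_ <- genes[genes$chrom == chrom, , drop = FALSE]
  cds_mask <- IRanges::IRanges(gsub_$cds_start, gsub_$cds_end)
  pos <- sample_positions(n, len - 10L, c(mask, cds_mask))
  pos <- pos[pos > 10L]
  if (!length(pos)) {
    return(data.frame(chrom = character(0), pos = integer(0), type = character(0),
                      len = integer(0), seq = character(0), stringsAsFactors = FALSE))
  }
  il <- sample(len_range[1L]:len_range[2L], length(pos), replace = TRUE)
  type <- sample(c("ins", "del"), length(pos), replace = TRUE)
  sq <- ifelse(type == "del", substring(seq, pos, pos + il - 1L),
               vapply(il, random_dna, ""))
  for (i in seq_along(pos)) {
    la <- left_align_indel(seq, pos[i], type[i], il[i], sq[i])
    pos[i] <- la$pos; sq[i] <- la$seq
  }
  data.frame(chrom = chrom, pos = pos, type = type, len = il, seq = sq,
             stringsAsFactors = FALSE)
}

## plant SV set on one chromosome copy; returns sv data.frame (with seq for
## large_ins)
plant_svs <- function(seq, chrom, n_dup, dup_rng, n_del, del_rng, n_ins, ins_rng,
                      mask) {
  len <- nchar(seq)
  out <- list()
  dups <- sample_intervals(n_dup, len, dup_rng, mask)
  mask <- c(mask, dups)
  if (length(dups)) {
    out$dup <- data.frame(chrom = chrom, start = IRanges::start(dups),
                          end = IRanges::end(dups), type = "tandem_dup",
                          seq = NA_character_, stringsAsFactors = FALSE)
  }
  dels <- sample_intervals(n_del, len, del_rng, mask)
  mask <- c(mask, dels)
  if (length(dels)) {
    out$del <- data.frame(chrom = chrom, start = IRanges::start(dels),
                          end = IRanges::end(dels), type = "large_del",
                          seq = NA_character_, stringsAsFactors = FALSE)
  }
  inss <- sample_intervals(n_ins, len, ins_rng, mask)
  if (length(inss)) {
    out$ins <- data.frame(chrom = chrom, start = IRanges::start(inss),
                          end = IRanges::start(inss), type = "large_ins",
                          seq = vapply(IRanges::width(inss), random_dna, ""),
                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      type = character(0), seq = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## mask of CDS intervals (plus margin) for one chromosome
cds_mask_of <- function(genes, chrom, margin = 10L) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(IRanges::IRanges())
  IRanges::IRanges(pmax(1L, g$cds_start - margin), g$cds_end + margin)
}

#' Derive sexed haplotypes, a B fragment and the truth table
#'
#' The female sample is two near-identical copies of the reference (residual
#' heterozygosity only). The male X-bearing haplotype equals the reference;
#' the male Y-bearing haplotype carries the planted neo-Y divergence, coding
#' disruptions, tandem duplications and large indel SVs, plus autosomal
#' heterozygosity. Ancestral disruptions are planted on every haplotype of
#' both sexes (but not the reference), so they surface as female-called
#' variants. A male-only B scaffold mosaics one subcentromeric slice of the
#' ancestral X and one slice of the neo element with B-private sequence.
#'
#' @param genome output of [simulate_genome()]
#' @param dp a [divergence_plan()]
#' @param seed integer RNG seed
#' @return list with `female` / `male` (each a list of two named
#'   haplotype-sequence vectors, `hapA` and `hapB`), `b_fragment` (single
#'   named sequence or NULL), `truth` (lists `snps`, `indels`, `disruptions`,
#'   `svs`, `poly`; positions 0-based in reference coordinates), and `poly`
#'   (read-level male polymorphism table used by [simulate_reads()])
#' @export
derive_haplotypes <- function(genome, dp, seed = 1L) {
  stopifnot(inherits(dp, "divergence_plan"))
  set.seed(as.integer(seed))
  seqs <- genome$seqs
  genes <- genome$genes
  chroms <- names(seqs)
  neo_genes <- genes[genes$chrom == "neo", , drop = FALSE]
  if (dp$pseudogene_fraction > 0 && "neo" %in% chroms && nrow(neo_genes) == 0L) {
    stop("pseudogene_fraction > 0 but the neo element carries no genes")
  }

  truth_snps <- list(); truth_indels <- list(); truth_disr <- list(); truth_svs <- list()

  ## --- ancestral disruptions (all haplotypes, both sexes) ---
  anc_sn <- list(); anc_in <- list()
  anc_gene_ids <- character(0)
  for (ch in chroms) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    n_anc <- round(dp$ancestral_fraction * nrow(g))
    if (n_anc < 1L) next
    pick <- g[sample.int(nrow(g), n_anc), , drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      d <- plant_disruption(seqs[[ch]], pick[k, ])
      anc_gene_ids <- c(anc_gene_ids, pick$gene_id[k])
      truth_disr[[length(truth_disr) + 1L]] <- data.frame(
        gene_id = pick$gene_id[k], chrom = ch, kind = d$kind,
        scope = "ancestral", stringsAsFactors = FALSE)
      if (!is.null(d$snps)) anc_sn[[length(anc_sn) + 1L]] <- d$snps
      if (!is.null(d$indels)) anc_in[[length(anc_in) + 1L]] <- d$indels
    }
  }
  anc_sn <- if (length(anc_sn)) do.call(rbind, anc_sn) else NULL
  anc_in <- if (length(anc_in)) do.call(rbind, anc_in) else NULL
  if (!is.null(anc_sn)) {
    truth_snps$anc <- cbind(anc_sn, carrier = "ancestral", haplotype = "all",
                            freq = 1)
  }
  if (!is.null(anc_in)) {
    truth_indels$anc <- cbind(anc_in, carrier = "ancestral", haplotype = "all")
  }
  anc_mask <- function(ch) {
    m <- IRanges::IRanges()
    if (!is.null(anc_sn)) {
      s <- anc_sn[anc_sn$chrom == ch, , drop = FALSE]
      if (nrow(s)) m <- c(m, IRanges::IRanges(s$pos, s$pos))
    }
    if (!is.null(anc_in)) {
      s <- anc_in[anc_in$chrom == ch, , drop = FALSE]
      if (nrow(s)) m <- c(m, IRanges::IRanges(s$pos, s$pos + s$len))
    }
    m
  }

  ## helper: build one haplotype copy = reference + ancestral edits + extras
  build_hap <- function(hap_chroms, extra, hapname, sex) {
    out <- character(0)
    for (ch in hap_chroms) {
      sn <- rbind(if (!is.null(anc_sn)) anc_sn[anc_sn$chrom == ch, , drop = FALSE],
                  extra$snps[extra$snps$chrom == ch, , drop = FALSE])
      ind <- rbind(if (!is.null(anc_in)) anc_in[anc_in$chrom == ch, , drop = FALSE],
                   extra$indels[extra$indels$chrom == ch, , drop = FALSE])
      sv <- extra$svs[extra$svs$chrom == ch, , drop = FALSE]
      out[ch] <- apply_edits(seqs[[ch]], sn, ind, sv)
    }
    out
  }

  no_extra <- list(snps = empty_snps()[, c("chrom", "pos", "ref", "alt")],
                   indels = data.frame(chrom = character(0), pos = integer(0),
                                       type = character(0), len = integer(0),
                                       seq = character(0), stringsAsFactors = FALSE),
                   svs = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), type = character(0),
                                    seq = character(0), stringsAsFactors = FALSE))

  ## --- per-haplotype extra edits ---
  baseline_extras <- function(hap_chroms, snp_rate, indel_rate, hapname, sex,
                              neoY = FALSE) {
    ex <- no_extra
    for (ch in hap_chroms) {
      mask <- c(anc_mask(ch), if (neoY && ch == "neo") neoY_cds_mask else IRanges::IRanges())
      is_neoY_chrom <- neoY && ch == "neo"
      ## SVs first so small edits avoid deleted intervals
      n_dup <- if (is_neoY_chrom) dp$neoY_tandem_dup_count else dp$tandem_dup_count
      sv <- plant_svs(seqs[[ch]], ch, n_dup, dp$tandem_dup_len_range,
                      dp$large_del_count, dp$large_del_len_range,
                      dp$large_ins_count, dp$large_ins_len_range,
                      c(mask, cds_mask_of(genes, ch, 0L)[0L])) # dups may hit CDS
      ## large dels/ins must not hit CDS or planted edits: re-filter
      if (nrow(sv)) {
        cdsm <- cds_mask_of(genes, ch)
        keep <- rep(TRUE, nrow(sv))
        notdup <- sv$type != "tandem_dup"
        if (any(notdup) && length(cdsm)) {
          ivs <- IRanges::IRanges(sv$start[notdup], sv$end[notdup])
          keep[notdup] <- !IRanges::overlapsAny(ivs, cdsm)
        }
        sv <- sv[keep, , drop = FALSE]
      }
      sv_mask <- if (nrow(sv)) IRanges::IRanges(sv$start, sv$end) else IRanges::IRanges()
      rate_here <- if (is_neoY_chrom) dp$snp_rate else snp_rate
      sn <- plant_snps(seqs[[ch]], ch, rate_here, genes, c(mask, sv_mask))
      irate_here <- if (is_neoY_chrom) dp$indel_rate else indel_rate
      ind <- plant_small_indels(seqs[[ch]], ch, irate_here, dp$indel_len_range,
                                genes, c(mask, sv_mask,
                                         if (nrow(sn)) IRanges::IRanges(sn$pos, sn$pos)
                                         else IRanges::IRanges()))
      ex$snps <- rbind(ex$snps, sn)
      ex$indels <- rbind(ex$indels, ind)
      ex$svs <- rbind(ex$svs, sv[, c("chrom", "start", "end", "type", "seq")])
    }
    ex
  }

  ## neo-Y disruptions: mask CDS positions already targeted
  neoY_disr <- NULL
  neoY_cds_mask <- IRanges::IRanges()
  if (nrow(neo_genes)) {
    n_ps <- round(dp$pseudogene_fraction * nrow(neo_genes))
    eligible <- neo_genes[!neo_genes$gene_id %in% anc_gene_ids, , drop = FALSE]
    n_ps <- min(n_ps, nrow(eligible))
    if (n_ps > 0L) {
      pick <- eligible[sample.int(nrow(eligible), n_ps), , drop = FALSE]
      dsn <- list(); din <- list()
      for (k in seq_len(nrow(pick))) {
        d <- plant_disruption(seqs[["neo"]], pick[k, ])
        truth_disr[[length(truth_disr) + 1L]] <- data.frame(
          gene_id = pick$gene_id[k], chrom = "neo", kind = d$kind,
          scope = "neoY", stringsAsFactors = FALSE)
        if (!is.null(d$snps)) dsn[[length(dsn) + 1L]] <- d$snps
        if (!is.null(d$indels)) din[[length(din) + 1L]] <- d$indels
      }
      neoY_disr <- list(snps = if (length(dsn)) do.call(rbind, dsn) else NULL,
                        indels = if (length(din)) do.call(rbind, din) else NULL)
      m <- IRanges::IRanges()
      if (!is.null(neoY_disr$snps)) {
        m <- c(m, IRanges::IRanges(neoY_disr$snps$pos, neoY_disr$snps$pos))
      }
      if (!is.null(neoY_disr$indels)) {
        m <- c(m, IRanges::IRanges(neoY_disr$indels$pos,
                                   neoY_disr$indels$pos + neoY_disr$indels$len))
      }
      neoY_cds_mask <- m
    }
  }

  ## female hapA = reference (+ancestral); hapB adds residual heterozygosity
  fB_extra <- baseline_extras(chroms, dp$female_het, dp$female_indel_rate,
                              "female_hapB", "female")
  ## female also carries baseline SVs on hapA
  fA_sv <- no_extra
  for (ch in chroms) {
    sv <- plant_svs(seqs[[ch]], ch, dp$tandem_dup_count, dp$tandem_dup_len_range,
                    dp$large_del_count, dp$large_del_len_range,
                    dp$large_ins_count, dp$large_ins_len_range, anc_mask(ch))
    cdsm <- cds_mask_of(genes, ch)
    if (nrow(sv) && length(cdsm)) {
      notdup <- sv$type != "tandem_dup"
      keep <- rep(TRUE, nrow(sv))
      if (any(notdup)) {
        keep[notdup] <- !IRanges::overlapsAny(
          IRanges::IRanges(sv$start[notdup], sv$end[notdup]), cdsm)
      }
      sv <- sv[keep, , drop = FALSE]
    }
    fA_sv$svs <- rbind(fA_sv$svs, sv[, c("chrom", "start", "end", "type", "seq")])
  }
  fA <- build_hap(chroms, fA_sv, "female_hapA", "female")
  fB <- build_hap(chroms, fB_extra, "female_hapB", "female")

  ## male hapA (X-bearing) = reference + ancestral + baseline SVs
  mA_sv <- no_extra
  for (ch in chroms) {
    sv <- plant_svs(seqs[[ch]], ch, dp$tandem_dup_count, dp$tandem_dup_len_range,
                    dp$large_del_count, dp$large_del_len_range,
                    dp$large_ins_count, dp$large_ins_len_range, anc_mask(ch))
    cdsm <- cds_mask_of(genes, ch)
    if (nrow(sv) && length(cdsm)) {
      notdup <- sv$type != "tandem_dup"
      keep <- rep(TRUE, nrow(sv))
      if (any(notdup)) {
        keep[notdup] <- !IRanges::overlapsAny(
          IRanges::IRanges(sv$start[notdup], sv$end[notdup]), cdsm)
      }
      sv <- sv[keep, , drop = FALSE]
    }
    mA_sv$svs <- rbind(mA_sv$svs, sv[, c("chrom", "start", "end", "type", "seq")])
  }
  mA <- build_hap(chroms, mA_sv, "male_hapA", "male")

  ## male hapB (Y-bearing): neo carries the neo-Y; autosomes carry male_het
  mB_chroms <- setdiff(chroms, "chrX")
  mB_extra <- baseline_extras(mB_chroms, dp$male_het, dp$female_indel_rate,
                              "male_hapB", "male", neoY = TRUE)
  mB_base_snps <- mB_extra$snps
  mB_base_indels <- mB_extra$indels
  if (!is.null(neoY_disr)) {
    if (!is.null(neoY_disr$snps)) {
      mB_extra$snps <- rbind(mB_extra$snps, neoY_disr$snps)
    }
    if (!is.null(neoY_disr$indels)) {
      mB_extra$indels <- rbind(mB_extra$indels, neoY_disr$indels)
    }
  }
  mB <- build_hap(mB_chroms, mB_extra, "male_hapB", "male")

  ## record truth
  rec_sn <- function(df, carrier, hapname) {
    if (is.null(df) || !nrow(df)) return(NULL)
    cbind(df, carrier = carrier, haplotype = hapname, freq = NA_real_)
  }
  truth_snps$fB <- rec_sn(fB_extra$snps, "neoX_polymorphism", "female_hapB")
  mB_neo <- mB_base_snps$chrom == "neo"
  truth_snps$mB_neo <- rec_sn(mB_base_snps[mB_neo, , drop = FALSE], "neoY", "male_hapB")
  truth_snps$mB_auto <- rec_sn(mB_base_snps[!mB_neo, , drop = FALSE],
                               "neoX_polymorphism", "male_hapB")
  if (!is.null(neoY_disr) && !is.null(neoY_disr$snps)) {
    truth_snps$disr <- rec_sn(neoY_disr$snps, "neoY", "male_hapB")
  }
  rec_in <- function(df, carrier, hapname) {
    if (is.null(df) || !nrow(df)) return(NULL)
    cbind(df, carrier = carrier, haplotype = hapname)
  }
  truth_indels$fB <- rec_in(fB_extra$indels, "neoX_polymorphism", "female_hapB")
  mBi_neo <- mB_base_indels$chrom == "neo"
  truth_indels$mB_neo <- rec_in(mB_base_indels[mBi_neo, , drop = FALSE], "neoY", "male_hapB")
  truth_indels$mB_auto <- rec_in(mB_base_indels[!mBi_neo, , drop = FALSE],
                                 "neoX_polymorphism", "male_hapB")
  if (!is.null(neoY_disr) && !is.null(neoY_disr$indels)) {
    truth_indels$disr <- rec_in(neoY_disr$indels, "neoY_disruption", "male_hapB")
  }
  rec_sv <- function(ex, hapname, sex) {
    if (!nrow(ex$svs)) return(NULL)
    cbind(ex$svs[, c("chrom", "start", "end", "type")], haplotype = hapname, sex = sex)
  }
  truth_svs$fA <- rec_sv(fA_sv, "female_hapA", "female")
  truth_svs$fB <- rec_sv(fB_extra, "female_hapB", "female")
  truth_svs$mA <- rec_sv(mA_sv, "male_hapA", "male")
  truth_svs$mB <- rec_sv(mB_extra, "male_hapB", "male")

  ## translate a reference position to male hapA coordinates (hapA carries
  ## ancestral indels and its own SVs, which shift everything downstream);
  ## returns NA for positions falling inside deleted intervals
  translate_mA <- function(ch, pos) {
    shift <- rep(0L, length(pos))
    drop <- rep(FALSE, length(pos))
    if (!is.null(anc_in)) {
      ai <- anc_in[anc_in$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(ai))) {
        if (ai$type[j] == "ins") {
          shift <- shift + ifelse(pos > ai$pos[j], ai$len[j], 0L)
        } else {
          inside <- pos >= ai$pos[j] & pos <= ai$pos[j] + ai$len[j] - 1L
          drop <- drop | inside
          shift <- shift - ifelse(pos > ai$pos[j] + ai$len[j] - 1L, ai$len[j], 0L)
        }
      }
    }
    sv <- mA_sv$svs[mA_sv$svs$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(sv))) {
      w <- sv$end[j] - sv$start[j] + 1L
      if (sv$type[j] == "tandem_dup") {
        shift <- shift + ifelse(pos > sv$end[j], w, 0L)
      } else if (sv$type[j] == "large_del") {
        inside <- pos >= sv$start[j] & pos <= sv$end[j]
        drop <- drop | inside
        shift <- shift - ifelse(pos > sv$end[j], w, 0L)
      } else if (sv$type[j] == "large_ins") {
        shift <- shift + ifelse(pos >= sv$start[j], nchar(sv$seq[j]), 0L)
      }
    }
    ifelse(drop, NA_integer_, pos + shift)
  }

  ## --- read-level male pooled polymorphism sites ---
  poly <- NULL
  if (dp$male_poly_rate > 0) {
    rows <- list()
    for (ch in chroms) {
      len <- nchar(seqs[[ch]])
      n <- rbinom(1L, len, dp$male_poly_rate)
      pos <- sample_positions(n, len, anc_mask(ch))
      if (!length(pos)) next
      gsub_ <- genes[genes$chrom == ch, , drop = FALSE]
      alt <- vapply(pos, function(p) {
        a <- safe_alt(seqs[[ch]], p, gene_at(gsub_, p))
        if (is.na(a)) "" else a
      }, "")
      keep <- nzchar(alt)
      if (!any(keep)) next
      hp <- translate_mA(ch, pos[keep])
      keep2 <- !is.na(hp)
      rows[[ch]] <- data.frame(
        chrom = ch, pos = pos[keep][keep2],
        hap_pos = hp[keep2],
        ref = substring(seqs[[ch]], pos[keep][keep2], pos[keep][keep2]),
        alt = alt[keep][keep2],
        freq = runif(sum(keep), dp$poly_freq_range[1L],
                     dp$poly_freq_range[2L])[keep2],
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      poly <- do.call(rbind, rows)
      rownames(poly) <- NULL
      truth_snps$poly <- cbind(poly[, c("chrom", "pos", "ref", "alt")],
                               carrier = "neoX_polymorphism",
                               haplotype = "male_pool", freq = poly$freq)
    }
  }

  ## --- B fragment ---
  b <- NULL
  if (dp$b_slice_len > 0 || dp$b_unique_len > 0) {
    sl <- dp$b_slice_len
    xs <- if (sl > 0 && "chrX" %in% chroms)
      substr(seqs[["chrX"]], 1001L, 1000L + sl) else ""
    nlen <- if ("neo" %in% chroms) nchar(seqs[["neo"]]) else 0L
    ns <- if (sl > 0 && nlen > sl + 1000L)
      substr(seqs[["neo"]], nlen - sl - 999L, nlen - 1000L) else ""
    uniq <- if (dp$b_unique_len > 0) random_dna(dp$b_unique_len, 0.40) else ""
    if (dp$plant_known_gene_on_b && nrow(genes) && nchar(uniq) > 3000L) {
      g1 <- genes[1L, ]
      cds <- substr(seqs[[g1$chrom]], g1$cds_start, g1$cds_end)
      substr(uniq, 1001L, 1000L + nchar(cds)) <- cds
    }
    bs <- paste0(xs, ns, uniq)
    if (nchar(bs) > 0) {
      mosaic_len <- nchar(xs) + nchar(ns)
      if (dp$b_snp_count > 0 && mosaic_len > dp$b_snp_count) {
        bp <- sort(sample.int(mosaic_len, dp$b_snp_count))
        for (p in bp) {
          refb <- substr(bs, p, p)
          altb <- sample(setdiff(BASES, refb), 1L)
          substr(bs, p, p) <- altb
          truth_snps$b <- rbind(truth_snps$b, data.frame(
            chrom = "B_scaffold", pos = p, ref = refb, alt = altb,
            carrier = "B", haplotype = "male_hapB", freq = NA_real_,
            stringsAsFactors = FALSE))
        }
      }
      b <- setNames(bs, "B_scaffold")
      mB <- c(mB, b)
    }
  }

  bind0 <- function(lst, empty) {
    lst <- Filter(Negate(is.null), lst)
    out <- if (length(lst)) do.call(rbind, lst) else empty
    rownames(out) <- NULL
    out
  }
  truth <- list(
    snps = local({
      x <- bind0(truth_snps, empty_snps())
      if (nrow(x)) x$pos <- x$pos - 1L # 0-based in the truth table
      x
    }),
    indels = local({
      x <- bind0(truth_indels, empty_indels())
      ## 0-based: deletions at the first deleted base; insertions keep the
      ## 0-based index of the reference base that follows the inserted run
      if (nrow(x)) x$pos <- ifelse(x$type == "del", x$pos - 1L, x$pos)
      x
    }),
    disruptions = bind0(truth_disr, data.frame(
      gene_id = character(0), chrom = character(0), kind = character(0),
      scope = character(0), stringsAsFactors = FALSE)),
    svs = local({
      x <- bind0(truth_svs, empty_svs())
      if (nrow(x)) { x$start <- x$start - 1L } # 0-based half-open
      x
    }),
    poly = poly
  )
  list(female = list(hapA = fA, hapB = fB),
       male = list(hapA = mA, hapB = mB),
       b_fragment = b, truth = truth, poly = poly,
       ancestral_gene_ids = anc_gene_ids)
}

#' Sequencing-library insert specification
#' @param mean,sd insert (outer) size mean and standard deviation, bp
#' @param read_len read length, bp
#' @return object of class `insert_spec`
#' @export
insert_spec <- function(mean = 500, sd = 50, read_len = 100L) {
  stopifnot(mean > 2 * read_len, sd > 0)
  structure(list(mean = mean, sd = sd, read_len = as.integer(read_len)),
            class = "insert_spec")
}

#' Simulate inward-facing paired-end reads from a haplotype set
#'
#' Fragments are drawn uniformly along each haplotype sequence; insert length
#' is Normal(mean, sd) truncated at twice the read length; mates face inward
#' (forward-reverse). Read names encode the origin haplotype, chromosome,
#' 1-based fragment start and insert length for truth-based evaluation.
#'
#' @param hapset named list of haplotype sequence vectors (e.g. the `male`
#'   element of [derive_haplotypes()] output)
#' @param ins an [insert_spec()]
#' @param coverage per-haplotype-copy fold coverage
#' @param err_rate per-base substitution error rate
#' @param seed integer RNG seed
#' @param poly optional read-level polymorphism table (chrom, pos 1-based,
#'   alt, freq) injected into reads of haplotype `poly_hap`
#' @param poly_hap haplotype name receiving polymorphism injection ("hapA")
#' @param chrom_copies named integer vector: copies of each chromosome across
#'   the whole haplotype set, used to convert per-site pool frequency into an
#'   injection probability (default: computed from `hapset`)
#' @param prefix read-name prefix
#' @return list with `reads1`, `reads2` (named character vectors; mate 2
#'   reverse-complemented as sequenced) and `meta` (per-pair origin table)
#' @export
simulate_reads <- function(hapset, ins, coverage, err_rate = 0.002, seed = 1L,
                           poly = NULL, poly_hap = "hapA", chrom_copies = NULL,
                           prefix = "sim") {
  stopifnot(inherits(ins, "insert_spec"), coverage > 0)
  set.seed(as.integer(seed))
  L <- ins$read_len
  if (is.null(chrom_copies)) {
    allc <- unlist(lapply(hapset, names))
    chrom_copies <- table(allc)
  }
  r1 <- list(); r2 <- list(); meta <- list()
  for (hap in names(hapset)) {
    for (ch in names(hapset[[hap]])) {
      seq <- hapset[[hap]][[ch]]
      len <- nchar(seq)
      if (L > len) stop("read length ", L, " exceeds length of ", ch)
      n <- round(coverage * len / (2 * L))
      if (n < 1L) next
      il <- pmin(len, pmax(2L * L, round(rnorm(n, ins$mean, ins$sd))))
      st <- floor(runif(n, 1, len - il + 1 + 1e-9))
      a <- substring(seq, st, st + L - 1L)
      b_start <- st + il - L
      b <- substring(seq, b_start, b_start + L - 1L)
      ## read-level polymorphism injection (forward-strand copies)
      if (!is.null(poly) && hap == poly_hap) {
        ps <- poly[poly$chrom == ch, , drop = FALSE]
        if (nrow(ps)) {
          copies <- as.integer(chrom_copies[ch])
          ordA <- order(st)
          stA <- st[ordA]
          ordB <- order(b_start)
          stB <- b_start[ordB]
          for (j in seq_len(nrow(ps))) {
            ## positions must be in the coordinate system of this haplotype
            p <- if (!is.null(ps$hap_pos)) ps$hap_pos[j] else ps$pos[j]
            pr <- min(1, ps$freq[j] * copies)
            lo <- findInterval(p - L, stA) + 1L
            hi <- findInterval(p, stA)
            if (hi >= lo) {
              idx <- ordA[lo:hi]
              hitL <- idx[runif(length(idx)) < pr]
              for (ii in hitL) substr(a[ii], p - st[ii] + 1L, p - st[ii] + 1L) <- ps$alt[j]
            }
            lo <- findInterval(p - L, stB) + 1L
            hi <- findInterval(p, stB)
            if (hi >= lo) {
              idx <- ordB[lo:hi]
              hitR <- idx[runif(length(idx)) < pr]
              for (ii in hitR) substr(b[ii], p - b_start[ii] + 1L, p - b_start[ii] + 1L) <- ps$alt[j]
            }
          }
        }
      }
      nm <- sprintf("%s|%s|%s|%d|%d|%d", prefix, hap, ch, st, il, seq_len(n))
      r1[[paste(hap, ch)]] <- setNames(a, nm)
      r2[[paste(hap, ch)]] <- setNames(b, nm)
      meta[[paste(hap, ch)]] <- data.frame(name = nm, hap = hap, chrom = ch,
                                           start = st, insert = il,
                                           stringsAsFactors = FALSE)
    }
  }
  reads1 <- unlist(unname(r1)); reads2 <- unlist(unname(r2))
  if (is.null(reads1)) {
    return(list(reads1 = character(0), reads2 = character(0),
                meta = data.frame()))
  }
  ## sequencing errors
  if (err_rate > 0) {
    inject <- function(rd) {
      ne <- rbinom(length(rd), L, err_rate)
      tot <- sum(ne)
      if (tot == 0L) return(rd)
      idx <- rep(seq_along(rd), ne)
      pos <- ceiling(runif(tot) * L)
      off <- sample.int(3L, tot, replace = TRUE)
      out <- cpp_apply_errors(rd, idx, pos, off)
      setNames(out, names(rd))
    }
    reads1 <- inject(reads1)
    reads2 <- inject(reads2)
  }
  ## mate 2 is sequenced from the opposite strand
  reads2 <- setNames(revcomp(reads2), names(reads2))
  list(reads1 = reads1, reads2 = reads2,
       meta = do.call(rbind, c(meta, list(make.row.names = FALSE))))
}
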