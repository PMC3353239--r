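## Neo-X / neo-Y allele reconstruction and coding-degeneration statistics.
##
## The neo-X allele of a gene is the reference CDS with female-derived
## alleles applied; the neo-Y allele additionally applies male-only alleles
## (candidate fixed neo-X/neo-Y differences, i.e. male-only calls at a
## heterozygous-like allele ratio). Disruption scanning flags premature
## stops, frameshifts and start-codon loss; genes disrupted already in the
## female-derived allele are ancestral pseudogenes and are excluded.

#' Reconstruct neo-X and neo-Y alleles for each gene
#'
#' Variants are applied position-descending so coordinates stay valid.
#' Minus-strand genes are reverse-complemented after application, so the
#' returned alleles are coding-strand sequences.
#'
#' @param genes gene-model data.frame
#' @param genome named character vector of reference sequences
#' @param female_calls VariantCall data.frame of female-observed calls
#'   (applied to obtain the neo-X allele)
#' @param male_only_calls VariantCall data.frame of male-only calls (applied
#'   on top to obtain the neo-Y allele); the caller is expected to pre-filter
#'   these to heterozygous-like ratios, see [select_male_only()]
#' @return AllelePair data.frame: gene_id, chrom, neoX_cds, neoY_cds,
#'   n_female_var, n_male_var, net_indel_female, net_indel_male, ok (FALSE
#'   when overlapping indels made the gene unresolvable)
#' @export
reconstruct_alleles <- function(genes, genome, female_calls, male_only_calls) {
  apply_calls <- function(cds, cds_start, cds_end, calls) {
    ## calls restricted to this CDS, position-descending; coordinates are
    ## 0-based on the chromosome, cds_start/cds_end 1-based inclusive
    if (!nrow(calls)) return(list(seq = cds, n = 0L, net = 0L, ok = TRUE))
    pos1 <- calls$pos + 1L
    ## an indel must fit wholly inside the CDS
    fits <- ifelse(calls$kind == "del",
                   pos1 >= cds_start & pos1 + nchar(calls$ref) - 1L <= cds_end,
                   pos1 >= cds_start & pos1 <= cds_end)
    calls <- calls[fits, , drop = FALSE]
    if (!nrow(calls)) return(list(seq = cds, n = 0L, net = 0L, ok = TRUE))
    ## overlapping edits are unresolvable
    lo <- calls$pos + 1L
    hi <- ifelse(calls$kind == "del", lo + nchar(calls$ref) - 1L, lo)
    if (any(IRanges::countOverlaps(IRanges::IRanges(lo, hi)) > 1L)) {
      return(list(seq = cds, n = nrow(calls), net = 0L, ok = FALSE))
    }
    ord <- order(-calls$pos)
    net <- 0L
    for (i in ord) {
      off <- calls$pos[i] + 1L - cds_start + 1L # 1-based offset in cds string
      if (calls$kind[i] == "snp") {
        substr(cds, off, off) <- calls$alt[i]
      } else if (calls$kind[i] == "del") {
        w <- nchar(calls$ref[i])
        cds <- paste0(substr(cds, 1L, off - 1L), substring(cds, off + w))
        net <- net - w
      } else {
        ## insertion before reference offset `off`
        cds <- paste0(substr(cds, 1L, off - 1L), calls$alt[i], substring(cds, off))
        net <- net + nchar(calls$alt[i])
      }
    }
    list(seq = cds, n = nrow(calls), net = net, ok = TRUE)
  }
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ref_cds <- substr(genome[[g$chrom]], g$cds_start, g$cds_end)
    fc <- female_calls[female_calls$chrom == g$chrom, , drop = FALSE]
    mc <- male_only_calls[male_only_calls$chrom == g$chrom, , drop = FALSE]
    x <- apply_calls(ref_cds, g$cds_start, g$cds_end, fc)
    ## male-only alleles are applied on top of the neo-X allele; indel
    ## coordinate shifts between the two call sets make a gene unresolvable
    ## only when edits overlap, which apply_calls detects on the union
    both <- rbind(fc[, c("kind", "chrom", "pos", "ref", "alt")],
                  mc[, c("kind", "chrom", "pos", "ref", "alt")])
    y_ref <- apply_calls(ref_cds, g$cds_start, g$cds_end, both)
    ok <- x$ok && y_ref$ok
    xs <- x$seq; ys <- y_ref$seq
    if (g$strand == "-") { xs <- revcomp(xs); ys <- revcomp(ys) }
    rows[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, neoX_cds = xs, neoY_cds = ys,
      n_female_var = x$n, n_male_var = y_ref$n - x$n,
      net_indel_female = x$net, net_indel_male = y_ref$net,
      ok = ok, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Select male-only calls at heterozygous-like allele ratios
#'
#' Candidate fixed neo-X/neo-Y differences: male-only calls whose male
#' alternative-allele ratio lies in `ratio_range` (a fixed difference is
#' present in the male read pool at roughly 1:1).
#'
#' @param calls VariantCall data.frame
#' @param ratio_range inclusive alt-ratio window, default `c(0.25, 0.75)`
#' @return filtered data.frame
#' @export
select_male_only <- function(calls, ratio_range = c(0.25, 0.75)) {
  calls[calls$partition == "male_only" &
        !is.na(calls$alt_ratio_male) &
        calls$alt_ratio_male >= ratio_range[1L] &
        calls$alt_ratio_male <= ratio_range[2L], , drop = FALSE]
}

#' Scan one allele for coding disruptions
#'
#' Flags: `premature_stop` (an in-frame stop strictly before the annotated
#' terminal codon; `cds_offset` is the 0-based nucleotide offset of that
#' stop), `frameshift` (allele length differs from the annotated CDS length
#' by a non-multiple of 3), `start_loss` (first codon is not ATG).
#'
#' @param allele coding-strand allele sequence
#' @param ref_len annotated CDS length, bp
#' @param gene_id gene identifier for the report
#' @return DisruptionFlag data.frame (possibly empty): gene_id, kind,
#'   cds_offset
#' @export
scan_disruptions <- function(allele, ref_len, gene_id = NA_character_) {
  out <- list()
  n <- nchar(allele)
  if (n < 6L) {
    warning("CDS of ", gene_id, " shorter than 6 bp; skipped")
    return(data.frame(gene_id = character(0), kind = character(0),
                      cds_offset = integer(0), stringsAsFactors = FALSE))
  }
  if (substr(allele, 1L, 3L) != "ATG") {
    out$start <- data.frame(gene_id = gene_id, kind = "start_loss",
                            cds_offset = 0L, stringsAsFactors = FALSE)
  }
  if ((n - ref_len) %% 3L != 0L) {
    out$fs <- data.frame(gene_id = gene_id, kind = "frameshift",
                         cds_offset = NA_integer_, stringsAsFactors = FALSE)
  }
  cods <- codons_of(allele)
  ncod <- length(cods)
  if (ncod >= 2L) {
    internal <- which(cods[-ncod] %in% STOP_CODONS)
    if (length(internal)) {
      out$stop <- data.frame(gene_id = gene_id, kind = "premature_stop",
                             cds_offset = 3L * (internal[1L] - 1L),
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), kind = character(0),
                      cds_offset = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan reconstructed allele pairs for disruptions on each allele
#'
#' @param alleles AllelePair data.frame from [reconstruct_alleles()]
#' @param genes gene-model data.frame (for annotated CDS lengths)
#' @return data.frame: gene_id, chrom, allele ("neoX"/"neoY"), kind,
#'   cds_offset
#' @export
scan_allele_disruptions <- function(alleles, genes) {
  len <- setNames(genes$cds_end - genes$cds_start + 1L, genes$gene_id)
  rows <- list()
  for (i in seq_len(nrow(alleles))) {
    if (!alleles$ok[i]) next
    gid <- alleles$gene_id[i]
    fx <- scan_disruptions(alleles$neoX_cds[i], len[[gid]], gid)
    fy <- scan_disruptions(alleles$neoY_cds[i], len[[gid]], gid)
    if (nrow(fx)) rows[[paste0(gid, "x")]] <-
      cbind(fx, chrom = alleles$chrom[i], allele = "neoX")
    if (nrow(fy)) rows[[paste0(gid, "y")]] <-
      cbind(fy, chrom = alleles$chrom[i], allele = "neoY")
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(0), kind = character(0), cds_offset = integer(0),
    chrom = character(0), allele = character(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[, c("gene_id", "chrom", "allele", "kind", "cds_offset")]
}

#' Remove ancestral pseudogenes from the neo-Y pseudogene set
#'
#' Genes disrupted in the female-derived (neo-X) allele already existed as
#' pseudogenes before the neo-sex chromosomes arose and are excluded; the
#' same female-based exclusion applies on every chromosome.
#'
#' @param flags output of [scan_allele_disruptions()]
#' @return list with `neoY` (data.frame of genes disrupted only on the
#'   male-derived allele: gene_id, chrom, kinds), `ancestral` (gene_id,
#'   chrom disrupted on the female-derived allele)
#' @export
filter_ancestral <- function(flags) {
  anc_ids <- unique(flags$gene_id[flags$allele == "neoX"])
  y <- flags[flags$allele == "neoY" & !flags$gene_id %in% anc_ids, , drop = FALSE]
  neoY <- if (nrow(y)) {
    agg <- tapply(y$kind, y$gene_id, function(k) paste(sort(unique(k)), collapse = ","))
    data.frame(gene_id = names(agg),
               chrom = y$chrom[match(names(agg), y$gene_id)],
               kinds = as.character(agg), stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), chrom = character(0),
               kinds = character(0), stringsAsFactors = FALSE)
  }
  anc <- flags[flags$allele == "neoX", , drop = FALSE]
  ancestral <- data.frame(gene_id = unique(anc$gene_id),
                          chrom = anc$chrom[match(unique(anc$gene_id), anc$gene_id)],
                          stringsAsFactors = FALSE)
  rownames(neoY) <- NULL
  list(neoY = neoY, ancestral = ancestral)
}

#' Pairwise pseudogene-enrichment test against the neo set
#'
#' Two-sided Fisher's exact test of pseudogene proportion on the neo element
#' against each other chromosome; no multiple-testing correction is applied.
#'
#' @param counts data.frame with chrom, pseudogenes, total
#' @param neo_chrom label of the neo-sex row (default "neo")
#' @return `counts` with a `p_vs_neo` column (NA for the neo row itself and
#'   for zero-total rows)
#' @export
pseudogene_enrichment <- function(counts, neo_chrom = "neo") {
  stopifnot(all(counts$total >= counts$pseudogenes))
  i0 <- match(neo_chrom, counts$chrom)
  if (is.na(i0)) stop("no row for the neo chromosome '", neo_chrom, "'")
  counts$p_vs_neo <- NA_real_
  for (i in seq_len(nrow(counts))) {
    if (i == i0 || counts$total[i] == 0L || counts$total[i0] == 0L) next
    m <- matrix(c(counts$pseudogenes[i0], counts$total[i0] - counts$pseudogenes[i0],
                  counts$pseudogenes[i], counts$total[i] - counts$pseudogenes[i]),
                nrow = 2L, byrow = TRUE)
    counts$p_vs_neo[i] <- fisher.test(m, alternative = "two.sided")$p.value
  }
  counts
}

## ---- Ka/Ks (Nei-Gojobori 1986, Jukes-Cantor corrected) -------------------

## per-codon synonymous site count: sum over the 3 positions of the fraction
## of single-base changes that are synonymous (stop-producing changes are
## not counted as possible changes)
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_1[[codon]]
  s <- 0
  for (p in 1:3) {
    alts <- setdiff(BASES, substr(codon, p, p))
    n_ok <- 0L; n_syn <- 0L
    for (b in alts) {
      nc <- codon
      substr(nc, p, p) <- b
      if (GENETIC_CODE_1[[nc]] == "*") next
      n_ok <- n_ok + 1L
      if (GENETIC_CODE_1[[nc]] == aa) n_syn <- n_syn + 1L
    }
    if (n_ok > 0L) s <- s + n_syn / 3
  }
  s
}

SYN_SITES <- local({
  v <- vapply(SENSE_CODONS, codon_syn_sites, 1)
  setNames(v, SENSE_CODONS)
})

## pathway-averaged (Ns, Na) differences between two codons
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(s = 0, n = 0))
  paths <- if (nd == 1L) list(pos) else {
    perms <- if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
    perms
  }
  tot_s <- 0; tot_n <- 0; n_valid <- 0L
  for (path in paths) {
    cur <- c1; s <- 0; n <- 0; valid <- TRUE
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GENETIC_CODE_1[[nxt]] == "*") { valid <- FALSE; break }
      if (GENETIC_CODE_1[[nxt]] == GENETIC_CODE_1[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) {
    ## all pathways pass through a stop; fall back to counting every
    ## difference as nonsynonymous
    return(c(s = 0, n = nd))
  }
  c(s = tot_s / n_valid, n = tot_n / n_valid)
}

#' Ka/Ks between two aligned coding sequences (Nei-Gojobori 1986)
#'
#' Pathway-averaged counting of synonymous and nonsynonymous differences
#' with Jukes-Cantor multiple-hit correction. Both sequences must be
#' frameshift-free, equal length and a multiple of 3; codons containing
#' ambiguity (N) or an in-frame stop in either sequence are skipped.
#'
#' @param seq1,seq2 coding-strand CDS strings
#' @return list: Ka, Ks, Na, Ns (substitution counts), Sa, Ss (site counts),
#'   n_codons
#' @export
kaks <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequences differ in length")
  if (nchar(seq1) %% 3L != 0L) stop("length is not a multiple of 3")
  c1 <- codons_of(seq1); c2 <- codons_of(seq2)
  keep <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2) &
    !(c1 %in% STOP_CODONS) & !(c2 %in% STOP_CODONS)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (!length(c1)) {
    return(list(Ka = NA_real_, Ks = NA_real_, Na = 0, Ns = 0, Sa = 0, Ss = 0,
                n_codons = 0L))
  }
  ## site counts averaged over the two sequences
  s1 <- sum(SYN_SITES[c1]); s2 <- sum(SYN_SITES[c2])
  Ss <- (s1 + s2) / 2
  Sa <- 3 * length(c1) - Ss
  d <- vapply(seq_along(c1), function(i) codon_path_diffs(c1[i], c2[i]), c(s = 0, n = 0))
  Ns <- sum(d["s", ]); Na <- sum(d["n", ])
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- if (Ss > 0) jc(Ns / Ss) else NA_real_
  Ka <- if (Sa > 0) jc(Na / Sa) else NA_real_
  list(Ka = Ka, Ks = Ks, Na = Na, Ns = Ns, Sa = Sa, Ss = Ss,
       n_codons = length(c1))
}

#' Per-gene Ka/Ks over reconstructed allele pairs
#'
#' Frameshifted or unresolvable genes are skipped (Ka/Ks requires an intact
#' reading frame); genes whose alleles differ in length are skipped with a
#' log record in the `skipped` attribute.
#'
#' @param alleles AllelePair data.frame
#' @return data.frame gene_id, chrom, Ka, Ks, Na, Ns, Sa, Ss
#' @export
kaks_table <- function(alleles) {
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(alleles))) {
    x <- alleles$neoX_cds[i]; y <- alleles$neoY_cds[i]
    if (!alleles$ok[i] || nchar(x) != nchar(y) || nchar(x) %% 3L != 0L) {
      skipped <- c(skipped, alleles$gene_id[i])
      next
    }
    if (grepl("N", x, fixed = TRUE) || grepl("N", y, fixed = TRUE)) {
      skipped <- c(skipped, alleles$gene_id[i])
      next
    }
    k <- kaks(x, y)
    rows[[i]] <- data.frame(gene_id = alleles$gene_id[i], chrom = alleles$chrom[i],
                            Ka = k$Ka, Ks = k$Ks, Na = k$Na, Ns = k$Ns,
                            Sa = k$Sa, Ss = k$Ss, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(0), chrom = character(0), Ka = numeric(0),
    Ks = numeric(0), Na = numeric(0), Ns = numeric(0), Sa = numeric(0),
    Ss = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

## ---- codon-usage bias indices --------------------------------------------

## synonymous families of the standard code (stop codons excluded); Met and
## Trp form single-codon families and are excluded from all indices
CODON_FAMILIES <- local({
  aa <- GENETIC_CODE_1[SENSE_CODONS]
  split(SENSE_CODONS, aa)
})

codon_counts <- function(seq) {
  cods <- codons_of(seq)
  cods <- cods[!grepl("[^ACGT]", cods)]
  table(factor(cods, levels = SENSE_CODONS))
}

#' Effective number of codons (Wright's ENC)
#'
#' Family homozygosity F = (n * sum(p^2) - 1) / (n - 1) averaged within each
#' degeneracy class; families with n < 2 are skipped, and a missing
#' degeneracy class falls back to the average F of the observed classes
#' (Wright's convention). Bounded to [20, 61].
#'
#' @param seq a CDS string
#' @return ENC scalar
#' @export
enc <- function(seq) {
  cnt <- codon_counts(seq)
  fam_F <- list()
  for (aa in names(CODON_FAMILIES)) {
    cods <- CODON_FAMILIES[[aa]]
    k <- length(cods)
    if (k < 2L) next
    n <- sum(cnt[cods])
    if (n < 2) next
    p <- cnt[cods] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    fam_F[[aa]] <- c(k = k, f = f)
  }
  if (!length(fam_F)) return(NA_real_)
  m <- do.call(rbind, fam_F)
  avgF <- function(k) {
    f <- m[m[, "k"] == k, "f"]
    if (length(f)) mean(f) else NA_real_
  }
  F2 <- avgF(2); F3 <- avgF(3); F4 <- avgF(4); F6 <- avgF(6)
  Fall <- mean(m[, "f"])
  if (is.na(F2)) F2 <- Fall
  if (is.na(F3)) F3 <- Fall
  if (is.na(F4)) F4 <- Fall
  if (is.na(F6)) F6 <- Fall
  eps <- 1e-12
  n_val <- 2 + 9 / max(F2, eps) + 1 / max(F3, eps) + 5 / max(F4, eps) +
    3 / max(F6, eps)
  min(max(n_val, 20), 61)
}

## relative adaptiveness weights from a reference sequence set
cai_weights <- function(ref_seqs) {
  cnt <- Reduce(`+`, lapply(ref_seqs, codon_counts))
  w <- setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  for (aa in names(CODON_FAMILIES)) {
    cods <- CODON_FAMILIES[[aa]]
    mx <- max(cnt[cods])
    if (mx == 0) { w[cods] <- 1; next }
    ## zero-count codons get a small nonzero weight so CAI stays positive
    w[cods] <- pmax(cnt[cods], 0.5) / mx
    w[cods] <- pmin(w[cods], 1)
  }
  w
}

## optimal codon per family = most frequent in the reference set
optimal_codons <- function(ref_seqs) {
  cnt <- Reduce(`+`, lapply(ref_seqs, codon_counts))
  unlist(lapply(CODON_FAMILIES, function(cods) {
    if (length(cods) < 2L) return(character(0))
    cods[which.max(cnt[cods])]
  }), use.names = FALSE)
}

#' Codon-usage bias indices (ENC, CAI, FOP, CBI) per sequence
#'
#' CAI uses relative-adaptiveness weights from a reference set (by default
#' the top `ref_fraction` of `ref_expression`-ranked sequences; when no
#' expression labels are given, the whole input defines the weights, making
#' the most frequent codon per family the optimum). FOP is the fraction of
#' optimal codons among synonymously variable codons; CBI follows
#' Bennetzen-Hall. Sequences containing N are assigned NA for all indices.
#'
#' @param seqs named character vector of CDSs
#' @param ref_expression optional numeric vector (same order) ranking the
#'   sequences; the top fraction defines the reference set
#' @param ref_fraction fraction of sequences forming the reference set
#' @return data.frame: name, ENC, CAI, FOP, CBI
#' @export
codon_bias <- function(seqs, ref_expression = NULL, ref_fraction = 0.1) {
  stopifnot(length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  refs <- if (!is.null(ref_expression)) {
    ntop <- max(1L, ceiling(ref_fraction * length(seqs)))
    seqs[order(-ref_expression)[seq_len(ntop)]]
  } else seqs
  w <- cai_weights(refs)
  opt <- optimal_codons(refs)
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (grepl("N", s, fixed = TRUE)) {
      return(data.frame(name = names(seqs)[i], ENC = NA_real_, CAI = NA_real_,
                        FOP = NA_real_, CBI = NA_real_, stringsAsFactors = FALSE))
    }
    cnt <- codon_counts(s)
    ## codons in synonymously variable families
    var_fams <- CODON_FAMILIES[lengths(CODON_FAMILIES) >= 2L]
    var_cods <- unlist(var_fams, use.names = FALSE)
    n_tot <- sum(cnt[var_cods])
    n_opt <- sum(cnt[opt])
    ## CAI over synonymously variable codons
    cai <- if (n_tot > 0) exp(sum(cnt[var_cods] * log(w[var_cods])) / n_tot)
           else NA_real_
    fop <- if (n_tot > 0) n_opt / n_tot else NA_real_
    ## CBI: expected optimal usage under uniform synonymous choice
    n_exp <- sum(vapply(var_fams, function(cods) sum(cnt[cods]) / length(cods), 1))
    cbi <- if (n_tot > n_exp) (n_opt - n_exp) / (n_tot - n_exp) else NA_real_
    data.frame(name = names(seqs)[i], ENC = enc(s), CAI = cai, FOP = fop,
               CBI = cbi, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
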