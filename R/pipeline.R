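## End-to-end orchestration: simulate -> map -> call variants -> scan SVs ->
## neo-Y degeneration statistics -> synteny scaffolding -> B-candidate
## subtraction -> report tables. A single config plus seed fully determines
## every output.

#' Pipeline configuration
#'
#' @param seed master RNG seed; every stage derives its stream from it
#' @param genome a [genome_plan()] (its own seed is overridden by `seed`)
#' @param divergence a [divergence_plan()]
#' @param insert an [insert_spec()]
#' @param coverage_female,coverage_male total (diploid) fold coverage per sex
#' @param err_rate per-base sequencing error rate
#' @param caller a [caller_params()]; when NULL the window/step are scaled to
#'   a tenth of the longest chromosome (and a tenth of that for the step) so
#'   density tracks stay meaningful at desk scale
#' @param sv an [sv_params()] (defaults to the insert spec above)
#' @param male_ratio_range heterozygous-like alt-ratio window for selecting
#'   candidate fixed neo-X/neo-Y differences
#' @param b_cov_threshold aligned-length cutoff for B candidates
#' @param write_reads write FASTQ files in [run_pipeline()] (large; default
#'   FALSE)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            genome = genome_plan(),
                            divergence = divergence_plan(),
                            insert = insert_spec(),
                            coverage_female = 30, coverage_male = 40,
                            err_rate = 0.002,
                            caller = NULL,
                            sv = NULL,
                            male_ratio_range = c(0.25, 0.75),
                            b_cov_threshold = 0.20,
                            write_reads = FALSE) {
  if (is.null(caller)) {
    win <- max(genome$chrom_specs$length) / 10
    caller <- caller_params(window = win, step = win / 10)
  }
  if (is.null(sv)) sv <- sv_params(ins = insert)
  genome$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), genome = genome,
                 divergence = divergence, insert = insert,
                 coverage_female = coverage_female,
                 coverage_male = coverage_male, err_rate = err_rate,
                 caller = caller, sv = sv,
                 male_ratio_range = male_ratio_range,
                 b_cov_threshold = b_cov_threshold,
                 write_reads = isTRUE(write_reads)),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#'
#' The configuration round-trips: [read_config()] on the written file
#' reconstructs an equivalent [pipeline_config()].
#'
#' @param config a [pipeline_config()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  obj <- strip(config)
  obj$genome$chrom_specs <- as.list(config$genome$chrom_specs)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path file written by [write_config()]
#' @return a [pipeline_config()]
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  gp <- do.call(genome_plan, c(
    list(chrom_specs = as.data.frame(y$genome$chrom_specs,
                                     stringsAsFactors = FALSE)),
    y$genome[c("gc_content", "mean_cds", "sd_cds", "flank", "seed")]))
  dp <- do.call(divergence_plan, y$divergence)
  ins <- do.call(insert_spec, y$insert)
  cp <- do.call(caller_params, y$caller)
  sv <- sv_params(ins = ins, sd_multiplier = y$sv$sd_multiplier,
                  min_support = y$sv$min_support,
                  cluster_window = y$sv$cluster_window,
                  dispersed_distance = y$sv$dispersed_distance)
  pipeline_config(seed = y$seed, genome = gp, divergence = dp, insert = ins,
                  coverage_female = y$coverage_female,
                  coverage_male = y$coverage_male, err_rate = y$err_rate,
                  caller = cp, sv = sv,
                  male_ratio_range = unlist(y$male_ratio_range),
                  b_cov_threshold = y$b_cov_threshold,
                  write_reads = y$write_reads)
}

#' Cut a hybridization-probe sequence from a scaffold
#'
#' @param seq source sequence
#' @param start 1-based start of the probe
#' @param len probe length (default 260 bp)
#' @param divergence per-base substitution divergence of the probe from its
#'   source
#' @param seed RNG seed
#' @return probe string
#' @export
make_probe <- function(seq, start = 1L, len = 260L, divergence = 0.05,
                       seed = 1L) {
  set.seed(as.integer(seed))
  p <- substr(seq, start, start + len - 1L)
  n <- rbinom(1L, nchar(p), divergence)
  if (n > 0L) {
    at <- sample.int(nchar(p), n)
    for (i in at) {
      substr(p, i, i) <- sample(setdiff(BASES, substr(p, i, i)), 1L)
    }
  }
  p
}

#' Fragment a genome into scaffolds with synteny-anchor hits
#'
#' Cuts each chromosome at intergenic points into scaffolds (randomly
#' reverse-complementing some, as draft assemblies do), and emits the
#' protein-anchor hit table, synteny map and true chromosome of each
#' scaffold, for exercising the synteny module against known truth.
#'
#' @param genome [simulate_genome()] output
#' @param n_frag number of fragments per chromosome
#' @param seed RNG seed
#' @param identity_noise anchors get identity in `[1 - identity_noise, 1]`
#' @return list: scaffolds, hits, synteny_map, protein_lengths, truth
#'   (scaffold_id -> chrom), flipped (scaffold ids stored reverse-complement)
#' @export
simulate_fragmentation <- function(genome, n_frag = 6L, seed = 1L,
                                   identity_noise = 0.1) {
  set.seed(as.integer(seed))
  scaffolds <- character(0)
  hits <- list(); map <- list(); truth <- list(); flipped <- character(0)
  sid <- 0L
  for (ch in names(genome$seqs)) {
    seq <- genome$seqs[[ch]]
    g <- genome$genes[genome$genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$cds_start), , drop = FALSE]
    len <- nchar(seq)
    ## candidate cut points: intergenic midpoints
    cuts <- integer(0)
    if (nrow(g) > 1L) {
      mids <- floor((g$cds_end[-nrow(g)] + g$cds_start[-1L]) / 2)
      k <- min(n_frag - 1L, length(mids))
      if (k > 0L) cuts <- sort(sample(mids, k))
    }
    bounds <- c(1L, cuts + 1L)
    ends <- c(cuts, len)
    for (i in seq_along(bounds)) {
      sid <- sid + 1L
      id <- sprintf("S%05d", sid)
      s <- substr(seq, bounds[i], ends[i])
      flip <- runif(1) < 0.3
      if (flip) { s <- revcomp(s); flipped <- c(flipped, id) }
      scaffolds[id] <- s
      truth[[id]] <- ch
      ## genes fully inside this scaffold become anchors
      inside <- g[g$cds_start >= bounds[i] & g$cds_end <= ends[i], , drop = FALSE]
      if (nrow(inside)) {
        slen <- nchar(s)
        s1 <- inside$cds_start - bounds[i] + 1L
        e1 <- inside$cds_end - bounds[i] + 1L
        if (flip) { tmp <- s1; s1 <- slen - e1 + 1L; e1 <- slen - tmp + 1L }
        strand_on_scaf <- if (flip) {
          ifelse(inside$strand == "+", "-", "+")
        } else inside$strand
        hits[[paste(ch, i)]] <- data.frame(
          scaffold_id = id, protein_id = inside$gene_id,
          score = e1 - s1 + 1L,
          identity = 1 - runif(nrow(inside), 0, identity_noise),
          prot_start = 1L, prot_end = (inside$cds_end - inside$cds_start + 1L) %/% 3L,
          scaf_start = s1, scaf_end = e1,
          orientation = strand_on_scaf, chrom = ch,
          stringsAsFactors = FALSE)
      }
    }
    g2 <- g
    map[[ch]] <- data.frame(chrom = ch, order = seq_len(nrow(g2)),
                            protein_id = g2$gene_id, orientation = g2$strand,
                            stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(hits, list(make.row.names = FALSE)))
  map <- do.call(rbind, c(map, list(make.row.names = FALSE)))
  plen <- setNames((genome$genes$cds_end - genome$genes$cds_start + 1L) %/% 3L,
                   genome$genes$gene_id)
  hits$prot_end <- unname(plen[hits$protein_id]) # aa units
  hits$prot_start <- 1L
  list(scaffolds = scaffolds, hits = hits, synteny_map = map,
       protein_lengths = plen, truth = unlist(truth), flipped = flipped)
}

## derive a reproducible sub-seed (kept below 2^31; double arithmetic so
## large master seeds cannot overflow R's 32-bit integers)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1999999) * 97 + k * 1009)
}

#' Run the full pipeline on one configuration
#'
#' Stage order: simulate -> map -> variants -> SV scan -> neo-Y statistics ->
#' synteny -> B-candidate subtraction -> report. When `outdir` is given,
#' every stage's artifacts are written as plain-text standard formats
#' (FASTA/GFF3/VCF/bedGraph/BEDPE/BED/TSV/JSON) before the next stage runs.
#'
#' @param config a [pipeline_config()]
#' @param outdir output directory (NULL = no files written)
#' @return list with every intermediate and report (see vignette)
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(fn, ...) if (!is.null(outdir)) fn(...)
  log <- list(seed = config$seed, started = "deterministic",
              params = list(coverage_female = config$coverage_female,
                            coverage_male = config$coverage_male,
                            err_rate = config$err_rate,
                            window = config$caller$window,
                            step = config$caller$step))

  ## --- stage 1: simulate ---
  genome <- simulate_genome(config$genome)
  hap <- derive_haplotypes(genome, config$divergence, sub_seed(config$seed, 1L))
  male_copies <- table(unlist(lapply(hap$male, names)))
  reads_f <- simulate_reads(hap$female, config$insert, config$coverage_female / 2,
                            config$err_rate, sub_seed(config$seed, 2L),
                            prefix = "f")
  reads_m <- simulate_reads(hap$male, config$insert, config$coverage_male / 2,
                            config$err_rate, sub_seed(config$seed, 3L),
                            poly = hap$poly, poly_hap = "hapA",
                            chrom_copies = male_copies, prefix = "m")
  emit(write_fasta, genome$seqs, file.path(outdir, "reference.fasta"))
  emit(write_gff3, genome$genes, file.path(outdir, "genes.gff3"))
  if (!is.null(outdir)) {
    for (nm in names(hap$truth)) {
      t <- hap$truth[[nm]]
      if (is.data.frame(t)) {
        write_tsv(t, file.path(outdir, sprintf("truth_%s.tsv", nm)))
      }
    }
    if (config$write_reads) {
      write_fastq(reads_f$reads1, file.path(outdir, "female_1.fastq"))
      write_fastq(reads_f$reads2, file.path(outdir, "female_2.fastq"))
      write_fastq(reads_m$reads1, file.path(outdir, "male_1.fastq"))
      write_fastq(reads_m$reads2, file.path(outdir, "male_2.fastq"))
    }
  }

  ## --- stage 2: map ---
  idx <- index_reference(genome$seqs)
  map_f <- map_reads(idx, reads_f)
  map_m <- map_reads(idx, reads_m)

  ## --- stage 3: variants ---
  pu_f <- pileup_from_mapping(genome$seqs, map_f, reads_f)
  pu_m <- pileup_from_mapping(genome$seqs, map_m, reads_m)
  snps <- call_snps(pu_m, pu_f, genome$seqs, config$caller)
  indels <- call_indels(map_m$gapped, map_f$gapped, pu_m, pu_f, config$caller)
  calls <- rbind(snps, indels)
  male_obs <- calls[calls$partition %in% c("male_only", "shared"), , drop = FALSE]
  female_obs <- calls[calls$partition %in% c("female_segregating", "shared"), , drop = FALSE]
  chrom_lengths <- setNames(nchar(genome$seqs), names(genome$seqs))
  dens_m <- window_density(male_obs[male_obs$kind == "snp", ], chrom_lengths,
                           config$caller)
  dens_f <- window_density(female_obs[female_obs$kind == "snp", ], chrom_lengths,
                           config$caller)
  table2_densities <- density_ratio_table(
    male_obs[male_obs$kind == "snp", ], female_obs[female_obs$kind == "snp", ],
    genome$genes, pu_m, pu_f, config$caller)
  spectrum <- allele_ratio_spectrum(male_obs[male_obs$kind == "snp", ], pu_m,
                                    config$caller)
  emit(write_vcf, calls, genome$seqs, file.path(outdir, "calls.vcf"))
  emit(write_vcf, male_obs, genome$seqs, file.path(outdir, "male.vcf"))
  emit(write_vcf, female_obs, genome$seqs, file.path(outdir, "female.vcf"))
  if (!is.null(outdir)) {
    write_bedgraph(data.frame(chrom = dens_m$chrom, start = dens_m$start,
                              end = dens_m$end, value = dens_m$density),
                   file.path(outdir, "density_male.bedgraph"), "male_snp_density")
    write_bedgraph(data.frame(chrom = dens_f$chrom, start = dens_f$start,
                              end = dens_f$end, value = dens_f$density),
                   file.path(outdir, "density_female.bedgraph"), "female_snp_density")
  }

  ## --- stage 4: SV scan ---
  cp_m <- classify_pairs(map_m$pairs, config$sv)
  cp_f <- classify_pairs(map_f$pairs, config$sv)
  read_len <- config$insert$read_len
  sv_m <- annotate_cds_overlap(cluster_anomalies(cp_m, config$sv, read_len),
                               genome$genes)
  sv_f <- annotate_cds_overlap(cluster_anomalies(cp_f, config$sv, read_len),
                               genome$genes)
  sv_report <- mf_ratio_report(sv_m, sv_f, cp_m, cp_f)
  if (!is.null(outdir)) {
    anom <- cp_m[!is.na(cp_m$anomaly) & cp_m$anomaly != "normal", , drop = FALSE]
    bedpe <- data.frame(chrom1 = anom$chrom1, start1 = anom$pos1,
                        end1 = anom$pos1 + read_len, chrom2 = anom$chrom2,
                        start2 = anom$pos2, end2 = anom$pos2 + read_len,
                        name = anom$anomaly)
    write_tsv(bedpe, file.path(outdir, "male_anomalies.bedpe"))
    write_tsv(sv_m, file.path(outdir, "sv_male.tsv"))
    write_tsv(sv_f, file.path(outdir, "sv_female.tsv"))
    bed <- data.frame(chrom = sv_m$chrom, start = sv_m$start, end = sv_m$end,
                      name = sv_m$type, score = sv_m$support)
    write.table(bed, file.path(outdir, "sv_male.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_tsv(sv_report$counts, file.path(outdir, "sv_mf_ratios.tsv"))
  }

  ## --- stage 5: neo-Y statistics ---
  male_only <- select_male_only(calls, config$male_ratio_range)
  alleles <- reconstruct_alleles(genome$genes, genome$seqs, female_obs, male_only)
  flags <- scan_allele_disruptions(alleles, genome$genes)
  pseudo <- filter_ancestral(flags)
  totals <- table(genome$genes$chrom)
  pseudo_counts <- data.frame(
    chrom = names(totals),
    pseudogenes = vapply(names(totals),
                         function(ch) sum(pseudo$neoY$chrom == ch), 1L),
    total = as.integer(totals), stringsAsFactors = FALSE)
  enrich <- if ("neo" %in% pseudo_counts$chrom) {
    pseudogene_enrichment(pseudo_counts, "neo")
  } else pseudo_counts
  kk <- kaks_table(alleles)
  cb <- codon_bias(setNames(alleles$neoX_cds, alleles$gene_id),
                   ref_expression = genome$genes$expression[
                     match(alleles$gene_id, genome$genes$gene_id)])
  cbY <- codon_bias(setNames(alleles$neoY_cds, alleles$gene_id),
                    ref_expression = genome$genes$expression[
                      match(alleles$gene_id, genome$genes$gene_id)])
  if (!is.null(outdir)) {
    write_tsv(flags, file.path(outdir, "disruption_flags.tsv"))
    write_tsv(pseudo$neoY, file.path(outdir, "pseudogenes_neoY.tsv"))
    write_tsv(enrich, file.path(outdir, "pseudogene_counts.tsv"))
    write_tsv(kk, file.path(outdir, "kaks.tsv"))
    write_tsv(cb, file.path(outdir, "codon_bias_neoX.tsv"))
    write_tsv(cbY, file.path(outdir, "codon_bias_neoY.tsv"))
    write_fasta(setNames(c(alleles$neoX_cds, alleles$neoY_cds),
                         c(paste0(alleles$gene_id, "_neoX"),
                           paste0(alleles$gene_id, "_neoY"))),
                file.path(outdir, "allele_pairs.fasta"))
  }

  ## --- stage 6: synteny ---
  frag <- simulate_fragmentation(genome, seed = sub_seed(config$seed, 4L))
  surv <- resolve_overlapping_hits(frag$hits)
  merged <- merge_by_gene(frag$scaffolds, surv)
  supers <- merge_by_synteny(merged$scaffolds, surv, frag$synteny_map,
                             frag$protein_lengths)
  nonN <- function(s) nchar(gsub("N", "", s, fixed = TRUE))
  stats_before <- n50(nchar(frag$scaffolds))
  stats_after <- n50(nchar(supers$scaffolds))
  assign <- assign_chromosomes(frag$hits)
  assembly <- list(before = stats_before, after = stats_after)
  if (!is.null(outdir)) {
    write_fasta(supers$scaffolds, file.path(outdir, "super_scaffolds.fasta"))
    if (nrow(supers$joins)) write_tsv(supers$joins, file.path(outdir, "joins.tsv"))
    write_tsv(assign, file.path(outdir, "chromosome_assignment.tsv"))
    jsonlite::write_json(assembly, file.path(outdir, "assembly_stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## --- stage 7: B candidates ---
  bchrom <- NULL
  if (!is.null(hap$b_fragment)) {
    male_assembly <- c(genome$seqs,
                       setNames(hap$male$hapB[["neo"]], "neoY_scaffold"),
                       hap$b_fragment)
    female_assembly <- genome$seqs
    cand <- subtract_assemblies(male_assembly, female_assembly,
                                config$b_cov_threshold)
    annotations <- if (config$divergence$plant_known_gene_on_b) {
      data.frame(scaffold_id = "B_scaffold",
                 protein_id = genome$genes$gene_id[1L],
                 stringsAsFactors = FALSE)
    } else data.frame(scaffold_id = character(0), protein_id = character(0))
    known <- data.frame(protein_id = genome$genes$gene_id)
    cand <- filter_known(cand, annotations, known)
    sl <- config$divergence$b_slice_len
    probe <- make_probe(hap$b_fragment, start = 2L * sl + 101L,
                        len = 260L, divergence = 0.05,
                        seed = sub_seed(config$seed, 5L))
    bait <- probe_bait(probe, male_assembly)
    centromeric <- c(chrX_cen = substr(genome$seqs[["chrX"]], 1L, 1000L + sl),
                     neo_cen = substr(genome$seqs[["neo"]],
                                      nchar(genome$seqs[["neo"]]) - sl - 999L,
                                      nchar(genome$seqs[["neo"]])))
    cenfrac <- centromeric_read_fraction(
      list(male = c(reads_m$reads1, reads_m$reads2),
           female = c(reads_f$reads1, reads_f$reads2)),
      centromeric)
    bchrom <- list(candidates = cand, probe = probe, bait = bait,
                   centromeric_fraction = cenfrac)
    if (!is.null(outdir)) {
      write_tsv(cand, file.path(outdir, "b_candidates.tsv"))
      write_tsv(bait, file.path(outdir, "probe_ranking.tsv"))
      write_tsv(cenfrac, file.path(outdir, "centromeric_fraction.tsv"))
    }
  }

  ## --- stage 8: report ---
  table2 <- make_table2(table2_densities, enrich, kk, sv_report)
  if (!is.null(outdir)) {
    write_tsv(table2, file.path(outdir, "table2_analog.tsv"))
    write_tsv(spectrum$summary, file.path(outdir, "allele_ratio_summary.tsv"))
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genome = genome, hap = hap, reads = list(female = reads_f, male = reads_m),
       mapping = list(female = map_f, male = map_m),
       pileups = list(female = pu_f, male = pu_m),
       calls = calls, male_obs = male_obs, female_obs = female_obs,
       densities = list(male = dens_m, female = dens_f),
       density_table = table2_densities, spectrum = spectrum,
       classified = list(male = cp_m, female = cp_f),
       svs = list(male = sv_m, female = sv_f), sv_report = sv_report,
       alleles = alleles, flags = flags, pseudo = pseudo,
       pseudo_counts = enrich, kaks = kk,
       codon_bias = list(neoX = cb, neoY = cbY),
       synteny = list(frag = frag, merged = merged, supers = supers,
                      assembly = assembly, assignment = assign),
       bchrom = bchrom, table2 = table2, config = config)
}

#' Assemble the per-chromosome comparison table
#'
#' One row per chromosome: exonic and intronic SNP density per sex with the
#' male/female ratio (printed as two decimals, integer once the ratio
#' reaches 10), pseudogene count / total genes, mean and sd of Ka (x 1000),
#' and the percentage of tandem duplications overlapping coding sequence
#' per sex.
#'
#' @param density_table [density_ratio_table()] output
#' @param pseudo_counts data.frame chrom, pseudogenes, total
#' @param kaks_tbl [kaks_table()] output
#' @param sv_report [mf_ratio_report()] output
#' @return data.frame (one row per chromosome present in `density_table`)
#' @export
make_table2 <- function(density_table, pseudo_counts, kaks_tbl, sv_report) {
  rows <- list()
  for (i in seq_len(nrow(density_table))) {
    ch <- density_table$chrom[i]
    pc <- pseudo_counts[pseudo_counts$chrom == ch, , drop = FALSE]
    ka <- kaks_tbl$Ka[kaks_tbl$chrom == ch]
    ka <- ka[!is.na(ka)]
    ov <- if (!is.null(sv_report$cds_overlap)) {
      sv_report$cds_overlap[sv_report$cds_overlap$chrom == ch, , drop = FALSE]
    } else NULL
    rows[[ch]] <- data.frame(
      chrom = ch,
      exonic_snp = sprintf("%.2f/%.2f(%s)", density_table$exonic_male[i],
                           density_table$exonic_female[i],
                           density_table$exonic_printed[i]),
      intronic_snp = sprintf("%.2f/%.2f(%s)", density_table$intronic_male[i],
                             density_table$intronic_female[i],
                             density_table$intronic_printed[i]),
      pseudogenes = if (nrow(pc)) sprintf("%d/%d", pc$pseudogenes, pc$total) else "NA",
      p_vs_neo = if (nrow(pc) && !is.null(pc$p_vs_neo)) pc$p_vs_neo else NA_real_,
      ka_mean_x1000 = if (length(ka)) round(mean(ka) * 1000, 2) else NA_real_,
      ka_sd_x1000 = if (length(ka) > 1L) round(stats::sd(ka) * 1000, 2) else NA_real_,
      tandem_dup_cds_pct = if (!is.null(ov) && nrow(ov)) {
        sprintf("%.1f/%.1f", ov$male_pct, ov$female_pct)
      } else "NA",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
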