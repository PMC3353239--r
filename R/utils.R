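## Shared sequence helpers and plain-text format writers.
## Sequences travel through the package as named character vectors of
## upper-case ACGTN strings; Biostrings is used at the file-format boundary.

#' Reverse complement of character sequences
#' @param x character vector of DNA strings
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA of given length and GC content (uses the current RNG stream)
#' @keywords internal
random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Split a CDS string into codons
#' @keywords internal
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a CDS (standard code); trailing partial codon dropped
#' @keywords internal
translate_cds <- function(seq) {
  paste(GENETIC_CODE_1[codons_of(seq)], collapse = "")
}

## ---- FASTA / FASTQ -------------------------------------------------------

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (constant Q30 qualities)
#' @param reads named character vector of read sequences
#' @param path output file
#' @return the path, invisibly
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("?", n), "") # '?' = Q30
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file (sequences only) into a named character vector
#' @param path input file
#' @return named character vector of read sequences
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

## ---- GFF3 ----------------------------------------------------------------

#' Write single-exon gene models to GFF3 (1-based inclusive)
#'
#' Emits one `gene` and one `CDS` feature per row of `genes`.
#'
#' @param genes data.frame with columns gene_id, chrom, cds_start, cds_end,
#'   gene_start, gene_end, strand (1-based inclusive coordinates)
#' @param path output file
#' @return the path, invisibly
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    g <- paste(genes$chrom, "neosex", "gene", genes$gene_start, genes$gene_end,
               ".", genes$strand, ".", paste0("ID=", genes$gene_id), sep = "\t")
    cds <- paste(genes$chrom, "neosex", "CDS", genes$cds_start, genes$cds_end,
                 ".", genes$strand, "0",
                 paste0("ID=", genes$gene_id, ".cds;Parent=", genes$gene_id),
                 sep = "\t")
    writeLines(as.vector(rbind(g, cds)), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file written by [write_gff3()]
#'
#' Accepts any GFF3 whose `CDS` rows carry `Parent=` (or `ID=`) attributes;
#' `gene` rows, when present, provide the genic span used as the "intron"
#' (non-coding genic) partition.
#'
#' @param path input file
#' @return gene-model data.frame (see [write_gff3()])
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      cds_start = integer(0), cds_end = integer(0),
                      gene_start = integer(0), gene_end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  attr_id <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "=[^;]+"), a))
    ifelse(lengths(regmatches(a, gregexpr(paste0(key, "=[^;]+"), a))) > 0,
           sub(paste0(key, "="), "", m), NA_character_)
  }
  cds <- f[f[, 3] == "CDS", , drop = FALSE]
  id <- attr_id(cds[, 9], "Parent")
  id[is.na(id)] <- sub("\\.cds$", "", attr_id(cds[, 9], "ID")[is.na(id)])
  out <- data.frame(gene_id = id, chrom = cds[, 1],
                    cds_start = as.integer(cds[, 4]), cds_end = as.integer(cds[, 5]),
                    strand = cds[, 7], stringsAsFactors = FALSE)
  gn <- f[f[, 3] == "gene", , drop = FALSE]
  if (nrow(gn)) {
    gid <- attr_id(gn[, 9], "ID")
    gs <- setNames(as.integer(gn[, 4]), gid)
    ge <- setNames(as.integer(gn[, 5]), gid)
    out$gene_start <- unname(gs[out$gene_id])
    out$gene_end <- unname(ge[out$gene_id])
  }
  if (is.null(out$gene_start)) out$gene_start <- out$cds_start
  out$gene_start[is.na(out$gene_start)] <- out$cds_start[is.na(out$gene_start)]
  if (is.null(out$gene_end)) out$gene_end <- out$cds_end
  out$gene_end[is.na(out$gene_end)] <- out$cds_end[is.na(out$gene_end)]
  out[, c("gene_id", "chrom", "cds_start", "cds_end",
          "gene_start", "gene_end", "strand")]
}

## ---- TSV / bedGraph / VCF ------------------------------------------------

#' Write a data.frame as tab-separated text
#' @param df data.frame
#' @param path output file
#' @return the path, invisibly
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read tab-separated text written by [write_tsv()]
#' @param path input file
#' @return data.frame
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}

#' Write a density track as bedGraph (0-based half-open)
#' @param track data.frame with chrom, start, end, value
#' @param path output file
#' @param name track name
#' @return the path, invisibly
#' @export
write_bedgraph <- function(track, path, name = "density") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  if (nrow(track)) {
    writeLines(paste(track$chrom, track$start, track$end,
                     formatC(track$value, format = "g"), sep = "\t"), con)
  }
  invisible(path)
}

#' Write variant calls as VCF 4.2 (1-based positions)
#'
#' Indels are emitted with the anchor-base convention: the reference base
#' preceding the event is prepended to REF and ALT.
#'
#' @param calls VariantCall data.frame from [call_snps()] / [call_indels()]
#' @param genome named character vector of reference sequences
#' @param path output file
#' @return the path, invisibly
#' @export
write_vcf <- function(calls, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
               "##INFO=<ID=PARTITION,Number=1,Type=String,Description=\"Sex partition of the site\">",
               "##INFO=<ID=MC,Number=2,Type=Integer,Description=\"Male ref,alt counts\">",
               "##INFO=<ID=FC,Number=2,Type=Integer,Description=\"Female ref,alt counts\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     sep = "\t")), con)
  if (nrow(calls)) {
    pos1 <- ref <- alt <- integer(nrow(calls))
    is_snp <- calls$kind == "snp"
    pos1 <- ifelse(is_snp, calls$pos + 1L, calls$pos) # anchor base for indels
    anchor <- substring(genome[calls$chrom], pos1, pos1)
    ref <- ifelse(is_snp, calls$ref,
           ifelse(calls$kind == "del", paste0(anchor, calls$ref), anchor))
    alt <- ifelse(is_snp, calls$alt,
           ifelse(calls$kind == "del", anchor, paste0(anchor, calls$alt)))
    info <- sprintf("PARTITION=%s;MC=%d,%d;FC=%d,%d", calls$partition,
                    calls$male_ref, calls$male_alt, calls$female_ref, calls$female_alt)
    writeLines(paste(calls$chrom, pos1, ".", ref, alt, ".", "PASS", info,
                     sep = "\t"), con)
  }
  invisible(path)
}
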