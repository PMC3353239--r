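## Synteny-guided super-scaffolding.
##
## Draft scaffolds are anchored to reference-species proteins via tabular
## alignment hits; scaffolds covering successive parts of one protein are
## merged in protein order, and scaffolds anchored to proteins that are
## conserved-adjacent across the reference panel are concatenated into
## super-scaffolds with 500-N spacers. Any ambiguity leaves scaffolds
## unmerged (conservative, deterministic policy).

#' Resolve overlapping hits: best scaffold per overlapping protein interval
#'
#' For each protein, among scaffolds whose hit intervals on the protein
#' overlap each other, only the top-scoring scaffold's hit survives;
#' non-overlapping hits all survive (they cover different protein parts).
#'
#' @param hits data.frame: scaffold_id, protein_id, score, identity,
#'   prot_start, prot_end (1-based inclusive on the protein),
#'   scaf_start, scaf_end, orientation ("+"/"-")
#' @return the surviving subset of `hits`
#' @export
resolve_overlapping_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  for (pr in unique(hits$protein_id)) {
    i <- which(hits$protein_id == pr)
    if (length(i) < 2L) next
    ## drop any hit overlapped on the protein by a higher-scoring hit
    for (a in i) {
      for (b in i) {
        if (a == b) next
        ov <- hits$prot_start[a] <= hits$prot_end[b] &
              hits$prot_start[b] <= hits$prot_end[a]
        if (ov && (hits$score[b] > hits$score[a] ||
                   (hits$score[b] == hits$score[a] &&
                    hits$scaffold_id[b] < hits$scaffold_id[a]))) {
          keep[a] <- FALSE
        }
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Merge scaffolds covering successive parts of one protein
#'
#' Scaffolds hitting non-overlapping intervals of a protein are concatenated
#' in protein-coordinate order, reverse-complementing scaffolds whose hit
#' orientation is "-". A scaffold required at incompatible positions (two
#' proteins disagree) is left unmerged and the conflict logged.
#'
#' @param scaffolds named character vector of scaffold sequences
#' @param hits surviving hits from [resolve_overlapping_hits()]
#' @return list with `scaffolds` (merged + untouched sequences), `members`
#'   (merged name -> ordered member table) and `conflicts` (character log)
#' @export
merge_by_gene <- function(scaffolds, hits) {
  conflicts <- character(0)
  members <- list()
  ## proteins hit by >= 2 scaffolds define candidate joins
  join_of <- list() # scaffold -> merged-group id
  groups <- list()  # group id -> data.frame(scaffold, orientation, order key)
  for (pr in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pr, , drop = FALSE]
    h <- h[order(h$prot_start), , drop = FALSE]
    if (length(unique(h$scaffold_id)) < 2L) next
    if (anyDuplicated(h$scaffold_id)) {
      conflicts <- c(conflicts, sprintf(
        "protein %s hit twice by one scaffold; left unmerged", pr))
      next
    }
    ## scaffolds already claimed by another protein's join conflict
    if (any(h$scaffold_id %in% names(join_of))) {
      clash <- intersect(h$scaffold_id, names(join_of))
      conflicts <- c(conflicts, sprintf(
        "scaffold %s required by several merge groups; left unmerged",
        paste(clash, collapse = ",")))
      next
    }
    gid <- sprintf("merge_%s", pr)
    groups[[gid]] <- data.frame(scaffold = h$scaffold_id,
                                orientation = h$orientation,
                                stringsAsFactors = FALSE)
    for (s in h$scaffold_id) join_of[[s]] <- gid
  }
  out <- scaffolds
  for (gid in names(groups)) {
    g <- groups[[gid]]
    if (!all(g$scaffold %in% names(out))) next
    parts <- vapply(seq_len(nrow(g)), function(i) {
      s <- out[[g$scaffold[i]]]
      if (g$orientation[i] == "-") revcomp(s) else s
    }, "")
    out <- out[!names(out) %in% g$scaffold]
    out[gid] <- paste(parts, collapse = "")
    members[[gid]] <- g
  }
  list(scaffolds = out, members = members, conflicts = conflicts)
}

#' Build super-scaffolds from conserved gene adjacency
#'
#' Scaffolds anchored (hit spanning over half the protein) to proteins that
#' are conserved-adjacent in the synteny map are ordered per the map and
#' joined with exactly 500 Ns; anchor orientation orients each scaffold. A
#' scaffold anchored to non-adjacent map positions is excluded and logged.
#'
#' @param scaffolds named character vector (typically [merge_by_gene()] output)
#' @param hits hit table (as in [resolve_overlapping_hits()]); only hits with
#'   `anchor_span_fraction` of the protein covered qualify as anchors
#' @param synteny_map data.frame: chrom, order (integer rank), protein_id,
#'   orientation; `conserved_adjacency` pairs are consecutive `order` values
#'   on one chromosome
#' @param protein_lengths named vector of protein lengths (aa) for the
#'   anchor-span rule
#' @param anchor_span_fraction minimum hit span as a fraction of the protein
#'   (default 0.5)
#' @param n_spacer number of Ns between joined scaffolds (default 500)
#' @return list with `scaffolds` (super-scaffolds + untouched), `joins`
#'   (AGP-style table: super_scaffold, part, scaffold, orientation),
#'   `excluded` (character log)
#' @export
merge_by_synteny <- function(scaffolds, hits, synteny_map, protein_lengths,
                             anchor_span_fraction = 0.5, n_spacer = 500L) {
  excluded <- character(0)
  span <- hits$prot_end - hits$prot_start + 1L
  frac <- span / protein_lengths[hits$protein_id]
  anchors <- hits[!is.na(frac) & frac > anchor_span_fraction, , drop = FALSE]
  anchors <- anchors[anchors$scaffold_id %in% names(scaffolds), , drop = FALSE]
  ## best anchor per (scaffold, protein)
  anchors <- anchors[order(-anchors$score), , drop = FALSE]
  anchors <- anchors[!duplicated(anchors[, c("scaffold_id", "protein_id")]), , drop = FALSE]
  map <- synteny_map[order(synteny_map$chrom, synteny_map$order), , drop = FALSE]
  ## positions are the map's own order ranks: conserved adjacency means
  ## consecutive order values on one chromosome
  map_pos <- setNames(map$order, map$protein_id)
  map_chrom <- setNames(map$chrom, map$protein_id)
  map_orient <- if (!is.null(map$orientation)) {
    setNames(map$orientation, map$protein_id)
  } else setNames(rep("+", nrow(map)), map$protein_id)
  ## scaffold -> set of anchored map rows
  an_rows <- split(seq_len(nrow(anchors)), anchors$scaffold_id)
  scaf_pos <- list()
  for (s in names(an_rows)) {
    pr <- anchors$protein_id[an_rows[[s]]]
    pr <- pr[pr %in% names(map_pos)]
    if (!length(pr)) next
    pp <- sort(unname(map_pos[pr]))
    if (length(unique(map_chrom[pr])) > 1L ||
        (length(pp) > 1L && any(diff(pp) != 1L))) {
      excluded <- c(excluded, sprintf(
        "scaffold %s anchored to non-adjacent synteny positions; excluded", s))
      next
    }
    ## scaffold orientation relative to the map: flip when the anchor's
    ## alignment orientation disagrees with the protein's map orientation
    o_hit <- anchors$orientation[an_rows[[s]][1L]]
    o_map <- unname(map_orient[anchors$protein_id[an_rows[[s]][1L]]])
    scaf_pos[[s]] <- list(lo = pp[1L], hi = pp[length(pp)],
                          orientation = if (identical(o_hit, o_map)) "+" else "-",
                          chrom = unname(map_chrom[pr[1L]]))
  }
  if (!length(scaf_pos)) {
    return(list(scaffolds = scaffolds, joins = data.frame(), excluded = excluded))
  }
  ## one scaffold per map position; overlapping claims are excluded
  tab <- data.frame(scaffold = names(scaf_pos),
                    lo = vapply(scaf_pos, `[[`, 1, "lo"),
                    hi = vapply(scaf_pos, `[[`, 1, "hi"),
                    orientation = vapply(scaf_pos, `[[`, "", "orientation"),
                    chrom = vapply(scaf_pos, `[[`, "", "chrom"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$lo), , drop = FALSE]
  drop <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(tab))[-1L]) {
    if (tab$chrom[i] == tab$chrom[i - 1L] && !drop[i - 1L] &&
        tab$lo[i] <= tab$hi[i - 1L]) {
      drop[i] <- TRUE
      excluded <- c(excluded, sprintf(
        "scaffold %s overlaps the map positions of %s; excluded",
        tab$scaffold[i], tab$scaffold[i - 1L]))
    }
  }
  tab <- tab[!drop, , drop = FALSE]
  ## chain scaffolds anchored to conserved-adjacent proteins
  out <- scaffolds
  joins <- list()
  for (ch in unique(tab$chrom)) {
    t2 <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(t2) < 2L) next
    ## chain only across conserved-adjacent map positions
    brk <- c(0L, which(t2$lo[-1L] != t2$hi[-nrow(t2)] + 1L), nrow(t2))
    for (b in seq_len(length(brk) - 1L)) {
      idx <- (brk[b] + 1L):brk[b + 1L]
      if (length(idx) < 2L) next
      g <- t2[idx, , drop = FALSE]
      parts <- vapply(seq_len(nrow(g)), function(i) {
        s <- out[[g$scaffold[i]]]
        if (g$orientation[i] == "-") revcomp(s) else s
      }, "")
      super_id <- sprintf("super_%s_%d", ch, b)
      out <- out[!names(out) %in% g$scaffold]
      out[super_id] <- paste(parts, collapse = strrep("N", n_spacer))
      joins[[super_id]] <- data.frame(super_scaffold = super_id,
                                      part = seq_len(nrow(g)),
                                      scaffold = g$scaffold,
                                      orientation = g$orientation,
                                      stringsAsFactors = FALSE)
    }
  }
  joins <- if (length(joins)) do.call(rbind, joins) else data.frame()
  rownames(joins) <- NULL
  list(scaffolds = out, joins = joins, excluded = excluded)
}

#' Assembly length statistics (total, count, N50)
#'
#' N50 is the largest scaffold length L such that scaffolds of length >= L
#' hold at least half the total assembly length; it is always a member of
#' the input length multiset.
#'
#' @param lengths positive numeric vector of scaffold lengths
#' @return list: total, count, n50
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length set")
  stopifnot(all(lengths > 0))
  l <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(l)
  list(total = sum(l), count = length(l),
       n50 = l[which(cum >= sum(l) / 2)[1L]])
}

#' Assign scaffolds to reference chromosomes
#'
#' Each scaffold takes the chromosome of its top hit ranked by the ratio of
#' identical bases to aligned span (identity x span / span = identity here,
#' computed as identity when `identical_bases` is absent).
#'
#' @param hits data.frame: scaffold_id, chrom (reference chromosome of the
#'   hit), identity, scaf_start, scaf_end; optionally identical_bases
#' @return data.frame: scaffold_id, chrom (NA when no hit), rank_ratio
#' @export
assign_chromosomes <- function(hits) {
  span <- abs(hits$scaf_end - hits$scaf_start) + 1L
  ident <- if (!is.null(hits$identical_bases)) hits$identical_bases else
    hits$identity * span
  ratio <- ident / span
  o <- order(hits$scaffold_id, -ratio)
  h <- hits[o, , drop = FALSE]
  r <- ratio[o]
  first <- !duplicated(h$scaffold_id)
  data.frame(scaffold_id = h$scaffold_id[first], chrom = h$chrom[first],
             rank_ratio = r[first], stringsAsFactors = FALSE)
}
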