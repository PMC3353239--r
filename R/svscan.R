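## Mate-pair-violation structural-variant scanner.
##
## Classification contract: a uniquely mapped pair is an anomaly when its
## mates sit on different chromosomes (interlocus), align reverse-forward
## (tandem-duplication signature), or span more/less than the library insert
## size by three standard deviations (deletion/insertion evidence). An SV
## call requires at least three concordant anomalous pairs.

#' Structural-variant scan parameters
#'
#' @param ins an [insert_spec()] describing the library
#' @param sd_multiplier span anomaly threshold in insert-size SDs (default 3)
#' @param min_support minimum concordant anomalous pairs per call (default 3)
#' @param cluster_window clustering window for supporting-pair breakpoints,
#'   bp; default mean + 3 sd of the insert (supporting pairs of one event
#'   cannot spread farther)
#' @param dispersed_distance same-chromosome distance beyond which a long
#'   span is treated as dispersed-duplication rather than deletion evidence
#'   (default 10 x insert mean)
#' @return object of class `sv_params`
#' @export
sv_params <- function(ins = insert_spec(), sd_multiplier = 3, min_support = 3L,
                      cluster_window = NULL, dispersed_distance = NULL) {
  stopifnot(min_support >= 1L, sd_multiplier > 0)
  if (is.null(cluster_window)) cluster_window <- ins$mean + 3 * ins$sd
  if (is.null(dispersed_distance)) dispersed_distance <- 10 * ins$mean
  structure(list(ins = ins, sd_multiplier = sd_multiplier,
                 min_support = as.integer(min_support),
                 cluster_window = cluster_window,
                 dispersed_distance = dispersed_distance),
            class = "sv_params")
}

#' Classify mate pairs into anomaly classes
#'
#' Precedence: different chromosomes -> `interlocus`; reverse-forward
#' orientation -> `rf_orientation`; same-strand mates -> `ff_orientation`
#' (inversion evidence, counted but not called); span > mean + k sd ->
#' `long_span`; span < mean - k sd -> `short_span`; otherwise `normal`.
#'
#' @param pairs PairAlignment data.frame ([align_pairs()]); only mapped,
#'   unique pairs are classified, others get NA
#' @param params an [sv_params()]
#' @return the input with an `anomaly` column added
#' @export
classify_pairs <- function(pairs, params = sv_params()) {
  mean_ <- params$ins$mean; sd_ <- params$ins$sd; k <- params$sd_multiplier
  cls <- rep(NA_character_, nrow(pairs))
  ok <- pairs$mapped & pairs$unique
  oc <- pairs$orientation_class
  cls[ok] <- ifelse(oc[ok] == "interlocus", "interlocus",
             ifelse(oc[ok] == "RF", "rf_orientation",
             ifelse(oc[ok] == "FF", "ff_orientation",
             ifelse(pairs$span[ok] > mean_ + k * sd_, "long_span",
             ifelse(pairs$span[ok] < mean_ - k * sd_, "short_span", "normal")))))
  pairs$anomaly <- cls
  pairs
}

## greedy 1-D clustering of sorted positions within a window; returns group ids
cluster_1d <- function(pos, window) {
  if (!length(pos)) return(integer(0))
  grp <- integer(length(pos))
  g <- 1L
  anchor <- pos[1L]
  grp[1L] <- 1L
  for (i in seq_along(pos)[-1L]) {
    if (pos[i] - anchor > window) {
      g <- g + 1L
      anchor <- pos[i]
    }
    grp[i] <- g
  }
  grp
}

#' Cluster anomalous pairs into structural-variant calls
#'
#' Same-type anomalies whose implied breakpoints lie within
#' `cluster_window` are merged; calls with fewer than `min_support`
#' supporting pairs are discarded. Intervals: a deletion spans from the
#' left-most inner mate end to the right-most inner mate start among
#' supporting pairs; a tandem duplication spans the RF-implied duplicated
#' unit (left-most reverse-mate start to right-most forward-mate end); an
#' insertion is reported at the clustered inner-gap midpoint; a dispersed
#' duplication anchors the clustered locus of its first mate. Long spans
#' beyond `dispersed_distance`, and interlocus pairs, are dispersed-
#' duplication evidence.
#'
#' @param pairs classified pairs from [classify_pairs()]
#' @param params an [sv_params()]
#' @param read_len read length used for inner coordinates (inferred from
#'   span and positions when NULL is not supplied)
#' @return SvCall data.frame: type, chrom, start, end (0-based half-open),
#'   support
#' @export
cluster_anomalies <- function(pairs, params = sv_params(), read_len = 100L) {
  p <- pairs[!is.na(pairs$anomaly) &
             !pairs$anomaly %in% c("normal", "ff_orientation"), , drop = FALSE]
  calls <- list()
  add_call <- function(type, chrom, start, end, support) {
    calls[[length(calls) + 1L]] <<- data.frame(
      type = type, chrom = chrom, start = start, end = end,
      support = support, stringsAsFactors = FALSE)
  }
  ## geometry helpers on same-chromosome pairs
  left_start <- pmin(p$pos1, p$pos2)
  right_start <- pmax(p$pos1, p$pos2)
  inner_lo <- left_start + read_len   # end of the left mate
  inner_hi <- right_start             # start of the right mate

  ## --- deletions: long spans below the dispersed-distance cutoff ---
  sel <- which(p$anomaly == "long_span" & p$span <= params$dispersed_distance)
  if (length(sel)) {
    o <- sel[order(p$chrom1[sel], inner_lo[sel])]
    for (ch in unique(p$chrom1[o])) {
      i <- o[p$chrom1[o] == ch]
      grp <- cluster_1d(inner_lo[i], params$cluster_window)
      for (g in split(i, grp)) {
        if (length(g) < params$min_support) next
        add_call("deletion", ch, min(inner_lo[g]), max(inner_hi[g]), length(g))
      }
    }
  }
  ## --- insertions: short spans ---
  sel <- which(p$anomaly == "short_span")
  if (length(sel)) {
    mid <- (inner_lo[sel] + inner_hi[sel]) %/% 2L
    o <- order(p$chrom1[sel], mid)
    sel <- sel[o]; mid <- mid[o]
    for (ch in unique(p$chrom1[sel])) {
      i <- which(p$chrom1[sel] == ch)
      grp <- cluster_1d(mid[i], params$cluster_window)
      for (g in split(i, grp)) {
        if (length(g) < params$min_support) next
        m <- round(mean(mid[g]))
        add_call("insertion", ch, m, m + 1L, length(g))
      }
    }
  }
  ## --- tandem duplications: RF pairs ---
  sel <- which(p$anomaly == "rf_orientation")
  if (length(sel)) {
    ## the reverse mate marks the duplication-unit start, the forward mate
    ## (to its right) lies near the unit end
    rev_start <- ifelse(p$strand1[sel] == "-", p$pos1[sel], p$pos2[sel])
    fwd_end <- ifelse(p$strand1[sel] == "+", p$pos1[sel], p$pos2[sel]) + read_len
    o <- order(p$chrom1[sel], rev_start)
    sel <- sel[o]; rev_start <- rev_start[o]; fwd_end <- fwd_end[o]
    for (ch in unique(p$chrom1[sel])) {
      i <- which(p$chrom1[sel] == ch)
      grp <- cluster_1d(rev_start[i], params$cluster_window)
      for (g in split(i, grp)) {
        if (length(g) < params$min_support) next
        add_call("tandem_duplication", ch, min(rev_start[g]), max(fwd_end[g]),
                 length(g))
      }
    }
  }
  ## --- dispersed duplications: interlocus or very long same-chromosome ---
  sel <- which(p$anomaly == "interlocus" |
               (p$anomaly == "long_span" & p$span > params$dispersed_distance))
  if (length(sel)) {
    chA <- p$chrom1[sel]; posA <- p$pos1[sel]
    chB <- p$chrom2[sel]; posB <- p$pos2[sel]
    o <- order(chA, posA)
    sel <- sel[o]; chA <- chA[o]; posA <- posA[o]; chB <- chB[o]; posB <- posB[o]
    for (ch in unique(chA)) {
      i <- which(chA == ch)
      grp <- cluster_1d(posA[i], params$cluster_window)
      for (g in split(i, grp)) {
        ## the partner ends must also co-locate (one common source locus)
        kk <- g[chB[g] == chB[g[1L]] &
                abs(posB[g] - posB[g[1L]]) <= params$cluster_window]
        if (length(kk) < params$min_support) next
        add_call("dispersed_duplication", ch, min(posA[kk]),
                 max(posA[kk]) + read_len, length(kk))
      }
    }
  }
  res <- if (length(calls)) do.call(rbind, calls) else data.frame(
    type = character(0), chrom = character(0), start = integer(0),
    end = integer(0), support = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag SV calls overlapping protein-coding sequence
#'
#' @param svs SvCall data.frame
#' @param genes gene-model data.frame
#' @return `svs` with a logical `cds_overlap` column (>= 1 bp intersection
#'   with any CDS)
#' @export
annotate_cds_overlap <- function(svs, genes) {
  svs$cds_overlap <- FALSE
  if (!nrow(svs)) return(svs)
  for (ch in unique(svs$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    i <- which(svs$chrom == ch)
    if (!nrow(g)) next
    cds <- IRanges::IRanges(g$cds_start, g$cds_end)
    ## svs are 0-based half-open; convert to 1-based inclusive
    iv <- IRanges::IRanges(svs$start[i] + 1L, pmax(svs$start[i] + 1L, svs$end[i]))
    svs$cds_overlap[i] <- IRanges::overlapsAny(iv, cds)
  }
  svs
}

#' Male/female SV ratio report
#'
#' @param male_svs,female_svs SvCall data.frames produced with identical
#'   [sv_params()]
#' @param male_pairs,female_pairs classified pairs (for violation rates);
#'   optional
#' @return list with `counts` (per chromosome x type: male, female, ratio;
#'   a female count of 0 yields an infinite-ratio marker, not an error),
#'   `cds_overlap` (per chromosome: percent of tandem duplications
#'   overlapping CDS, per sex) and `violation` (per sex: anomalous pairs /
#'   mapped pairs)
#' @export
mf_ratio_report <- function(male_svs, female_svs,
                            male_pairs = NULL, female_pairs = NULL) {
  types <- c("insertion", "deletion", "tandem_duplication", "dispersed_duplication")
  chroms <- sort(unique(c(male_svs$chrom, female_svs$chrom)))
  grid <- expand.grid(chrom = chroms, type = types, stringsAsFactors = FALSE)
  cnt <- function(svs, ch, ty) sum(svs$chrom == ch & svs$type == ty)
  grid$male <- mapply(cnt, list(male_svs)[rep(1, nrow(grid))], grid$chrom, grid$type)
  grid$female <- mapply(cnt, list(female_svs)[rep(1, nrow(grid))], grid$chrom, grid$type)
  grid$ratio <- ifelse(grid$female > 0, grid$male / grid$female,
                       ifelse(grid$male > 0, Inf, NA))
  ov <- NULL
  if (!is.null(male_svs$cds_overlap) && !is.null(female_svs$cds_overlap)) {
    pct <- function(svs, ch) {
      td <- svs[svs$chrom == ch & svs$type == "tandem_duplication", , drop = FALSE]
      if (!nrow(td)) NA_real_ else 100 * mean(td$cds_overlap)
    }
    ov <- data.frame(chrom = chroms,
                     male_pct = vapply(chroms, function(ch) pct(male_svs, ch), 1),
                     female_pct = vapply(chroms, function(ch) pct(female_svs, ch), 1),
                     stringsAsFactors = FALSE)
  }
  viol <- NULL
  vrate <- function(pairs) {
    ok <- pairs$mapped & pairs$unique
    if (!sum(ok)) return(NA_real_)
    sum(!pairs$anomaly[ok] %in% "normal") / sum(ok)
  }
  if (!is.null(male_pairs) && !is.null(female_pairs)) {
    viol <- data.frame(sex = c("male", "female"),
                       violation_rate = c(vrate(male_pairs), vrate(female_pairs)),
                       stringsAsFactors = FALSE)
  }
  list(counts = grid, cds_overlap = ov, violation = viol)
}
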