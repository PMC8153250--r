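#' @title Promoter chromatin quantification
#' @description Window-based histone-mark scoring around proximal TSSs
#'   (summed fold enrichment over 50 bp upstream and 500 bp downstream),
#'   replicate-averaged fold changes between timepoints, transcription
#'   factor target calling from peak files (a qualifying peak with linear
#'   enrichment above 4, i.e. log2 > 2, with its summit within 300 bp of the
#'   TSS, in at least 2 of 3 replicates), and metagene matrices.
#' @name chromatin_promoter
NULL

#' Promoter window score for a chromatin mark
#'
#' Sums per-bp fold enrichment over the 50 bases 5' of the TSS (`up_sum`)
#' and the 500 bases from the TSS 3'-ward (`down_sum`), strand-aware, and
#' forms their ratio. The default orientation is `down_sum / up_sum`, so
#' that a gain of mark downstream of the proximal TSS increases the score;
#' set `orientation = "up_over_down"` for the inverse. Uncovered bases count
#' as 0; a zero denominator yields an `NA` ratio (the gene is excluded from
#' fold changes).
#'
#' @param track fold-enrichment [signal_track()] (unstranded).
#' @param chrom chromosome.
#' @param tss 0-based TSS position.
#' @param strand gene strand, `"+"` or `"-"`.
#' @param up_width,down_width window widths in bp (defaults 50 and 500).
#' @param orientation `"down_over_up"` (default) or `"up_over_down"`.
#' @return list with `up_sum`, `down_sum`, `ratio`.
#' @export
promoter_mark_score <- function(track, chrom, tss, strand,
                                up_width = 50L, down_width = 500L,
                                orientation = c("down_over_up",
                                                "up_over_down")) {
  orientation <- match.arg(orientation)
  if (strand == "+") {
    up <- track_window_sum(track, chrom, tss - up_width, tss)
    down <- track_window_sum(track, chrom, tss, tss + down_width)
  } else {
    up <- track_window_sum(track, chrom, tss + 1L, tss + 1L + up_width)
    down <- track_window_sum(track, chrom, tss + 1L - down_width, tss + 1L)
  }
  num <- if (orientation == "down_over_up") down else up
  den <- if (orientation == "down_over_up") up else down
  list(up_sum = up, down_sum = down,
       ratio = if (den == 0) NA_real_ else num / den)
}

#' Replicate-mean fold change of the promoter score
#'
#' Per replicate, `fc = ratio_b / ratio_a` (timepoint b over a; here the
#' meiotic over the premeiotic score); the result is the arithmetic mean
#' over replicates with both timepoints defined. Missing replicates reduce
#' the averaging set.
#'
#' @param ratio_a,ratio_b promoter-score ratios per replicate at the two
#'   timepoints (equal-length numeric vectors; `NA` allowed).
#' @return the replicate-mean fold change (`NA` when no replicate is
#'   complete).
#' @export
mark_fold_change <- function(ratio_a, ratio_b) {
  stopifnot(length(ratio_a) == length(ratio_b))
  fc <- ratio_b / ratio_a
  fc[!is.finite(fc)] <- NA_real_
  if (all(is.na(fc))) return(NA_real_)
  mean(fc, na.rm = TRUE)
}

#' Promoter-mark fold-change table for a set of genes
#'
#' Convenience wrapper applying [promoter_mark_score()] and
#' [mark_fold_change()] across genes, marks and replicate track pairs.
#'
#' @param tracks list of fold-enrichment tracks whose `sample` metadata is
#'   unused but whose `timepoint` and `replicate` fields identify the
#'   timepoint/replicate of each track; names are free.
#' @param anchors data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param timepoint_a,timepoint_b timepoint labels.
#' @inheritParams promoter_mark_score
#' @return data.table with `gene_id` and `fc_mean`.
#' @export
promoter_mark_table <- function(tracks, anchors,
                                timepoint_a = "premeiotic",
                                timepoint_b = "meiotic",
                                up_width = 50L, down_width = 500L,
                                orientation = "down_over_up") {
  anchors <- as.data.table(anchors)
  tps <- vapply(tracks, function(t) t$timepoint, character(1))
  reps <- vapply(tracks, function(t) as.integer(t$replicate), integer(1))
  rep_ids <- sort(unique(reps))
  ratios <- function(tp, i) {
    tr <- tracks[tps == tp & reps == rep_ids[i]]
    if (!length(tr)) return(rep(NA_real_, nrow(anchors)))
    vapply(seq_len(nrow(anchors)), function(g)
      promoter_mark_score(tr[[1L]], anchors$chrom[g], anchors$tss[g],
                          anchors$strand[g], up_width, down_width,
                          orientation)$ratio, numeric(1))
  }
  ra <- sapply(seq_along(rep_ids), function(i) ratios(timepoint_a, i))
  rb <- sapply(seq_along(rep_ids), function(i) ratios(timepoint_b, i))
  ra <- matrix(ra, nrow = nrow(anchors)); rb <- matrix(rb, nrow = nrow(anchors))
  fc <- vapply(seq_len(nrow(anchors)), function(g)
    mark_fold_change(ra[g, ], rb[g, ]), numeric(1))
  data.table(gene_id = anchors$gene_id, fc_mean = fc)
}

#' Transcription-factor target call from replicate peak files
#'
#' A replicate qualifies when it contains at least one peak whose log2
#' enrichment over input exceeds `min_log2_enrichment` and whose summit lies
#' within `max_dist` bp of the TSS; the promoter is a target when at least
#' `min_replicates` replicates qualify.
#'
#' @param peaks_by_rep list of [read_narrowpeak()] tables, one per replicate.
#' @param chrom,tss promoter location (0-based TSS).
#' @param max_dist summit-to-TSS distance bound in bp (default 300).
#' @param min_log2_enrichment strict threshold on `log2(signalValue)`
#'   (default 2, i.e. linear enrichment > 4).
#' @param min_replicates replicates required (default 2).
#' @return list with `is_target`, `n_qualifying` and `nearest_dist`
#'   (per-replicate summit distance of the best qualifying peak, `NA` when
#'   none).
#' @export
tf_target_call <- function(peaks_by_rep, chrom, tss, max_dist = 300L,
                           min_log2_enrichment = 2, min_replicates = 2L) {
  per <- vapply(peaks_by_rep, function(pk) {
    pk <- as.data.table(pk)
    sel <- pk$chrom == chrom & log2(pk$signalValue) > min_log2_enrichment
    pk <- pk[sel, ]
    if (!nrow(pk)) return(NA_real_)
    d <- abs(pk$summit - tss)
    min(d)
  }, numeric(1))
  qual <- !is.na(per) & per <= max_dist
  list(is_target = sum(qual) >= min_replicates, n_qualifying = sum(qual),
       nearest_dist = per)
}

#' Metagene matrix around anchor positions
#'
#' Extracts per-bp track values over `tss - flank .. tss + flank` for every
#' anchor, oriented so that upstream is always on the left (minus-strand
#' rows are reversed). Rows extending past a contig end are padded with
#' `NA`; the column-mean profile ignores missing values.
#'
#' @param track a [signal_track()].
#' @param anchors data.frame with `chrom`, `pos`, `strand`.
#' @param flank half-window in bp.
#' @param chrom_sizes optional named vector of contig lengths for edge
#'   padding (otherwise rows are taken as-is, uncovered bases = 0).
#' @return numeric matrix (anchors x 2*flank+1) with columns `-flank..flank`
#'   and attribute `profile` (column means ignoring `NA`).
#' @export
metagene_matrix <- function(track, anchors, flank = 500L,
                            chrom_sizes = NULL) {
  anchors <- as.data.table(anchors)
  w <- 2L * flank + 1L
  mat <- matrix(NA_real_, nrow = nrow(anchors), ncol = w,
                dimnames = list(NULL, as.character(-flank:flank)))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]; p <- anchors$pos[i]
    from <- p - flank; to <- p + flank + 1L
    vals <- track_window_values(track, ch, max(0L, from), to)
    if (from < 0L) vals <- c(rep(NA_real_, -from), vals)
    if (!is.null(chrom_sizes) && to > chrom_sizes[[ch]]) {
      over <- to - chrom_sizes[[ch]]
      vals[(w - over + 1L):w] <- NA_real_
    }
    if (anchors$strand[i] == "-") vals <- rev(vals)
    mat[i, ] <- vals
  }
  attr(mat, "profile") <- colMeans(mat, na.rm = TRUE)
  mat
}
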