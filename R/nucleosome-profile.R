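#' @title Nucleosome calling and repositioning features
#' @description A defined, dependency-free nucleosome caller on dyad
#'   coverage: Gaussian-kernel smoothing of dyad counts, greedy acceptance
#'   of local density maxima under a minimum-spacing constraint, occupancy
#'   (summed dyads within +/-73 bp) and fuzziness (weighted standard
#'   deviation of dyad positions within +/-73 bp). Downstream: +1/-1
#'   assignment relative to proximal TSSs and between-timepoint shift and
#'   fuzziness-change features. The caller is a documented stand-in for
#'   DANPOS-style callers: it preserves the three reported quantities
#'   (position, occupancy, fuzziness) without reproducing their scores
#'   numerically.
#' @name nucleosome_profile
NULL

#' Call nucleosomes from a dyad-count track
#'
#' Dyad counts are smoothed with a Gaussian kernel (sd `smoothing_bw`,
#' truncated at 4 sd). Local maxima of the smoothed density are accepted
#' greedily in decreasing density order, subject to a minimum spacing;
#' occupancy and fuzziness are then computed from the raw dyads within
#' +/-73 bp (one nucleosome half-width) of each accepted position, and
#' calls below `min_occupancy` raw dyads are dropped.
#'
#' @param dyads unstranded dyad-count [signal_track()].
#' @param smoothing_bw Gaussian kernel sd in bp (default 15).
#' @param min_spacing minimum distance between accepted calls in bp
#'   (default 120).
#' @param min_occupancy minimum raw dyad count within +/-73 bp (default 20).
#' @param half_width window half-width for occupancy/fuzziness (default 73).
#' @return data.table of calls: `chrom`, `dyad_pos`, `occupancy`,
#'   `fuzziness`, `density`, sorted by position.
#' @export
call_nucleosomes <- function(dyads, smoothing_bw = 15, min_spacing = 120L,
                             min_occupancy = 20, half_width = 73L) {
  stopifnot(inherits(dyads, "SignalTrack"))
  empty <- data.table(chrom = character(), dyad_pos = integer(),
                      occupancy = numeric(), fuzziness = numeric(),
                      density = numeric())
  if (!nrow(dyads$runs)) return(empty)
  half_k <- as.integer(ceiling(4 * smoothing_bw))
  kernel <- stats::dnorm(-half_k:half_k, sd = smoothing_bw)
  out <- lapply(split(dyads$runs, dyads$runs$chrom), function(runs) {
    lo <- min(runs$start) - half_k
    hi <- max(runs$end) + half_k
    v <- numeric(hi - lo)
    for (i in seq_len(nrow(runs)))
      v[(runs$start[i] - lo + 1L):(runs$end[i] - lo)] <- v[(runs$start[i] - lo + 1L):(runs$end[i] - lo)] + runs$value[i]
    dens <- as.numeric(stats::filter(v, kernel, sides = 2))
    dens[is.na(dens)] <- 0
    n <- length(dens)
    is_max <- dens > 0 &
      dens > c(-Inf, dens[-n]) &
      dens >= c(dens[-1L], -Inf)
    peaks <- which(is_max)
    if (!length(peaks)) return(NULL)
    ord <- peaks[order(dens[peaks], decreasing = TRUE)]
    accepted <- integer(0)
    for (p in ord) {
      if (!length(accepted) || all(abs(accepted - p) >= min_spacing))
        accepted <- c(accepted, p)
    }
    accepted <- sort(accepted)
    pos <- lo + accepted - 1L
    occ <- numeric(length(pos)); fuzz <- numeric(length(pos))
    for (j in seq_along(pos)) {
      a <- pos[j] - lo - half_width + 1L
      b <- pos[j] - lo + half_width + 1L
      idx <- max(1L, a):min(length(v), b)
      w <- v[idx]
      p_at <- lo + idx - 1L
      occ[j] <- sum(w)
      if (occ[j] > 0) {
        mu <- sum(w * p_at) / sum(w)
        fuzz[j] <- sqrt(sum(w * (p_at - mu)^2) / sum(w))
      }
    }
    keep <- occ >= min_occupancy
    if (!any(keep)) return(NULL)
    data.table(chrom = runs$chrom[1L], dyad_pos = pos[keep],
               occupancy = occ[keep], fuzziness = fuzz[keep],
               density = dens[accepted][keep])
  })
  out <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (!nrow(out)) return(empty)
  setorder(out, chrom, dyad_pos)
  out[]
}

#' Assign +1 and -1 nucleosomes relative to a TSS
#'
#' The +1 nucleosome is the call with the smallest dyad position strictly 3'
#' of the TSS (strand-aware) within `max_lookout` bp; the -1 nucleosome is
#' the nearest call strictly 5' within the same lookout. Either may be
#' absent.
#'
#' @param calls nucleosome-call table from [call_nucleosomes()].
#' @param chrom,tss,strand promoter location.
#' @param max_lookout search window in bp (default 500).
#' @return list with `plus_one` and `minus_one` (one-row data.tables or
#'   `NULL`).
#' @export
assign_flanking <- function(calls, chrom, tss, strand, max_lookout = 500L) {
  calls <- as.data.table(calls)
  sel <- calls$chrom == chrom        # hoisted: avoid NSE capture of `chrom`
  cc <- calls[sel, ]
  rel <- if (strand == "+") cc$dyad_pos - tss else tss - cc$dyad_pos
  down <- which(rel > 0 & rel <= max_lookout)
  up <- which(rel < 0 & rel >= -max_lookout)
  plus_one <- if (length(down)) cc[down[which.min(rel[down])]] else NULL
  minus_one <- if (length(up)) cc[up[which.max(rel[up])]] else NULL
  list(plus_one = plus_one, minus_one = minus_one)
}

#' Between-timepoint nucleosome shift and fuzziness change
#'
#' The shift is the strand-oriented signed displacement of the dyad between
#' timepoints: negative when the nucleosome moves toward the TSS (into the
#' nucleosome-depleted region). Fuzziness change is timepoint b minus
#' timepoint a.
#'
#' @param flank_a,flank_b [assign_flanking()] results at the two timepoints
#'   (a = premeiotic, b = meiotic).
#' @param strand gene strand.
#' @param which_one `"plus_one"` or `"minus_one"`.
#' @return list with `shift` and `fuzziness_change` (`NA` when the call is
#'   missing at either timepoint).
#' @export
nucleosome_shift <- function(flank_a, flank_b, strand,
                             which_one = "plus_one") {
  a <- flank_a[[which_one]]; b <- flank_b[[which_one]]
  if (is.null(a) || is.null(b))
    return(list(shift = NA_real_, fuzziness_change = NA_real_))
  s <- if (strand == "+") 1 else -1
  list(shift = s * (b$dyad_pos - a$dyad_pos),
       fuzziness_change = b$fuzziness - a$fuzziness)
}

#' Nucleosome repositioning features for a set of promoters
#'
#' @param calls_a,calls_b nucleosome calls at the two timepoints.
#' @param anchors data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @param max_lookout +1/-1 search window in bp.
#' @return data.table with per-gene `plus_one_shift`,
#'   `plus_one_fuzziness_change`, `minus_one_shift`,
#'   `minus_one_fuzziness_change`.
#' @export
nucleosome_feature_table <- function(calls_a, calls_b, anchors,
                                     max_lookout = 500L) {
  anchors <- as.data.table(anchors)
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    ch <- anchors$chrom[i]; t <- anchors$tss[i]; s <- anchors$strand[i]
    fa <- assign_flanking(calls_a, ch, t, s, max_lookout)
    fb <- assign_flanking(calls_b, ch, t, s, max_lookout)
    p <- nucleosome_shift(fa, fb, s, "plus_one")
    m <- nucleosome_shift(fa, fb, s, "minus_one")
    data.table(gene_id = anchors$gene_id[i],
               plus_one_shift = p$shift,
               plus_one_fuzziness_change = p$fuzziness_change,
               minus_one_shift = m$shift,
               minus_one_fuzziness_change = m$fuzziness_change)
  })
  rbindlist(rows)
}
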