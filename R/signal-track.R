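#' Signal tracks
#'
#' A `SignalTrack` holds a per-base, non-negative genomic signal (5'-end tag
#' counts, ribosome-footprint 5' counts, ChIP fold enrichment, or nucleosome
#' dyad counts) as a set of non-overlapping runs in 0-based half-open
#' coordinates. Absent positions are implicitly 0. Strand is meaningful for
#' 5'-end and footprint tracks (`"+"`/`"-"`) and `"."` for unstranded
#' ChIP/MNase tracks.
#'
#' @param runs data.frame/data.table with columns `chrom`, `start`, `end`,
#'   `value` (0-based half-open; `value >= 0`).
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param units free-text units tag (e.g. `"tags"`, `"fold_enrichment"`,
#'   `"dyads"`).
#' @param sample,timepoint,replicate optional sample metadata.
#' @return an object of class `SignalTrack`.
#' @examples
#' tr <- signal_track(data.frame(chrom = "chr1", start = 10L, end = 12L,
#'                               value = 3), strand = "+", units = "tags")
#' track_window_sum(tr, "chr1", 0, 100) # 6
#' @export
signal_track <- function(runs, strand = ".", units = "signal",
                         sample = NA_character_, timepoint = NA_character_,
                         replicate = NA_integer_) {
  stopifnot(strand %in% c("+", "-", "."))
  dt <- as.data.table(runs)
  if (nrow(dt) == 0L) {
    dt <- data.table(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
  }
  required <- c("chrom", "start", "end", "value")
  if (!all(required %in% names(dt)))
    stop("runs must have columns chrom, start, end, value")
  dt <- dt[, required, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start),
            end = as.integer(end), value = as.numeric(value))]
  if (nrow(dt)) {
    if (any(dt$start < 0L) || any(dt$end <= dt$start))
      stop("invalid interval: need 0 <= start < end")
    if (any(dt$value < 0)) stop("SignalTrack values must be >= 0")
    setorder(dt, chrom, start)
    ov <- dt[, any(start[-1L] < end[-.N]), by = chrom]$V1
    if (any(ov)) stop("overlapping runs in SignalTrack")
  }
  structure(list(runs = dt, strand = strand, units = units, sample = sample,
                 timepoint = timepoint, replicate = replicate),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack [%s] strand=%s units=%s: %d runs on %d sequence(s)\n",
              ifelse(is.na(x$sample), "-", x$sample), x$strand, x$units,
              nrow(x$runs), length(unique(x$runs$chrom))))
  invisible(x)
}

#' Sum of a track over a window
#'
#' @param track a [signal_track()].
#' @param chrom sequence name.
#' @param start,end window, 0-based half-open.
#' @return total signal (value times covered bases) in the window.
#' @export
track_window_sum <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "SignalTrack"), end >= start)
  sel <- track$runs$chrom == chrom   # hoisted: avoid NSE capture of `chrom`
  dt <- track$runs[sel]
  if (!nrow(dt)) return(0)
  ov <- pmin(dt$end, end) - pmax(dt$start, start)
  sum(dt$value[ov > 0] * ov[ov > 0])
}

#' Dense per-base values of a track over a window
#'
#' Uncovered bases are 0; bases outside the window are not returned. The
#' window may extend past the covered span (padded with 0).
#'
#' @inheritParams track_window_sum
#' @return numeric vector of length `end - start`, element i giving the value
#'   at base `start + i - 1`.
#' @export
track_window_values <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "SignalTrack"), end >= start)
  out <- numeric(end - start)
  sel <- track$runs$chrom == chrom
  dt <- track$runs[sel]
  if (!nrow(dt)) return(out)
  s <- pmax(dt$start, start); e <- pmin(dt$end, end)
  keep <- which(e > s)
  for (i in keep) out[(s[i] - start + 1L):(e[i] - start)] <- dt$value[i]
  # note: runs are half-open, hence (s - start + 1) .. (e - start)
  out
}

#' Per-position (single-base) representation of a track
#'
#' Expands runs into one row per covered base; practical only for sparse
#' tag/dyad tracks.
#'
#' @param track a [signal_track()].
#' @return data.table with columns `chrom`, `pos`, `value`.
#' @export
track_positions <- function(track) {
  dt <- track$runs
  if (!nrow(dt)) return(data.table(chrom = character(), pos = integer(),
                                   value = numeric()))
  n <- dt$end - dt$start
  data.table(chrom = rep(dt$chrom, n),
             pos = unlist(lapply(seq_len(nrow(dt)),
                                 function(i) dt$start[i]:(dt$end[i] - 1L))),
             value = rep(dt$value, n))
}

# Build a single-base-run track from a per-position count table.
positions_to_track <- function(pos_dt, strand = ".", units = "tags", ...) {
  if (!nrow(pos_dt)) return(signal_track(NULL, strand = strand, units = units, ...))
  dt <- as.data.table(pos_dt)[, .(value = sum(value)), by = .(chrom, pos)]
  dt <- dt[value > 0]
  signal_track(dt[, .(chrom, start = pos, end = pos + 1L, value)],
               strand = strand, units = units, ...)
}
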