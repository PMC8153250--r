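#' @title uORF inventory and translation calls
#' @description ATG counting in 5'-extended transcript leaders, per-uORF
#'   translation calls from ribosome-footprint 5' counts (at least
#'   `min_reads` footprints across the first `window_codons` codons), the
#'   first-2/last-2 uORF translation summary, the upstream ATG background
#'   frequency, and translational efficiency.
#' @name uorf_translation
NULL

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# 1-based substring of a 0-based half-open genomic interval
.gseq <- function(genome, chrom, start, end) {
  substr(genome[[chrom]], start + 1L, end)
}

#' Count leader ATGs between the distal and proximal TSS
#'
#' Scans the transcript-strand sequence of the leader (the region between
#' the distal LUTI TSS and the proximal TSS, distal included, proximal
#' excluded) for ATG occurrences at every offset, frame-agnostically.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome.
#' @param distal_tss,prox_tss 0-based TSS positions; the distal TSS must be
#'   5' of the proximal one on `strand`.
#' @param strand `"+"` or `"-"`.
#' @return list with `n_atg` and `uorf_starts` (genomic positions of the
#'   `A` of each ATG, in 5' to 3' transcript order).
#' @export
count_leader_atgs <- function(genome, chrom, distal_tss, prox_tss, strand) {
  if (strand == "+") {
    if (distal_tss >= prox_tss)
      stop("distal TSS must be 5' (left) of proximal TSS on +")
    txseq <- .gseq(genome, chrom, distal_tss, prox_tss)
  } else {
    if (distal_tss <= prox_tss)
      stop("distal TSS must be 5' (right) of proximal TSS on -")
    txseq <- .revcomp(.gseq(genome, chrom, prox_tss + 1L, distal_tss + 1L))
  }
  hits <- gregexpr("ATG", txseq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(list(n_atg = 0L, uorf_starts = integer()))
  off <- as.integer(hits) - 1L
  starts <- if (strand == "+") distal_tss + off else distal_tss - off
  list(n_atg = length(starts), uorf_starts = starts)
}

#' Is a uORF translated?
#'
#' A uORF is called translated when at least `min_reads` footprint 5' counts
#' fall across its first `window_codons` codons (the ATG codon is codon 1;
#' default 6 codons = 18 nt, threshold 4 reads).
#'
#' @param fp_track footprint [signal_track()] on the same strand as the uORF.
#' @param chrom chromosome.
#' @param uorf_start genomic position of the `A` of the uORF's ATG.
#' @param strand `"+"` or `"-"`.
#' @param min_reads minimum summed footprint count (inclusive).
#' @param window_codons codons scanned from the ATG.
#' @return logical flag.
#' @export
uorf_translated <- function(fp_track, chrom, uorf_start, strand,
                            min_reads = 4, window_codons = 6L) {
  w <- 3L * window_codons
  tot <- if (strand == "+")
    track_window_sum(fp_track, chrom, uorf_start, uorf_start + w)
  else
    track_window_sum(fp_track, chrom, uorf_start - w + 1L, uorf_start + 1L)
  tot >= min_reads
}

#' Per-gene uORF profiles for LUTI calls
#'
#' @param genome named character vector of chromosome sequences.
#' @param calls locus-call table ([discover_loci()]); only `luti_candidate`
#'   rows are profiled.
#' @param fp_tracks named list of footprint tracks, one per strand (names
#'   `"+"` and `"-"`), or a single unstranded-use track applied to both.
#' @inheritParams uorf_translated
#' @return data.table: `gene_id`, `chrom`, `strand`, `distal_tss`,
#'   `prox_tss`, `n_atg`, and list-columns `uorf_starts`, `translated`.
#' @export
uorf_profiles <- function(genome, calls, fp_tracks, min_reads = 4,
                          window_codons = 6L) {
  calls <- as.data.table(calls)[class == "luti_candidate"]
  if (inherits(fp_tracks, "SignalTrack"))
    fp_tracks <- list(`+` = fp_tracks, `-` = fp_tracks)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i]
    atg <- count_leader_atgs(genome, cl$chrom, cl$distal_tss, cl$prox_tss,
                             cl$strand)
    tr <- vapply(atg$uorf_starts, function(u)
      uorf_translated(fp_tracks[[cl$strand]], cl$chrom, u, cl$strand,
                      min_reads, window_codons), logical(1))
    data.table(gene_id = cl$gene_id, chrom = cl$chrom, strand = cl$strand,
               distal_tss = cl$distal_tss, prox_tss = cl$prox_tss,
               n_atg = atg$n_atg, uorf_starts = list(atg$uorf_starts),
               translated = list(tr))
  })
  rbindlist(rows)
}

#' Translation frequency of the first-2 and last-2 uORFs
#'
#' Over genes with at least `min_uorfs` uORFs (set `strict = TRUE` for a
#' strictly-greater-than threshold), the fraction of genes whose uORF at
#' rank 1, rank 2, penultimate and last position is called translated. For a
#' gene with exactly 4 uORFs, uORFs 1 and 2 count toward the first two and
#' uORFs 3 and 4 toward the last two.
#'
#' @param profiles output of [uorf_profiles()].
#' @param min_uorfs qualifying uORF count (default 4, inclusive).
#' @param strict if `TRUE`, require strictly more than `min_uorfs` uORFs.
#' @return named numeric of length 4 (`first_1`, `first_2`, `penultimate`,
#'   `last`) with attribute `n` (number of qualifying genes); a zero-length
#'   result with a warning when no gene qualifies.
#' @export
first_last_summary <- function(profiles, min_uorfs = 4L, strict = FALSE) {
  profiles <- as.data.table(profiles)
  q <- if (strict) profiles$n_atg > min_uorfs else profiles$n_atg >= min_uorfs
  profiles <- profiles[q]
  if (!nrow(profiles)) {
    warning("no gene qualifies for the first/last uORF summary")
    return(structure(numeric(0), n = 0L))
  }
  flags <- vapply(profiles$translated, function(tr) {
    n <- length(tr)
    c(first_1 = tr[1L], first_2 = tr[2L],
      penultimate = tr[n - 1L], last = tr[n])
  }, logical(4))
  structure(rowMeans(flags), n = nrow(profiles))
}

#' ATG background frequency upstream of non-LUTI TSSs
#'
#' Counts ATG occurrences on the gene strand within `window` bp 5' of each
#' TSS, divided by the scanned length. Windows truncated at a contig edge
#' are flagged.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tss data.frame with `chrom`, `pos`, `strand` (and optionally
#'   `gene_id`).
#' @param window upstream window in bp (default 500).
#' @return data.table with `n_atg`, `window_len`, `freq` (ATGs per bp) and
#'   `truncated` per input row.
#' @export
atg_background <- function(genome, tss, window = 500L) {
  tss <- as.data.table(tss)
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    ch <- tss$chrom[i]; p <- tss$pos[i]; s <- tss$strand[i]
    L <- nchar(genome[[ch]])
    if (s == "+") {
      from <- max(0L, p - window); to <- p
      seq <- .gseq(genome, ch, from, to)
    } else {
      from <- p + 1L; to <- min(L, p + 1L + window)
      seq <- .revcomp(.gseq(genome, ch, from, to))
    }
    wl <- nchar(seq)
    hits <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
    n <- if (hits[1L] == -1L) 0L else length(hits)
    data.table(chrom = ch, pos = p, strand = s, n_atg = n, window_len = wl,
               freq = n / wl, truncated = wl < window)
  })
  out <- rbindlist(rows)
  if ("gene_id" %in% names(tss)) out <- cbind(tss[, .(gene_id)], out)
  out
}

#' Reads per kilobase per million mapped reads
#'
#' @param reads read count on the feature.
#' @param feature_len_bp feature length in bp.
#' @param total_reads total mapped reads in the library.
#' @return RPKM value(s).
#' @export
rpkm <- function(reads, feature_len_bp, total_reads) {
  reads / (feature_len_bp / 1e3) / (total_reads / 1e6)
}

#' Translational efficiency
#'
#' Footprint RPKM over the CDS divided by transcript-abundance RPKM.
#' Undefined (NA, with a warning) when the transcript RPKM is zero.
#'
#' @param fp_rpkm ribosome-footprint RPKM.
#' @param rna_rpkm transcript RPKM.
#' @return TE value(s).
#' @export
translational_efficiency <- function(fp_rpkm, rna_rpkm) {
  out <- fp_rpkm / rna_rpkm
  if (any(rna_rpkm == 0)) {
    warning("zero transcript RPKM: TE undefined for some genes")
    out[rna_rpkm == 0] <- NA_real_
  }
  out
}
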