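#' @title 5'-extended isoform discovery
#' @description Finds transcription start events that are induced between
#'   two timepoints, validates them against long-read spans covering an
#'   entire neighboring CDS, requires a second CDS-proximal promoter on the
#'   same strand for a LUTI call, and classifies the remaining events as
#'   canonical, antisense, intragenic or intergenic.
#' @name isoform_discovery
NULL

#' 5' end of alignment spans
#'
#' @param spans data.frame with `start`, `end`, `strand` (0-based half-open).
#' @return integer vector of 5'-most covered bases (`start` on `+`,
#'   `end - 1` on `-`).
#' @export
read_five_prime <- function(spans) {
  ifelse(spans$strand == "+", spans$start, spans$end - 1L)
}

#' Induction filter for candidate clusters
#'
#' A cluster passes when the TPM mean over both timepoints exceeds
#' `min_mean_tpm` and the pseudocount log2 fold change (timepoint b over a)
#' exceeds `min_log2fc`; both inequalities are strict.
#'
#' @param mean_a,mean_b replicate-mean TPM at the two timepoints (vectors).
#' @param pseudocount TPM pseudocount for the fold change.
#' @param min_mean_tpm,min_log2fc strict thresholds (defaults 2 and 2).
#' @return logical vector.
#' @export
induction_filter <- function(mean_a, mean_b, pseudocount = 0.1,
                             min_mean_tpm = 2, min_log2fc = 2) {
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  (mean_a + mean_b) / 2 > min_mean_tpm & lfc > min_log2fc
}

#' Count long reads linking a TSS to a fully spanned CDS
#'
#' Counts same-strand reads whose 5' end lies within `near_window` bp of the
#' TSS and whose span contains the whole CDS interval.
#'
#' @param tss TSS position (0-based).
#' @param chrom,strand location of the TSS.
#' @param gene one-row data.frame with `start`, `end` (the CDS, 0-based
#'   half-open).
#' @param reads long-read spans ([read_bed6()] format).
#' @param near_window matching window around the TSS in bp.
#' @return integer count of supporting reads.
#' @export
spanning_read_check <- function(tss, chrom, strand, gene, reads,
                                near_window = 50L) {
  reads <- as.data.table(reads)
  sel <- reads$chrom == chrom & reads$strand == strand  # hoisted (NSE)
  r <- reads[sel]
  if (!nrow(r)) return(0L)
  near <- abs(read_five_prime(r) - tss) <= near_window
  sum(near & r$start <= gene$start & r$end >= gene$end)
}

# Strand-aware signed distance from a TSS to a CDS 5' end (positive when the
# CDS 5' end lies downstream of the TSS).
.dist_to_cds5 <- function(tss, gene_start, gene_end, strand) {
  if (strand == "+") gene_start - tss else tss - (gene_end - 1L)
}

#' Classify one induced transcription start event
#'
#' Decision cascade (strand-aware), applied to a candidate that already
#' passed the induction filter:
#' 1. a same-strand CDS is fully contained in at least one long read
#'    starting near this TSS *and* a second same-strand promoter-level
#'    cluster lies strictly between this TSS and the CDS 5' end:
#'    `luti_candidate`;
#' 2. same spanning evidence but no closer downstream promoter: `canonical`;
#' 3. TSS inside a gene body on the opposite strand: `antisense`;
#' 4. TSS inside a gene body on the same strand without full-CDS spanning:
#'    `intragenic`;
#' 5. otherwise `intergenic`.
#'
#' When several genes are spanned, the gene whose CDS 5' end is nearest
#' downstream is chosen. The proximal promoter of a LUTI call is the
#' intervening cluster closest to the CDS.
#'
#' @param candidate one-row cluster table entry (from
#'   [aggregate_clusters()]) for the induced cluster.
#' @param clusters promoter-level cluster table used for the
#'   downstream-promoter requirement (normally all strict-mode aggregates).
#' @param genes gene models ([read_gff3()] format, 0-based half-open CDS).
#' @param reads long-read spans ([read_bed6()] format).
#' @param near_window bp window matching read 5' ends to the TSS.
#' @return one-row data.table: `cluster_id`, `gene_id`, `class`,
#'   `chrom`, `strand`, `distal_tss`, `prox_tss`, `prox_cluster_id`,
#'   `spanning_read_count`.
#' @export
classify_locus <- function(candidate, clusters, genes, reads,
                           near_window = 50L) {
  d <- candidate$dominant_pos
  ch <- candidate$chrom
  s <- candidate$strand
  genes <- as.data.table(genes)
  out <- data.table(cluster_id = candidate$cluster_id, gene_id = NA_character_,
                    class = "intergenic", chrom = ch, strand = s,
                    distal_tss = d, prox_tss = NA_integer_,
                    prox_cluster_id = NA_character_,
                    spanning_read_count = 0L)
  gsame <- genes[genes$chrom == ch & genes$strand == s, ]
  if (nrow(gsame)) {
    nspan <- vapply(seq_len(nrow(gsame)), function(i)
      spanning_read_check(d, ch, s, gsame[i], reads, near_window), integer(1))
    dist5 <- vapply(seq_len(nrow(gsame)), function(i)
      .dist_to_cds5(d, gsame$start[i], gsame$end[i], s), numeric(1))
    hit <- which(nspan >= 1L & dist5 > 0)
    if (length(hit)) {
      g <- gsame[hit[which.min(dist5[hit])]]
      cds5 <- if (s == "+") g$start else g$end - 1L
      out[, `:=`(gene_id = g$gene_id, spanning_read_count =
                   spanning_read_check(d, ch, s, g, reads, near_window))]
      cl <- as.data.table(clusters)
      cl <- cl[cl$chrom == ch & cl$strand == s &
                 cl$cluster_id != candidate$cluster_id, ]
      between <- if (s == "+") cl$dominant_pos > d & cl$dominant_pos < cds5
                 else cl$dominant_pos < d & cl$dominant_pos > cds5
      cl <- cl[between]
      if (nrow(cl)) {
        prox <- cl[if (s == "+") which.max(cl$dominant_pos)
                   else which.min(cl$dominant_pos)]
        out[, `:=`(class = "luti_candidate", prox_tss = prox$dominant_pos,
                   prox_cluster_id = prox$cluster_id)]
      } else {
        out[, class := "canonical"]
      }
      return(out[])
    }
  }
  host_opp <- genes[genes$chrom == ch & genes$strand != s &
                      genes$start <= d & d < genes$end, ]
  if (nrow(host_opp)) {
    out[, `:=`(class = "antisense", gene_id = host_opp$gene_id[1L])]
    return(out[])
  }
  host_same <- gsame[gsame$start <= d & d < gsame$end, ]
  if (nrow(host_same)) {
    out[, `:=`(class = "intragenic", gene_id = host_same$gene_id[1L])]
    return(out[])
  }
  out[]
}

#' Discover and classify induced transcription start events
#'
#' Applies [induction_filter()] to promoter-level clusters and classifies
#' every passing cluster with [classify_locus()].
#'
#' @param aggregates promoter-level cluster table (strict-mode
#'   [aggregate_clusters()] output).
#' @param samples sample sheet (`sample`, `timepoint`, `replicate`).
#' @param genes gene models.
#' @param reads long-read spans.
#' @param timepoint_a,timepoint_b the reference (premeiotic) and induced
#'   (meiotic) timepoint labels.
#' @param pseudocount TPM pseudocount for the induction fold change.
#' @param min_mean_tpm,min_log2fc induction thresholds.
#' @param near_window bp window matching read 5' ends to TSSs.
#' @return data.table of locus calls, one row per induced cluster.
#' @export
discover_loci <- function(aggregates, samples, genes, reads,
                          timepoint_a = "premeiotic",
                          timepoint_b = "meiotic", pseudocount = 0.1,
                          min_mean_tpm = 2, min_log2fc = 2,
                          near_window = 50L) {
  m <- cluster_timepoint_means(aggregates, samples)
  pass <- induction_filter(m[, timepoint_a], m[, timepoint_b], pseudocount,
                           min_mean_tpm, min_log2fc)
  cand <- as.data.table(aggregates)[which(pass)]
  if (!nrow(cand))
    return(data.table(cluster_id = character(), gene_id = character(),
                      class = character(), chrom = character(),
                      strand = character(), distal_tss = integer(),
                      prox_tss = integer(), prox_cluster_id = character(),
                      spanning_read_count = integer()))
  rbindlist(lapply(seq_len(nrow(cand)), function(i)
    classify_locus(cand[i], aggregates, genes, reads, near_window)))
}
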