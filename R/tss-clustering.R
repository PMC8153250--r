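#' @title 5'-end tag (CTSS) clustering
#' @description TPM normalization of per-base 5'-end tag counts, distance
#'   based ("distclu") clustering with singleton rules, promoter-level
#'   aggregation and dominant-position calling. Two parameter sets mirror
#'   common practice: a strict set for isoform discovery
#'   (`threshold = 2`, `maxDist = 5`, `removeSingletons = TRUE`,
#'   `keepSingletonsAbove = 3`, then aggregation with `tpmThreshold = 1`,
#'   `maxDist = 50`) and a permissive set for quantification
#'   (`threshold = 1`, `removeSingletons = FALSE`).
#' @name tss_clustering
NULL

#' Assemble a CTSS table from stranded 5'-end tag tracks
#'
#' @param tracks named list of [signal_track()]s (one per sample and strand;
#'   track `sample` metadata identifies the sample, tracks of the same sample
#'   on both strands are combined).
#' @return data.table with columns `chrom`, `pos`, `strand` and one
#'   `count_<sample>` column per sample.
#' @export
ctss_from_tracks <- function(tracks) {
  stopifnot(length(tracks) > 0)
  per <- lapply(tracks, function(tr) {
    dt <- track_positions(tr)
    if (!nrow(dt)) return(NULL)
    dt[, `:=`(strand = tr$strand, sample = tr$sample)]
    dt
  })
  long <- rbindlist(per)
  if (!nrow(long))
    stop("no tag positions in any track")
  wide <- data.table::dcast(long, chrom + pos + strand ~ sample,
                            value.var = "value", fun.aggregate = sum, fill = 0)
  samples <- setdiff(names(wide), c("chrom", "pos", "strand"))
  setnames(wide, samples, paste0("count_", samples))
  setorder(wide, chrom, strand, pos)
  wide[]
}

.count_cols <- function(ctss) grep("^count_", names(ctss), value = TRUE)
.tpm_cols <- function(ctss) grep("^tpm_", names(ctss), value = TRUE)

#' Tags-per-million normalization of a CTSS table
#'
#' Per sample, `TPM = count / library total * 1e6`, so each sample's TPM sums
#' to 1e6 across all positions.
#'
#' @param ctss CTSS table from [ctss_from_tracks()].
#' @return the table with one `tpm_<sample>` column added per count column.
#' @export
normalize_tpm <- function(ctss) {
  ctss <- copy(as.data.table(ctss))
  cc <- .count_cols(ctss)
  if (!length(cc)) stop("no count_<sample> columns found")
  for (col in cc) {
    total <- sum(ctss[[col]])
    if (total <= 0) stop(sprintf("zero library size for sample '%s'",
                                 sub("^count_", "", col)))
    ctss[, (sub("^count_", "tpm_", col)) := ctss[[col]] / total * 1e6]
  }
  ctss[]
}

#' Dominant position of a TSS cluster
#'
#' The member with maximal pooled TPM; ties are broken by the 5'-most member
#' (lowest coordinate on `+`, highest on `-`).
#'
#' @param pos integer member positions.
#' @param pooled pooled TPM of each member.
#' @param strand `"+"` or `"-"`.
#' @return the dominant position.
#' @export
dominant_position <- function(pos, pooled, strand) {
  if (!length(pos)) stop("empty cluster has no dominant position")
  best <- which(pooled == max(pooled))
  cand <- pos[best]
  if (strand == "-") max(cand) else min(cand)
}

.empty_clusters <- function(ctss) {
  out <- data.table(cluster_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    n_members = integer(), dominant_pos = integer(),
                    pooled_tpm = numeric())
  for (col in c(.count_cols(ctss), .tpm_cols(ctss))) out[, (col) := numeric()]
  out[, members := list()]
  out[]
}

# Build the cluster table for a membership assignment. `cid` is an integer
# cluster label per row of `seeds` (a subset of the ctss table).
.build_clusters <- function(seeds, cid) {
  tc <- .tpm_cols(seeds)
  cc <- .count_cols(seeds)
  seeds <- copy(seeds)[, .cid := cid]
  out <- seeds[, {
    sums <- lapply(.SD, sum)
    names(sums) <- c(cc, tc)
    pooled_pos <- rowSums(as.matrix(.SD[, tc, with = FALSE]))
    c(list(start = min(pos), end = max(pos), n_members = .N,
           members = list(pos),
           dominant_pos = dominant_position(pos, pooled_pos, strand[1L]),
           pooled_tpm = sum(pooled_pos)),
      sums)
  }, by = .(chrom, strand, .cid), .SDcols = c(cc, tc)]
  out[, .cid := NULL]
  out[, cluster_id := sprintf("%s:%s:%d-%d", chrom, strand, start, end)]
  setorder(out, chrom, strand, start)
  data.table::setcolorder(out, c("cluster_id", "chrom", "strand", "start",
                                 "end", "n_members", "dominant_pos",
                                 "pooled_tpm"))
  out[]
}

#' Distance-based clustering of CTSS positions
#'
#' Positions whose pooled TPM (sum over all samples) reaches `threshold`
#' become seeds; seeds on the same chromosome and strand merge transitively
#' whenever consecutive positions are at most `max_dist` bp apart. With
#' `remove_singletons`, a resulting single-position cluster is dropped unless
#' its pooled TPM exceeds `keep_singletons_above`.
#'
#' @param ctss TPM-normalized CTSS table ([normalize_tpm()]).
#' @param threshold seed threshold on pooled TPM (inclusive).
#' @param max_dist maximum merge distance in bp.
#' @param remove_singletons drop single-position clusters?
#' @param keep_singletons_above pooled-TPM value above which (strictly) a
#'   singleton is kept regardless.
#' @return cluster table: `cluster_id`, `chrom`, `strand`, `start`, `end`
#'   (member bounds, 0-based inclusive), `n_members`, `dominant_pos`,
#'   `pooled_tpm`, per-sample `count_*`/`tpm_*` sums and a `members`
#'   list-column of positions.
#' @export
cluster_ctss <- function(ctss, threshold = 2, max_dist = 5,
                         remove_singletons = TRUE, keep_singletons_above = 3) {
  if (max_dist < 0) stop("max_dist must be >= 0")
  ctss <- as.data.table(ctss)
  tc <- .tpm_cols(ctss)
  if (!length(tc)) stop("run normalize_tpm() first")
  pooled <- rowSums(as.matrix(ctss[, tc, with = FALSE]))
  seeds <- ctss[pooled >= threshold]
  if (!nrow(seeds)) return(.empty_clusters(ctss))
  setorder(seeds, chrom, strand, pos)
  new_block <- seeds[, c(TRUE, diff(pos) > max_dist), by = .(chrom, strand)]$V1
  cid <- cumsum(new_block)
  out <- .build_clusters(seeds, cid)
  if (remove_singletons)
    out <- out[n_members > 1L | pooled_tpm > keep_singletons_above]
  out[]
}

#' Aggregate TSS clusters into promoter-level clusters
#'
#' Clusters with pooled TPM at or above `tpm_threshold` merge into a single
#' promoter-level cluster whenever the gap between their boundaries is at
#' most `max_dist` bp (chained transitively), so all activity expected from a
#' single promoter is represented by one aggregate. Member lists concatenate
#' and statistics are recomputed.
#'
#' @param clusters cluster table from [cluster_ctss()].
#' @param ctss the TPM-normalized CTSS table the clusters were built from.
#' @param tpm_threshold minimum pooled TPM for a cluster to enter aggregation.
#' @param max_dist maximum boundary gap in bp.
#' @return a cluster table in the same format as [cluster_ctss()].
#' @export
aggregate_clusters <- function(clusters, ctss, tpm_threshold = 1,
                               max_dist = 50) {
  cl <- as.data.table(clusters)[pooled_tpm >= tpm_threshold]
  if (!nrow(cl)) return(cl)
  setorder(cl, chrom, strand, start)
  new_block <- cl[, c(TRUE, if (.N > 1L) start[-1L] - end[-.N] > max_dist),
                  by = .(chrom, strand)]$V1
  aid <- cumsum(new_block)
  members <- cl[, .(chrom, strand, members, .aid = aid)]
  long <- members[, .(pos = unlist(members)), by = .(chrom, strand, .aid)]
  ctss <- as.data.table(ctss)
  seeds <- ctss[long, on = c("chrom", "strand", "pos")]
  .build_clusters(seeds, seeds$.aid)
}

#' Mean cluster TPM per timepoint
#'
#' @param clusters cluster table ([cluster_ctss()] / [aggregate_clusters()]).
#' @param samples data.frame with columns `sample`, `timepoint` (and
#'   optionally `replicate`) describing the `tpm_<sample>` columns.
#' @return matrix (clusters x timepoints) of replicate-mean TPM.
#' @export
cluster_timepoint_means <- function(clusters, samples) {
  samples <- as.data.table(samples)
  tps <- unique(samples$timepoint)
  out <- sapply(tps, function(tp) {
    cols <- paste0("tpm_", samples[timepoint == tp]$sample)
    cols <- intersect(cols, names(clusters))
    if (!length(cols)) return(rep(NA_real_, nrow(clusters)))
    rowMeans(as.matrix(as.data.table(clusters)[, cols, with = FALSE]))
  })
  out <- matrix(out, nrow = nrow(clusters),
                dimnames = list(NULL, tps))
  out
}

#' Log2 fold change of cluster abundance between timepoints
#'
#' A pseudocount log2 fold change on replicate-mean TPM:
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))`, with timepoint b
#' conventionally the later (meiotic prophase) one.
#'
#' @inheritParams cluster_timepoint_means
#' @param timepoint_a,timepoint_b timepoint labels in `samples$timepoint`.
#' @param pseudocount TPM pseudocount (default 0.1).
#' @return numeric vector, one log2 fold change per cluster.
#' @export
log2_fold_change <- function(clusters, samples, timepoint_a, timepoint_b,
                             pseudocount = 0.1) {
  m <- cluster_timepoint_means(clusters, samples)
  unname(log2((m[, timepoint_b] + pseudocount) /
                (m[, timepoint_a] + pseudocount)))
}
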