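#' @title End-to-end LUTI pipeline
#' @description Glue from a study (synthetic or loaded from disk) to locus
#'   calls and the per-gene feature table: strict clustering + aggregation
#'   for discovery, permissive clustering for quantification, then
#'   chromatin and nucleosome features per LUTI gene.
#' @name pipeline
NULL

#' Find the cluster containing a position
#'
#' @param clusters cluster table ([cluster_ctss()] format).
#' @param chrom,strand,pos query location.
#' @return the row index of the containing cluster, or `NA` if none.
#' @export
locate_cluster <- function(clusters, chrom, strand, pos) {
  hit <- which(clusters$chrom == chrom & clusters$strand == strand &
                 clusters$start <= pos & pos <= clusters$end)
  if (!length(hit)) NA_integer_ else hit[1L]
}

#' Run discovery on a study
#'
#' Strict-mode clustering (`threshold = 2`, `maxDist = 5`,
#' `removeSingletons = TRUE`, `keepSingletonsAbove = 3`), promoter-level
#' aggregation (`tpmThreshold = 1`, `maxDist = 50`), induction filtering
#' and locus classification.
#'
#' @param study a `luti_study` ([generate_study()]) or equivalent list with
#'   `tlseq_tracks`, `samples`, `genes`, `reads`.
#' @param pseudocount TPM pseudocount for fold changes.
#' @param near_window long-read 5'-end matching window (bp).
#' @return list with `ctss`, `clusters_strict`, `aggregates`,
#'   `clusters_permissive`, `calls`.
#' @export
run_discovery <- function(study, pseudocount = 0.1, near_window = 50L) {
  ctss <- normalize_tpm(ctss_from_tracks(study$tlseq_tracks))
  strict <- cluster_ctss(ctss, threshold = 2, max_dist = 5,
                         remove_singletons = TRUE, keep_singletons_above = 3)
  aggregates <- aggregate_clusters(strict, ctss, tpm_threshold = 1,
                                   max_dist = 50)
  permissive <- cluster_ctss(ctss, threshold = 1, max_dist = 5,
                             remove_singletons = FALSE)
  calls <- discover_loci(aggregates, study$samples, study$genes, study$reads,
                         pseudocount = pseudocount, near_window = near_window)
  list(ctss = ctss, clusters_strict = strict, aggregates = aggregates,
       clusters_permissive = permissive, calls = calls)
}

# replicate-mean TPM of the permissive cluster containing `pos`
.quant_at <- function(clusters, samples, chrom, strand, pos) {
  i <- locate_cluster(clusters, chrom, strand, pos)
  if (is.na(i)) return(c(NA_real_, NA_real_))
  m <- cluster_timepoint_means(clusters[i], samples)
  c(m[1L, "premeiotic"], m[1L, "meiotic"])
}

#' Assemble the per-gene feature table for LUTI calls
#'
#' One row per `luti_candidate`: proximal-isoform quantification and
#' repression class, LUTI abundance (meiotic TPM of the distal cluster in
#' permissive mode), promoter chromatin fold changes, nucleosome
#' repositioning features, TSS distance and CDS length. The
#' `plus_one_shift_toward_ndr` column is the sign-flipped +1 shift
#' (positive when the nucleosome moves toward the NDR), the orientation
#' used in the correlation analysis.
#'
#' @param study a `luti_study`.
#' @param disc result of [run_discovery()] (computed if `NULL`).
#' @param pseudocount TPM pseudocount for the proximal log2 fold change.
#' @return data.table of per-gene features.
#' @export
luti_feature_table <- function(study, disc = NULL, pseudocount = 0.1) {
  if (is.null(disc)) disc <- run_discovery(study, pseudocount = pseudocount)
  calls <- disc$calls[class == "luti_candidate"]
  perm <- disc$clusters_permissive
  genes <- as.data.table(study$genes)
  feats <- rbindlist(lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i]
    prox <- .quant_at(perm, study$samples, cl$chrom, cl$strand, cl$prox_tss)
    dist <- .quant_at(perm, study$samples, cl$chrom, cl$strand, cl$distal_tss)
    g <- genes[gene_id == cl$gene_id]
    data.table(gene_id = cl$gene_id, chrom = cl$chrom, strand = cl$strand,
               distal_tss = cl$distal_tss, prox_tss = cl$prox_tss,
               tss_distance = abs(cl$distal_tss - cl$prox_tss),
               cds_length = g$end - g$start,
               prox_tpm_pre = prox[1L], prox_tpm_mei = prox[2L],
               luti_tpm = dist[2L])
  }))
  if (!nrow(feats)) return(feats)
  feats[, prox_log2fc := log2((prox_tpm_mei + pseudocount) /
                                (prox_tpm_pre + pseudocount))]
  feats[, repression_class := classify_repression(prox_tpm_pre, prox_tpm_mei)]
  anchors <- feats[, .(gene_id, chrom, tss = prox_tss, strand)]
  if (length(study$chip_tracks)) {
    for (mark in names(study$chip_tracks)) {
      fc <- promoter_mark_table(study$chip_tracks[[mark]], anchors)
      setnames(fc, "fc_mean", paste0(tolower(mark), "_fc"))
      feats <- fc[feats, on = "gene_id"]
    }
  }
  if (length(study$mnase_tracks)) {
    nc_pre <- call_nucleosomes(study$mnase_tracks$premeiotic)
    nc_mei <- call_nucleosomes(study$mnase_tracks$meiotic)
    nf <- nucleosome_feature_table(nc_pre, nc_mei, anchors)
    feats <- nf[feats, on = "gene_id"]
  }
  if ("plus_one_shift" %in% names(feats))
    feats[, plus_one_shift_toward_ndr := -plus_one_shift]
  feats[]
}

#' Run the full pipeline on a study
#'
#' @inheritParams run_discovery
#' @return list with the [run_discovery()] elements plus `features`.
#' @export
run_luti_pipeline <- function(study, pseudocount = 0.1, near_window = 50L) {
  disc <- run_discovery(study, pseudocount, near_window)
  disc$features <- luti_feature_table(study, disc, pseudocount)
  disc
}

#' Load a study written by [generate_study()] back from disk
#'
#' @param dir the study directory.
#' @return a `luti_study`-shaped list (without the `config`).
#' @export
load_study <- function(dir) {
  samples <- read_feature_table(file.path(dir, "samples.tsv"))
  tl <- list()
  for (i in seq_len(nrow(samples))) {
    smp <- samples$sample[i]
    for (s in c("plus", "minus")) {
      f <- file.path(dir, "tlseq", sprintf("%s.%s.bedgraph", smp, s))
      if (file.exists(f))
        tl[[sprintf("%s.%s", smp, s)]] <-
          read_bedgraph(f, ifelse(s == "plus", "+", "-"), units = "tags",
                        sample = smp, timepoint = samples$timepoint[i],
                        replicate = samples$replicate[i])
    }
  }
  reads_f <- file.path(dir, "longreads_meiotic.bed")
  fp <- list()
  for (s in c("plus", "minus")) {
    f <- file.path(dir, "footprints", sprintf("fp_meiotic.%s.bedgraph", s))
    if (file.exists(f))
      fp[[ifelse(s == "plus", "+", "-")]] <-
        read_bedgraph(f, ifelse(s == "plus", "+", "-"), units = "footprints",
                      sample = "fp_meiotic", timepoint = "meiotic")
  }
  chip <- list()
  chip_files <- list.files(file.path(dir, "chip"), full.names = TRUE)
  for (f in chip_files) {
    nm <- sub("\\.bedgraph$", "", basename(f))
    parts <- strsplit(nm, "_")[[1L]]
    mark <- parts[1L]; tp <- parts[2L]
    r <- as.integer(sub("rep", "", parts[3L]))
    chip[[mark]] <- c(chip[[mark]],
                      list(read_bedgraph(f, ".", units = "fold_enrichment",
                                         sample = nm, timepoint = tp,
                                         replicate = r)))
  }
  peaks <- lapply(list.files(file.path(dir, "peaks"), full.names = TRUE),
                  read_narrowpeak)
  mnase <- list()
  for (tp in c("premeiotic", "meiotic")) {
    f <- file.path(dir, "mnase", sprintf("mnase_%s.bedgraph", tp))
    if (file.exists(f))
      mnase[[tp]] <- read_bedgraph(f, ".", units = "dyads",
                                   sample = sprintf("mnase_%s", tp),
                                   timepoint = tp, replicate = 1L)
  }
  list(genome = read_genome_fasta(file.path(dir, "genome.fa")),
       genes = read_gff3(file.path(dir, "genes.gff3")),
       truth = read_feature_table(file.path(dir, "truth.tsv")),
       samples = samples, tlseq_tracks = tl,
       reads = if (file.exists(reads_f)) read_bed6(reads_f) else data.table(),
       fp_tracks = fp, chip_tracks = chip, peaks = peaks,
       mnase_tracks = mnase)
}
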