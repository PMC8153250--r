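#' @title Synthetic study generator
#' @description Generates a complete synthetic two-timepoint study
#'   (premeiotic vs meiotic prophase): genome, gene annotation, planted
#'   loci of five classes (LUTI, canonical, antisense, intergenic,
#'   intragenic) and all six data modalities (5'-end tags at 2 timepoints x
#'   3 replicates, long-read spans, ribosome footprints under a
#'   leaky-scanning model, ChIP fold-enrichment tracks for two histone
#'   marks at 2 timepoints x 3 replicates, TF peak calls, and nucleosome
#'   dyad counts at 2 timepoints) together with a truth table. The output
#'   is fully determined by the seed.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults are the package's stated world: 30/30/10/10/10 planted loci,
#' triplicate 5'-end tag and ChIP libraries, negative-binomial tag noise
#' with dispersion 0.2, 0.1 sd Gaussian track noise, leaky-scanning uORF
#' initiation probability 0.5, nucleosome dyad sd 15 bp with spacing
#' 165 bp, a planted +1 shift of -15 bp and fuzziness increase of +10 bp at
#' repressed loci. See the methods vignette for the rationale of every
#' default.
#'
#' @param seed integer seed; the whole study is a deterministic function of
#'   it.
#' @param n_luti,n_canonical,n_antisense,n_intergenic,n_intragenic planted
#'   locus counts per class.
#' @param tlseq_replicates,chip_replicates replicate counts (default 3).
#' @param tag_dispersion negative-binomial dispersion of tag counts
#'   (`var = mu + d mu^2`); 0 means deterministic expected counts.
#' @param track_noise_sd Gaussian sd of the ChIP fold-enrichment noise per
#'   10-bp bin.
#' @param bg_positions_per_slot,bg_mean_count non-induced background tag
#'   positions per locus slot and their expected per-sample count.
#' @param n_long_reads long reads per validated locus.
#' @param fp_depth scanning ribosomes per LUTI leader.
#' @param uorf_p_init per-uORF initiation probability.
#' @param nuc_dyads_plus_one,nuc_dyads_other dyads sampled for the +1 and
#'   for every other planted nucleosome.
#' @param nuc_sd,nuc_spacing dyad sd and array spacing in bp.
#' @param plus_one_shift_repressed,plus_one_shift_intermediate planted +1
#'   dyad displacement (bp, negative = toward the NDR).
#' @param fuzziness_delta_repressed,fuzziness_delta_intermediate planted +1
#'   dyad-sd increase (bp).
#' @param tf_bound_fraction fraction of LUTI/canonical promoters bound by
#'   the TF.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_luti = 30L, n_canonical = 30L,
                       n_antisense = 10L, n_intergenic = 10L,
                       n_intragenic = 10L, tlseq_replicates = 3L,
                       chip_replicates = 3L, tag_dispersion = 0.2,
                       track_noise_sd = 0.1, bg_positions_per_slot = 10L,
                       bg_mean_count = 400, n_long_reads = 3L,
                       fp_depth = 200L, uorf_p_init = 0.5,
                       nuc_dyads_plus_one = 300L, nuc_dyads_other = 175L,
                       nuc_sd = 15, nuc_spacing = 165L,
                       plus_one_shift_repressed = -15,
                       plus_one_shift_intermediate = -6,
                       fuzziness_delta_repressed = 10,
                       fuzziness_delta_intermediate = 4,
                       tf_bound_fraction = 0.6) {
  cfg <- as.list(environment())
  counts <- c(n_luti, n_canonical, n_antisense, n_intergenic, n_intragenic,
              tlseq_replicates, chip_replicates, bg_positions_per_slot,
              n_long_reads, fp_depth)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (tag_dispersion < 0 || track_noise_sd < 0)
    stop("noise parameters must be >= 0")
  if (uorf_p_init < 0 || uorf_p_init > 1)
    stop("uorf_p_init must be in [0, 1]")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

.SLOT_W <- 5000L
.CDS_LOCAL <- 2500L
.PROX_OFF <- 120L

# negative-binomial (or deterministic) tag counts around mu
.tag_counts <- function(mu, dispersion) {
  if (dispersion <= 0) return(round(mu))
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Remove every transcript-strand ATG from genome[chrom][start, end) (0-based
# half-open, plus-strand frame of the string; strand handled by caller giving
# the transcript-strand pattern).
.scrub_atg <- function(seqs, chrom, start, end, strand) {
  region <- substr(seqs[[chrom]], start + 1L, end)
  pat <- if (strand == "+") "ATG" else "CAT"  # revcomp of ATG on the + string
  repeat {
    hits <- gregexpr(pat, region, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) break
    # replace the G (or the C of CAT) to break the codon without creating
    # a new ATG: ATG -> ATC, CAT -> GAT
    for (h in as.integer(hits)) {
      at <- if (strand == "+") h + 2L else h
      substr(region, at, at) <- if (strand == "+") "C" else "G"
    }
  }
  substr(seqs[[chrom]], start + 1L, end) <- region
  seqs
}

.insert_codon <- function(seqs, chrom, pos0, strand, codon = "ATG") {
  # place `codon` so that its first transcript base sits at genomic pos0
  s <- if (strand == "+") codon else .revcomp(codon)
  at <- if (strand == "+") pos0 + 1L else pos0 - 1L
  substr(seqs[[chrom]], at, at + 2L) <- s
  seqs
}

#' Simulate leaky-scanning ribosome footprints over a uORF ladder
#'
#' A scanning ribosome initiates at uORF i with probability `p[i]`
#' conditioned on not having initiated upstream, so the expected footprint
#' count at uORF i is `depth * p_i * prod(1 - p_j, j < i)`. Initiated
#' ribosomes deposit one footprint 5' count at a uniform position within
#' the uORF's first 6 codons (18 nt).
#'
#' @param init_probs per-uORF initiation probabilities, 5' to 3' order.
#' @param uorf_starts genomic positions of the uORF ATGs (5' to 3' order).
#' @param chrom,strand location of the leader.
#' @param depth number of scanning ribosomes.
#' @return a stranded footprint [signal_track()].
#' @export
simulate_footprints <- function(init_probs, uorf_starts, chrom, strand,
                                depth = 1000L) {
  stopifnot(length(init_probs) == length(uorf_starts))
  if (any(init_probs < 0 | init_probs > 1))
    stop("initiation probabilities must lie in [0, 1]")
  k <- length(init_probs)
  if (k == 0L || depth == 0L)
    return(signal_track(NULL, strand = strand, units = "footprints"))
  none <- cumprod(1 - init_probs)
  q <- init_probs * c(1, none[-k])
  counts <- as.vector(stats::rmultinom(1, depth, c(q, max(0, 1 - sum(q)))))[seq_len(k)]
  pos <- unlist(lapply(seq_len(k), function(i) {
    if (counts[i] == 0L) return(integer())
    off <- sample(0:17, counts[i], replace = TRUE)
    if (strand == "+") uorf_starts[i] + off else uorf_starts[i] - off
  }))
  if (!length(pos))
    return(signal_track(NULL, strand = strand, units = "footprints"))
  positions_to_track(data.table(chrom = chrom, pos = pos, value = 1),
                     strand = strand, units = "footprints")
}

# --- locus layout ----------------------------------------------------------

# Lay out loci in fixed 5-kb slots on two chromosomes; local (plus-frame)
# coordinates are mirrored for minus-strand loci.
.plan_loci <- function(cfg) {
  classes <- rep(c("luti", "canonical", "antisense", "intergenic",
                   "intragenic"),
                 c(cfg$n_luti, cfg$n_canonical, cfg$n_antisense,
                   cfg$n_intergenic, cfg$n_intragenic))
  n <- length(classes)
  if (n == 0L)
    return(list(loci = data.table(), chrom_sizes = c(chrI = .SLOT_W)))
  chrom <- c(rep("chrI", ceiling(n / 2)), rep("chrII", n - ceiling(n / 2)))
  slot <- c(seq_len(ceiling(n / 2)), seq_len(n - ceiling(n / 2))) - 1L
  slot_start <- slot * .SLOT_W
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cds_len <- 3L * sample(200:500, n, replace = TRUE)
  tssd <- sample(300:800, n, replace = TRUE)
  mirror <- function(x) .SLOT_W - 1L - x
  loci <- data.table(gene_id = sprintf("g%03d", seq_len(n)), class = classes,
                     chrom = chrom, slot_start = slot_start, strand = strand,
                     cds_len = cds_len, tss_distance = tssd)
  # plus-frame local coordinates
  loci[, `:=`(cds_start_l = .CDS_LOCAL, cds_end_l = .CDS_LOCAL + cds_len)]
  loci[, tss_l := .CDS_LOCAL - .PROX_OFF]            # prox / canonical TSS
  loci[class %in% c("antisense", "intragenic"),
       tss_l := .CDS_LOCAL + cds_len %/% 2L]          # mid-CDS event TSS
  loci[class == "intergenic", tss_l := .CDS_LOCAL]
  # only LUTI loci have a distinct distal promoter; for the other classes
  # the "distal" coordinate is the event TSS itself
  loci[, distal_l := ifelse(class == "luti", tss_l - tss_distance, tss_l)]
  # genomic coordinates (strand-aware mirroring within the slot)
  flip <- loci$strand == "-"
  loci[, cds_start := slot_start + ifelse(flip, .SLOT_W - cds_end_l, cds_start_l)]
  loci[, cds_end := slot_start + ifelse(flip, .SLOT_W - cds_start_l, cds_end_l)]
  loci[, tss := slot_start + ifelse(flip, mirror(tss_l), tss_l)]
  loci[, distal_tss := slot_start + ifelse(flip, mirror(distal_l), distal_l)]
  # event strand: antisense transcribes opposite to its host gene
  loci[, event_strand := strand]
  loci[class == "antisense", event_strand := ifelse(strand == "+", "-", "+")]
  # repression state for LUTI loci (others NA)
  loci[, `:=`(repression_state = NA_character_, prox_fc = NA_real_)]
  nl <- sum(classes == "luti")
  if (nl) {
    states <- rep(c("repressed", "intermediate", "non_repressed"),
                  length.out = nl)
    fc_lo <- c(repressed = 0.08, intermediate = 0.35, non_repressed = 1.4)
    fc_hi <- c(repressed = 0.20, intermediate = 0.80, non_repressed = 1.9)
    fc <- runif(nl, fc_lo[states], fc_hi[states])
    loci[class == "luti", `:=`(repression_state = states, prox_fc = fc)]
  }
  # planted effect sizes, monotone in repression
  loci[, mark_gain := NA_real_]
  loci[class == "luti", mark_gain := 1 + 2 * (1 - pmin(prox_fc, 1))]
  loci[, k4_gain := NA_real_]
  loci[class == "luti", k4_gain := 1 + 0.5 * (repression_state == "repressed")]
  loci[, plus_one_shift := NA_real_]
  loci[, fuzziness_delta := NA_real_]
  loci[class == "luti", plus_one_shift := c(
    repressed = cfg$plus_one_shift_repressed,
    intermediate = cfg$plus_one_shift_intermediate,
    non_repressed = 0)[repression_state]]
  loci[class == "luti", fuzziness_delta := c(
    repressed = cfg$fuzziness_delta_repressed,
    intermediate = cfg$fuzziness_delta_intermediate,
    non_repressed = 0)[repression_state]]
  # expression levels (expected dominant-position tag totals per replicate)
  loci[, `:=`(e_pre = 0, e_mei = 0, e_prox_pre = NA_real_,
              e_prox_mei = NA_real_)]
  loci[class == "luti",
       e_mei := round(runif(.N, 200, 400) * (1 + 3 * (1 - pmin(prox_fc, 1))))]
  loci[class == "luti", e_prox_pre := round(runif(.N, 300, 600))]
  loci[class == "luti", e_prox_mei := round(e_prox_pre * prox_fc)]
  loci[class == "canonical", e_mei := round(runif(.N, 200, 600))]
  loci[class %in% c("antisense", "intergenic", "intragenic"),
       e_mei := round(runif(.N, 150, 400))]
  # uORFs for LUTI loci
  loci[, n_uorfs := NA_integer_]
  loci[class == "luti", n_uorfs := sample(2:10, .N, replace = TRUE)]
  # TF binding at LUTI/canonical promoters
  loci[, tf_bound := FALSE]
  pr <- loci$class %in% c("luti", "canonical")
  loci[pr, tf_bound := runif(sum(pr)) < cfg$tf_bound_fraction]
  n_chr1 <- ceiling(n / 2)
  sizes <- c(chrI = n_chr1 * .SLOT_W,
             chrII = max(1L, n - n_chr1) * .SLOT_W)
  list(loci = loci, chrom_sizes = sizes)
}

# --- modality builders -----------------------------------------------------

.gen_genome <- function(plan, cfg) {
  seqs <- lapply(plan$chrom_sizes, .rand_dna)
  loci <- plan$loci
  luti <- loci[class == "luti"]
  uorf_starts <- vector("list", nrow(loci))
  names(uorf_starts) <- loci$gene_id
  for (i in seq_len(nrow(luti))) {
    l <- luti[i]
    s <- l$event_strand
    # leader on the genome: [distal, prox) on +, (prox, distal] on -
    if (s == "+") {
      seqs <- .scrub_atg(seqs, l$chrom, l$distal_tss, l$tss, "+")
    } else {
      seqs <- .scrub_atg(seqs, l$chrom, l$tss + 1L, l$distal_tss + 1L, "-")
    }
    offs <- sort(sample(seq(10L, l$tss_distance - 30L, by = 24L), l$n_uorfs))
    gpos <- if (s == "+") l$distal_tss + offs else l$distal_tss - offs
    for (p in gpos) seqs <- .insert_codon(seqs, l$chrom, p, s, "ATG")
    uorf_starts[[l$gene_id]] <- gpos
  }
  # start codon of every annotated CDS
  for (i in seq_len(nrow(loci))) {
    l <- loci[i]
    if (l$class == "intergenic") next
    # the CDS start codon in gene orientation
    at <- if (l$strand == "+") l$cds_start else l$cds_end - 1L
    seqs <- .insert_codon(seqs, l$chrom, at, l$strand, "ATG")
  }
  list(genome = unlist(seqs), uorf_starts = uorf_starts)
}

.gen_genes <- function(plan) {
  g <- plan$loci[class != "intergenic",
                 .(gene_id, chrom, start = cds_start, end = cds_end, strand)]
  setorder(g, chrom, start)
  g
}

.jitter_weights <- c(0.1, 0.2, 0.4, 0.2, 0.1)

# expected per-position tag table for one promoter
.promoter_positions <- function(chrom, tss, e_total) {
  data.table(chrom = chrom, pos = tss + (-2L:2L),
             mu = e_total * .jitter_weights)
}

.gen_tlseq <- function(plan, cfg) {
  loci <- plan$loci
  # background positions, shared across samples and timepoints
  bg <- loci[, {
    pos <- slot_start + sample(100:800, cfg$bg_positions_per_slot)
    .(pos = pos, strand = sample(c("+", "-"), length(pos), replace = TRUE),
      mu = rep(cfg$bg_mean_count, length(pos)))
  }, by = .(gene_id, chrom)][, .(chrom, pos, strand, mu)]
  promoters <- rbindlist(list(
    loci[e_mei > 0, .(chrom, tss = distal_tss, strand = event_strand,
                      mu_pre = e_pre, mu_mei = e_mei)][
      , .(chrom, tss, strand, mu_pre, mu_mei)],
    loci[class == "luti", .(chrom, tss = tss, strand = event_strand,
                            mu_pre = e_prox_pre, mu_mei = e_prox_mei)]))
  # note: distal_tss == tss for non-LUTI classes by construction
  tracks <- list()
  samples <- data.table(sample = character(), timepoint = character(),
                        replicate = integer())
  for (tp in c("premeiotic", "meiotic")) {
    for (r in seq_len(cfg$tlseq_replicates)) {
      smp <- sprintf("%s_rep%d", tp, r)
      samples <- rbind(samples, data.table(sample = smp, timepoint = tp,
                                           replicate = r))
      mu_col <- if (tp == "premeiotic") promoters$mu_pre else promoters$mu_mei
      pp <- promoters[, .(chrom, tss, strand)][, mu := mu_col]
      pos_tab <- pp[, .promoter_positions(chrom, tss, mu),
                    by = .(row = seq_len(nrow(pp)))]
      pos_tab[, strand := pp$strand[row]]
      all_tab <- rbind(pos_tab[, .(chrom, pos, strand, mu)],
                       bg[, .(chrom, pos, strand, mu)])
      all_tab[, value := .tag_counts(mu, cfg$tag_dispersion)]
      for (s in c("+", "-")) {
        tr <- positions_to_track(all_tab[strand == s & value > 0,
                                         .(chrom, pos, value)],
                                 strand = s, units = "tags", sample = smp,
                                 timepoint = tp, replicate = r)
        tracks[[sprintf("%s.%s", smp, ifelse(s == "+", "plus", "minus"))]] <- tr
      }
    }
  }
  list(tracks = tracks, samples = samples)
}

.gen_longreads <- function(plan, cfg) {
  loci <- plan$loci[class %in% c("luti", "canonical")]
  if (!nrow(loci)) return(data.table(chrom = character(), start = integer(),
                                     end = integer(), name = character(),
                                     score = numeric(), strand = character()))
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i]
    n <- cfg$n_long_reads
    jit <- sample(-10:10, n, replace = TRUE)
    extra <- sample(20:60, n, replace = TRUE)
    if (l$strand == "+") {
      start <- l$distal_tss + jit
      end <- l$cds_end + extra
    } else {
      start <- l$cds_start - extra
      end <- l$distal_tss + jit + 1L
    }
    data.table(chrom = l$chrom, start = start, end = end,
               name = sprintf("%s_read%d", l$gene_id, seq_len(n)),
               score = 60, strand = l$strand)
  })
  out <- rbindlist(rows)
  setorder(out, chrom, start)
  out
}

.gen_footprints <- function(plan, cfg, uorf_starts) {
  luti <- plan$loci[class == "luti"]
  parts <- list(`+` = list(), `-` = list())
  for (i in seq_len(nrow(luti))) {
    l <- luti[i]
    us <- uorf_starts[[l$gene_id]]
    tr <- simulate_footprints(rep(cfg$uorf_p_init, length(us)), us, l$chrom,
                              l$event_strand, cfg$fp_depth)
    parts[[l$event_strand]] <- c(parts[[l$event_strand]], list(tr$runs))
  }
  out <- lapply(c("+", "-"), function(s) {
    runs <- rbindlist(parts[[s]])
    if (!nrow(runs))
      return(signal_track(NULL, strand = s, units = "footprints",
                          sample = "fp_meiotic", timepoint = "meiotic"))
    pos <- track_positions(signal_track(runs, strand = s))
    positions_to_track(pos, strand = s, units = "footprints",
                       sample = "fp_meiotic", timepoint = "meiotic")
  })
  names(out) <- c("+", "-")
  out
}

.gen_chip <- function(plan, cfg) {
  loci <- plan$loci
  bin <- 10L
  base_from <- loci$slot_start + 1000L
  base_to <- loci$slot_start + 4600L
  out <- list(H3K36me3 = list(), H3K4me2 = list())
  for (mark in names(out)) {
    for (tp in c("premeiotic", "meiotic")) {
      for (r in seq_len(cfg$chip_replicates)) {
        rows <- lapply(seq_len(nrow(loci)), function(i) {
          l <- loci[i]
          starts <- seq(base_from[i], base_to[i] - bin, by = bin)
          val <- rep(1, length(starts))
          gain <- if (mark == "H3K36me3") l$mark_gain else l$k4_gain
          if (tp == "meiotic" && l$class == "luti" && !is.na(gain) &&
              gain != 1) {
            if (l$event_strand == "+") {
              w_from <- l$tss; w_to <- l$tss + 500L
            } else {
              w_from <- l$tss + 1L - 500L; w_to <- l$tss + 1L
            }
            el <- starts >= w_from & starts < w_to
            val[el] <- gain
          }
          if (cfg$track_noise_sd > 0)
            val <- pmax(0, val + rnorm(length(val), sd = cfg$track_noise_sd))
          data.table(chrom = l$chrom, start = starts, end = starts + bin,
                     value = val)
        })
        tr <- signal_track(rbindlist(rows), strand = ".",
                           units = "fold_enrichment",
                           sample = sprintf("%s_%s_rep%d", mark, tp, r),
                           timepoint = tp, replicate = r)
        out[[mark]] <- c(out[[mark]], list(tr))
      }
    }
  }
  out
}

.gen_peaks <- function(plan, cfg) {
  loci <- plan$loci[class %in% c("luti", "canonical")]
  reps <- seq_len(cfg$chip_replicates)
  decoy_mode <- sample(c("single_rep", "weak", "none"), nrow(loci),
                       replace = TRUE)
  lapply(reps, function(r) {
    rows <- lapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i]
      anchor <- l$distal_tss
      mk_peak <- function(signal) {
        off <- 100L + sample(-20:20, 1)
        data.table(chrom = l$chrom, start = anchor - 100L,
                   end = anchor + 100L,
                   name = sprintf("%s_peak", l$gene_id), score = 1000,
                   strand = ".", signalValue = signal, pValue = 10,
                   qValue = 5, peak = off)
      }
      if (l$tf_bound) return(mk_peak(8))
      if (decoy_mode[i] == "single_rep" && r == 1L) return(mk_peak(8))
      if (decoy_mode[i] == "weak") return(mk_peak(3))
      NULL
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    pk <- if (length(rows)) rbindlist(rows) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character(),
                 signalValue = numeric(), pValue = numeric(),
                 qValue = numeric(), peak = integer())
    if (nrow(pk)) pk[, summit := start + peak]
    pk
  })
}

.gen_mnase <- function(plan, cfg) {
  loci <- plan$loci[class %in% c("luti", "canonical")]
  offsets <- c(-140L, 60L, 60L + cfg$nuc_spacing, 60L + 2L * cfg$nuc_spacing,
               60L + 3L * cfg$nuc_spacing)
  is_plus_one <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  out <- list()
  for (tp in c("premeiotic", "meiotic")) {
    parts <- lapply(seq_len(nrow(loci)), function(i) {
      l <- loci[i]
      sgn <- if (l$event_strand == "+") 1L else -1L
      state <- if (is.na(l$repression_state)) "none" else l$repression_state
      offs <- offsets
      sds <- rep(cfg$nuc_sd, length(offsets))
      if (tp == "meiotic" && l$class == "luti" && state != "none" &&
          state != "non_repressed") {
        offs[2L] <- offs[2L] + l$plus_one_shift
        sds[2L] <- sds[2L] + l$fuzziness_delta
        sds[3:5] <- sds[3:5] + l$fuzziness_delta / 2
      }
      centers <- l$tss + sgn * as.integer(round(offs))
      nd <- ifelse(is_plus_one, cfg$nuc_dyads_plus_one, cfg$nuc_dyads_other)
      pos <- unlist(lapply(seq_along(centers), function(k)
        round(rnorm(nd[k], centers[k], sds[k]))))
      bg <- l$slot_start + sample(0:(.SLOT_W - 1L), 150L, replace = TRUE)
      data.table(chrom = l$chrom, pos = as.integer(c(pos, bg)), value = 1)
    })
    out[[tp]] <- positions_to_track(rbindlist(parts), strand = ".",
                                    units = "dyads",
                                    sample = sprintf("mnase_%s", tp),
                                    timepoint = tp, replicate = 1L)
  }
  out
}

# --- study assembly --------------------------------------------------------

#' Generate a full synthetic study
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, every modality is written
#'   to disk (FASTA, GFF3, bedGraph, BED6, narrowPeak, TSV truth table).
#' @param modalities subset of
#'   `c("tlseq", "longreads", "footprints", "chip", "peaks", "mnase")` to
#'   generate (the genome, annotation and truth table are always built).
#' @return a list of class `luti_study` with elements `config`, `genome`,
#'   `chrom_sizes`, `genes`, `truth`, `samples`, `tlseq_tracks`, `reads`,
#'   `fp_tracks`, `chip_tracks`, `peaks`, `mnase_tracks`.
#' @export
generate_study <- function(config = sim_config(), outdir = NULL,
                           modalities = c("tlseq", "longreads", "footprints",
                                          "chip", "peaks", "mnase")) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    plan <- .plan_loci(config)
    if (!nrow(plan$loci)) {
      study <- list(config = config, genome = setNames(
        .rand_dna(.SLOT_W), "chrI"), chrom_sizes = plan$chrom_sizes,
        genes = data.table(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character()),
        truth = data.table(), samples = data.table(),
        tlseq_tracks = list(), reads = data.table(), fp_tracks = list(),
        chip_tracks = list(), peaks = list(), mnase_tracks = list())
      class(study) <- "luti_study"
      if (!is.null(outdir)) .write_study(study, outdir)
      return(study)
    }
    # sanity: planted loci must not overlap across slots
    loci <- plan$loci
    spans <- loci[, .(chrom,
                      lo = pmin(distal_tss, tss, cds_start) - 900L,
                      hi = pmax(distal_tss, tss, cds_end) + 900L)]
    setorder(spans, chrom, lo)
    if (any(spans[, if (.N > 1L) any(lo[-1L] < hi[-.N]) else FALSE,
                  by = chrom]$V1))
      stop("planted loci overlap; reduce locus counts or sizes")
    gen <- .gen_genome(plan, config)
    tl <- if ("tlseq" %in% modalities) .gen_tlseq(plan, config) else
      list(tracks = list(), samples = data.table())
    reads <- if ("longreads" %in% modalities) .gen_longreads(plan, config)
      else data.table()
    fp <- if ("footprints" %in% modalities)
      .gen_footprints(plan, config, gen$uorf_starts) else list()
    chip <- if ("chip" %in% modalities) .gen_chip(plan, config) else list()
    peaks <- if ("peaks" %in% modalities) .gen_peaks(plan, config) else list()
    mnase <- if ("mnase" %in% modalities) .gen_mnase(plan, config) else list()
    truth <- loci[, .(gene_id, class, chrom, strand = event_strand,
                      gene_strand = strand, slot_start,
                      distal_tss, prox_tss = ifelse(class == "luti", tss,
                                                    NA_integer_),
                      tss, cds_start, cds_end, cds_length = cds_len,
                      tss_distance = ifelse(class == "luti", tss_distance,
                                            NA_integer_),
                      n_uorfs, repression_state, prox_fc, mark_gain, k4_gain,
                      plus_one_shift, fuzziness_delta, tf_bound,
                      e_pre, e_mei, e_prox_pre, e_prox_mei,
                      luti_expression = ifelse(class == "luti", "off;high",
                                               NA_character_))]
    truth$uorf_starts <- vapply(truth$gene_id, function(g) {
      u <- gen$uorf_starts[[g]]
      if (is.null(u)) NA_character_ else paste(u, collapse = ",")
    }, character(1))
    study <- list(config = config, genome = gen$genome,
                  chrom_sizes = plan$chrom_sizes, genes = .gen_genes(plan),
                  truth = truth, samples = tl$samples,
                  tlseq_tracks = tl$tracks, reads = reads, fp_tracks = fp,
                  chip_tracks = chip, peaks = peaks, mnase_tracks = mnase)
    class(study) <- "luti_study"
    if (!is.null(outdir)) .write_study(study, outdir)
    study
  })
}

#' @export
print.luti_study <- function(x, ...) {
  cat(sprintf("luti_study: %d loci (%s), seed %d\n", nrow(x$truth),
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", "),
              x$config$seed))
  invisible(x)
}

.write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(study$genome, file.path(outdir, "genome.fa"))
  write_gff3(study$genes, file.path(outdir, "genes.gff3"))
  write_feature_table(study$truth, file.path(outdir, "truth.tsv"))
  write_feature_table(study$samples, file.path(outdir, "samples.tsv"))
  if (length(study$tlseq_tracks)) {
    d <- file.path(outdir, "tlseq"); dir.create(d, showWarnings = FALSE)
    for (nm in names(study$tlseq_tracks))
      write_bedgraph(study$tlseq_tracks[[nm]],
                     file.path(d, paste0(nm, ".bedgraph")))
  }
  if (nrow(study$reads))
    write_bed6(study$reads, file.path(outdir, "longreads_meiotic.bed"))
  if (length(study$fp_tracks)) {
    d <- file.path(outdir, "footprints"); dir.create(d, showWarnings = FALSE)
    write_bedgraph(study$fp_tracks[["+"]],
                   file.path(d, "fp_meiotic.plus.bedgraph"))
    write_bedgraph(study$fp_tracks[["-"]],
                   file.path(d, "fp_meiotic.minus.bedgraph"))
  }
  if (length(study$chip_tracks)) {
    d <- file.path(outdir, "chip"); dir.create(d, showWarnings = FALSE)
    for (mark in names(study$chip_tracks))
      for (tr in study$chip_tracks[[mark]])
        write_bedgraph(tr, file.path(d, paste0(tr$sample, ".bedgraph")))
  }
  if (length(study$peaks)) {
    d <- file.path(outdir, "peaks"); dir.create(d, showWarnings = FALSE)
    for (r in seq_along(study$peaks))
      write_narrowpeak(study$peaks[[r]],
                       file.path(d, sprintf("tf_rep%d.narrowPeak", r)))
  }
  if (length(study$mnase_tracks)) {
    d <- file.path(outdir, "mnase"); dir.create(d, showWarnings = FALSE)
    for (tr in study$mnase_tracks)
      write_bedgraph(tr, file.path(d, paste0(tr$sample, ".bedgraph")))
  }
  invisible(outdir)
}
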