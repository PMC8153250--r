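# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately re-derive results by enumeration/simulation and never
# call the implementation paths they check.

# Connected components of the "within max_dist" graph over thresholded
# positions, O(n^2), then the singleton rule. Returns a list of sorted
# member-position vectors, ordered by first member.
oracle_distclu <- function(pos, pooled, threshold, max_dist,
                           remove_singletons, keep_singletons_above) {
  keep <- pooled >= threshold
  pos <- pos[keep]; pooled <- pooled[keep]
  n <- length(pos)
  if (!n) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_dist
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    frontier <- i
    comp[i] <- k
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- k
      frontier <- nb
    }
  }
  out <- lapply(seq_len(k), function(c) sort(pos[comp == c]))
  if (remove_singletons) {
    tot <- vapply(seq_len(k), function(c) sum(pooled[comp == c]), numeric(1))
    keep2 <- lengths(out) > 1L | tot > keep_singletons_above
    out <- out[keep2]
  }
  out[order(vapply(out, min, numeric(1)))]
}

# Brute-force aggregation oracle: clusters (list of member vectors) with
# pooled TPM >= tpm_threshold merge transitively when boundary gaps are
# <= max_dist.
oracle_aggregate <- function(members, pooled, tpm_threshold, max_dist) {
  keep <- pooled >= tpm_threshold
  members <- members[keep]
  n <- length(members)
  if (!n) return(list())
  lo <- vapply(members, min, numeric(1))
  hi <- vapply(members, max, numeric(1))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- max(lo[i], lo[j]) - min(hi[i], hi[j]) <= max_dist
  comp <- rep(NA_integer_, n); k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L; frontier <- i; comp[i] <- k
    while (length(frontier)) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- k
      frontier <- nb
    }
  }
  out <- lapply(seq_len(k), function(c) sort(unlist(members[comp == c])))
  out[order(vapply(out, min, numeric(1)))]
}

# Build a single-sample CTSS table from bare positions/counts (one chrom).
make_ctss <- function(pos, count, strand = "+", chrom = "chrI",
                      sample = "s1") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand)
  dt[[paste0("count_", sample)]] <- count
  normalize_tpm(dt)
}

# CTSS table with the pooled TPM forced to given values (library size chosen
# so TPM == count numerically: total = 1e6).
make_ctss_tpm <- function(pos, tpm, strand = "+", chrom = "chrI") {
  dt <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                               strand = strand, count_s1 = tpm)
  pad <- data.table::data.table(chrom = "chrPAD", pos = 1L, strand = "+",
                                count_s1 = 1e6 - sum(tpm))
  normalize_tpm(rbind(dt, pad))
}

# Naive per-offset ATG scan.
oracle_count_atg <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(0L)
  hits <- 0L
  for (i in 1:(n - 2)) if (substr(seq, i, i + 2) == "ATG") hits <- hits + 1L
  hits
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Monte-Carlo leaky-scanning oracle: explicit per-ribosome sequential
# Bernoulli scan. Returns expected per-uORF initiation counts per `depth`
# ribosomes, estimated from `n_rib` simulated ribosomes.
oracle_leaky_counts <- function(p, depth, n_rib = 1e5) {
  k <- length(p)
  hits <- integer(k)
  for (r in seq_len(n_rib)) {
    for (i in seq_len(k)) {
      if (runif(1) < p[i]) { hits[i] <- hits[i] + 1L; break }
    }
  }
  hits / n_rib * depth
}

# Monte-Carlo oracle for the per-rank probability that a uORF receives at
# least `min_reads` of `depth` ribosomes under leaky scanning (multinomial
# tail simulated from explicit per-ribosome scans, per replicate locus).
oracle_translated_freq <- function(p, depth, min_reads = 4, n_loci = 2000) {
  k <- length(p)
  trans <- matrix(FALSE, n_loci, k)
  for (l in seq_len(n_loci)) {
    counts <- integer(k)
    for (r in seq_len(depth)) {
      for (i in seq_len(k)) {
        if (runif(1) < p[i]) { counts[i] <- counts[i] + 1L; break }
      }
    }
    trans[l, ] <- counts >= min_reads
  }
  colMeans(trans)
}

# Rank-then-Pearson Spearman oracle (explicit formula, mid-ranks).
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact signed-rank p by enumerating all 2^n sign assignments (no ties).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# small deterministic study configuration for fast tests; ... overrides
small_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_luti = 6L, n_canonical = 6L, n_antisense = 2L,
         n_intergenic = 2L, n_intragenic = 2L),
    list(...))
  do.call(sim_config, args)
}
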