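test_that("TPM normalization matches its definition and conserves 1e6", {
  ctss <- make_ctss(pos = c(10, 20), count = c(10, 1e6 - 10))
  expect_equal(ctss$tpm_s1[1], 10)

  ctss <- make_ctss(pos = c(1, 5, 9, 13), count = rep(7, 4))
  expect_equal(ctss$tpm_s1, rep(2.5e5, 4))
  expect_equal(sum(ctss$tpm_s1), 1e6, tolerance = 1e-6)

  bad <- data.table::data.table(chrom = "chrI", pos = 1L, strand = "+",
                                count_s1 = 0)
  expect_error(normalize_tpm(bad), "zero library size")
})

test_that("distclu clustering follows threshold, distance and singleton rules", {
  # 100 (3 TPM) + 104 (2.5 TPM), maxDist 5 -> one cluster
  ctss <- make_ctss_tpm(c(100, 104), c(3, 2.5))
  cl <- cluster_ctss(ctss, threshold = 2, max_dist = 5)
  expect_equal(cl[cl$chrom == "chrI", ]$members[[1]], c(100L, 104L))

  # gap 6 > maxDist 5 -> two clusters (both above keepSingletonsAbove)
  ctss <- make_ctss_tpm(c(100, 106), c(4, 4))
  cl <- cluster_ctss(ctss, threshold = 2, max_dist = 5)
  expect_equal(nrow(cl[cl$chrom == "chrI", ]), 2L)

  # lone position at 2.5 TPM dropped; at 3.5 TPM kept (keepSingletonsAbove 3)
  drop <- cluster_ctss(make_ctss_tpm(100, 2.5), threshold = 2, max_dist = 5,
                       remove_singletons = TRUE, keep_singletons_above = 3)
  expect_false(any(drop$chrom == "chrI"))
  keep <- cluster_ctss(make_ctss_tpm(100, 3.5), threshold = 2, max_dist = 5,
                       remove_singletons = TRUE, keep_singletons_above = 3)
  expect_true(any(keep$chrom == "chrI"))

  expect_error(cluster_ctss(make_ctss_tpm(100, 3), max_dist = -1),
               "max_dist")
})

test_that("aggregation merges by boundary gap and applies the TPM floor", {
  # clusters [100-110] and [140-150]: gap 30 <= 50 -> one aggregate
  ctss <- make_ctss_tpm(c(100, 110, 140, 150), c(5, 5, 5, 5))
  cl <- cluster_ctss(ctss, threshold = 2, max_dist = 10)
  expect_equal(nrow(cl[cl$chrom == "chrI", ]), 2L)
  agg <- aggregate_clusters(cl, ctss, tpm_threshold = 1, max_dist = 50)
  agg <- agg[agg$chrom == "chrI", ]
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$start, 100L)
  expect_equal(agg$end, 150L)

  # clusters 200 bp apart stay separate
  ctss <- make_ctss_tpm(c(100, 300), c(5, 5))
  cl <- cluster_ctss(ctss, threshold = 2, max_dist = 5)
  agg <- aggregate_clusters(cl, ctss, tpm_threshold = 1, max_dist = 50)
  expect_equal(nrow(agg[agg$chrom == "chrI", ]), 2L)

  # sub-threshold cluster (0.5 TPM) is excluded from aggregation
  ctss <- make_ctss_tpm(c(100, 130), c(5, 0.5))
  cl <- cluster_ctss(ctss, threshold = 0.1, max_dist = 5,
                     remove_singletons = FALSE)
  agg <- aggregate_clusters(cl, ctss, tpm_threshold = 1, max_dist = 50)
  agg <- agg[agg$chrom == "chrI", ]
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$members[[1]], 100L)
})

test_that("dominant position takes the pooled-TPM maximum, 5'-most on ties", {
  expect_equal(dominant_position(c(100L, 104L), c(5, 3), "+"), 100L)
  expect_equal(dominant_position(c(100L, 104L), c(5, 5), "+"), 100L)
  expect_equal(dominant_position(c(100L, 104L), c(5, 5), "-"), 104L)
  expect_equal(dominant_position(42L, 1, "+"), 42L)
  expect_error(dominant_position(integer(), numeric(), "+"), "empty")
})

test_that("log2 fold change uses replicate means and the pseudocount", {
  clusters <- data.table::data.table(tpm_a1 = c(2, 2), tpm_a2 = c(2, 0),
                                     tpm_b1 = c(8, 4), tpm_b2 = c(8, 4))
  samples <- data.table::data.table(sample = c("a1", "a2", "b1", "b2"),
                                    timepoint = c("pre", "pre", "mei", "mei"))
  expect_equal(log2_fold_change(clusters, samples, "pre", "mei",
                                pseudocount = 0)[1], 2)
  expect_equal(log2_fold_change(clusters, samples, "pre", "pre",
                                pseudocount = 0)[1], 0)
  # 0 -> 4 TPM with pseudocount 0.5: log2(4.5/0.5) = log2(9)
  clusters2 <- data.table::data.table(tpm_a1 = 0, tpm_b1 = 4)
  samples2 <- data.table::data.table(sample = c("a1", "b1"),
                                     timepoint = c("pre", "mei"))
  expect_equal(log2_fold_change(clusters2, samples2, "pre", "mei",
                                pseudocount = 0.5), log2(9))
})

test_that("clustering equals the brute-force oracle on random instances", {
  set.seed(11)
  params <- list(strict = list(th = 2, rs = TRUE, ka = 3),
                 permissive = list(th = 1, rs = FALSE, ka = 3))
  for (rep in 1:30) {
    n <- sample(5:120, 1)
    pos <- sort(sample.int(2000, n))
    tpm <- round(runif(n, 0, 6), 2)
    ctss <- make_ctss_tpm(pos, tpm)
    for (p in params) {
      got <- cluster_ctss(ctss, threshold = p$th, max_dist = 5,
                          remove_singletons = p$rs,
                          keep_singletons_above = p$ka)
      got <- got[got$chrom == "chrI", ]
      want <- oracle_distclu(pos, tpm, p$th, 5, p$rs, p$ka)
      expect_equal(unname(got$members), want)
      # aggregation oracle on top of the strict clusters
      agg <- aggregate_clusters(got, ctss, tpm_threshold = 1, max_dist = 50)
      agg <- agg[agg$chrom == "chrI", ]
      want_agg <- oracle_aggregate(want, vapply(want, function(m)
        sum(tpm[match(m, pos)]), numeric(1)), 1, 50)
      expect_equal(unname(agg$members), want_agg)
    }
  }
})

test_that("clustering is invariant to input order and strand mirroring", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 60
    pos <- sort(sample.int(3000, n))
    tpm <- round(runif(n, 0, 5), 2)
    ctss <- make_ctss_tpm(pos, tpm)
    base <- cluster_ctss(ctss, threshold = 2, max_dist = 5)
    base <- base[base$chrom == "chrI", ]

    perm <- sample.int(n)
    shuf <- make_ctss_tpm(pos[perm], tpm[perm])
    got <- cluster_ctss(shuf, threshold = 2, max_dist = 5)
    expect_equal(got[got$chrom == "chrI", ]$members, base$members)

    # mirror the instance onto the minus strand: x -> 5000 - x
    mir <- make_ctss_tpm(5000L - pos, tpm, strand = "-")
    gotm <- cluster_ctss(mir, threshold = 2, max_dist = 5)
    gotm <- gotm[gotm$chrom == "chrI", ]
    expect_equal(lapply(rev(gotm$members), function(m) sort(5000L - m)),
                 base$members)
    expect_equal(rev(5000L - gotm$dominant_pos), base$dominant_pos)
  }
})

test_that("aggregation never decreases total pooled TPM of surviving clusters", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    pos <- sort(sample.int(4000, n))
    tpm <- round(runif(n, 0, 4), 2)
    ctss <- make_ctss_tpm(pos, tpm)
    cl <- cluster_ctss(ctss, threshold = 1, max_dist = 5,
                       remove_singletons = FALSE)
    agg <- aggregate_clusters(cl, ctss, tpm_threshold = 1, max_dist = 50)
    surviving <- cl[cl$pooled_tpm >= 1 & cl$chrom == "chrI", ]
    expect_gte(sum(agg[agg$chrom == "chrI", ]$pooled_tpm) + 1e-9,
               sum(surviving$pooled_tpm))
  }
})
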