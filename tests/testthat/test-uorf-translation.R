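test_that("leader ATG counting is frame-agnostic and strand-aware", {
  # plus strand: genome positions 0..5 hold the leader
  genome <- c(chrI = "ATGATGCCCCCC")
  got <- count_leader_atgs(genome, "chrI", 0L, 6L, "+")
  expect_equal(got$n_atg, 2L)
  expect_equal(got$uorf_starts, c(0L, 3L))

  genome2 <- c(chrI = "ATATGGCCCCCC")
  got2 <- count_leader_atgs(genome2, "chrI", 0L, 6L, "+")
  expect_equal(got2$n_atg, 1L)
  expect_equal(got2$uorf_starts, 2L)

  # minus strand: leader [5, 11) on the genome, revcomp "ATGCCC" -> GGGCAT
  genome3 <- c(chrI = "CCCCCGGGCATC")
  got3 <- count_leader_atgs(genome3, "chrI", 10L, 4L, "-")
  expect_equal(got3$n_atg, 1L)
  expect_equal(got3$uorf_starts, 10L)

  expect_error(count_leader_atgs(genome, "chrI", 6L, 0L, "+"), "distal")
  expect_error(count_leader_atgs(genome, "chrI", 4L, 10L, "-"), "distal")
})

test_that("leader ATG counting equals the naive scan on random sequences", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(30:300, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    genome <- c(chrI = seq)
    got <- count_leader_atgs(genome, "chrI", 0L, nchar(seq), "+")
    expect_equal(got$n_atg, oracle_count_atg(seq))
    # strand symmetry: the reverse-complemented genome with flipped strand
    rc <- c(chrI = oracle_revcomp(seq))
    gotm <- count_leader_atgs(rc, "chrI", nchar(seq) - 1L, -1L, "-")
    expect_equal(gotm$n_atg, got$n_atg)
    expect_equal(sort(nchar(seq) - 1L - gotm$uorf_starts), sort(got$uorf_starts))
  }
})

test_that("uORF translation needs >= 4 footprints in the first 6 codons", {
  mk_fp <- function(pos, val, strand = "+")
    signal_track(data.table::data.table(chrom = "chrI", start = pos,
                                        end = pos + 1L, value = val),
                 strand = strand, units = "footprints")
  expect_true(uorf_translated(mk_fp(c(100L, 110L, 117L), c(2, 1, 1)),
                              "chrI", 100L, "+"))
  expect_false(uorf_translated(mk_fp(c(100L, 110L, 117L), c(1, 1, 1)),
                               "chrI", 100L, "+"))
  # the 18th nt is in the window, the 19th is not
  expect_true(uorf_translated(mk_fp(117L, 4), "chrI", 100L, "+"))
  expect_false(uorf_translated(mk_fp(118L, 4), "chrI", 100L, "+"))
  # empty track: untranslated
  expect_false(uorf_translated(signal_track(NULL, strand = "+"),
                               "chrI", 100L, "+"))
  # minus strand: window extends to lower coordinates
  expect_true(uorf_translated(mk_fp(83L, 4, "-"), "chrI", 100L, "-"))
  expect_false(uorf_translated(mk_fp(82L, 4, "-"), "chrI", 100L, "-"))
})

test_that("first/last summary ranks uORFs 5' to 3'", {
  prof <- data.table::data.table(
    gene_id = c("a", "b"), n_atg = c(4L, 5L),
    translated = list(c(TRUE, TRUE, TRUE, TRUE),
                      c(TRUE, TRUE, TRUE, TRUE, TRUE)))
  s <- first_last_summary(prof)
  expect_equal(as.numeric(s), rep(1, 4))
  expect_equal(attr(s, "n"), 2L)

  # a 4-uORF gene: ranks 1,2 are the first two, 3,4 the last two
  prof2 <- data.table::data.table(
    gene_id = "a", n_atg = 4L,
    translated = list(c(TRUE, TRUE, FALSE, FALSE)))
  s2 <- first_last_summary(prof2)
  expect_equal(as.numeric(s2), c(1, 1, 0, 0))

  # genes below the qualifying count are excluded
  prof3 <- rbind(prof2, data.table::data.table(
    gene_id = "b", n_atg = 2L, translated = list(c(FALSE, FALSE))))
  expect_equal(attr(first_last_summary(prof3), "n"), 1L)
  expect_equal(attr(suppressWarnings(
    first_last_summary(prof3, min_uorfs = 4, strict = TRUE)), "n"), 0L)
  expect_warning(first_last_summary(prof3[n_atg < 1]), "no gene qualifies")
})

test_that("ATG background frequency matches arithmetic and the iid expectation", {
  # 5 ATGs in a 500 bp window -> 0.01 per bp
  seq <- paste(c(rep("C", 100), rep(c("ATG", "CCCCC"), 5),
                 rep("C", 360)), collapse = "")
  genome <- c(chrI = seq)
  bg <- atg_background(genome, data.table::data.table(
    chrom = "chrI", pos = 500L, strand = "+"))
  expect_equal(bg$freq, 5 / 500)
  expect_false(bg$truncated)

  # ATG-free window
  genome2 <- c(chrI = paste(rep("C", 600), collapse = ""))
  expect_equal(atg_background(genome2, data.table::data.table(
    chrom = "chrI", pos = 550L, strand = "+"))$freq, 0)

  # truncation at the contig edge is flagged
  expect_true(atg_background(genome2, data.table::data.table(
    chrom = "chrI", pos = 100L, strand = "+"))$truncated)

  # mean frequency over random windows approaches the iid expectation:
  # P(ATG at an offset) = 1/64 over 498 offsets of a 500 bp window
  set.seed(22)
  n_win <- 400L
  seqs <- vapply(seq_len(n_win), function(i)
    paste(sample(c("A", "C", "G", "T"), 520, replace = TRUE), collapse = ""),
    character(1))
  freqs <- vapply(seqs, function(s)
    atg_background(c(chrI = s), data.table::data.table(
      chrom = "chrI", pos = 510L, strand = "+"))$freq, numeric(1))
  expectation <- 498 / 64 / 500
  # per-window count is approx Poisson(498/64); sd of the mean frequency
  sd_mean <- sqrt(498 / 64) / 500 / sqrt(n_win)
  expect_lt(abs(mean(freqs) - expectation), 3 * sd_mean)
})

test_that("RPKM and translational efficiency follow their definitions", {
  expect_equal(rpkm(1000, 2000, 1e6), 500)
  expect_equal(translational_efficiency(10, 20), 0.5)
  expect_equal(translational_efficiency(7, 7), 1)
  expect_warning(te <- translational_efficiency(5, 0), "zero transcript")
  expect_true(is.na(te))
})

test_that("uORF profiles integrate leader scan and footprint calls", {
  st <- generate_study(small_config(seed = 5),
                       modalities = c("tlseq", "longreads", "footprints"))
  disc <- run_discovery(st)
  prof <- uorf_profiles(st$genome, disc$calls, st$fp_tracks)
  truth <- st$truth[st$truth$class == "luti", ]
  m <- merge(prof, truth[, c("gene_id", "n_uorfs")], by = "gene_id")
  # planted uORF counts are exact ground truth
  expect_equal(m$n_atg, m$n_uorfs)
  # translation frequency decreases with rank under leaky scanning
  long <- prof[prof$n_atg >= 4, ]
  first2 <- mean(vapply(long$translated, function(t) mean(t[1:2]), numeric(1)))
  last2 <- mean(vapply(long$translated, function(t)
    mean(t[c(length(t) - 1L, length(t))]), numeric(1)))
  expect_gt(first2, last2)
})
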