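# minimal cluster rows for classify_locus
mk_cluster <- function(id, chrom, strand, dom) {
  data.table::data.table(cluster_id = id, chrom = chrom, strand = strand,
                         dominant_pos = as.integer(dom))
}

mk_read <- function(chrom, start, end, strand, name = "r") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), name = name, score = 60,
                         strand = strand)
}

test_that("induction filter applies both strict thresholds", {
  expect_true(induction_filter(0.5, 4.5, pseudocount = 0))   # mean 2.5, lfc ~3.2
  expect_false(induction_filter(0.2, 3.6, pseudocount = 0))  # mean 1.9, lfc big
  expect_false(induction_filter(1.25, 5, pseudocount = 0))   # lfc exactly 2
  expect_true(induction_filter(1.25, 5.0001, pseudocount = 0))
})

test_that("spanning reads must start near the TSS and contain the whole CDS", {
  gene <- data.table::data.table(start = 500L, end = 1100L)
  # read 5' at the TSS, ending past the CDS: counted
  expect_equal(spanning_read_check(200L, "c", "+", gene,
                                   mk_read("c", 200, 1110, "+")), 1L)
  # read covering only half the CDS: not counted
  expect_equal(spanning_read_check(200L, "c", "+", gene,
                                   mk_read("c", 200, 800, "+")), 0L)
  # 5' end at tss + near_window + 1: outside the window
  expect_equal(spanning_read_check(200L, "c", "+", gene,
                                   mk_read("c", 251, 1200, "+"),
                                   near_window = 50L), 0L)
  expect_equal(spanning_read_check(200L, "c", "+", gene,
                                   mk_read("c", 250, 1200, "+"),
                                   near_window = 50L), 1L)
  # minus-strand: 5' end is end - 1
  gene_m <- data.table::data.table(start = 100L, end = 700L)
  expect_equal(spanning_read_check(900L, "c", "-", gene_m,
                                   mk_read("c", 80, 901, "-")), 1L)
})

test_that("the classification cascade follows the documented rules", {
  genes <- data.table::data.table(gene_id = "gA", chrom = "c",
                                  start = 1000L, end = 1900L, strand = "+")
  reads <- mk_read("c", 195, 1950, "+")

  # rule 1: spanning read + intervening promoter -> LUTI
  clusters <- rbind(mk_cluster("distal", "c", "+", 200),
                    mk_cluster("prox", "c", "+", 880))
  call <- classify_locus(clusters[1], clusters, genes, reads)
  expect_equal(call$class, "luti_candidate")
  expect_equal(call$gene_id, "gA")
  expect_equal(call$prox_tss, 880L)
  expect_gte(call$spanning_read_count, 1L)

  # rule 2: spanning read but no intervening promoter -> canonical
  call2 <- classify_locus(clusters[1], clusters[1], genes, reads)
  expect_equal(call2$class, "canonical")

  # the second promoter must lie strictly between TSS and CDS 5' end
  not_between <- rbind(mk_cluster("distal", "c", "+", 200),
                       mk_cluster("inside_cds", "c", "+", 1200))
  expect_equal(classify_locus(not_between[1], not_between, genes,
                              reads)$class, "canonical")

  # rule 3: TSS mid-CDS on the opposite strand -> antisense
  anti <- mk_cluster("anti", "c", "-", 1450)
  expect_equal(classify_locus(anti, anti, genes, reads)$class, "antisense")

  # rule 4: TSS mid-CDS, same strand, no spanning evidence -> intragenic
  intra <- mk_cluster("intra", "c", "+", 1450)
  expect_equal(classify_locus(intra, intra, genes,
                              reads[0])$class, "intragenic")

  # rule 5: otherwise intergenic
  inter <- mk_cluster("inter", "c", "+", 5000)
  expect_equal(classify_locus(inter, inter, genes, reads)$class,
               "intergenic")
})

test_that("classification is invariant to translation and strand mirroring", {
  genes <- data.table::data.table(gene_id = "gA", chrom = "c",
                                  start = 1000L, end = 1900L, strand = "+")
  reads <- mk_read("c", 195, 1950, "+")
  clusters <- rbind(mk_cluster("distal", "c", "+", 200),
                    mk_cluster("prox", "c", "+", 880))
  base <- classify_locus(clusters[1], clusters, genes, reads)

  # genome-wide translation by +7777
  sh <- 7777L
  genes_t <- data.table::copy(genes)[, `:=`(start = start + sh,
                                            end = end + sh)]
  reads_t <- data.table::copy(reads)[, `:=`(start = start + sh,
                                            end = end + sh)]
  clusters_t <- data.table::copy(clusters)[, dominant_pos := dominant_pos + sh]
  got_t <- classify_locus(clusters_t[1], clusters_t, genes_t, reads_t)
  expect_equal(got_t$class, base$class)
  expect_equal(got_t$prox_tss - sh, base$prox_tss)

  # strand mirroring around L = 10000: x -> L - 1 - x, intervals flip
  L <- 10000L
  genes_m <- data.table::data.table(gene_id = "gA", chrom = "c",
                                    start = L - genes$end,
                                    end = L - genes$start, strand = "-")
  reads_m <- data.table::data.table(chrom = "c", start = L - reads$end,
                                    end = L - reads$start, name = "r",
                                    score = 60, strand = "-")
  clusters_m <- rbind(
    mk_cluster("distal", "c", "-", L - 1L - 200L),
    mk_cluster("prox", "c", "-", L - 1L - 880L))
  got_m <- classify_locus(clusters_m[1], clusters_m, genes_m, reads_m)
  expect_equal(got_m$class, base$class)
  expect_equal(L - 1L - got_m$prox_tss, base$prox_tss)
})

test_that("the synthetic study is classified exactly at zero noise", {
  st <- generate_study(small_config(seed = 3, tag_dispersion = 0),
                       modalities = c("tlseq", "longreads"))
  disc <- run_discovery(st)
  truth <- st$truth
  calls <- disc$calls
  got <- table(calls$class)
  expect_equal(unname(got[c("luti_candidate", "canonical", "antisense",
                            "intergenic", "intragenic")]),
               unname(table(truth$class)[c("luti", "canonical", "antisense",
                                           "intergenic", "intragenic")]))
  luti_truth <- truth[truth$class == "luti", ]
  luti_calls <- calls[calls$class == "luti_candidate", ]
  expect_setequal(luti_calls$gene_id, luti_truth$gene_id)
  # distal and proximal dominant positions sit on the planted TSSs
  m <- merge(luti_calls, luti_truth, by = "gene_id")
  expect_true(all(abs(m$distal_tss.x - m$distal_tss.y) <= 2))
  expect_true(all(abs(m$prox_tss.x - m$prox_tss.y) <= 2))
  expect_true(all(m$spanning_read_count >= 1))
})
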