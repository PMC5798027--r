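# CNS calling: threshold/merge/length/CDS-exclusion rules and annotation.

test_that("call_cns merges across sub-threshold gaps and averages over all
          bases of the merged interval", {
  # scores: 4 bases at 0.8, 2 at 0.5, 4 at 0.9, rest 0 (clade of 10)
  matched <- c(8, 8, 8, 8, 5, 5, 9, 9, 9, 9, rep(0, 10))
  tr <- make_track(matched, 10)
  cns <- call_cns(tr, make_regions(20))
  expect_equal(nrow(cns), 1)
  expect_equal(c(cns$start, cns$end), c(0, 10))
  # oracle-computed mean over the merged interval, gap bases included
  expect_equal(cns$mean_score, sum(matched[1:10]) / 10 / 10)  # 0.78
  orc <- oracle_call_cns(matched / 10, rep(FALSE, 20))
  expect_equal(unname(cbind(cns$start + 1, cns$end)), unname(orc))
})

test_that("stated rules: no merge across gaps > 3, short fragments drop,
          CDS-trimmed candidates below 6 bp drop", {
  # runs of 4 and 5 separated by gap 5: nothing survives
  m <- c(rep(8, 4), rep(0, 5), rep(8, 5), rep(0, 6))
  expect_equal(nrow(call_cns(make_track(m, 10), make_regions(20))), 0)

  # run [0,10) with CDS on [0,5): candidate [5,10) is 5 bp < 6
  m2 <- c(rep(8, 10), rep(0, 10))
  regions <- make_regions(20, cds = data.frame(start = 0, end = 5))
  expect_equal(nrow(call_cns(make_track(m2, 10), regions)), 0)

  expect_error(call_cns(make_track(m2, 10), regions, threshold = 1.5),
               "threshold")
})

test_that("a merge never bridges a CDS base even within the gap
          allowance", {
  m <- c(rep(8, 6), 0, rep(8, 6), rep(0, 7))
  regions <- make_regions(20, cds = data.frame(start = 6, end = 7))
  cns <- call_cns(make_track(m, 10), regions)
  expect_equal(nrow(cns), 2)
  expect_equal(cns$start, c(0, 7))
  expect_equal(cns$end, c(6, 13))
})

test_that("call_cns equals the naive oracle on randomized tracks", {
  set.seed(42)
  for (i in 1:2000) {
    L <- sample(30:60, 1)
    matched <- sample(0:10, L, replace = TRUE)
    is_cds <- stats::runif(L) < 0.2
    regions <- make_regions(L)
    regions$labels$chr1[is_cds] <- 1L
    cns <- call_cns(make_track(matched, 10), regions)
    orc <- oracle_call_cns(matched / 10, is_cds)
    expect_equal(unname(cbind(cns$start + 1, cns$end)), unname(orc))
  }
})

test_that("total CNS bp is monotone in threshold, merge gap and minimum
          length", {
  set.seed(8)
  matched <- sample(0:10, 500, replace = TRUE)
  tr <- make_track(matched, 10)
  regions <- make_regions(500)
  bp <- function(cns) sum(cns$length)
  th_sweep <- vapply(seq(0.1, 1, 0.1), function(th)
    bp(call_cns(tr, regions, threshold = th)), 0)
  expect_true(all(diff(th_sweep) <= 0))
  mg_sweep <- vapply(0:6, function(g)
    bp(call_cns(tr, regions, merge_gap = g)), 0)
  expect_true(all(diff(mg_sweep) >= 0))
  ml_sweep <- vapply(c(1, 3, 6, 10, 20), function(ml)
    bp(call_cns(tr, regions, min_len = ml)), 0)
  expect_true(all(diff(ml_sweep) <= 0))
  # output is sorted, disjoint, never on CDS
  regions2 <- make_regions(500, cds = data.frame(start = c(100, 300),
                                                 end = c(150, 310)))
  cns <- call_cns(tr, regions2)
  expect_true(all(diff(cns$start) > 0))
  expect_true(all(cns$start[-1] >= cns$end[-nrow(cns)]))
  for (i in seq_len(nrow(cns)))
    expect_false(any(regions2$labels$chr1[(cns$start[i] + 1):cns$end[i]] ==
                       1L))
})

test_that("categorize_cns picks the majority label with the stated tie
          priority", {
  L <- 30
  lab <- rep(5L, L)          # intergenic
  lab[1:7] <- 4L             # intron on [0,7)
  regions <- region_index(list(chr1 = lab))
  cns <- data.frame(chrom = "chr1", start = 0, end = 10)
  expect_equal(categorize_cns(cns, regions), "intron")   # 7 vs 3

  lab2 <- rep(4L, 10); lab2[1:5] <- 3L  # 5 bp UTR3 + 5 bp intron
  expect_equal(categorize_cns(data.frame(chrom = "chr1", start = 0,
                                         end = 10),
                              region_index(list(chr1 = lab2))), "UTR3")

  expect_equal(categorize_cns(cns, region_index(list(chr1 = rep(5L, 30)))),
               "intergenic")
})

test_that("summarize_cns reports totals, lower-middle medians and
          percentages that sum to 100", {
  one <- structure(data.frame(chrom = "chr1", start = 0, end = 8,
                              length = 8, mean_score = 0.8,
                              category = "intron",
                              stringsAsFactors = FALSE),
                   class = c("cns_set", "data.frame"))
  s <- summarize_cns(one, "test")
  expect_equal(s$total_number, 1)
  expect_equal(s$mean_length, 8L)
  expect_equal(s$median_length, 8)
  expect_equal(unname(s$pct_category["intron"]), 100)

  set.seed(12)
  n <- 101
  many <- structure(data.frame(
    chrom = "chr1", start = seq(0, by = 50, length.out = n),
    end = seq(0, by = 50, length.out = n) + sample(6:40, n, TRUE),
    mean_score = stats::runif(n, 0.7, 1),
    category = sample(c("intergenic", "UTR5", "UTR3", "intron"), n, TRUE),
    stringsAsFactors = FALSE), class = c("cns_set", "data.frame"))
  many$length <- many$end - many$start
  s2 <- summarize_cns(many, "x")
  expect_equal(sum(s2$pct_category), 100, tolerance = 1e-9)
  expect_equal(s2$total_length, sum(many$length))
  expect_equal(s2$median_length, sort(many$length)[51])
  # even count: lower middle
  s3 <- summarize_cns(many[1:4, ], "x")
  expect_equal(s3$median_length, sort(many$length[1:4])[2])
})

test_that("constrained_fraction matches truth bookkeeping on fixtures and
          handles degenerate tracks", {
  regions <- make_regions(100)
  expect_equal(constrained_fraction(make_track(integer(100), 10),
                                    regions)$genome_fraction, 0)
  expect_equal(constrained_fraction(make_track(rep(10L, 100), 10),
                                    regions)$genome_fraction, 1)

  set.seed(3)
  matched <- sample(0:10, 1000, replace = TRUE)
  tr <- make_track(matched, 10)
  cf <- constrained_fraction(tr, make_regions(1000), threshold = 0.7)
  expect_equal(cf$constrained_bp, sum(matched >= 7))
})

test_that("downstream-gene association is strand-aware and windowed", {
  genes <- data.frame(gene_id = c("gp", "gm", "gfar"), chrom = "chr1",
                      start = c(500, 2000, 9000), end = c(900, 2400, 9400),
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = paste0(genes$gene_id, ".1"),
                   gene_id = genes$gene_id, chrom = "chr1",
                   start = genes$start, end = genes$end,
                   strand = genes$strand, stringsAsFactors = FALSE)
  models <- gene_models(genes, tx, .empty <- data.frame(
    tx_id = character(0), gene_id = character(0), chrom = character(0),
    start = numeric(0), end = numeric(0), strand = character(0)),
    .empty, .empty, .empty, .empty)
  cns <- structure(data.frame(
    chrom = "chr1", start = c(100, 2500), end = c(200, 2600),
    length = 100, mean_score = 0.9, category = "intergenic",
    stringsAsFactors = FALSE), class = c("cns_set", "data.frame"))
  # gp TSS at 500: 300 bp downstream of CNS[100,200) on + strand
  # gm TSS at 2399: CNS[2500,2600) starts 100 bp 5' on the - strand
  hits <- genes_downstream_of_cns(cns, models, window = 1000)
  expect_setequal(hits, c("gp", "gm"))
  expect_length(genes_downstream_of_cns(cns, models, window = 50), 0)
  empty <- cns[0, ]
  expect_length(genes_downstream_of_cns(empty, models), 0)
})

test_that("bigfoot genes need both a large span and enough CNSs", {
  genes <- data.frame(gene_id = c("big", "small"), chrom = "chr1",
                      start = c(0, 10000), end = c(5000, 11000),
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = paste0(genes$gene_id, ".1"),
                   gene_id = genes$gene_id, chrom = "chr1",
                   start = genes$start, end = genes$end, strand = "+",
                   stringsAsFactors = FALSE)
  e <- data.frame(tx_id = character(0), gene_id = character(0),
                  chrom = character(0), start = numeric(0),
                  end = numeric(0), strand = character(0))
  models <- gene_models(genes, tx, e, e, e, e, e)
  mk <- function(starts) structure(data.frame(
    chrom = "chr1", start = starts, end = starts + 20, length = 20,
    mean_score = 0.9, category = "intron", stringsAsFactors = FALSE),
    class = c("cns_set", "data.frame"))
  expect_equal(bigfoot_genes(models, mk(seq(100, 4500, by = 800))), "big")
  expect_length(bigfoot_genes(models, mk(seq(100, 4500, by = 1500))), 0)
  expect_length(bigfoot_genes(models, mk(seq(10100, 10900, by = 130))), 0)
})

test_that("feature overlap fractions match planted truth", {
  sim <- simulate_cns_data(sim_config(seed = 21, genome_length = 20000,
                                      n_genes = 3, n_elements = 12))
  el <- sim$truth$elements
  # declare half the elements "repeat" features
  feats <- el[seq(1, nrow(el), by = 2), ]
  feats$name <- "repeat"
  cns <- structure(cbind(el, length = el$end - el$start, mean_score = 1,
                         category = "intergenic"),
                   class = c("cns_set", "data.frame"))
  ov <- feature_overlap(cns, feats)
  expect_equal(ov$fraction, nrow(feats) / nrow(el))
  expect_equal(unname(ov$by_class["repeat"]), ov$fraction)
  none <- feature_overlap(cns[0, ], feats)
  expect_true(is.na(none$fraction))
})
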