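# Population-level selection statistics.

test_that("classify_snp_sites uses the stated class boundaries", {
  # scores 0, 0.2, 0.3, 0.7, 0.89, 0.9, 1 for a clade of 100
  tr <- make_track(c(0L, 20L, 30L, 70L, 89L, 90L, 100L), 100)
  snps <- snp_records(rep("chr1", 7), 0:6, rep("A", 7), rep("C", 7),
                      rep(100, 7), rep(5, 7))
  cls <- classify_snp_sites(snps, tr)
  expect_equal(as.character(cls),
               c("nonconserved", "nonconserved", NA, "conserved",
                 "conserved", "extreme", "extreme"))
})

test_that("classify_snp_sites equals a per-site lookup oracle on random
          tracks", {
  set.seed(55)
  n_sp <- 10L
  matched <- sample(0:n_sp, 500, replace = TRUE)
  tr <- make_track(matched, n_sp)
  pos <- sample(0:499, 200)
  snps <- snp_records(rep("chr1", 200), pos, rep("A", 200), rep("C", 200),
                      rep(100, 200), rep(5, 200))
  cls <- classify_snp_sites(snps, tr)
  oracle <- vapply(pos, function(p) {
    s <- matched[p + 1] / n_sp
    if (s <= 0.2) "nonconserved"
    else if (s >= 0.9) "extreme"
    else if (s >= 0.7) "conserved"
    else NA_character_
  }, "")
  expect_equal(as.character(cls), oracle)
})

test_that("maf_spectrum bins respect the rare bound and the fold cap", {
  tr <- make_track(rep(0L, 10), 10)
  snps <- snp_records(rep("chr1", 3), c(0, 1, 2), rep("A", 3), rep("C", 3),
                      c(1000, 100, 100), c(5, 98, 2))
  cls <- classify_snp_sites(snps, tr)
  spec <- maf_spectrum(snps, cls)
  expect_equal(sum(spec), 3)
  expect_equal(unname(spec["nonconserved", 1]), 1)  # MAF 0.005: rare bin
  expect_equal(unname(spec["nonconserved", 2]), 2)  # 0.02 twice (folded)
  # per-class counts sum to the class SNP totals
  expect_equal(unname(rowSums(spec)), as.vector(table(cls)))
})

test_that("folding never exceeds 0.5 and spectra account for every
          classified SNP", {
  set.seed(91)
  n <- 500
  an <- 1000
  ac <- sample(1:999, n, replace = TRUE)
  snps <- snp_records(rep("chr1", n), sample(0:999, n), rep("A", n),
                      rep("C", n), rep(an, n), ac)
  expect_true(all(snps$maf <= 0.5))
  tr <- make_track(sample(0:10, 1000, replace = TRUE), 10)
  cls <- classify_snp_sites(snps, tr)
  spec <- maf_spectrum(snps, cls)
  expect_equal(sum(spec), sum(!is.na(cls)))
})

test_that("maf_spectrum recovers beta-mixture class shapes within 3
          binomial SDs", {
  set.seed(33)
  n <- 4000
  shapes <- list(nonconserved = c(0.8, 3), extreme = c(0.25, 10))
  for (cl in names(shapes)) {
    maf <- 0.5 * stats::rbeta(n, shapes[[cl]][1], shapes[[cl]][2])
    ac <- pmin(pmax(round(maf * 6000), 1), 3000)
    snps <- snp_records(rep("chr1", n), seq_len(n) - 1, rep("A", n),
                        rep("C", n), rep(6000, n), ac)
    m <- if (cl == "extreme") 10L else 0L
    tr <- make_track(rep(m, n), 10)
    spec <- maf_spectrum(snps, classify_snp_sites(snps, tr))
    p_rare <- stats::pbeta(0.02, shapes[[cl]][1], shapes[[cl]][2])
    got <- spec[cl, 1]
    expect_lt(abs(got - n * p_rare), 3 * sqrt(n * p_rare * (1 - p_rare)))
  }
})

test_that("snp_depletion computes density folds with edge cases", {
  genome <- genome_dict(c(chr1 = 10000), "ref")
  # 2/kb genome-wide vs 1/kb inside the constrained half
  snps <- snp_records(rep("chr1", 20),
                      c(seq(0, 4995, length.out = 15),
                        seq(5000, 9995, length.out = 5)),
                      rep("A", 20), rep("C", 20), rep(100, 20), rep(5, 20))
  constrained <- data.frame(chrom = "chr1", start = 5000, end = 10000)
  d <- snp_depletion(snps, constrained, genome)
  expect_equal(d$fold, (20 / 10000) / (5 / 5000))
  whole <- snp_depletion(snps, data.frame(chrom = "chr1", start = 0,
                                          end = 10000), genome)
  expect_equal(whole$fold, 1)
  none <- snp_depletion(snps, data.frame(chrom = "chr1", start = 4996,
                                         end = 4999), genome)
  expect_equal(none$fold, Inf)
})

test_that("invariant sites are exactly the full-coverage identical
          columns and sit inside the extreme class", {
  set.seed(14)
  matched <- sample(0:10, 300, replace = TRUE)
  tr <- make_track(matched, 10)
  inv <- invariant_sites(tr)
  expect_equal(inv$pos, which(matched == 10) - 1)
  snps <- snp_records(rep("chr1", nrow(inv)), inv$pos,
                      rep("A", nrow(inv)), rep("C", nrow(inv)),
                      rep(100, nrow(inv)), rep(5, nrow(inv)))
  expect_true(all(classify_snp_sites(snps, tr) == "extreme"))
})

test_that("tabulate_effects counts one entry per effect record and
          handles the empty case", {
  tab <- tabulate_effects(c("missense_variant", "missense_variant",
                            "intron_variant"))
  expect_equal(tab$count[tab$type == "missense_variant"], 2)
  expect_equal(tab$percentage[tab$type == "missense_variant"], 66.67)
  expect_equal(sum(tab$percentage), 100, tolerance = 0.1)
  empty <- tabulate_effects(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("effects at invariant sites match planted truth in the
          simulator", {
  sim <- simulate_cns_data(sim_config(seed = 61, genome_length = 20000,
                                      n_genes = 4, n_elements = 15,
                                      snp_density = 0.02))
  tr <- score_genome(sim$blocks, "all", sim$clade_map, sim$genome)
  inv <- invariant_sites(tr)
  eff <- effects_at_sites(sim$snps, inv)
  truth <- sim$truth$snp_classes
  at_inv <- truth[paste(truth$chrom, truth$pos) %in%
                    paste(inv$chrom, inv$pos) & !is.na(truth$effect), ]
  expect_equal(sort(eff), sort(at_inv$effect))
  expect_equal(nrow(tabulate_effects(effects_at_sites(sim$snps,
                                                      inv[0, ]))), 0)
})

test_that("variation_correlation recovers exact counts and degenerate
          inputs", {
  counts <- data.frame(intra = c(3, 7, 0, 12), inter = c(5, 2, 0, 9))
  w <- build_variation_world(counts)
  vc <- variation_correlation(w$models, w$snps, w$track)
  expect_equal(vc$per_gene$intra, counts$intra)
  expect_equal(vc$per_gene$inter, counts$inter)
  expect_equal(vc$r, stats::cor(counts$intra, counts$inter))

  ident <- build_variation_world(data.frame(intra = c(1, 5, 9),
                                            inter = c(1, 5, 9)))
  expect_equal(variation_correlation(ident$models, ident$snps,
                                     ident$track)$r, 1)

  const <- build_variation_world(data.frame(intra = c(2, 4, 8),
                                            inter = c(3, 3, 3)))
  expect_true(is.na(variation_correlation(const$models, const$snps,
                                          const$track)$r))
})

test_that("species_sum inter mode sums mismatches over species", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 10,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = "g.1", gene_id = "g", chrom = "chr1", start = 0,
                   end = 10, strand = "+", stringsAsFactors = FALSE)
  e <- tx[0, c(1, 2, 3, 4, 5, 6)]
  models <- gene_models(genes, tx, e, e, e, e, e)
  tr <- score_track("t", 5L, list(chr1 = list(
    matched = c(2L, 5L, rep(0L, 8)), aligned = c(5L, 5L, rep(0L, 8)))))
  snps <- snp_records(character(0), numeric(0), character(0),
                      character(0), numeric(0), numeric(0))
  pos_mode <- variation_correlation(models, snps, tr)$per_gene$inter
  sum_mode <- variation_correlation(models, snps, tr,
                                    inter_mode = "species_sum")$
    per_gene$inter
  expect_equal(pos_mode, 1)
  expect_equal(sum_mode, 3)
})

test_that("outlier_genes flags relaxed and lineage-restricted patterns", {
  # gene A spans invariant sites carrying a high-MAF SNP; gene B is clean
  matched <- c(rep(10L, 50), rep(3L, 50))
  tr <- make_track(matched, 10, aligned = rep(10L, 100))
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chr1",
                      start = c(0, 50), end = c(50, 100), strand = "+",
                      stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = c("A.1", "B.1"), gene_id = c("A", "B"),
                   chrom = "chr1", start = genes$start, end = genes$end,
                   strand = "+", stringsAsFactors = FALSE)
  e <- tx[0, ]
  models <- gene_models(genes, tx, e, e, e, e, e)
  snps <- snp_records(c("chr1", "chr1"), c(10, 70), c("A", "A"),
                      c("C", "C"), c(100, 100), c(30, 30))
  rel <- outlier_genes(models, snps, tr, maf_min = 0.1)
  expect_equal(rel$genes, "A")
  expect_equal(nrow(rel$snps), 1)
  none <- outlier_genes(models, snps, tr, maf_min = 0.4)
  expect_length(none$genes, 0)
  # maf_min 0: every invariant-site SNP flagged
  all_inv <- outlier_genes(models, snps, tr, maf_min = 0)
  expect_equal(nrow(all_inv$snps), 1)

  # lineage-restricted: no SNPs but many cross-species mismatches
  lr <- outlier_genes(models, snps[0, ], tr,
                      mode = "conserved_in_reference_only",
                      inter_ceiling = 40)
  expect_equal(lr$genes, "B")
})
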