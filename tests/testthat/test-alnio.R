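# Readers/writers and the single 0-based half-open coordinate convention.

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("read_maf parses blocks, gaps in the reference consume no
          coordinate, and empty files give empty streams", {
  f <- write_tmp(c("##maf version=1", "a score=100",
                   "s ref.chr1 10 4 + 1000 AC-GT",
                   "s sp1.chrX 0 5 + 500 ACAGT", ""))
  blocks <- read_maf(f, "ref")
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$ref_start, 10)
  expect_equal(block_ref_span(blocks[[1]]), 4)
  expect_equal(blocks[[1]]$score, 100)
  expect_named(blocks[[1]]$rows, "sp1")

  expect_length(read_maf(write_tmp(character(0)), "ref"), 0)
})

test_that("read_maf rejects malformed blocks and flags unknown species", {
  ragged <- write_tmp(c("a", "s ref.chr1 0 4 + 100 ACGT",
                        "s sp1.c 0 5 + 100 ACGTT"))
  expect_error(read_maf(ragged, "ref"), "ragged.*block 1")

  noref <- write_tmp(c("a", "s sp1.c 0 4 + 100 ACGT",
                       "s sp2.c 0 4 + 100 ACGT"))
  expect_error(read_maf(noref, "ref"), "0 reference rows")

  revref <- write_tmp(c("a", "s ref.chr1 0 4 - 100 ACGT",
                        "s sp1.c 0 4 + 100 ACGT"))
  expect_error(read_maf(revref, "ref"), "forward strand")

  cmap <- clade_map(list(all = "sp1"))
  stranger <- write_tmp(c("a", "s ref.chr1 0 4 + 100 ACGT",
                          "s spX.c 0 4 + 100 ACGT"))
  expect_warning(b <- read_maf(stranger, "ref", cmap), "spX")
  expect_named(b[[1]]$rows, "spX")  # row kept
})

test_that("read_maf honors the optional minimum block-score filter", {
  f <- write_tmp(c("a score=500", "s ref.chr1 0 4 + 100 ACGT",
                   "s sp1.c 0 4 + 100 ACGT",
                   "a score=2000", "s ref.chr1 10 4 + 100 ACGT",
                   "s sp1.c 0 4 + 100 ACGT"))
  expect_length(read_maf(f, "ref"), 2)
  expect_length(read_maf(f, "ref", min_block_score = 1000), 1)
})

test_that("MAF round-trips through write_maf against the generator", {
  sim <- simulate_cns_data(sim_config(seed = 5, genome_length = 20000,
                                      n_genes = 2, n_elements = 4,
                                      n_species = 3))
  f <- tempfile()
  write_maf(sim$blocks, f, sim$genome)
  back <- read_maf(f, "refsp", sim$clade_map)
  expect_length(back, length(sim$blocks))
  expect_equal(vapply(back, block_ref_span, 0),
               vapply(sim$blocks, block_ref_span, 0))
  expect_equal(vapply(back, `[[`, "", "ref_text"),
               vapply(sim$blocks, `[[`, "", "ref_text"))
  expect_equal(lapply(back, `[[`, "rows"), lapply(sim$blocks, `[[`, "rows"))
})

test_that("read_gff3 derives introns and UTRs (hand-derived two-exon
          case, strand symmetry, single-exon degenerate case)", {
  genome <- genome_dict(c(chr1 = 1000), "ref")
  m <- read_gff3(write_tmp(toy_gff_lines("+")), genome)
  expect_equal(m$introns[c("start", "end")],
               data.frame(start = 100, end = 200))
  expect_equal(m$utr5[c("start", "end")], data.frame(start = 0, end = 50))
  expect_equal(m$utr3[c("start", "end")],
               data.frame(start = 250, end = 300))

  mm <- read_gff3(write_tmp(toy_gff_lines("-")), genome)
  expect_equal(mm$utr5[c("start", "end")],
               data.frame(start = 250, end = 300))
  expect_equal(mm$utr3[c("start", "end")], data.frame(start = 0, end = 50))

  single <- c("##gff-version 3",
              "chr1\tt\tgene\t1\t90\t.\t+\t.\tID=g1",
              "chr1\tt\tmRNA\t1\t90\t.\t+\t.\tID=t1;Parent=g1",
              "chr1\tt\texon\t1\t90\t.\t+\t.\tParent=t1",
              "chr1\tt\tCDS\t1\t90\t.\t+\t0\tParent=t1")
  ms <- read_gff3(write_tmp(single), genome)
  expect_equal(nrow(ms$introns), 0)
  expect_equal(nrow(ms$utr5), 0)
  expect_equal(nrow(ms$utr3), 0)
})

test_that("read_gff3 rejects CDS outside exons and out-of-bounds
          features", {
  genome <- genome_dict(c(chr1 = 1000), "ref")
  bad_cds <- c("##gff-version 3",
               "chr1\tt\tgene\t1\t300\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1",
               "chr1\tt\tCDS\t51\t150\t.\t+\t0\tParent=t1")
  expect_error(read_gff3(write_tmp(bad_cds), genome), "outside its parent")

  beyond <- c("##gff-version 3",
              "chr1\tt\tgene\t900\t1200\t.\t+\t.\tID=g1")
  expect_error(read_gff3(write_tmp(beyond), genome), "beyond chromosome")
})

test_that("GFF3 1-based to internal 0-based conversion is exact at the
          chromosome boundary", {
  genome <- genome_dict(c(chr1 = 100), "ref")
  lines <- c("##gff-version 3", "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
             "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
             "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1",
             "chr1\tt\tCDS\t1\t100\t.\t+\t0\tParent=t1")
  m <- read_gff3(write_tmp(lines), genome)
  # first base is position 0, end is half-open at the chromosome length
  expect_equal(m$genes$start, 0)
  expect_equal(m$genes$end, 100)
  # one past the end errors
  lines[2] <- "chr1\tt\tgene\t1\t101\t.\t+\t.\tID=g1"
  expect_error(read_gff3(write_tmp(lines), genome), "beyond chromosome")
})

test_that("read_vcf computes folded MAF and skips or splits
          multiallelics", {
  vcf <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1,length=1000>",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"ac\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"an\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t1\t.\tA\tC\t.\tPASS\tAC=3;AN=100",
           "chr1\t10\t.\tG\tT\t.\tPASS\tAC=98;AN=100",
           "chr1\t20\t.\tG\tT,C\t.\tPASS\tAC=5,2;AN=100")
  f <- write_tmp(vcf)
  expect_warning(snps <- read_vcf(f), "1 multiallelic")
  expect_equal(nrow(snps), 2)
  expect_equal(snps$pos, c(0, 9))        # 1-based VCF -> 0-based internal
  expect_equal(snps$maf, c(0.03, 0.02))  # folding: 98/100 -> 0.02
  expect_equal(attr(snps, "n_multiallelic"), 1)

  split <- read_vcf(f, multiallelic = "split")
  expect_equal(nrow(split), 4)
  expect_equal(split$alt[3:4], c("T", "C"))
})

test_that("VCF round-trips through write_vcf with ANN annotations", {
  snps <- snp_records("chr1", c(4, 9), c("A", "G"), c("T", "C"),
                      c(6000, 6000), c(30, 2999),
                      effects = list("missense_variant", NULL),
                      impacts = list("MODERATE", NULL))
  genome <- genome_dict(c(chr1 = 100), "ref")
  f <- tempfile(fileext = ".vcf")
  write_vcf(snps, f, genome)
  back <- read_vcf(f)
  expect_equal(back$pos, snps$pos)
  expect_equal(back$maf, snps$maf)
  expect_equal(back$effects[[1]], "missense_variant")
  expect_equal(back$impacts[[1]], "MODERATE")
  expect_null(back$effects[[2]])
})

test_that("bedGraph writer merges runs of equal value and round-trips", {
  tr <- make_track(c(0, 0, 7, 7, 10, 10, 10, 0, 0, 0), 10)
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, f, drop_zero = FALSE)
  body <- readLines(f)[-1]
  expect_length(body, 4)   # 0-run, 0.7-run, 1.0-run, 0-run
  back <- read_bedgraph(f)
  expect_equal(back$start, c(0, 2, 4, 7))
  expect_equal(back$end, c(2, 4, 7, 10))
  expect_equal(back$value, c(0, 0.7, 1, 0))
})

test_that("BED round-trips 0-based half-open at the chromosome start", {
  iv <- data.frame(chrom = "chr1", start = c(0, 50), end = c(10, 60),
                   name = c("a", "b"), score = c(1, 2),
                   strand = c("+", "-"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".bed")
  write_bed(iv, f)
  expect_equal(strsplit(readLines(f)[1], "\t")[[1]][2:3], c("0", "10"))
  back <- read_bed(f)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$name, iv$name)
  expect_equal(back$strand, iv$strand)
})

test_that("read_motifs accepts IUPAC patterns and names offenders", {
  f <- write_tmp(c("TATABOX\tTATAWAW", "GBOX\tCACGTG"))
  m <- read_motifs(f)
  expect_equal(m$pattern, c("TATAWAW", "CACGTG"))
  bad <- write_tmp(c("OK\tACGT", "BROKEN\tACXGT"))
  expect_error(read_motifs(bad), "BROKEN.*non-IUPAC")
})
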