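#' Simulation configuration
#'
#' Describes the synthetic world every other module is tested against: a
#' random reference chromosome; gene models with UTR/intron structure;
#' planted conserved elements kept out of coding sequence; per-species
#' alignment rows that are the reference mutated i.i.d. per base at
#' 1 - match probability; population SNPs whose density is depleted in
#' constrained regions and whose folded MAF distribution shifts lower with
#' conservation; and IUPAC motifs planted inside the elements.
#'
#' Alignment blocks tile the genome (default 90 bp, the typical size of
#' chained-and-netted blocks).  Conserved-element blocks contain every
#' species; background and CDS blocks contain each species independently
#' with probability `background_align_prob` / `cds_align_prob`, emulating
#' the patchy alignability of noncoding plant sequence — in real
#' reference-anchored alignments most intergenic sequence simply fails to
#' align across species, which is what makes a fixed-denominator score
#' informative.
#'
#' @param seed Master RNG seed (mandatory); one substream is derived per
#'   simulation stage so adding an output never perturbs the others.
#' @param genome_length,chrom_name Reference chromosome size and name.
#' @param reference Reference species name.
#' @param n_species Number of non-reference species.
#' @param clades Named list of species vectors, or NULL for a single clade
#'   "all" holding every species.
#' @param background_match,cds_match,element_match Per-base probability
#'   that an aligned species base equals the reference base, by region.
#' @param background_align_prob,cds_align_prob Per-species probability of
#'   being present in a background / CDS block (elements always align all
#'   species).
#' @param block_size Background block tiling size (bp).
#' @param gap_prob Per-base probability of a gap ('-') in a species row
#'   (default 0: indel-free blocks).
#' @param n_genes,n_exons,exon_len,intron_len,utr5_len,utr3_len Gene-model
#'   geometry.
#' @param n_elements,element_len_range,element_min_sep Planted conserved
#'   elements: count, length range (uniform), and minimum separation so
#'   that distinct elements never merge during calling.
#' @param snp_density Genome-wide average SNP density (SNPs/bp).
#' @param snp_depletion_fold Target fold depletion: genome-average SNP
#'   density over the density inside constrained regions (elements + CDS).
#' @param an Total allele number (default 6000, i.e. 3,000 diploid
#'   genomes).
#' @param maf_beta Named list of c(shape1, shape2) per conservation class;
#'   folded MAF is 0.5 * Beta(shape1, shape2).
#' @param effect_fraction Fraction of SNPs carrying an effect annotation.
#' @param effect_types Named numeric vector of sampling proportions over
#'   SnpEff-style effect types.
#' @param motifs data.frame(name, pattern) of IUPAC motifs to plant and
#'   export.
#' @param motif_density Expected planted motif instances per element bp.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 100000, chrom_name = "chr1",
                       reference = "refsp", n_species = 10, clades = NULL,
                       background_match = 0.5, cds_match = 0.9,
                       element_match = 0.95,
                       background_align_prob = 0.6, cds_align_prob = 0.95,
                       block_size = 90, gap_prob = 0,
                       n_genes = 20, n_exons = 3, exon_len = 300,
                       intron_len = 400, utr5_len = 150, utr3_len = 250,
                       n_elements = 60, element_len_range = c(20, 150),
                       element_min_sep = 20,
                       snp_density = 0.01, snp_depletion_fold = 1.36,
                       an = 6000,
                       maf_beta = list(nonconserved = c(0.8, 3),
                                       conserved = c(0.5, 6),
                                       extreme = c(0.25, 10)),
                       effect_fraction = 0.6,
                       effect_types = c(missense_variant = 0.10,
                                        synonymous_variant = 0.05,
                                        intron_variant = 0.15,
                                        downstream_gene_variant = 0.25,
                                        upstream_gene_variant = 0.20,
                                        intergenic_region = 0.15,
                                        `3_prime_UTR_variant` = 0.05,
                                        `5_prime_UTR_variant` = 0.05),
                       motifs = data.frame(
                         name = c("TATABOX", "GBOXCORE", "SITEII"),
                         pattern = c("TATAWAW", "CACGTG", "TGGGCY"),
                         stringsAsFactors = FALSE),
                       motif_density = 0.002) {
  if (missing(seed)) stop("'seed' is mandatory")
  probs <- c(background_match, cds_match, element_match,
             background_align_prob, cds_align_prob, gap_prob,
             effect_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (snp_depletion_fold < 1) stop("snp_depletion_fold must be >= 1")
  species <- sprintf("sp%02d", seq_len(n_species))
  if (is.null(clades)) clades <- list(all = species)
  cfg <- as.list(environment())
  cfg$species <- species
  structure(cfg, class = "sim_config")
}

.sub_seeds <- function(seed, n = 8) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a concrete instance of an IUPAC pattern
.instantiate_motif <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) sample(sets[[ch]], 1L), ""),
        collapse = "")
}

# place n non-overlapping intervals of given lengths uniformly, avoiding
# 'forbidden' intervals (data.frame start/end) and keeping min_sep spacing
.place_intervals <- function(n, lens, L, forbidden, min_sep) {
  placed_s <- numeric(0); placed_e <- numeric(0)
  tries <- 0
  while (length(placed_s) < n && tries < n * 2000) {
    tries <- tries + 1
    len <- lens[length(placed_s) + 1]
    s <- sample.int(L - len, 1L) - 1L
    e <- s + len
    clash_forb <- nrow(forbidden) > 0 &&
      any(forbidden$end > s - min_sep & forbidden$start < e + min_sep)
    clash_self <- length(placed_s) > 0 &&
      any(placed_e > s - min_sep & placed_s < e + min_sep)
    if (!clash_forb && !clash_self) {
      placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
    }
  }
  if (length(placed_s) < n)
    stop("could not place ", n, " elements without overlap; ",
         "genome too crowded")
  o <- order(placed_s)
  data.frame(start = placed_s[o], end = placed_e[o])
}

.sim_gene_models <- function(cfg) {
  if (cfg$n_genes == 0) {
    e <- .empty_feat()
    g <- data.frame(gene_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    strand = character(0), stringsAsFactors = FALSE)
    t <- data.frame(tx_id = character(0), gene_id = character(0),
                    chrom = character(0), start = numeric(0),
                    end = numeric(0), strand = character(0),
                    stringsAsFactors = FALSE)
    return(gene_models(g, t, e, e, e, e, e))
  }
  span <- cfg$n_exons * cfg$exon_len + (cfg$n_exons - 1) * cfg$intron_len
  slots <- .place_intervals(cfg$n_genes, rep(span, cfg$n_genes),
                            cfg$genome_length,
                            data.frame(start = numeric(0), end = numeric(0)),
                            min_sep = 200)
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                      chrom = cfg$chrom_name, start = slots$start,
                      end = slots$end, strand = strands,
                      stringsAsFactors = FALSE)
  transcripts <- genes
  names(transcripts)[1] <- "tx_id"
  transcripts$gene_id <- genes$gene_id
  transcripts$tx_id <- paste0(genes$gene_id, ".1")
  transcripts <- transcripts[c("tx_id", "gene_id", "chrom", "start", "end",
                               "strand")]
  exons <- cds <- introns <- utr5 <- utr3 <- .empty_feat()
  for (i in seq_len(cfg$n_genes)) {
    es <- slots$start[i] + (seq_len(cfg$n_exons) - 1) *
      (cfg$exon_len + cfg$intron_len)
    ee <- es + cfg$exon_len
    tx <- transcripts$tx_id[i]
    exons <- rbind(exons, .feat_df(tx, genes$gene_id[i], cfg$chrom_name,
                                   es, ee, strands[i]))
    if (cfg$n_exons > 1L)
      introns <- rbind(introns, .feat_df(tx, genes$gene_id[i],
                                         cfg$chrom_name, ee[-cfg$n_exons],
                                         es[-1], strands[i]))
    # 5'-UTR occupies the start of the 5'-most exon, 3'-UTR the end of the
    # 3'-most, in genomic coordinates flipped by strand
    if (strands[i] == "+") {
      u5 <- c(es[1], es[1] + cfg$utr5_len)
      u3 <- c(ee[cfg$n_exons] - cfg$utr3_len, ee[cfg$n_exons])
    } else {
      u5 <- c(ee[cfg$n_exons] - cfg$utr5_len, ee[cfg$n_exons])
      u3 <- c(es[1], es[1] + cfg$utr3_len)
    }
    utr5 <- rbind(utr5, .feat_df(tx, genes$gene_id[i], cfg$chrom_name,
                                 u5[1], u5[2], strands[i]))
    utr3 <- rbind(utr3, .feat_df(tx, genes$gene_id[i], cfg$chrom_name,
                                 u3[1], u3[2], strands[i]))
    cs <- es; ce <- ee
    if (strands[i] == "+") {
      cs[1] <- cs[1] + cfg$utr5_len
      ce[cfg$n_exons] <- ce[cfg$n_exons] - cfg$utr3_len
    } else {
      cs[1] <- cs[1] + cfg$utr3_len
      ce[cfg$n_exons] <- ce[cfg$n_exons] - cfg$utr5_len
    }
    cds <- rbind(cds, .feat_df(tx, genes$gene_id[i], cfg$chrom_name, cs, ce,
                               strands[i]))
  }
  gene_models(genes, transcripts, exons, cds, introns, utr5, utr3)
}

# mutate a reference substring into one species row
.mutate_row <- function(ref_chars, match_prob, gap_prob) {
  n <- length(ref_chars)
  out <- ref_chars
  mut <- stats::runif(n) >= match_prob
  if (any(mut)) {
    alts <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                     "A", "C", "G"), nrow = 3,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
    idx <- which(mut)
    pick <- sample.int(3L, length(idx), replace = TRUE)
    out[idx] <- alts[cbind(pick, match(ref_chars[idx], colnames(alts)))]
  }
  if (gap_prob > 0) {
    g <- stats::runif(n) < gap_prob
    out[g] <- "-"
  }
  out
}

#' Generate a synthetic CNS-discovery data set
#'
#' Deterministic given the config seed: builds the reference, gene models,
#' planted conserved elements, reference-anchored alignment blocks,
#' population SNPs and motif annotations in memory, and (optionally) writes
#' ref.fa, aln.maf, genes.gff3, snps.vcf, motifs.tsv, clades.tsv plus
#' truth/ files to `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or NULL to skip file output.
#' @return List of class `cns_simulation`: config, genome ([genome_dict()]),
#'   ref_seq (character), blocks, models, snps, motifs, clade_map, truth
#'   (elements, constrained, snp_classes, motif_hits) and, when written,
#'   files.
#' @export
simulate_cns_data <- function(config, outdir = NULL) {
  cfg <- config
  seeds <- .sub_seeds(cfg$seed, 8)
  genome <- genome_dict(stats::setNames(cfg$genome_length, cfg$chrom_name),
                        cfg$reference)
  cmap <- clade_map(cfg$clades, cfg$reference)

  set.seed(seeds[1])
  ref_chars <- sample(c("A", "C", "G", "T"), cfg$genome_length,
                      replace = TRUE)

  set.seed(seeds[2])
  models <- .sim_gene_models(cfg)

  set.seed(seeds[3])
  lens <- sample(cfg$element_len_range[1]:cfg$element_len_range[2],
                 cfg$n_elements, replace = TRUE)
  elements <- .place_intervals(cfg$n_elements, lens, cfg$genome_length,
                               models$cds, cfg$element_min_sep)
  elements <- data.frame(chrom = rep(cfg$chrom_name, nrow(elements)),
                         start = elements$start, end = elements$end,
                         name = rep("element", nrow(elements)),
                         stringsAsFactors = FALSE)

  # plant motif instances inside elements (into the reference itself, so
  # they propagate into every species row and into the written FASTA)
  set.seed(seeds[4])
  motif_hits <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0), name = character(0),
                           stringsAsFactors = FALSE)
  if (nrow(cfg$motifs) && cfg$motif_density > 0) {
    el_bp <- sum(elements$end - elements$start)
    n_plant <- stats::rpois(1, cfg$motif_density * el_bp)
    for (k in seq_len(n_plant)) {
      mi <- sample.int(nrow(cfg$motifs), 1L)
      pat <- cfg$motifs$pattern[mi]
      klen <- nchar(pat)
      ei <- sample.int(nrow(elements), 1L)
      if (elements$end[ei] - elements$start[ei] < klen) next
      s <- elements$start[ei] +
        sample.int(elements$end[ei] - elements$start[ei] - klen + 1L, 1L) - 1L
      # overlapping plants would clobber earlier instances; skip them
      if (nrow(motif_hits) &&
          any(motif_hits$end > s & motif_hits$start < s + klen)) next
      inst <- strsplit(.instantiate_motif(pat), "", fixed = TRUE)[[1]]
      ref_chars[(s + 1):(s + klen)] <- inst
      motif_hits <- rbind(motif_hits, data.frame(
        chrom = cfg$chrom_name, start = s, end = s + klen,
        name = cfg$motifs$name[mi], stringsAsFactors = FALSE))
    }
  }

  # partition the chromosome into element / CDS / background pieces
  cds_red <- IRanges::reduce(IRanges::IRanges(models$cds$start + 1,
                                              models$cds$end))
  lab <- rep("bg", cfg$genome_length)
  for (i in seq_len(nrow(elements)))
    lab[(elements$start[i] + 1):elements$end[i]] <- "el"
  if (length(cds_red))
    for (i in seq_along(cds_red))
      lab[BiocGenerics::start(cds_red)[i]:BiocGenerics::end(cds_red)[i]] <-
        "cds"
  r <- rle(lab)
  piece_end <- cumsum(r$lengths)
  piece_start <- piece_end - r$lengths   # 0-based half-open
  pieces <- data.frame(start = piece_start, end = piece_end,
                       kind = r$values, stringsAsFactors = FALSE)

  set.seed(seeds[5])
  blocks <- list()
  cursor <- stats::setNames(numeric(cfg$n_species), cfg$species)
  for (pi in seq_len(nrow(pieces))) {
    kind <- pieces$kind[pi]
    starts <- if (kind == "bg")
      seq(pieces$start[pi], pieces$end[pi] - 1, by = cfg$block_size)
    else pieces$start[pi]
    for (bs in starts) {
      be <- min(bs + if (kind == "bg") cfg$block_size else
        (pieces$end[pi] - bs), pieces$end[pi])
      sub_ref <- ref_chars[(bs + 1):be]
      present <- switch(kind,
        el = rep(TRUE, cfg$n_species),
        cds = stats::runif(cfg$n_species) < cfg$cds_align_prob,
        bg = stats::runif(cfg$n_species) < cfg$background_align_prob)
      if (!any(present)) next
      match_p <- switch(kind, el = cfg$element_match, cds = cfg$cds_match,
                        bg = cfg$background_match)
      rows <- character(0)
      row_starts <- numeric(0)
      for (si in which(present)) {
        rc <- .mutate_row(sub_ref, match_p, cfg$gap_prob)
        rows <- c(rows, paste(rc, collapse = ""))
        row_starts <- c(row_starts, cursor[[cfg$species[si]]])
        cursor[[cfg$species[si]]] <- cursor[[cfg$species[si]]] +
          sum(rc != "-")
      }
      names(rows) <- cfg$species[present]
      names(row_starts) <- cfg$species[present]
      blocks[[length(blocks) + 1L]] <- alignment_block(
        ref_chrom = cfg$chrom_name, ref_start = bs,
        ref_text = paste(sub_ref, collapse = ""), rows = rows,
        score = length(rows) * (be - bs),
        row_starts = row_starts,
        row_src_sizes = stats::setNames(rep(cfg$genome_length,
                                            sum(present)),
                                        cfg$species[present]),
        row_strands = stats::setNames(rep("+", sum(present)),
                                      cfg$species[present]))
    }
  }

  # SNPs: constrained = elements + CDS; inside rate solved so that
  # genome-average density / constrained density = the target fold
  set.seed(seeds[6])
  constrained <- lab != "bg"
  c_frac <- mean(constrained)
  f <- cfg$snp_depletion_fold
  # solve: avg = (1-c) r_out + c r_in,  avg / r_in = f,  avg = snp_density
  r_in <- cfg$snp_density / f
  r_out <- (cfg$snp_density - c_frac * r_in) / (1 - c_frac)
  rate <- ifelse(constrained, r_in, r_out)
  is_snp <- stats::runif(cfg$genome_length) < rate
  pos <- which(is_snp) - 1L
  cls <- ifelse(lab[pos + 1] == "el", "extreme",
                ifelse(lab[pos + 1] == "cds", "conserved", "nonconserved"))
  beta <- cfg$maf_beta
  maf <- numeric(length(pos))
  for (cc in names(beta)) {
    sel <- cls == cc
    maf[sel] <- 0.5 * stats::rbeta(sum(sel), beta[[cc]][1], beta[[cc]][2])
  }
  ac <- pmin(pmax(round(maf * cfg$an), 1), floor(cfg$an / 2))
  refA <- ref_chars[pos + 1]
  altA <- vapply(refA, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "", USE.NAMES = FALSE)
  has_eff <- stats::runif(length(pos)) < cfg$effect_fraction
  eff_type <- rep(NA_character_, length(pos))
  eff_type[has_eff] <- sample(names(cfg$effect_types), sum(has_eff),
                              replace = TRUE, prob = cfg$effect_types)
  impact_of <- c(missense_variant = "MODERATE",
                 synonymous_variant = "LOW", intron_variant = "MODIFIER",
                 downstream_gene_variant = "MODIFIER",
                 upstream_gene_variant = "MODIFIER",
                 intergenic_region = "MODIFIER",
                 `3_prime_UTR_variant` = "MODIFIER",
                 `5_prime_UTR_variant` = "MODIFIER")
  effects <- lapply(eff_type, function(t) if (is.na(t)) NULL else t)
  impacts <- lapply(eff_type, function(t)
    if (is.na(t)) NULL else unname(impact_of[t]))
  snps <- snp_records(rep(cfg$chrom_name, length(pos)), pos, refA, altA,
                      rep(cfg$an, length(pos)), ac, effects, impacts)

  cons_r <- rle(constrained)
  ce <- cumsum(cons_r$lengths); cs <- ce - cons_r$lengths
  constrained_iv <- data.frame(chrom = cfg$chrom_name,
                               start = cs[cons_r$values],
                               end = ce[cons_r$values],
                               stringsAsFactors = FALSE)

  sim <- structure(list(
    config = cfg, genome = genome,
    ref_seq = paste(ref_chars, collapse = ""), blocks = blocks,
    models = models, snps = snps, motifs = cfg$motifs, clade_map = cmap,
    truth = list(elements = elements, constrained = constrained_iv,
                 snp_classes = data.frame(chrom = cfg$chrom_name, pos = pos,
                                          class = cls,
                                          effect = eff_type,
                                          stringsAsFactors = FALSE),
                 motif_hits = motif_hits,
                 rates = list(r_in = r_in, r_out = r_out,
                              constrained_fraction = c_frac))),
    class = "cns_simulation")
  if (!is.null(outdir)) sim$files <- write_simulation(sim, outdir)
  sim
}

#' Write a simulation bundle to disk
#'
#' @param sim A `cns_simulation` from [simulate_cns_data()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  cfg <- sim$config
  files <- c(ref = file.path(outdir, "ref.fa"),
             maf = file.path(outdir, "aln.maf"),
             gff = file.path(outdir, "genes.gff3"),
             vcf = file.path(outdir, "snps.vcf"),
             motifs = file.path(outdir, "motifs.tsv"),
             clades = file.path(outdir, "clades.tsv"),
             truth_elements = file.path(outdir, "truth", "elements.bed"),
             truth_snps = file.path(outdir, "truth", "snp_classes.tsv"),
             truth_motifs = file.path(outdir, "truth", "motif_hits.tsv"),
             truth_params = file.path(outdir, "truth", "params.json"))
  seqs <- Biostrings::DNAStringSet(stats::setNames(sim$ref_seq,
                                                   cfg$chrom_name))
  Biostrings::writeXStringSet(seqs, files[["ref"]])
  write_maf(sim$blocks, files[["maf"]], sim$genome)
  write_gff3(sim$models, files[["gff"]])
  write_vcf(sim$snps, files[["vcf"]], sim$genome)
  utils::write.table(sim$motifs, files[["motifs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  clade_lines <- vapply(names(sim$clade_map$clades), function(nm)
    paste0(nm, "\t", paste(sim$clade_map$clades[[nm]], collapse = ",")), "")
  writeLines(clade_lines, files[["clades"]])
  write_bed(sim$truth$elements, files[["truth_elements"]])
  utils::write.table(sim$truth$snp_classes, files[["truth_snps"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$motif_hits, files[["truth_motifs"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  par <- cfg[!vapply(cfg, is.function, NA)]
  par$motifs <- NULL
  jsonlite::write_json(par, files[["truth_params"]], auto_unbox = TRUE,
                       digits = NA)
  files
}

#' Simulate correlated per-gene intra/inter substitution counts
#'
#' Bivariate Poisson-lognormal: per gene, latent rates are lognormal with
#' correlated Gaussian components; counts are conditionally Poisson.  The
#' latent correlation is calibrated analytically so the expected Pearson
#' correlation of the *counts* equals `target_r` (Poisson noise and
#' lognormal skew attenuate the latent correlation; the closed-form
#' count-scale moments of the Poisson-lognormal let us invert that).
#'
#' @param n_genes Number of genes.
#' @param target_r Target Pearson correlation of the counts.
#' @param mean_intra,mean_inter Mean counts.
#' @param sigma Lognormal sigma of the latent rates (both margins).
#' @return data.frame: intra, inter (non-negative integer counts).
#' @export
sim_variation_counts <- function(n_genes, target_r, mean_intra = 20,
                                 mean_inter = 30, sigma = 0.6) {
  v1 <- mean_intra + mean_intra^2 * (exp(sigma^2) - 1)
  v2 <- mean_inter + mean_inter^2 * (exp(sigma^2) - 1)
  need_cov <- target_r * sqrt(v1 * v2)
  rho <- log(1 + need_cov / (mean_intra * mean_inter)) / sigma^2
  if (rho > 1)
    stop("target_r unattainable at this sigma (latent rho ", round(rho, 3),
         " > 1)")
  z1 <- stats::rnorm(n_genes)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_genes)
  l1 <- mean_intra * exp(sigma * z1 - sigma^2 / 2)
  l2 <- mean_inter * exp(sigma * z2 - sigma^2 / 2)
  data.frame(intra = stats::rpois(n_genes, l1),
             inter = stats::rpois(n_genes, l2))
}

#' Materialize intra/inter counts as gene models, SNPs and a track
#'
#' Builds a minimal single-species world in which
#' [variation_correlation()] recovers exactly the given per-gene counts:
#' genes are laid head to tail; the first `inter` bases of each gene are
#' aligned-but-mismatched, the rest aligned-and-matched; `intra` SNPs are
#' placed on distinct positions inside the gene.
#'
#' @param counts data.frame with intra and inter columns
#'   ([sim_variation_counts()]).
#' @param gap Gap between consecutive genes (bp).
#' @return List: models, snps, track, genome.
#' @export
build_variation_world <- function(counts, gap = 10) {
  n <- nrow(counts)
  lens <- pmax(counts$intra, counts$inter) + 5
  starts <- cumsum(c(0, lens[-n] + gap))
  ends <- starts + lens
  L <- ends[n] + gap
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                      chrom = "chr1", start = starts, end = ends,
                      strand = "+", stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = paste0(genes$gene_id, ".1"),
                   gene_id = genes$gene_id, chrom = "chr1", start = starts,
                   end = ends, strand = "+", stringsAsFactors = FALSE)
  exons <- .feat_df(tx$tx_id, tx$gene_id, "chr1", starts, ends, "+")
  models <- gene_models(genes, tx, exons, .empty_feat(), .empty_feat(),
                        .empty_feat(), .empty_feat())
  aligned <- integer(L); matched <- integer(L)
  snp_pos <- numeric(0)
  for (i in seq_len(n)) {
    span <- (starts[i] + 1):ends[i]
    aligned[span] <- 1L
    matched[span] <- 1L
    if (counts$inter[i] > 0)
      matched[span[seq_len(counts$inter[i])]] <- 0L
    if (counts$intra[i] > 0)
      snp_pos <- c(snp_pos, starts[i] + seq_len(counts$intra[i]) - 1)
  }
  track <- score_track("all", 1L, list(chr1 = list(matched = matched,
                                                   aligned = aligned)))
  snps <- snp_records(rep("chr1", length(snp_pos)), snp_pos,
                      rep("A", length(snp_pos)), rep("C", length(snp_pos)),
                      rep(100, length(snp_pos)), rep(5, length(snp_pos)))
  list(models = models, snps = snps, track = track,
       genome = genome_dict(c(chr1 = L), "refsp"))
}
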