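#' Classify SNP sites by conservation
#'
#' Sites are binned by conservation score into nonconserved
#' (`[0, 0.2]`), conserved (`[0.7, 0.9)`) and extreme (`[0.9, 1.0]`);
#' scores in `(0.2, 0.7)` are unclassified.  The 0.9 boundary belongs to the
#' extreme class so the classes partition.  Comparisons use the exact
#' rational score.
#'
#' @param snps A [snp_records()] table.
#' @param track A [score_track()].
#' @return Factor with levels nonconserved/conserved/extreme and NA for
#'   unclassified sites, parallel to `snps` rows.
#' @export
classify_snp_sites <- function(snps, track) {
  n <- track$n_species
  m <- vapply(seq_len(nrow(snps)), function(i) {
    ch <- track$chroms[[snps$chrom[i]]]
    if (is.null(ch)) stop("track has no chromosome ", snps$chrom[i])
    p <- snps$pos[i] + 1
    if (p < 1 || p > length(ch$matched))
      stop("SNP position outside chromosome: ", snps$chrom[i], ":",
           snps$pos[i])
    ch$matched[p]
  }, 0L)
  cls <- rep(NA_character_, nrow(snps))
  cls[score_ge(m, n, 0.9)] <- "extreme"
  cls[score_ge(m, n, 0.7) & score_lt(m, n, 0.9)] <- "conserved"
  cls[m * 5 <= n] <- "nonconserved"
  factor(cls, levels = c("nonconserved", "conserved", "extreme"))
}

#' Default MAF bin edges: a rare bin below 0.01, then ten equal bins up to
#' 0.5
#' @return Numeric vector of bin edges.
#' @export
maf_bin_edges <- function() c(0, 0.01, 0.01 + 0.049 * (1:10))

#' Minor-allele-frequency spectrum by conservation class
#'
#' @param snps A [snp_records()] table.
#' @param classes Factor from [classify_snp_sites()] (unclassified sites are
#'   dropped).
#' @param bin_edges Increasing bin edges on `[0, 0.5]`; bins are
#'   right-open except the last (default [maf_bin_edges()]).
#' @return Matrix of counts, one row per class, one column per bin.
#' @export
maf_spectrum <- function(snps, classes, bin_edges = maf_bin_edges()) {
  keep <- !is.na(classes)
  maf <- snps$maf[keep]
  cls <- classes[keep]
  # right-open bins except the last, which keeps the folded maximum 0.5
  bins <- cut(maf, breaks = bin_edges, right = FALSE, include.lowest = TRUE)
  table(class = cls, maf_bin = bins)
}

#' SNP-density depletion in constrained regions
#'
#' Fold depletion = genome-wide SNP density / density inside constrained
#' regions; a fold above 1 indicates SNP depletion under purifying
#' selection.
#'
#' @param snps A [snp_records()] table.
#' @param constrained data.frame of intervals (chrom, start, end; 0-based
#'   half-open).
#' @param genome A [genome_dict()].
#' @return List: fold (Inf when no constrained SNP), density_genome,
#'   density_constrained, n_constrained_snps, constrained_bp.
#' @export
snp_depletion <- function(snps, constrained, genome) {
  genome_bp <- sum(genome$lengths)
  dens_g <- nrow(snps) / genome_bp
  cons_bp <- sum(constrained$end - constrained$start)
  if (cons_bp <= 0) stop("constrained regions are empty")
  inside <- logical(nrow(snps))
  for (chrom in unique(constrained$chrom)) {
    iv <- constrained[constrained$chrom == chrom, ]
    sel <- which(snps$chrom == chrom)
    if (!length(sel)) next
    ir_snp <- IRanges::IRanges(snps$pos[sel] + 1, width = 1)
    ir_c <- IRanges::IRanges(iv$start + 1, iv$end)
    inside[sel] <- IRanges::overlapsAny(ir_snp, ir_c)
  }
  n_in <- sum(inside)
  dens_c <- n_in / cons_bp
  list(fold = if (n_in == 0) Inf else dens_g / dens_c,
       density_genome = dens_g, density_constrained = dens_c,
       n_constrained_snps = n_in, constrained_bp = cons_bp)
}

#' Invariant sites: zero cross-species mismatches at full clade coverage
#'
#' @param track A [score_track()].
#' @return data.frame: chrom, pos (0-based) of positions where every clade
#'   species carries the reference base (matched = clade size).
#' @export
invariant_sites <- function(track) {
  out <- lapply(names(track$chroms), function(chrom) {
    p <- which(track$chroms[[chrom]]$matched == track$n_species)
    if (!length(p)) return(NULL)
    data.frame(chrom = chrom, pos = p - 1, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, NA)]
  if (!length(out))
    return(data.frame(chrom = character(0), pos = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Effect annotations of SNPs at given sites
#'
#' @param snps A [snp_records()] table.
#' @param sites data.frame (chrom, pos), e.g. from [invariant_sites()].
#' @return Character vector with one entry per SNP effect record at the
#'   sites (a SNP carrying several effect records contributes each once).
#' @export
effects_at_sites <- function(snps, sites) {
  key <- paste(sites$chrom, sites$pos)
  at <- paste(snps$chrom, snps$pos) %in% key
  unlist(snps$effects[at], use.names = FALSE)
}

#' Tabulate effect types
#'
#' @param effects Character vector of effect types (one entry per effect
#'   record).
#' @return data.frame of class `effect_tabulation`: type, count, percentage
#'   (100 * count / total, rounded to 2 decimals), sorted by type.
#' @export
tabulate_effects <- function(effects) {
  if (!length(effects)) {
    out <- data.frame(type = character(0), count = integer(0),
                      percentage = numeric(0), stringsAsFactors = FALSE)
  } else {
    t <- table(effects)
    out <- data.frame(type = names(t), count = as.integer(t),
                      percentage = round(100 * as.integer(t) / sum(t), 2),
                      stringsAsFactors = FALSE)
    out <- out[order(out$type), ]
    rownames(out) <- NULL
  }
  class(out) <- c("effect_tabulation", "data.frame")
  out
}

#' Per-gene intraspecific vs interspecific variation
#'
#' For each gene span: `intra` counts population SNPs inside the span,
#' `inter` counts cross-species substitutions — by default the number of
#' span positions with at least one aligned species mismatching the
#' reference; with `inter_mode = "species_sum"` mismatches are summed over
#' species.
#'
#' @param models A [gene_models()] object.
#' @param snps A [snp_records()] table.
#' @param track A [score_track()].
#' @param inter_mode "positions" (default) or "species_sum".
#' @return List: per_gene (data.frame gene_id, intra, inter), r (Pearson
#'   correlation; NA when either vector is constant), p (two-sided t
#'   approximation).
#' @export
variation_correlation <- function(models, snps, track,
                                  inter_mode = c("positions",
                                                 "species_sum")) {
  inter_mode <- match.arg(inter_mode)
  g <- models$genes
  mm <- lapply(track$chroms, function(ch) {
    v <- if (inter_mode == "positions")
      as.numeric(ch$aligned >= 1L & ch$matched < ch$aligned)
    else as.numeric(ch$aligned - ch$matched)
    c(0, cumsum(v))
  })
  inter <- mapply(function(chrom, s, e) {
    cm <- mm[[chrom]]
    if (is.null(cm)) stop("track has no chromosome ", chrom)
    cm[e + 1] - cm[s + 1]
  }, g$chrom, g$start, g$end)
  intra <- vapply(seq_len(nrow(g)), function(i)
    sum(snps$chrom == g$chrom[i] & snps$pos >= g$start[i] &
          snps$pos < g$end[i]), 0)
  sd1 <- stats::sd(intra); sd2 <- stats::sd(inter)
  r <- if (is.na(sd1) || is.na(sd2) || sd1 == 0 || sd2 == 0) NA_real_
    else stats::cor(intra, inter)
  p <- if (is.na(r)) NA_real_ else {
    n <- length(intra)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(per_gene = data.frame(gene_id = g$gene_id, intra = as.numeric(intra),
                             inter = as.numeric(inter),
                             stringsAsFactors = FALSE),
       r = r, p = p)
}

#' Outlier genes under relaxed or lineage-restricted selection
#'
#' Mode "relaxed_in_reference": SNPs with folded MAF at or above `maf_min`
#' sitting on invariant sites (high population variation where all other
#' species agree), grouped by gene span; returns the genes and the flagged
#' SNPs.  Mode "conserved_in_reference_only": genes with few population
#' SNPs (`intra <= intra_floor`) but many cross-species substitutions
#' (`inter >= inter_ceiling`).
#'
#' @param models A [gene_models()] object.
#' @param snps A [snp_records()] table.
#' @param track A [score_track()].
#' @param maf_min Folded MAF threshold for the relaxed mode (default 0.01).
#' @param mode See description.
#' @param intra_floor,inter_ceiling Thresholds for the lineage-restricted
#'   mode.
#' @return List: genes (character vector) and, in relaxed mode, snps (the
#'   flagged subset of `snps`).
#' @export
outlier_genes <- function(models, snps, track, maf_min = 0.01,
                          mode = c("relaxed_in_reference",
                                   "conserved_in_reference_only"),
                          intra_floor = 0, inter_ceiling = 10) {
  mode <- match.arg(mode)
  g <- models$genes
  if (mode == "relaxed_in_reference") {
    inv <- invariant_sites(track)
    key <- paste(inv$chrom, inv$pos)
    flag <- paste(snps$chrom, snps$pos) %in% key & snps$maf >= maf_min
    hits <- snps[flag, ]
    genes <- g$gene_id[vapply(seq_len(nrow(g)), function(i)
      any(hits$chrom == g$chrom[i] & hits$pos >= g$start[i] &
            hits$pos < g$end[i]), NA)]
    list(genes = genes, snps = hits)
  } else {
    vc <- variation_correlation(models, snps, track)$per_gene
    list(genes = vc$gene_id[vc$intra <= intra_floor &
                              vc$inter >= inter_ceiling])
  }
}
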