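#' Call conserved noncoding sequences from a score track
#'
#' The calling pipeline is fixed: (1) mask CDS-labeled bases; (2) take
#' maximal runs of non-CDS bases with conservation score at or above
#' `threshold`; (3) merge runs separated by at most `merge_gap` bases,
#' provided the gap contains no CDS base (a merge never bridges coding
#' sequence); (4) drop merged fragments shorter than `min_len`.  The mean
#' score of a merged CNS averages over all of its bases, including
#' sub-threshold gap bases.  Threshold comparisons use the exact rational
#' `matched / n_species`.
#'
#' @param track A [score_track()].
#' @param regions A [region_index()] on the same genome.
#' @param threshold Score threshold (default 0.7: conserved in at least 70%
#'   of the clade).
#' @param merge_gap Maximum gap (bp) bridged when merging runs (default 3).
#' @param min_len Minimum retained fragment length (default 6).
#' @return data.frame of class `cns_set`: chrom, start, end (0-based
#'   half-open), length, mean_score, category; sorted and disjoint.
#' @export
call_cns <- function(track, regions, threshold = 0.7, merge_gap = 3,
                     min_len = 6) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  out <- list()
  cds_code <- .region_code(regions, "CDS")
  for (chrom in names(regions$labels)) {
    lab <- regions$labels[[chrom]]
    ch <- track$chroms[[chrom]]
    if (is.null(ch)) stop("track has no chromosome ", chrom)
    is_cds <- lab == cds_code
    ok <- score_ge(ch$matched, track$n_species, threshold) & !is_cds
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ri <- which(r$values)
    if (!length(ri)) next
    iv_s <- starts[ri]; iv_e <- ends[ri]           # 1-based inclusive
    ms <- iv_s[1]; me <- iv_e[1]
    merged_s <- integer(0); merged_e <- integer(0)
    if (length(ri) > 1L) {
      for (k in 2:length(ri)) {
        gap_len <- iv_s[k] - me - 1L
        gap_has_cds <- gap_len > 0L && any(is_cds[(me + 1L):(iv_s[k] - 1L)])
        if (gap_len <= merge_gap && !gap_has_cds) {
          me <- iv_e[k]
        } else {
          merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
          ms <- iv_s[k]; me <- iv_e[k]
        }
      }
    }
    merged_s <- c(merged_s, ms); merged_e <- c(merged_e, me)
    len <- merged_e - merged_s + 1L
    keep <- len >= min_len
    if (!any(keep)) next
    merged_s <- merged_s[keep]; merged_e <- merged_e[keep]
    cm <- c(0, cumsum(ch$matched))
    msum <- cm[merged_e + 1L] - cm[merged_s]
    out[[chrom]] <- data.frame(
      chrom = chrom, start = merged_s - 1L, end = merged_e,
      length = merged_e - merged_s + 1L,
      mean_score = msum / track$n_species / (merged_e - merged_s + 1L),
      stringsAsFactors = FALSE)
  }
  cns <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               length = numeric(0), mean_score = numeric(0),
               stringsAsFactors = FALSE)
  rownames(cns) <- NULL
  cns$category <- categorize_cns(cns, regions)
  class(cns) <- c("cns_set", "data.frame")
  cns
}

#' Categorize CNS intervals by majority region overlap
#'
#' Each CNS receives the non-CDS label with the largest bp overlap; ties are
#' broken by the fixed priority UTR5 > UTR3 > intron > intergenic.
#'
#' @param cns data.frame with chrom/start/end columns.
#' @param regions A [region_index()].
#' @return Character vector of categories.
#' @export
categorize_cns <- function(cns, regions) {
  cats <- c("UTR5", "UTR3", "intron", "intergenic")
  codes <- match(cats, regions$levels)
  vapply(seq_len(nrow(cns)), function(i) {
    lab <- regions$labels[[cns$chrom[i]]][(cns$start[i] + 1):cns$end[i]]
    counts <- vapply(codes, function(cd) sum(lab == cd), 0)
    cats[which.max(counts)]   # first max wins = stated priority
  }, "")
}

#' Round a mean CNS length from printed totals
#'
#' The reported mean length is the total CNS length divided by the CNS
#' count, rounded to the nearest integer bp — the same convention
#' [summarize_cns()] applies.
#'
#' @param total_length Sum of CNS lengths (bp).
#' @param total_number Number of CNSs.
#' @return Mean length in integer bp.
#' @export
mean_length_from_totals <- function(total_length, total_number) {
  as.integer(round(total_length / total_number))
}

#' Summarize a CNS set
#'
#' @param cns A `cns_set` data.frame from [call_cns()].
#' @param clade Clade label to attach.
#' @return List of class `cns_summary`: clade, total_number, mean_length
#'   (nearest integer bp), median_length (lower middle for even counts),
#'   total_length, and pct_category (percentages over
#'   intergenic/UTR5/UTR3/intron, summing to 100).
#' @export
summarize_cns <- function(cns, clade = NA_character_) {
  n <- nrow(cns)
  cats <- c("intergenic", "UTR5", "UTR3", "intron")
  if (n == 0L) {
    pct <- stats::setNames(rep(NA_real_, 4), cats)
    return(structure(list(clade = clade, total_number = 0L,
                          mean_length = NA_integer_, median_length = NA_real_,
                          total_length = 0, pct_category = pct),
                     class = "cns_summary"))
  }
  lens <- sort(cns$length)
  med <- lens[floor((n + 1) / 2)]   # lower middle when n is even
  pct <- 100 * vapply(cats, function(cc) sum(cns$category == cc), 0) / n
  structure(list(clade = clade, total_number = n,
                 mean_length = mean_length_from_totals(sum(cns$length), n),
                 median_length = med, total_length = sum(cns$length),
                 pct_category = pct),
            class = "cns_summary")
}

#' @export
print.cns_summary <- function(x, ...) {
  cat("<cns_summary>", if (!is.na(x$clade)) paste0("clade: ", x$clade), "\n")
  cat("  total number :", x$total_number, "\n")
  cat("  mean length  :", x$mean_length, "bp\n")
  cat("  median length:", x$median_length, "bp\n")
  cat("  total length :", format(x$total_length, big.mark = ","), "bp\n")
  for (nm in names(x$pct_category))
    cat(sprintf("  %% in %-10s: %.2f\n", nm, x$pct_category[[nm]]))
  invisible(x)
}

#' Genome fraction and per-class bp of constrained sites
#'
#' Raw per-base accounting of sites at or above the threshold, before any
#' merge or length rule (so CDS is included): the quantity behind
#' "fraction of the genome evolving under constraint".
#'
#' @param track A [score_track()].
#' @param regions A [region_index()].
#' @param threshold Score threshold (default 0.7).
#' @return List: genome_fraction, genome_bp, constrained_bp (total), and
#'   by_class (named vector of constrained bp per region class).
#' @export
constrained_fraction <- function(track, regions, threshold = 0.7) {
  cov <- coverage_by_region(track, regions, threshold)
  genome_bp <- sum(cov$bp)
  constrained <- sum(cov$bp_ge)
  list(genome_fraction = constrained / genome_bp, genome_bp = genome_bp,
       constrained_bp = constrained,
       by_class = stats::setNames(cov$bp_ge, cov$region))
}

#' Genes with a CNS within a window upstream of their TSS
#'
#' A gene is reported when its transcription start site lies within `window`
#' bp downstream of a CNS on the gene's strand (default), i.e. the CNS sits
#' just 5' of the gene — the cis-regulatory configuration.  With
#' `direction = "cns_downstream_of_gene"` the test is mirrored.
#'
#' @param cns A `cns_set` data.frame.
#' @param models A [gene_models()] object.
#' @param window Window size in bp (default 1000).
#' @param direction See description.
#' @return Character vector of gene ids.
#' @export
genes_downstream_of_cns <- function(cns, models, window = 1000,
                                    direction = c("gene_downstream_of_cns",
                                                  "cns_downstream_of_gene")) {
  direction <- match.arg(direction)
  if (nrow(cns) == 0L) return(character(0))
  anchors <- gene_anchors(models)
  hit <- vapply(seq_len(nrow(anchors)), function(i) {
    same <- cns$chrom == anchors$chrom[i]
    if (!any(same)) return(FALSE)
    s <- cns$start[same]; e <- cns$end[same]
    plus <- anchors$strand[i] != "-"
    if (direction == "gene_downstream_of_cns") {
      d <- if (plus) anchors$tss[i] - e else s - 1 - anchors$tss[i]
    } else {
      d <- if (plus) s - 1 - anchors$tes[i] else anchors$tes[i] - e
    }
    any(d >= 0 & d <= window)
  }, NA)
  anchors$gene_id[hit]
}

#' Bigfoot genes: large gene spaces dense in CNSs
#'
#' @param models A [gene_models()] object.
#' @param cns A `cns_set` data.frame.
#' @param span_min Minimum gene span in bp, exclusive (default 4000).
#' @param min_cns Minimum number of CNSs overlapping the span +/- `window`
#'   (default 6).
#' @param window Flank added to the gene span when counting CNSs (default
#'   1000).
#' @return Character vector of gene ids.
#' @export
bigfoot_genes <- function(models, cns, span_min = 4000, min_cns = 6,
                          window = 1000) {
  g <- models$genes
  big <- (g$end - g$start) > span_min
  if (!any(big) || nrow(cns) == 0L) return(character(0))
  g <- g[big, ]
  counts <- vapply(seq_len(nrow(g)), function(i) {
    same <- cns$chrom == g$chrom[i]
    sum(same & cns$end > g$start[i] - window & cns$start < g$end[i] + window)
  }, 0)
  g$gene_id[counts >= min_cns]
}

#' Fraction of CNSs overlapping annotated features
#'
#' @param cns A `cns_set` data.frame.
#' @param features data.frame with chrom, start, end and a `name` column
#'   giving the feature class (e.g. repeat family, miRNA, lncRNA), as read
#'   by [read_bed()].
#' @return List: fraction (CNSs with >= 1 bp overlap over total CNSs; `NA`
#'   when there are no CNSs) and by_class (named vector of per-class CNS
#'   fractions).
#' @export
feature_overlap <- function(cns, features) {
  if (nrow(cns) == 0L)
    return(list(fraction = NA_real_, by_class = stats::setNames(
      numeric(0), character(0))))
  cns_gr <- GenomicRanges::GRanges(cns$chrom,
                                   IRanges::IRanges(cns$start + 1, cns$end))
  feat_gr <- GenomicRanges::GRanges(features$chrom,
                                    IRanges::IRanges(features$start + 1,
                                                     features$end))
  ov <- GenomicRanges::findOverlaps(cns_gr, feat_gr)
  fraction <- length(unique(S4Vectors::queryHits(ov))) / nrow(cns)
  classes <- unique(features$name)
  by_class <- vapply(classes, function(cl) {
    sel <- which(features$name == cl)
    length(unique(S4Vectors::queryHits(
      ov[S4Vectors::subjectHits(ov) %in% sel]))) / nrow(cns)
  }, 0)
  list(fraction = fraction, by_class = by_class)
}
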