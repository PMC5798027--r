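#' Gene-level conservation scores
#'
#' The score of a gene is the mean per-base conservation score over its
#' span (TSS to TES, introns and UTRs included).  With `exon_only = TRUE`
#' only exonic bases are averaged.
#'
#' @param track A [score_track()].
#' @param models A [gene_models()] object.
#' @param exon_only Average exon bases only (default FALSE).
#' @return data.frame: gene_id, chrom, start, end, n_bases, mean_score.
#' @export
gene_scores <- function(track, models, exon_only = FALSE) {
  g <- models$genes
  cums <- lapply(track$chroms, function(ch) c(0, cumsum(ch$matched)))
  span_sum <- function(chrom, start, end) {
    cm <- cums[[chrom]]
    if (is.null(cm)) stop("track has no chromosome ", chrom)
    cm[end + 1] - cm[start + 1]
  }
  if (!exon_only) {
    msum <- mapply(span_sum, g$chrom, g$start, g$end)
    nb <- g$end - g$start
  } else {
    msum <- numeric(nrow(g)); nb <- numeric(nrow(g))
    ex <- models$exons
    for (i in seq_len(nrow(g))) {
      ei <- ex[ex$gene_id == g$gene_id[i], ]
      if (nrow(ei) == 0L) next
      # overlapping exons across isoforms: count each base once
      ir <- IRanges::reduce(IRanges::IRanges(ei$start + 1, ei$end))
      msum[i] <- sum(mapply(span_sum, rep(g$chrom[i], length(ir)),
                            BiocGenerics::start(ir) - 1,
                            BiocGenerics::end(ir)))
      nb[i] <- sum(BiocGenerics::width(ir))
    }
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
             end = g$end, n_bases = nb,
             mean_score = ifelse(nb > 0, msum / track$n_species / nb,
                                 NA_real_),
             stringsAsFactors = FALSE)
}

#' Highly conserved gene set
#'
#' @param scores Output of [gene_scores()].
#' @param cutoff Inclusive score cutoff (default 0.9: conserved in at least
#'   90% of the clade on average).
#' @return Character vector of gene ids with mean score >= cutoff.
#' @export
highly_conserved <- function(scores, cutoff = 0.9) {
  scores$gene_id[!is.na(scores$mean_score) & scores$mean_score >= cutoff]
}

#' Clade-exclusive and common gene sets
#'
#' @param sets Named list of gene-id vectors, one per clade.
#' @return List: exclusive (named list, genes in exactly that clade's set),
#'   common (genes in every set), union (all genes in any set).
#' @export
clade_exclusive <- function(sets) {
  u <- unique(unlist(sets, use.names = FALSE))
  common <- u
  for (s in sets) common <- intersect(common, s)
  exclusive <- lapply(names(sets), function(nm) {
    others <- unique(unlist(sets[setdiff(names(sets), nm)],
                            use.names = FALSE))
    setdiff(sets[[nm]], others)
  })
  names(exclusive) <- names(sets)
  list(exclusive = exclusive, common = common, union = u)
}

#' Positional conservation meta-profile around TSS or TES
#'
#' Averages the conservation score at each offset in
#' `-flank ... +flank` around the chosen anchor, strand-aware (offsets are
#' flipped for minus-strand genes so that positive offsets always point
#' downstream in transcript orientation).  Positions falling outside the
#' chromosome are skipped and tracked in the per-offset `n`.
#'
#' @param track A [score_track()].
#' @param models A [gene_models()] object.
#' @param anchor "TSS" or "TES".
#' @param flank Flank size in bp (default 1000).
#' @return data.frame: offset, mean (NA where n = 0), n.
#' @export
meta_profile <- function(track, models, anchor = c("TSS", "TES"),
                         flank = 1000) {
  anchor <- match.arg(anchor)
  anchors <- gene_anchors(models)
  offs <- (-flank):flank
  sums <- numeric(length(offs))
  n <- integer(length(offs))
  for (i in seq_len(nrow(anchors))) {
    ch <- track$chroms[[anchors$chrom[i]]]
    if (is.null(ch)) stop("track has no chromosome ", anchors$chrom[i])
    a <- if (anchor == "TSS") anchors$tss[i] else anchors$tes[i]
    sgn <- if (anchors$strand[i] == "-") -1L else 1L
    pos <- a + sgn * offs          # 0-based genomic positions
    ok <- pos >= 0 & pos < length(ch$matched)
    sums[ok] <- sums[ok] + ch$matched[pos[ok] + 1L] / track$n_species
    n[ok] <- n[ok] + 1L
  }
  data.frame(offset = offs, mean = ifelse(n > 0, sums / n, NA_real_), n = n)
}

#' Mean conservation score by exon class
#'
#' Classes: first exon, internal exons, last exon (5'-to-3' in transcript
#' orientation) and the UTR parts of exons.  Transcripts with fewer than
#' three exons do not contribute to the internal class; single-exon
#' transcripts contribute to neither first nor last.
#'
#' @param track A [score_track()].
#' @param models A [gene_models()] object.
#' @return data.frame: class, mean_score (NA when no bases), n_bases.
#' @export
exon_rank_profile <- function(track, models) {
  cums <- lapply(track$chroms, function(ch) c(0, cumsum(ch$matched)))
  span_sum <- function(chrom, start, end) {
    cm <- cums[[chrom]]
    cm[end + 1] - cm[start + 1]
  }
  acc <- list(first = c(0, 0), internal = c(0, 0), last = c(0, 0),
              utr = c(0, 0))
  add <- function(acc, cls, chrom, start, end) {
    if (end > start) {
      acc[[cls]][1] <- acc[[cls]][1] + span_sum(chrom, start, end)
      acc[[cls]][2] <- acc[[cls]][2] + (end - start)
    }
    acc
  }
  for (tx in models$transcripts$tx_id) {
    ex <- models$exons[models$exons$tx_id == tx, ]
    if (nrow(ex) < 2L) next
    ex <- ex[order(ex$start), ]
    minus <- ex$strand[1] == "-"
    first_i <- if (minus) nrow(ex) else 1L
    last_i <- if (minus) 1L else nrow(ex)
    acc <- add(acc, "first", ex$chrom[first_i], ex$start[first_i],
               ex$end[first_i])
    acc <- add(acc, "last", ex$chrom[last_i], ex$start[last_i],
               ex$end[last_i])
    if (nrow(ex) >= 3L)
      for (k in setdiff(seq_len(nrow(ex)), c(first_i, last_i)))
        acc <- add(acc, "internal", ex$chrom[k], ex$start[k], ex$end[k])
  }
  for (utab in list(models$utr5, models$utr3))
    for (k in seq_len(nrow(utab)))
      acc <- add(acc, "utr", utab$chrom[k], utab$start[k], utab$end[k])
  data.frame(
    class = names(acc),
    mean_score = vapply(acc, function(a)
      if (a[2] > 0) a[1] / track$n_species / a[2] else NA_real_, 0),
    n_bases = vapply(acc, `[`, 0, 2),
    stringsAsFactors = FALSE, row.names = NULL)
}
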