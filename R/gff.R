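#' Gene-model collection
#'
#' Internal container for gene models parsed from GFF3.  All coordinates are
#' 0-based half-open.  Introns are the within-transcript gaps between exons;
#' UTRs are taken from explicit `five_prime_UTR`/`three_prime_UTR` features
#' when present, otherwise derived as exon-minus-CDS on the appropriate side
#' of the coding span.
#'
#' @param genes,transcripts,exons,cds,introns,utr5,utr3 data.frames; see
#'   [read_gff3()] for columns.
#' @return An object of class `gene_models`.
#' @keywords internal
#' @export
gene_models <- function(genes, transcripts, exons, cds, introns, utr5, utr3) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, introns = introns, utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$cds), "CDS segments\n")
  invisible(x)
}

.empty_feat <- function() {
  data.frame(tx_id = character(0), gene_id = character(0),
             chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

.feat_df <- function(tx_id, gene_id, chrom, start, end, strand) {
  data.frame(tx_id = tx_id, gene_id = gene_id, chrom = chrom,
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS (and optional UTR) features into 0-based
#' half-open coordinates.  A CDS segment that is not contained in one of its
#' transcript's exons, or any feature extending beyond its chromosome, is a
#' format error.
#'
#' @param path Path to a GFF3 file.
#' @param genome [genome_dict()] used to validate feature bounds.
#' @return A [gene_models()] object with data.frames `genes` (gene_id, chrom,
#'   start, end, strand), `transcripts` (tx_id, gene_id, ...), `exons`,
#'   `cds`, `introns`, `utr5`, `utr3` (tx_id, gene_id, chrom, start, end,
#'   strand).
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,   # to 0-based half-open
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    stringsAsFactors = FALSE)
  parent <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, nrow(df))
  df$parent <- parent

  for (k in seq_len(nrow(df))) {
    if (df$end[k] > chrom_length(genome, df$chrom[k]) || df$start[k] < 0)
      stop("feature beyond chromosome length: ", df$type[k], " ",
           df$chrom[k], ":", df$start[k], "-", df$end[k])
  }

  gdf <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gdf$id, chrom = gdf$chrom, start = gdf$start,
                      end = gdf$end, strand = gdf$strand,
                      stringsAsFactors = FALSE)
  tdf <- df[df$type %in% c("mRNA", "transcript"), ]
  transcripts <- data.frame(tx_id = tdf$id, gene_id = tdf$parent,
                            chrom = tdf$chrom, start = tdf$start,
                            end = tdf$end, strand = tdf$strand,
                            stringsAsFactors = FALSE)
  tx_gene <- stats::setNames(transcripts$gene_id, transcripts$tx_id)
  tx_strand <- stats::setNames(transcripts$strand, transcripts$tx_id)
  tx_chrom <- stats::setNames(transcripts$chrom, transcripts$tx_id)

  pick <- function(types) {
    s <- df[df$type %in% types & df$parent %in% names(tx_gene), ]
    .feat_df(s$parent, unname(tx_gene[s$parent]), s$chrom, s$start, s$end,
             unname(tx_strand[s$parent]))
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  utr5 <- pick("five_prime_UTR")
  utr3 <- pick("three_prime_UTR")

  introns <- .empty_feat()
  d_utr5 <- .empty_feat()
  d_utr3 <- .empty_feat()
  for (tx in transcripts$tx_id) {
    ex <- exons[exons$tx_id == tx, ]
    if (nrow(ex) == 0L) next
    ex <- ex[order(ex$start), ]
    cd <- cds[cds$tx_id == tx, ]
    # CDS containment check
    if (nrow(cd)) {
      for (k in seq_len(nrow(cd))) {
        inside <- any(ex$start <= cd$start[k] & ex$end >= cd$end[k])
        if (!inside)
          stop("CDS segment outside its parent exons in transcript ", tx)
      }
    }
    if (nrow(ex) > 1L) {
      gs <- ex$end[-nrow(ex)]
      ge <- ex$start[-1L]
      keep <- ge > gs
      if (any(keep))
        introns <- rbind(introns, .feat_df(tx, tx_gene[[tx]], tx_chrom[[tx]],
                                           gs[keep], ge[keep], tx_strand[[tx]]))
    }
    if (nrow(cd) && !any(utr5$tx_id == tx) && !any(utr3$tx_id == tx)) {
      cmin <- min(cd$start); cmax <- max(cd$end)
      left <- .clip_intervals(ex$start, ex$end, -Inf, cmin)
      right <- .clip_intervals(ex$start, ex$end, cmax, Inf)
      if (tx_strand[[tx]] == "-") { tmp <- left; left <- right; right <- tmp }
      # 'left' is now the 5' side in transcript orientation
      if (nrow(left))
        d_utr5 <- rbind(d_utr5, .feat_df(tx, tx_gene[[tx]], tx_chrom[[tx]],
                                         left$start, left$end, tx_strand[[tx]]))
      if (nrow(right))
        d_utr3 <- rbind(d_utr3, .feat_df(tx, tx_gene[[tx]], tx_chrom[[tx]],
                                         right$start, right$end, tx_strand[[tx]]))
    }
  }
  if (nrow(d_utr5)) utr5 <- rbind(utr5, d_utr5)
  if (nrow(d_utr3)) utr3 <- rbind(utr3, d_utr3)
  gene_models(genes, transcripts, exons, cds, introns, utr5, utr3)
}

# clip a set of [start,end) intervals to the window [lo,hi)
.clip_intervals <- function(start, end, lo, hi) {
  s <- pmax(start, lo); e <- pmin(end, hi)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Write gene models as GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tcnscan\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type,
            as.integer(start) + 1L, as.integer(end), strand, attrs)
  g <- models$genes
  for (i in seq_len(nrow(g))) {
    writeLines(fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                   paste0("ID=", g$gene_id[i])), con)
    tx <- models$transcripts[models$transcripts$gene_id == g$gene_id[i], ]
    for (j in seq_len(nrow(tx))) {
      writeLines(fmt(tx$chrom[j], "mRNA", tx$start[j], tx$end[j], tx$strand[j],
                     paste0("ID=", tx$tx_id[j], ";Parent=", g$gene_id[i])), con)
      for (tab in list(c("exon", "exons"), c("CDS", "cds"))) {
        ff <- models[[tab[[2]]]]
        ff <- ff[ff$tx_id == tx$tx_id[j], ]
        for (k in seq_len(nrow(ff)))
          writeLines(fmt(ff$chrom[k], tab[[1]], ff$start[k], ff$end[k],
                         ff$strand[k], paste0("Parent=", tx$tx_id[j])), con)
      }
    }
  }
  invisible(path)
}

#' Transcription start/end sites per gene
#'
#' Gene span is the union extent over transcripts; the TSS (TES) is the
#' extreme 5' (3') base of any transcript, strand-aware, as a 0-based
#' position.
#'
#' @param models A [gene_models()] object.
#' @return data.frame: gene_id, chrom, start, end, strand, tss, tes.
#' @export
gene_anchors <- function(models) {
  g <- models$genes
  plus <- g$strand != "-"
  data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
             end = g$end, strand = g$strand,
             tss = ifelse(plus, g$start, g$end - 1),
             tes = ifelse(plus, g$end - 1, g$start),
             stringsAsFactors = FALSE)
}
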