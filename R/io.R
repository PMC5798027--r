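#' Write intervals as BED6
#'
#' For a `cns_set`, name is the category and score is
#' `round(1000 * mean_score)`; for a plain interval data.frame, optional
#' `name`/`score`/`strand` columns are used when present.
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  name <- if (inherits(intervals, "cns_set")) intervals$category
    else if (!is.null(intervals$name)) intervals$name
    else rep(".", nrow(intervals))
  score <- if (inherits(intervals, "cns_set"))
      round(1000 * intervals$mean_score)
    else if (!is.null(intervals$score)) intervals$score
    else rep(0, nrow(intervals))
  strand <- if (!is.null(intervals$strand)) intervals$strand
    else rep(".", nrow(intervals))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     name, score, strand), path)
  invisible(path)
}

#' Read a BED file
#'
#' @param path Path to a BED3..BED6 file.
#' @return data.frame: chrom, start, end (0-based half-open) and, when the
#'   file has them, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- ifelse(st == "*", ".", st)
  out
}

#' Write a conservation track as bedGraph
#'
#' Runs of equal score are merged into single lines; zero runs are kept so
#' the track tiles the genome.
#'
#' @param track A [score_track()].
#' @param path Output path.
#' @param drop_zero If TRUE (default), omit zero-score runs.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"conservation_%s\"",
                     track$clade), con)
  for (chrom in names(track$chroms)) {
    sc <- track$chroms[[chrom]]$matched / track$n_species
    r <- rle(sc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                         as.integer(starts[keep]), as.integer(ends[keep]),
                         r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a bedGraph file (track line allowed).
#' @return data.frame: chrom, start, end (0-based half-open), value.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Read an IUPAC motif table
#'
#' Two tab-separated columns: motif name and IUPAC pattern.  A pattern
#' containing a non-IUPAC letter, or shorter than `min_len`, is a format
#' error naming the motif.
#'
#' @param path Path to the motif TSV.
#' @param min_len Minimum pattern length (default 4).
#' @return data.frame: name, pattern.
#' @export
read_motifs <- function(path, min_len = 4) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("name", "pattern"))
  for (i in seq_len(nrow(df))) {
    check_iupac(df$pattern[i], df$name[i], min_len = min_len)
  }
  df
}

#' Write per-base matched/aligned counts as TSV
#'
#' @param track A [score_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tpos\tmatched\taligned\tscore", con)
  for (chrom in names(track$chroms)) {
    ch <- track$chroms[[chrom]]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%g", chrom,
                       seq_along(ch$matched) - 1L, ch$matched, ch$aligned,
                       ch$matched / track$n_species), con)
  }
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @param reference Reference species name for the returned dictionary.
#' @return List: seq (a `Biostrings::DNAStringSet`), genome (a
#'   [genome_dict()]).
#' @export
read_reference <- function(path, reference) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  list(seq = seqs,
       genome = genome_dict(stats::setNames(Biostrings::width(seqs),
                                            names(seqs)), reference))
}
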