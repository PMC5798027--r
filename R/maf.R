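#' Alignment block
#'
#' One reference-anchored block of a multiple alignment.  The reference row
#' is stored separately from the other species; all rows (including the
#' reference) have identical text length, and the number of non-gap
#' characters in the reference row equals the reference span covered.
#'
#' @param ref_chrom Reference chromosome name.
#' @param ref_start 0-based offset of the first reference base in the block.
#' @param ref_text Reference row text (may contain '-').
#' @param rows Named character vector: species name -> aligned row text.
#' @param score Optional numeric block score from the aligner.
#' @param row_starts,row_src_sizes,row_strands Optional named vectors with
#'   per-species start offsets, source sequence sizes and strands; used when
#'   writing MAF, ignored by scoring.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(ref_chrom, ref_start, ref_text, rows,
                            score = NA_real_, row_starts = NULL,
                            row_src_sizes = NULL, row_strands = NULL) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("'rows' must be uniquely named by species")
  widths <- nchar(c(ref_text, rows))
  if (length(unique(widths)) != 1L)
    stop("ragged alignment block: row lengths ", paste(widths, collapse = ","))
  structure(
    list(ref_chrom = ref_chrom, ref_start = as.numeric(ref_start),
         ref_text = ref_text, rows = rows, score = score,
         row_starts = row_starts, row_src_sizes = row_src_sizes,
         row_strands = row_strands),
    class = "alignment_block")
}

#' Reference span (bp) covered by a block
#' @param block An `alignment_block`.
#' @return Number of non-gap reference characters.
#' @export
block_ref_span <- function(block) {
  nchar(gsub("-", "", block$ref_text, fixed = TRUE))
}

.maf_species <- function(src, split_regex = "\\.") {
  strsplit(src, split_regex)[[1]][1]
}

.maf_seqname <- function(src, split_regex = "\\.") {
  sub(paste0("^[^.]*", "\\."), "", src)
}

#' Read a MAF 1.0 alignment file
#'
#' Parses a reference-anchored Multiple Alignment Format file into a list of
#' [alignment_block()] objects.  Species are identified by the text before
#' the first '.' of each "s" line source name (the UCSC convention);
#' `split_regex` overrides that.  Exactly one row per block must belong to
#' the reference species, and that row must be on the forward strand.
#'
#' @param path Path to an uncompressed MAF file.
#' @param ref_species Reference species name.
#' @param clade_map Optional [clade_map()]; rows from species outside the map
#'   (and not the reference) trigger a warning but are kept.
#' @param min_block_score Optional numeric; blocks whose "a score=" value is
#'   below this are dropped (mirrors upstream chain-score filtering; default
#'   off).
#' @param split_regex Regex splitting species from sequence name.
#' @return List of `alignment_block` objects, in file order.
#' @export
read_maf <- function(path, ref_species, clade_map = NULL,
                     min_block_score = NULL, split_regex = "\\.") {
  lines <- readLines(path)
  blocks <- list()
  known <- if (!is.null(clade_map)) c(all_species(clade_map), ref_species)
  unknown_seen <- character(0)
  i <- 1L
  n <- length(lines)
  block_idx <- 0L
  while (i <= n) {
    line <- lines[[i]]
    if (!startsWith(line, "a")) { i <- i + 1L; next }
    block_idx <- block_idx + 1L
    score <- NA_real_
    m <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1]]
    if (length(m) == 2L) score <- as.numeric(m[[2]])
    srcs <- character(0); starts <- numeric(0); sizes <- numeric(0)
    strands <- character(0); srcsizes <- numeric(0); texts <- character(0)
    i <- i + 1L
    while (i <= n && (startsWith(lines[[i]], "s") || startsWith(lines[[i]], "i") ||
                      startsWith(lines[[i]], "e") || startsWith(lines[[i]], "q"))) {
      if (startsWith(lines[[i]], "s")) {
        f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
        if (length(f) < 7L)
          stop("malformed s line in block ", block_idx, " of ", path)
        srcs <- c(srcs, f[[2]]); starts <- c(starts, as.numeric(f[[3]]))
        sizes <- c(sizes, as.numeric(f[[4]])); strands <- c(strands, f[[5]])
        srcsizes <- c(srcsizes, as.numeric(f[[6]])); texts <- c(texts, f[[7]])
      }
      i <- i + 1L
    }
    if (length(srcs) == 0L) next
    if (length(unique(nchar(texts))) != 1L)
      stop("ragged row lengths in block ", block_idx, " of ", path)
    species <- vapply(srcs, .maf_species, "", split_regex = split_regex,
                      USE.NAMES = FALSE)
    is_ref <- species == ref_species
    if (sum(is_ref) != 1L)
      stop("block ", block_idx, " of ", path, " has ", sum(is_ref),
           " reference rows (expected exactly 1)")
    r <- which(is_ref)
    if (strands[[r]] != "+")
      stop("block ", block_idx, " of ", path,
           ": reference row must be on the forward strand")
    if (!is.null(known)) {
      unk <- setdiff(species[!is_ref], known)
      unknown_seen <- union(unknown_seen, unk)
    }
    if (!is.null(min_block_score) && !is.na(score) && score < min_block_score)
      next
    rows <- stats::setNames(texts[!is_ref], species[!is_ref])
    blocks[[length(blocks) + 1L]] <- alignment_block(
      ref_chrom = .maf_seqname(srcs[[r]], split_regex),
      ref_start = starts[[r]], ref_text = texts[[r]], rows = rows,
      score = score,
      row_starts = stats::setNames(starts[!is_ref], species[!is_ref]),
      row_src_sizes = stats::setNames(srcsizes[!is_ref], species[!is_ref]),
      row_strands = stats::setNames(strands[!is_ref], species[!is_ref]))
  }
  if (length(unknown_seen))
    warning("MAF contains species outside the clade map (rows kept): ",
            paste(unknown_seen, collapse = ", "))
  blocks
}

#' Write alignment blocks as MAF 1.0
#'
#' @param blocks List of [alignment_block()] objects.
#' @param path Output path.
#' @param genome [genome_dict()] providing reference chromosome sizes.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path, genome) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    hdr <- if (is.na(b$score)) "a" else sprintf("a score=%g", b$score)
    writeLines(hdr, con)
    span <- block_ref_span(b)
    writeLines(sprintf("s %s.%s %d %d + %d %s", genome$reference, b$ref_chrom,
                       as.integer(b$ref_start), span,
                       as.integer(chrom_length(genome, b$ref_chrom)),
                       b$ref_text), con)
    for (sp in names(b$rows)) {
      st <- if (!is.null(b$row_starts)) b$row_starts[[sp]] else 0
      ss <- if (!is.null(b$row_src_sizes)) b$row_src_sizes[[sp]] else
        nchar(gsub("-", "", b$rows[[sp]], fixed = TRUE))
      sd <- if (!is.null(b$row_strands)) b$row_strands[[sp]] else "+"
      writeLines(sprintf("s %s.%s %d %d %s %d %s", sp, b$ref_chrom,
                         as.integer(st),
                         nchar(gsub("-", "", b$rows[[sp]], fixed = TRUE)),
                         sd, as.integer(ss), b$rows[[sp]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
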