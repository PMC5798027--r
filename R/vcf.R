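#' SNP record table
#'
#' Biallelic population variants with folded minor-allele frequencies.
#' Positions are 0-based internally.
#'
#' @param chrom,pos,ref,alt,an,ac Vectors of equal length: chromosome,
#'   0-based position, reference and alternate alleles, total allele number
#'   (AN) and alternate allele count (AC).
#' @param effects Optional list column: per SNP, a character vector of
#'   SnpEff-style effect (annotation) types; `NULL` entries mean
#'   unannotated.
#' @param impacts Optional list column of impact classes parallel to
#'   `effects` (HIGH/MODERATE/LOW/MODIFIER).
#' @return data.frame of class `snp_records` with columns chrom, pos, ref,
#'   alt, an, ac, maf, effects, impacts.
#' @export
snp_records <- function(chrom, pos, ref, alt, an, ac,
                        effects = NULL, impacts = NULL) {
  n <- length(pos)
  if (any(ac < 0 | ac > an)) stop("AC must satisfy 0 <= AC <= AN")
  maf <- ifelse(an > 0, pmin(ac / an, 1 - ac / an), NA_real_)
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   an = as.numeric(an), ac = as.numeric(ac), maf = maf,
                   stringsAsFactors = FALSE)
  df$effects <- if (is.null(effects)) vector("list", n) else effects
  df$impacts <- if (is.null(impacts)) vector("list", n) else impacts
  class(df) <- c("snp_records", "data.frame")
  df
}

# SnpEff v4 ANN subfields: Allele|Annotation|Impact|Gene_Name|...
.parse_ann <- function(ann_strings) {
  effects <- vector("list", length(ann_strings))
  impacts <- vector("list", length(ann_strings))
  for (i in seq_along(ann_strings)) {
    s <- ann_strings[[i]]
    if (length(s) == 0L || all(is.na(s))) next
    recs <- unlist(strsplit(s, ",", fixed = TRUE), use.names = FALSE)
    parts <- strsplit(recs, "|", fixed = TRUE)
    eff <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "unknown", "")
    imp <- vapply(parts, function(p) if (length(p) >= 3L) p[[3]] else "unknown", "")
    effects[[i]] <- eff
    impacts[[i]] <- imp
  }
  list(effects = effects, impacts = impacts)
}

#' Read biallelic SNPs from a VCF
#'
#' Multiallelic records are skipped with a warning by default (the skipped
#' count is attached as attribute `n_multiallelic`) or naively split into
#' one record per ALT allele sharing the site's AN.  AC and AN are read from
#' INFO; SnpEff-style effect annotations are parsed from the ANN field when
#' present.
#'
#' @param path Path to an uncompressed VCF 4.x file.
#' @param multiallelic Either "skip" (default) or "split".
#' @return A [snp_records()] data.frame.
#' @export
read_vcf <- function(path, multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  info <- VariantAnnotation::info(vcf)
  if (is.null(info$AC) || is.null(info$AN))
    stop("VCF must carry AC and AN INFO fields")
  ac_l <- info$AC
  an <- as.numeric(info$AN)
  ann <- if (!is.null(info$ANN)) as.list(info$ANN) else NULL

  multi <- n_alt > 1L
  n_multi <- sum(multi)
  idx <- which(!multi)
  if (multiallelic == "skip") {
    if (n_multi > 0L)
      warning(n_multi, " multiallelic record(s) skipped")
    take_i <- idx
    take_a <- rep(1L, length(idx))
  } else {
    take_i <- rep(seq_along(n_alt), n_alt)
    take_a <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  }
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[take_i]
  pos <- BiocGenerics::start(rr)[take_i] - 1   # to 0-based
  refA <- as.character(VariantAnnotation::ref(vcf))[take_i]
  altA <- mapply(function(i, a) as.character(alt[[i]][a]), take_i, take_a,
                 USE.NAMES = FALSE)
  if (length(take_i) == 0L) altA <- character(0)
  ac <- mapply(function(i, a) {
    v <- ac_l[[i]]
    if (length(v) >= a) as.numeric(v[[a]]) else NA_real_
  }, take_i, take_a, USE.NAMES = FALSE)
  if (length(take_i) == 0L) ac <- numeric(0)
  eff <- imp <- NULL
  if (!is.null(ann)) {
    parsed <- .parse_ann(ann[take_i])
    eff <- parsed$effects
    imp <- parsed$impacts
  }
  out <- snp_records(chrom, pos, refA, altA, an[take_i], ac,
                     effects = eff, impacts = imp)
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write SNPs as VCF 4.2
#'
#' @param snps A [snp_records()] table.
#' @param path Output path.
#' @param genome [genome_dict()] for contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, genome) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$lengths),
            as.integer(genome$lengths)),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Impact | Gene_Name'\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- sprintf("AC=%d;AN=%d", as.integer(snps$ac), as.integer(snps$an))
  ann <- vapply(seq_len(nrow(snps)), function(i) {
    eff <- snps$effects[[i]]
    if (is.null(eff) || !length(eff)) return("")
    imp <- snps$impacts[[i]]
    if (is.null(imp)) imp <- rep("MODIFIER", length(eff))
    paste0(";ANN=", paste(sprintf("%s|%s|%s|GENE", snps$alt[i], eff, imp),
                          collapse = ","))
  }, "")
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s%s", snps$chrom,
                     as.integer(snps$pos) + 1L, snps$ref, snps$alt,
                     info, ann), con)
  invisible(path)
}
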