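#' Region index: per-base partition of the reference
#'
#' Every reference base carries exactly one label out of CDS, UTR5, UTR3,
#' intron, intergenic.  When transcripts overlap, the precedence
#' CDS > UTR5 > UTR3 > intron > intergenic decides.
#'
#' @param labels Named list: chromosome -> integer vector of codes into
#'   `levels`.
#' @param levels Character vector of class labels (fixed order).
#' @return Object of class `region_index`.
#' @keywords internal
#' @export
region_index <- function(labels,
                         levels = c("CDS", "UTR5", "UTR3", "intron",
                                    "intergenic")) {
  structure(list(labels = labels, levels = levels), class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  tot <- table(factor(unlist(x$labels, use.names = FALSE), levels = seq_along(x$levels),
                      labels = x$levels))
  cat("<region_index>\n")
  print(tot)
  invisible(x)
}

.region_code <- function(regions, label) match(label, regions$levels)

#' Build a region index from gene models
#'
#' Paints labels in increasing precedence (introns, then 3'-UTR, 5'-UTR and
#' finally CDS) over an intergenic background, so the stated precedence
#' holds wherever transcripts overlap.
#'
#' @param models A [gene_models()] object.
#' @param genome A [genome_dict()].
#' @return A [region_index()].
#' @export
build_region_index <- function(models, genome) {
  labels <- lapply(genome$lengths, function(L) rep(5L, as.integer(L)))
  paint <- function(labels, feat, code) {
    for (i in seq_len(nrow(feat))) {
      ch <- feat$chrom[i]
      if (feat$end[i] > feat$start[i])
        labels[[ch]][(feat$start[i] + 1):feat$end[i]] <- code
    }
    labels
  }
  labels <- paint(labels, models$introns, 4L)
  labels <- paint(labels, models$utr3, 3L)
  labels <- paint(labels, models$utr5, 2L)
  labels <- paint(labels, models$cds, 1L)
  region_index(labels)
}

#' Per-class base counts of a region index
#' @param regions A [region_index()].
#' @return Named numeric vector of bp per class.
#' @export
region_bp <- function(regions) {
  out <- stats::setNames(numeric(length(regions$levels)), regions$levels)
  for (lab in regions$labels) {
    t <- tabulate(lab, nbins = length(regions$levels))
    out <- out + t
  }
  out
}
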