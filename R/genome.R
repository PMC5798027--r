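#' Genome dictionary
#'
#' A minimal container tying chromosome lengths to the name of the reference
#' species.  All coordinates elsewhere in the package are 0-based half-open
#' and are validated against these lengths.
#'
#' @param lengths Named numeric/integer vector of chromosome lengths (bp).
#' @param reference Single string, the reference species name (the species
#'   whose rows anchor every MAF block).
#' @return An object of class `genome_dict`.
#' @examples
#' genome_dict(c(chr1 = 1e5), "osat")
#' @export
genome_dict <- function(lengths, reference) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.character(reference) || length(reference) != 1L || !nzchar(reference))
    stop("'reference' must be a single species name")
  structure(
    list(lengths = stats::setNames(as.numeric(lengths), names(lengths)),
         reference = reference),
    class = "genome_dict")
}

#' @export
print.genome_dict <- function(x, ...) {
  cat("<genome_dict> reference:", x$reference, "\n")
  cat(" ", length(x$lengths), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  len <- genome$lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  len
}

#' Clade map
#'
#' An ordered set of clades, each a set of non-reference species names.
#' Clades may nest (e.g. BEP within Poaceae within Poales within monocots
#' within all); every conservation score is computed independently per clade.
#'
#' @param clades Named list of character vectors; names are clade names in
#'   display order, values are the species in each clade.
#' @param reference Optional reference species name; if given, it is checked
#'   to be absent from every clade set.
#' @return An object of class `clade_map`.
#' @examples
#' clade_map(list(inner = c("sp1", "sp2"), all = c("sp1", "sp2", "sp3")))
#' @export
clade_map <- function(clades, reference = NULL) {
  if (!is.list(clades) || is.null(names(clades)) || anyDuplicated(names(clades)))
    stop("'clades' must be a uniquely named list of species vectors")
  for (nm in names(clades)) {
    sp <- clades[[nm]]
    if (!is.character(sp) || length(sp) == 0L)
      stop("clade '", nm, "' is empty")
    if (anyDuplicated(sp))
      stop("clade '", nm, "' lists a species twice")
    if (!is.null(reference) && reference %in% sp)
      stop("reference species '", reference, "' must not appear in clade '",
           nm, "'")
  }
  structure(list(clades = lapply(clades, as.character), reference = reference),
            class = "clade_map")
}

#' @export
print.clade_map <- function(x, ...) {
  cat("<clade_map>", length(x$clades), "clade(s)\n")
  for (nm in names(x$clades))
    cat("  ", nm, ": ", length(x$clades[[nm]]), " species\n", sep = "")
  invisible(x)
}

clade_species <- function(cmap, clade) {
  sp <- cmap$clades[[clade]]
  if (is.null(sp)) stop("unknown clade: ", clade)
  sp
}

all_species <- function(cmap) unique(unlist(cmap$clades, use.names = FALSE))
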