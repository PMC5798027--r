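#' Per-base conservation score track
#'
#' For one clade, holds per reference position the number of clade species
#' with any aligned base (`aligned`) and the number whose aligned base is
#' identical to the reference base (`matched`).  The conservation score at a
#' position is `matched / n_species`, where `n_species` is the clade size
#' (the reference is never counted): 1 means the site is ultraconserved
#' across the whole clade, 0 that it is not seen in any other species.
#' Counts are stored as integers so that threshold comparisons can be done
#' on exact rationals.
#'
#' @param clade Clade name.
#' @param n_species Clade size (number of non-reference species).
#' @param chroms Named list: chromosome -> list(matched = integer vector,
#'   aligned = integer vector) of length equal to the chromosome.
#' @return An object of class `score_track`.
#' @export
score_track <- function(clade, n_species, chroms) {
  for (nm in names(chroms)) {
    ch <- chroms[[nm]]
    if (length(ch$matched) != length(ch$aligned))
      stop("matched/aligned length mismatch on ", nm)
    if (any(ch$matched > ch$aligned) || any(ch$aligned > n_species) ||
        any(ch$matched < 0))
      stop("count invariant violated on ", nm,
           " (need 0 <= matched <= aligned <= n_species)")
  }
  structure(list(clade = clade, n_species = as.integer(n_species),
                 chroms = chroms),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat("<score_track> clade:", x$clade, "(", x$n_species, "species ),",
      length(x$chroms), "chromosome(s)\n")
  invisible(x)
}

#' Numeric conservation scores for one chromosome
#' @param track A [score_track()].
#' @param chrom Chromosome name.
#' @return Numeric vector `matched / n_species`.
#' @export
track_scores <- function(track, chrom) {
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) stop("track has no chromosome ", chrom)
  ch$matched / track$n_species
}

# matched/n >= threshold on the exact rational (threshold snapped to 1e-6)
score_ge <- function(matched, n_species, threshold) {
  matched * 1e6 >= round(threshold * 1e6) * n_species
}

# strictly below: matched/n < threshold
score_lt <- function(matched, n_species, threshold) {
  !score_ge(matched, n_species, threshold)
}

.MATCHABLE <- c("A", "C", "G", "T")

#' Score one alignment column
#'
#' Counts, over the species of one clade, how many have any aligned base at
#' the column (`aligned`) and how many carry a base identical to the
#' reference base (`matched`).  Comparison is case-insensitive; 'N' (or any
#' non-ACGT character) never matches on either side, and a gap or missing
#' species counts as unaligned.
#'
#' @param ref_base Single reference nucleotide.
#' @param aligned_bases Named character vector, species -> aligned base;
#'   species absent from the vector are unaligned, '-' is a gap.
#' @param clade_species Character vector of clade species names.
#' @return Named integer vector c(matched =, aligned =).
#' @export
score_column <- function(ref_base, aligned_bases, clade_species) {
  b <- toupper(aligned_bases[names(aligned_bases) %in% clade_species])
  aligned <- sum(!is.na(b) & b != "-")
  rb <- toupper(ref_base)
  matched <- if (rb %in% .MATCHABLE)
    sum(!is.na(b) & b == rb) else 0L
  c(matched = as.integer(matched), aligned = as.integer(aligned))
}

#' Compute a conservation score track for one clade
#'
#' Streams reference-anchored alignment blocks and accumulates per-base
#' matched/aligned counts for the species of one clade.  Positions covered
#' by no block score 0.  If two blocks align a species twice to one
#' reference position, the earlier block in file order wins; a single
#' warning with the duplicate count is emitted at the end (upstream net
#' filtering should make this impossible).
#'
#' @param blocks List of [alignment_block()] (e.g. from [read_maf()]).
#' @param clade Clade name.
#' @param clade_map A [clade_map()].
#' @param genome A [genome_dict()].
#' @param match_mode "identity" (default): a species matches only when its
#'   base equals the reference base; "aligned": any aligned base counts as a
#'   match (sensitivity analysis).
#' @return A [score_track()].
#' @export
score_genome <- function(blocks, clade, clade_map, genome,
                         match_mode = c("identity", "aligned")) {
  match_mode <- match.arg(match_mode)
  species <- clade_species(clade_map, clade)
  n_sp <- length(species)
  block_chrom <- vapply(blocks, `[[`, "", "ref_chrom")
  n_dup <- 0
  chroms <- vector("list", length(genome$lengths))
  names(chroms) <- names(genome$lengths)
  for (chrom in names(genome$lengths)) {
    L <- as.integer(genome$lengths[[chrom]])
    matched <- integer(L)
    aligned <- integer(L)
    visited <- matrix(FALSE, nrow = L, ncol = n_sp,
                      dimnames = list(NULL, species))
    for (bi in which(block_chrom == chrom)) {
      b <- blocks[[bi]]
      ref_chars <- toupper(strsplit(b$ref_text, "", fixed = TRUE)[[1]])
      nongap <- ref_chars != "-"
      span <- sum(nongap)
      if (b$ref_start + span > L)
        stop("block ", bi, " extends past end of ", chrom)
      pos <- b$ref_start + seq_len(span)  # 1-based array index
      rb <- ref_chars[nongap]
      rb_ok <- rb %in% .MATCHABLE
      for (sp in intersect(names(b$rows), species)) {
        rc <- toupper(strsplit(b$rows[[sp]], "", fixed = TRUE)[[1]])[nongap]
        has_base <- rc != "-"
        if (!any(has_base)) next
        new <- has_base & !visited[pos, sp]
        dup <- sum(has_base) - sum(new)
        if (dup > 0) n_dup <- n_dup + dup
        if (!any(new)) next
        visited[pos[new], sp] <- TRUE
        aligned[pos[new]] <- aligned[pos[new]] + 1L
        hit <- if (match_mode == "identity") new & rb_ok & rc == rb else new
        if (any(hit))
          matched[pos[hit]] <- matched[pos[hit]] + 1L
      }
    }
    chroms[[chrom]] <- list(matched = matched, aligned = aligned)
  }
  if (n_dup > 0)
    warning("species aligned more than once at ", n_dup,
            " (position, species) pairs; first block in file order kept")
  score_track(clade, n_sp, chroms)
}

#' Fraction of each region class at or above a score threshold
#'
#' @param track A [score_track()].
#' @param regions A [region_index()] on the same genome.
#' @param min_score Threshold in `[0, 1]`.
#' @return data.frame: region (class label), bp (class size), bp_ge
#'   (bases with score >= min_score), fraction.  Empty classes report
#'   `NA` fractions.
#' @export
coverage_by_region <- function(track, regions, min_score) {
  if (min_score < 0 || min_score > 1) stop("min_score must be in [0, 1]")
  lev <- regions$levels
  bp <- stats::setNames(numeric(length(lev)), lev)
  hit <- bp
  for (chrom in names(regions$labels)) {
    lab <- regions$labels[[chrom]]
    ch <- track$chroms[[chrom]]
    if (is.null(ch)) stop("track has no chromosome ", chrom)
    ge <- score_ge(ch$matched, track$n_species, min_score)
    for (k in seq_along(lev)) {
      sel <- lab == k
      bp[k] <- bp[k] + sum(sel)
      hit[k] <- hit[k] + sum(ge[sel])
    }
  }
  data.frame(region = lev, bp = as.numeric(bp), bp_ge = as.numeric(hit),
             fraction = ifelse(bp > 0, hit / bp, NA_real_),
             stringsAsFactors = FALSE)
}
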