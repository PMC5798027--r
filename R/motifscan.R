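# IUPAC bit encoding: A=1, C=2, G=4, T=8; N in a *sequence* gets its own
# bit (16) so that an unknown base satisfies only the pattern letter 'N'.
.IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 31L)
.SEQ_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)
.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

#' Validate an IUPAC motif pattern
#'
#' @param pattern IUPAC string.
#' @param name Motif name used in error messages.
#' @param min_len Minimum length (default 4).
#' @return `pattern`, invisibly; errors on invalid letters or short
#'   patterns.
#' @export
check_iupac <- function(pattern, name = pattern, min_len = 4) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(.IUPAC_BITS))
  if (length(bad))
    stop("motif '", name, "' contains non-IUPAC letter(s): ",
         paste(bad, collapse = ", "))
  if (length(chars) < min_len)
    stop("motif '", name, "' is shorter than ", min_len, " bp")
  invisible(pattern)
}

#' Reverse-complement an IUPAC pattern
#' @param pattern IUPAC string.
#' @return Reverse-complemented pattern.
#' @export
revcomp_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(rev(unname(.IUPAC_COMP[chars])), collapse = "")
}

.encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- .SEQ_BITS[chars]
  codes[is.na(codes)] <- 16L   # any unexpected letter behaves like N
  unname(codes)
}

# forward-strand hit positions (1-based) of an IUPAC pattern
.scan_forward <- function(codes, pattern) {
  k <- nchar(pattern)
  n <- length(codes)
  if (n < k) return(integer(0))
  masks <- unname(.IUPAC_BITS[strsplit(toupper(pattern), "",
                                       fixed = TRUE)[[1]]])
  ok <- bitwAnd(codes[seq_len(n - k + 1L)], masks[1L]) > 0L
  if (k > 1L) for (j in 2:k) {
    idx <- which(ok)
    if (!length(idx)) break
    ok[idx] <- bitwAnd(codes[idx + j - 1L], masks[j]) > 0L
  }
  which(ok)
}

#' Count IUPAC motif hits in a sequence
#'
#' Every (position, strand) window matching the pattern counts; overlapping
#' hits all count, and a palindromic site counts once per strand unless
#' `dedup = TRUE` collapses the two strands to unique positions.  'N' in
#' the sequence satisfies only the pattern letter 'N'.
#'
#' @param seq Nucleotide string.
#' @param pattern IUPAC pattern (validated with [check_iupac()]).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param dedup Count unique positions irrespective of strand (default
#'   FALSE).
#' @return Integer hit count.
#' @export
scan_motif <- function(seq, pattern, both_strands = TRUE, dedup = FALSE) {
  check_iupac(pattern, min_len = 1)
  codes <- .encode_seq(seq)
  fwd <- .scan_forward(codes, pattern)
  if (!both_strands) return(length(fwd))
  rev <- .scan_forward(codes, revcomp_iupac(pattern))
  if (dedup) length(union(fwd, rev)) else length(fwd) + length(rev)
}

#' Number of scan windows in a set of sequences
#'
#' Windows extending past an element end are not scanned and not counted.
#'
#' @param lengths Integer vector of sequence lengths.
#' @param k Motif length.
#' @param both_strands Double the count for two-strand scans (default TRUE).
#' @return Total window count.
#' @export
scan_windows <- function(lengths, k, both_strands = TRUE) {
  w <- sum(pmax(lengths - k + 1, 0))
  if (both_strands) 2 * w else w
}

#' Motif enrichment from hit counts
#'
#' Under a binomial-per-window null with background rate
#' `p = obs_bg / bp_bg`:
#' `expected = p * bp_cns`, `z = (obs_cns - expected) /
#' sqrt(bp_cns * p * (1 - p))`, and the chi-squared statistic comes from the
#' 2x2 hit/non-hit by CNS/background table with 1 df, no continuity
#' correction.  A motif is flagged enriched when z > 2 (strict).
#'
#' @param obs_cns,bp_cns Hits and scanned windows in the CNS set.
#' @param obs_bg,bp_bg Hits and scanned windows in the background.
#' @return List: p_bg, expected, fold, z, chi2, chi2_p, enriched.  With
#'   `bp_cns = 0` all statistics are NA; with a zero background rate and
#'   positive observed hits, z and fold are Inf.
#' @export
motif_enrichment <- function(obs_cns, bp_cns, obs_bg, bp_bg) {
  if (bp_bg <= 0) stop("background has no scanned windows")
  p <- obs_bg / bp_bg
  if (bp_cns == 0)
    return(list(p_bg = p, expected = NA_real_, fold = NA_real_, z = NA_real_,
                chi2 = NA_real_, chi2_p = NA_real_, enriched = NA))
  expected <- p * bp_cns
  if (p == 0) {
    z <- if (obs_cns > 0) Inf else 0
    fold <- if (obs_cns > 0) Inf else NA_real_
    return(list(p_bg = p, expected = 0, fold = fold, z = z, chi2 = NA_real_,
                chi2_p = NA_real_, enriched = obs_cns > 0))
  }
  z <- (obs_cns - expected) / sqrt(bp_cns * p * (1 - p))
  a <- as.numeric(obs_cns); b <- as.numeric(bp_cns) - a
  c_ <- as.numeric(obs_bg); d <- as.numeric(bp_bg) - c_
  N <- a + b + c_ + d
  chi2 <- N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  list(p_bg = p, expected = expected, fold = obs_cns / expected, z = z,
       chi2 = chi2, chi2_p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       enriched = z > 2)
}

#' Extract CNS sequences from the reference
#'
#' @param cns A `cns_set` data.frame.
#' @param seqs A `Biostrings::DNAStringSet` keyed by chromosome.
#' @return Character vector of CNS sequences.
#' @export
cns_sequences <- function(cns, seqs) {
  vapply(seq_len(nrow(cns)), function(i)
    as.character(Biostrings::subseq(seqs[[cns$chrom[i]]],
                                    cns$start[i] + 1, cns$end[i])), "")
}

#' Motif enrichment table over CNS categories
#'
#' Scans every motif over each CNS category's sequences and over a
#' background sequence set (by default the genome with CNS bases excised,
#' keeping the 2x2 tables disjoint), and reports one row per (motif,
#' category).
#'
#' @param cns_seqs_by_category Named list: category -> character vector of
#'   CNS sequences.
#' @param bg_seqs Character vector of background sequences.
#' @param motifs data.frame with name/pattern columns ([read_motifs()]).
#' @param both_strands Scan both strands (default TRUE).
#' @return data.frame: motif, category, obs, windows, obs_bg, windows_bg,
#'   expected, fold, z, chi2, chi2_p, enriched.
#' @export
enrichment_table <- function(cns_seqs_by_category, bg_seqs, motifs,
                             both_strands = TRUE) {
  rows <- list()
  for (mi in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[mi]
    k <- nchar(pat)
    obs_bg <- sum(vapply(bg_seqs, scan_motif, 0L, pattern = pat,
                         both_strands = both_strands, USE.NAMES = FALSE))
    wb <- scan_windows(nchar(bg_seqs), k, both_strands)
    for (cat in names(cns_seqs_by_category)) {
      seqs <- cns_seqs_by_category[[cat]]
      obs <- sum(vapply(seqs, scan_motif, 0L, pattern = pat,
                        both_strands = both_strands, USE.NAMES = FALSE))
      wc <- scan_windows(nchar(seqs), k, both_strands)
      e <- motif_enrichment(obs, wc, obs_bg, wb)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = motifs$name[mi], category = cat, obs = obs, windows = wc,
        obs_bg = obs_bg, windows_bg = wb, expected = e$expected,
        fold = e$fold, z = e$z, chi2 = e$chi2, chi2_p = e$chi2_p,
        enriched = e$enriched, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(0), category = character(0),
                      obs = integer(0), windows = numeric(0),
                      obs_bg = integer(0), windows_bg = numeric(0),
                      expected = numeric(0), fold = numeric(0),
                      z = numeric(0), chi2 = numeric(0), chi2_p = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Background sequences: the genome with CNS bases excised
#'
#' @param cns A `cns_set` data.frame.
#' @param seqs A `Biostrings::DNAStringSet` keyed by chromosome.
#' @return Character vector of inter-CNS segments.
#' @export
background_sequences <- function(cns, seqs) {
  out <- character(0)
  for (chrom in names(seqs)) {
    L <- length(seqs[[chrom]])
    iv <- cns[cns$chrom == chrom, ]
    iv <- iv[order(iv$start), ]
    cur <- 0
    for (i in seq_len(nrow(iv))) {
      if (iv$start[i] > cur)
        out <- c(out, as.character(Biostrings::subseq(seqs[[chrom]],
                                                      cur + 1, iv$start[i])))
      cur <- max(cur, iv$end[i])
    }
    if (cur < L)
      out <- c(out, as.character(Biostrings::subseq(seqs[[chrom]], cur + 1,
                                                    L)))
  }
  out
}
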