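# Independent brute-force oracles and small fixture builders.  These are
# written against the definitions, not the package internals, and stay
# loop-and-lookup simple on purpose.

# per-column counting oracle: literal reading of the score definition
oracle_column <- function(ref_base, bases, clade) {
  matched <- 0L; aligned <- 0L
  for (sp in clade) {
    b <- bases[[sp]]
    if (is.null(b) || is.na(b) || b == "-") next
    aligned <- aligned + 1L
    if (toupper(b) %in% c("A", "C", "G", "T") &&
        toupper(b) == toupper(ref_base))
      matched <- matched + 1L
  }
  c(matched = matched, aligned = aligned)
}

# naive left-to-right CNS caller over numeric scores; returns a matrix of
# 1-based inclusive (start, end) rows
oracle_call_cns <- function(score, is_cds, threshold = 0.7, merge_gap = 3,
                            min_len = 6) {
  n <- length(score)
  ok <- score >= threshold & !is_cds
  runs <- list(); i <- 1L
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  merged <- list()
  for (r in runs) {
    if (length(merged)) {
      last <- merged[[length(merged)]]
      gap <- r[1] - last[2] - 1L
      gap_cds <- gap > 0L && any(is_cds[(last[2] + 1L):(r[1] - 1L)])
      if (gap <= merge_gap && !gap_cds) {
        merged[[length(merged)]] <- c(last[1], r[2])
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  keep <- vapply(merged, function(m) m[2] - m[1] + 1L >= min_len, NA)
  out <- do.call(rbind, merged[keep])
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# regex-free sliding-window motif counter over IUPAC sets
oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))
  count_one <- function(seq_chars, pat_chars) {
    k <- length(pat_chars); n <- length(seq_chars)
    hits <- 0L
    if (n < k) return(0L)
    for (i in 1:(n - k + 1)) {
      ok <- TRUE
      for (j in 1:k)
        if (!(seq_chars[i + j - 1] %in% sets[[pat_chars[j]]])) {
          ok <- FALSE; break
        }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  sc <- strsplit(toupper(seq), "")[[1]]
  pc <- strsplit(toupper(pattern), "")[[1]]
  total <- count_one(sc, pc)
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
              N = "N")
    total <- total + count_one(sc, rev(unname(comp[pc])))
  }
  total
}

# build a score_track straight from matched counts (aligned >= matched)
make_track <- function(matched, n_species, clade = "test",
                       chrom = "chr1", aligned = NULL) {
  if (is.null(aligned)) aligned <- pmax(matched, matched)
  aligned <- pmax(aligned, matched)
  tr <- list(list(matched = as.integer(matched),
                  aligned = as.integer(pmin(aligned, n_species))))
  names(tr) <- chrom
  score_track(clade, n_species, tr)
}

# all-intergenic region index with optional CDS intervals (0-based)
make_regions <- function(L, cds = NULL, chrom = "chr1") {
  lab <- rep(5L, L)
  if (!is.null(cds))
    for (i in seq_len(nrow(cds))) lab[(cds$start[i] + 1):cds$end[i]] <- 1L
  labels <- list(lab)
  names(labels) <- chrom
  region_index(labels)
}

# two-exon toy transcript shared across alnio/cnscall tests:
# exons [0,100) and [200,300), CDS [50,250), forward strand
toy_gff_lines <- function(strand = "+") {
  c("##gff-version 3",
    sprintf("chr1\ttoy\tgene\t1\t300\t.\t%s\t.\tID=g1", strand),
    sprintf("chr1\ttoy\tmRNA\t1\t300\t.\t%s\t.\tID=t1;Parent=g1", strand),
    sprintf("chr1\ttoy\texon\t1\t100\t.\t%s\t.\tParent=t1", strand),
    sprintf("chr1\ttoy\texon\t201\t300\t.\t%s\t.\tParent=t1", strand),
    sprintf("chr1\ttoy\tCDS\t51\t100\t.\t%s\t0\tParent=t1", strand),
    sprintf("chr1\ttoy\tCDS\t201\t250\t.\t%s\t0\tParent=t1", strand))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
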