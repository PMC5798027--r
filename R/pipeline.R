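#' Read a flat key=value or JSON run configuration
#'
#' Flat files hold one `key = value` pair per line (# comments allowed);
#' values that parse as numbers become numeric.  JSON files (extension
#' .json) are read with jsonlite.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln)
    key <- trimws(kv[[1]])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Read a clade map file
#'
#' Two tab-separated columns: clade name, comma-separated species list.
#'
#' @param path Path to the clades TSV.
#' @param reference Optional reference species name (validated absent).
#' @return A [clade_map()].
#' @export
read_clades <- function(path, reference = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  clades <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2) stop("bad clade line: ", ln)
    clades[[f[[1]]]] <- strsplit(f[[2]], ",", fixed = TRUE)[[1]]
  }
  clade_map(clades, reference)
}

.default_params <- function() {
  list(threshold = 0.7, merge_gap = 3, min_len = 6, gene_cutoff = 0.9,
       maf_rare = 0.01, z_cutoff = 2, chi2_alpha = 0.01,
       bigfoot_span = 4000, bigfoot_count = 6, downstream_window = 1000)
}

#' Run the full discovery pipeline on one configuration
#'
#' Stage order is fixed: read inputs, score every clade, call CNSs,
#' summarize, compute gene scores, population-selection statistics and
#' motif enrichment, then write a manifest with MD5 checksums of every
#' output.  Required config keys: `maf`, `gff`, `vcf`, `fasta`, `clades`,
#' `motifs` (input paths), `reference` (species name) and `outdir`; all
#' thresholds default to the conventional values (threshold 0.7, merge_gap
#' 3, min_len 6, gene_cutoff 0.9, maf_rare 0.01, z_cutoff 2, chi2_alpha
#' 0.01, bigfoot_span 4000, bigfoot_count 6, downstream_window 1000) and
#' can be overridden per key.  Missing input paths abort before any
#' compute.
#'
#' @param config Named list (or path to a config file readable by
#'   [read_run_config()]).
#' @param log Function used for progress messages (default [message()]).
#' @return data.frame manifest (file, md5), invisibly; also written to
#'   `outdir/manifest.tsv`.
#' @export
run_all <- function(config, log = message) {
  if (is.character(config)) config <- read_run_config(config)
  params <- utils::modifyList(.default_params(),
                              config[names(config) %in%
                                       names(.default_params())])
  req <- c("maf", "gff", "vcf", "fasta", "clades", "motifs")
  for (k in c(req, "reference", "outdir"))
    if (is.null(config[[k]])) stop("config key missing: ", k)
  missing <- req[!vapply(req, function(k) file.exists(config[[k]]), NA)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(unlist(config[missing]), collapse = ", "))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }

  stage <- "read-inputs"
  res <- tryCatch({
    log(sprintf("[%s] params: %s", stage,
                paste(names(params), unlist(params), sep = "=",
                      collapse = " ")))
    ref <- read_reference(config$fasta, config$reference)
    cmap <- read_clades(config$clades, config$reference)
    blocks <- read_maf(config$maf, config$reference, cmap)
    models <- read_gff3(config$gff, ref$genome)
    snps <- read_vcf(config$vcf)
    motifs <- read_motifs(config$motifs)
    log(sprintf("[%s] %d blocks, %d genes, %d SNPs, %d motifs",
                stage, length(blocks), nrow(models$genes), nrow(snps),
                nrow(motifs)))
    regions <- build_region_index(models, ref$genome)
    summaries <- list()
    tracks <- list()
    cns_by_clade <- list()
    for (clade in names(cmap$clades)) {
      stage <- paste0("score:", clade)
      tr <- score_genome(blocks, clade, cmap, ref$genome)
      tracks[[clade]] <- tr
      write_bedgraph(tr, emit(file.path(outdir,
                                        sprintf("score_%s.bedgraph",
                                                clade))))
      stage <- paste0("call:", clade)
      cns <- call_cns(tr, regions, params$threshold, params$merge_gap,
                      params$min_len)
      cns_by_clade[[clade]] <- cns
      write_bed(cns, emit(file.path(outdir, sprintf("cns_%s.bed", clade))))
      s <- summarize_cns(cns, clade)
      summaries[[clade]] <- data.frame(
        clade = clade, total_number = s$total_number,
        mean_length = s$mean_length, median_length = s$median_length,
        total_length = s$total_length,
        pct_intergenic = s$pct_category[["intergenic"]],
        pct_utr5 = s$pct_category[["UTR5"]],
        pct_utr3 = s$pct_category[["UTR3"]],
        pct_intron = s$pct_category[["intron"]],
        stringsAsFactors = FALSE)
      log(sprintf("[%s] %d CNSs, %s bp", stage, s$total_number,
                  format(s$total_length, big.mark = ",")))
    }
    utils::write.table(do.call(rbind, summaries),
                       emit(file.path(outdir, "cns_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    focal <- if (!is.null(config[["clade"]])) config[["clade"]] else
      names(cmap$clades)[[1]]
    track <- tracks[[focal]]
    cns <- cns_by_clade[[focal]]

    stage <- "gene-scores"
    gs <- gene_scores(track, models)
    utils::write.table(gs[c("gene_id", "mean_score", "n_bases")],
                       emit(file.path(outdir, "gene_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(highly_conserved(gs, params$gene_cutoff),
               emit(file.path(outdir, "highly_conserved_genes.txt")))

    stage <- "popsel"
    classes <- classify_snp_sites(snps, track)
    spec <- maf_spectrum(snps, classes)
    utils::write.table(as.data.frame.matrix(unclass(spec)),
                       emit(file.path(outdir, "maf_spectrum.tsv")),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    inv <- invariant_sites(track)
    tab <- tabulate_effects(effects_at_sites(snps, inv))
    utils::write.table(tab, emit(file.path(outdir, "invariant_effects.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vc <- variation_correlation(models, snps, track)
    utils::write.table(vc$per_gene,
                       emit(file.path(outdir, "gene_variation.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log(sprintf("[%s] %d invariant sites, Pearson r = %s", stage, nrow(inv),
                format(vc$r, digits = 3)))

    stage <- "motifs"
    by_cat <- split(cns_sequences(cns, ref$seq), cns$category)
    bg <- background_sequences(cns, ref$seq)
    et <- enrichment_table(by_cat, bg, motifs)
    utils::write.table(et, emit(file.path(outdir, "motif_enrichment.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "manifest"
    manifest <- data.frame(file = basename(outputs),
                           md5 = unname(tools::md5sum(outputs)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest
  }, error = function(e) {
    partial <- data.frame(file = basename(outputs),
                          md5 = unname(tools::md5sum(outputs)),
                          stringsAsFactors = FALSE)
    utils::write.table(partial, file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
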