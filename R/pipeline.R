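#' Run configuration for the full comparison pipeline
#'
#' Collects every tunable threshold with its default. Thresholds follow the
#' field's conventional values: syntenic blocks >= 3 kb at >= 99.9%
#' identity, repeats > 80 bp at > 90% identity, ORFs >= 100 aa, contig
#' linkages at depth >= 10, repeat-evidence edge window 500 bp.
#'
#' @param min_block_len,min_block_identity Syntenic-block admission.
#' @param repeat_min_len,repeat_min_identity Repeat-catalog thresholds
#'   (strict bounds).
#' @param orf_min_aa Minimum ORF length in amino acids.
#' @param min_link_depth Contig-linkage depth threshold.
#' @param edge_window Repeat-evidence distance window (bases).
#' @param min_exact_repeat Minimum exact short-repeat length for the edge
#'   scan.
#' @param mosaic_min_hit,mosaic_min_identity Mosaic-annotation thresholds.
#' @param min_report Minimum unique-region span reported.
#' @param seed Seed recorded with the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(min_block_len = 3000, min_block_identity = 0.999,
                       repeat_min_len = 80, repeat_min_identity = 0.90,
                       orf_min_aa = 100, min_link_depth = 10,
                       edge_window = 500, min_exact_repeat = 10,
                       mosaic_min_hit = 30, mosaic_min_identity = 0.80,
                       min_report = 100, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' One-command structural comparison of two circular genomes
#'
#' Runs the full pipeline: local matching, block chaining, arrangements,
#' repeat catalogs, sub-circle prediction, breakpoints and event inference,
#' unique regions (genome B) with mosaic annotation and integration
#' signatures, ORF comparison and SNP calling. Deterministic given the
#' inputs and config. When `out_dir` is given, every table is written as
#' TSV/BED/GFF3 plus a `summary.txt` and the resolved config.
#'
#' @param gA,gB The two [circular_genome()]s (A is the reference
#'   orientation).
#' @param panel Optional list of panel genomes for mosaic annotation.
#' @param annotations Optional CDS annotation data frame on genome A (see
#'   [read_annotations()]).
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param stages Character vector of stages to run; any of `"orfs"`,
#'   `"mosaic"`, `"signatures"` can be dropped to save time.
#' @return List of class `comparison_report`.
#' @export
run_compare <- function(gA, gB, panel = NULL, annotations = NULL,
                        config = run_config(), out_dir = NULL,
                        stages = c("orfs", "mosaic", "signatures")) {
  res <- list(config = config)
  frs <- find_local_matches(gA, gB, min_len = 80, min_identity = 0.9)
  res$fragments <- frs
  blocks <- chain_fragments(frs, min_block_len = config$min_block_len,
                            min_block_identity = config$min_block_identity)
  res$blocks <- blocks
  res$arrangement_A <- block_arrangement(blocks, "A")
  res$arrangement_B <- block_arrangement(blocks, "B")
  res$catalog_A <- build_repeat_catalog(gA, min_len = config$repeat_min_len,
                                        min_identity = config$repeat_min_identity)
  res$catalog_B <- build_repeat_catalog(gB, min_len = config$repeat_min_len,
                                        min_identity = config$repeat_min_identity)
  res$subcircles <- subcircle_report(res$catalog_A, gA, res$catalog_B, gB)
  res$breakpoints <- diff_arrangements(res$arrangement_A, res$arrangement_B)
  res$unique_regions <- extract_unique_regions(gB, blocks, which = "B",
                                               min_report = config$min_report,
                                               fragments = frs)
  res$events <- infer_events(res$breakpoints, blocks,
                             catalogs = list(A = res$catalog_A,
                                             B = res$catalog_B),
                             genomes = list(A = gA, B = gB),
                             edge_window = config$edge_window,
                             min_exact_repeat = config$min_exact_repeat,
                             regions = res$unique_regions)
  if ("mosaic" %in% stages && !is.null(panel) &&
      nrow(res$unique_regions) > 0) {
    res$mosaic <- lapply(seq_len(nrow(res$unique_regions)), function(i)
      mosaic_coverage(res$unique_regions[i, ], gB, panel,
                      min_hit = config$mosaic_min_hit,
                      min_identity = config$mosaic_min_identity))
  }
  if ("signatures" %in% stages && nrow(res$unique_regions) > 0) {
    res$signatures <- lapply(seq_len(nrow(res$unique_regions)), function(i)
      detect_integration_signature(res$unique_regions[i, ], gB))
  }
  res$snps <- call_snps(blocks, gA, gB, annotations = annotations)
  if ("orfs" %in% stages) {
    res$orfs_A <- find_orfs(gA, min_aa = config$orf_min_aa)
    res$orfs_B <- find_orfs(gB, min_aa = config$orf_min_aa)
    res$unique_orfs <- compare_orf_sets(res$orfs_A, res$orfs_B, gA, gB,
                                        blocks)
  }
  res <- structure(res, class = "comparison_report")
  if (!is.null(out_dir)) write_report(res, gA, gB, out_dir)
  res
}

subcircle_report <- function(catA, gA, catB, gB) {
  one <- function(cat, g) {
    d <- as.data.frame(cat)
    d <- d[d$orientation == "direct" & d$size_class == "large", ,
           drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    d <- d[order(-d$length), , drop = FALSE][1, ]
    sz <- predict_subgenomic_circles(g$length, d)
    data.frame(genome = g$id, repeat_name = d$name,
               repeat_length = d$length, size1 = sz[1], size2 = sz[2])
  }
  out <- rbind(one(catA, gA), one(catB, gB))
  if (is.null(out))
    out <- data.frame(genome = character(0), repeat_name = character(0),
                      repeat_length = numeric(0), size1 = numeric(0),
                      size2 = numeric(0))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(report_summary(x), sep = "\n")
  invisible(x)
}

report_summary <- function(res) {
  c(sprintf("syntenic blocks:      %d", nrow(res$blocks)),
    sprintf("arrangement A:        %s", format_arrangement(res$arrangement_A)),
    sprintf("arrangement B:        %s", format_arrangement(res$arrangement_B)),
    sprintf("repeats (A/B):        %d / %d", nrow(res$catalog_A),
            nrow(res$catalog_B)),
    sprintf("breakpoints:          %d", nrow(res$breakpoints)),
    sprintf("events:               %d (%s)", nrow(res$events),
            if (nrow(res$events)) paste(res$events$type, collapse = ", ")
            else "-"),
    sprintf("unique regions (B):   %d (total %d bp)",
            nrow(res$unique_regions), round(sum(res$unique_regions$span))),
    sprintf("SNPs in blocks:       %d", nrow(res$snps)),
    if (!is.null(res$unique_orfs))
      sprintf("unique ORFs (A/B):    %d / %d", nrow(res$unique_orfs$unique_A),
              nrow(res$unique_orfs$unique_B)) else NULL)
}

write_report <- function(res, gA, gB, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_fragments_tsv(res$fragments, p("fragments.tsv"))
  write_blocks(res$blocks, p("blocks"))
  writeLines(c(paste0(res$arrangement_A$genome_id, "\t",
                      format_arrangement(res$arrangement_A)),
               paste0(res$arrangement_B$genome_id, "\t",
                      format_arrangement(res$arrangement_B))),
             p("arrangements.txt"))
  write_repeat_catalog(res$catalog_A, p("repeats_A"))
  write_repeat_catalog(res$catalog_B, p("repeats_B"))
  write_tsv(res$subcircles, p("subcircles.tsv"))
  write_tsv(as.data.frame(res$breakpoints), p("breakpoints.tsv"))
  write_tsv(as.data.frame(res$events), p("events.tsv"))
  write_tsv(as.data.frame(res$unique_regions), p("unique_regions_B.tsv"))
  if (!is.null(res$mosaic)) {
    cov <- do.call(rbind, lapply(res$mosaic, function(m)
      data.frame(region_id = m$region_id, covered = m$covered,
                 coverage = m$coverage)))
    write_tsv(cov, p("mosaic_coverage.tsv"))
    write_tsv(do.call(rbind, lapply(res$mosaic, function(m)
      if (nrow(m$hits)) cbind(region_id = m$region_id, m$hits) else NULL)),
      p("mosaic_hits.tsv"))
  }
  if (!is.null(res$signatures)) {
    sig <- do.call(rbind, lapply(res$signatures, function(s)
      data.frame(region_id = s$region_id,
                 outer = if (is.null(s$outer)) NA else s$outer$length,
                 inner = if (is.null(s$inner)) NA else s$inner$length,
                 complete = s$complete)))
    write_tsv(sig, p("signatures.tsv"))
  }
  write_tsv(as.data.frame(res$snps), p("snps.tsv"))
  if (!is.null(res$orfs_A)) {
    write_orfs_gff3(res$orfs_A, p("orfs_A.gff3"))
    write_orfs_gff3(res$orfs_B, p("orfs_B.gff3"))
    write_tsv(res$unique_orfs$unique_A, p("unique_orfs_A.tsv"))
    write_tsv(res$unique_orfs$unique_B, p("unique_orfs_B.tsv"))
  }
  writeLines(report_summary(res), p("summary.txt"))
  cfg <- res$config
  writeLines(c(sprintf("mitostruct %s",
                       as.character(utils::packageVersion("mitostruct"))),
               paste0(names(cfg), " = ", unlist(cfg))), p("config.txt"))
  invisible(out_dir)
}

#' Write a CDS annotation table as GFF3
#' @param ann Data frame `gene`, `start`, `end`, `strand`, `part`
#'   (1-based inclusive).
#' @param genome_id Sequence id for column 1.
#' @param path Output path.
#' @export
write_annotations_gff3 <- function(ann, genome_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann))) {
    writeLines(sprintf(
      "%s\tmitostruct\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s_%d;gene=%s",
      genome_id, ann$start[i], ann$end[i], ann$strand[i], ann$gene[i],
      ann$part[i], ann$gene[i]), con)
  }
  invisible(path)
}
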