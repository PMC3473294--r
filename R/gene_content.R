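# ORF prediction, ORF-set comparison, SNP calling with effect
# classification, and motif scanning.

GENETIC_CODE_VEC <- NULL  # populated lazily from Biostrings::GENETIC_CODE

genetic_code <- function() {
  if (is.null(GENETIC_CODE_VEC))
    utils::assignInMyNamespace("GENETIC_CODE_VEC", Biostrings::GENETIC_CODE)
  GENETIC_CODE_VEC
}

translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- unname(genetic_code()[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Predict ORFs on a circular genome
#'
#' All six frames are scanned on the doubled circle, so ORFs crossing the
#' origin are found once with a wrap-capable interval. An ORF is
#' ATG-initiated, stop-terminated (TAA/TAG/TGA, standard code), has no
#' internal stop, and encodes at least `min_aa` amino acids (stop
#' excluded). ORFs wholly nested in a longer same-frame ORF are suppressed
#' (per stop-to-stop region, the first ATG wins).
#'
#' @param g A [circular_genome()].
#' @param min_aa Minimum protein length in amino acids. Default 100.
#' @return Data frame of class `orf_set`: `orf_id`, `start` (0-based
#'   position of the leftmost base of the interval on the forward strand),
#'   `span` (bases incl. stop codon), `strand`, `aa_len`, `protein`.
#' @export
find_orfs <- function(g, min_aa = 100) {
  L <- g$length
  res <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") g$seq else revcomp(g$seq)
    dbl <- if (g$topology == "circular") paste0(seq, seq) else seq
    n <- nchar(dbl)
    chars <- strsplit(dbl, "")[[1]]
    for (f in 0:2) {
      starts <- seq.int(f + 1L, n - 2L, by = 3L)
      codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      last_stop <- 0L  # codon index of previous stop (0 = region open at left)
      first_atg <- NA_integer_
      for (ci in seq_along(codons)) {
        if (is_atg[ci] && is.na(first_atg)) first_atg <- ci
        if (is_stop[ci]) {
          if (!is.na(first_atg)) {
            a <- starts[first_atg] - 1L       # 0-based start on this strand
            e <- starts[ci] + 2L              # 0-based end (exclusive)
            len <- e - a
            aa <- (len %/% 3L) - 1L
            if (aa >= min_aa && a < L && len <= L) {
              res[[length(res) + 1L]] <- list(strand = strand, s = a,
                                              len = len)
            }
          }
          first_atg <- NA_integer_
          last_stop <- ci
        }
      }
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(orf_id = character(0), start = numeric(0),
                      span = numeric(0), strand = character(0),
                      aa_len = numeric(0), protein = character(0))
    return(structure(out, class = c("orf_set", "data.frame"),
                     genome = g$id, L = L))
  }
  df <- do.call(rbind, lapply(res, as.data.frame))
  # map minus-strand coordinates back to forward coordinates
  fwd_start <- ifelse(df$strand == "+", circ_norm(df$s, L),
                      circ_norm(L - df$s - df$len, L))
  df$start <- fwd_start
  df <- df[!duplicated(df[c("start", "len", "strand")]), , drop = FALSE]
  prot <- vapply(seq_len(nrow(df)), function(i) {
    s <- extract_interval(g, df$start[i], df$len[i], strand = df$strand[i])
    translate_codons(substr(s, 1, nchar(s) - 3))
  }, character(1))
  out <- data.frame(start = df$start, span = df$len, strand = df$strand,
                    aa_len = (df$len %/% 3) - 1, protein = prot)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  out <- cbind(orf_id = sprintf("orf%d_%d", out$aa_len,
                                seq_len(nrow(out))), out)
  rownames(out) <- NULL
  structure(out, class = c("orf_set", "data.frame"), genome = g$id, L = L)
}

#' Compare ORF complements between two genomes
#'
#' An ORF is genome-specific if no region of the partner genome matches it
#' at >= `min_identity` nucleotide identity over >= `min_cover` of its
#' length. Each unique ORF is annotated with its position relative to the
#' syntenic blocks ("in block k" / "between blocks x and y").
#'
#' @param orfsA,orfsB [find_orfs()] results for the two genomes.
#' @param gA,gB The two genomes.
#' @param blocks `syntenic_blocks` for the pairing (optional, for location
#'   annotation).
#' @param min_identity Default 0.95.
#' @param min_cover Default 0.90.
#' @return List with data frames `unique_A` and `unique_B`.
#' @export
compare_orf_sets <- function(orfsA, orfsB, gA, gB, blocks = NULL,
                             min_identity = 0.95, min_cover = 0.90) {
  list(unique_A = orf_unique(orfsA, gA, gB, blocks, "A", min_identity,
                             min_cover),
       unique_B = orf_unique(orfsB, gB, gA, blocks, "B", min_identity,
                             min_cover))
}

orf_unique <- function(orfs, g, partner, blocks, side, min_identity,
                       min_cover) {
  d <- as.data.frame(orfs)
  if (nrow(d) == 0L) return(cbind(d, location = character(0)))
  # concatenate ORF sequences with N spacers: Ns never match nor extend, so
  # one matcher run against the partner genome serves all ORFs
  seqs <- vapply(seq_len(nrow(d)), function(i)
    extract_interval(g, d$start[i], d$span[i], strand = d$strand[i]),
    character(1))
  spacer <- strrep("N", 20)
  cat_seq <- paste(seqs, collapse = spacer)
  offs <- cumsum(c(0, utils::head(nchar(seqs), -1) + 20))
  qq <- circular_genome(cat_seq, id = "orfs", topology = "linear")
  frs <- as.data.frame(suppressMessages(find_local_matches(
    qq, partner, min_len = 30, min_identity = min_identity)))
  covered <- rep(0, nrow(d))
  if (nrow(frs)) {
    for (i in seq_len(nrow(d))) {
      lo <- offs[i]; hi <- offs[i] + nchar(seqs[i])
      sel <- frs$a_start < hi & (frs$a_start + frs$a_span) > lo
      if (any(sel)) {
        ss <- pmax(frs$a_start[sel], lo); ee <- pmin(frs$a_start[sel] +
                                                       frs$a_span[sel], hi)
        covered[i] <- sum(merged_union_within(lo, hi - lo, ss, ee - ss,
                                              nchar(cat_seq) + 1)$span)
      }
    }
  }
  uniq <- d[covered / d$span < min_cover, , drop = FALSE]
  loc <- vapply(seq_len(nrow(uniq)), function(i)
    locate_relative_to_blocks(uniq$start[i], uniq$span[i], blocks, side),
    character(1))
  out <- cbind(uniq, location = loc)
  rownames(out) <- NULL
  out
}

locate_relative_to_blocks <- function(start, span, blocks, side) {
  if (is.null(blocks) || nrow(as.data.frame(blocks)) == 0L)
    return("unplaced")
  b <- as.data.frame(blocks)
  L <- if (side == "A") attr(blocks, "L1") else attr(blocks, "L2")
  bs <- if (side == "A") b$a_start else b$b_start
  bp <- if (side == "A") b$a_span else b$b_span
  mid <- circ_norm(start + span %/% 2, L)
  inside <- which(circ_norm(mid - bs, L) < bp)
  if (length(inside)) return(sprintf("in block %d", b$block_id[inside[1]]))
  arr <- block_arrangement(blocks, which = side)
  gp <- arr$gaps
  gi <- which(circ_norm(mid - gp$start, L) < gp$span)
  if (length(gi))
    sprintf("between blocks %d and %d", gp$after_block[gi[1]],
            gp$before_block[gi[1]])
  else "unplaced"
}

#' Call SNPs inside syntenic blocks
#'
#' Positionwise comparison of the two genomes inside each block (after
#' orientation normalization). Blocks whose two intervals differ in span
#' cannot be compared positionwise (indels present); they are skipped with
#' a warning and listed in `attr(, "skipped_blocks")`. Substitutions falling
#' in annotated CDS get `gene`, `cds_pos`, `codon_index` and `aa_change`
#' computed from the standard genetic code; RNA editing is not modelled.
#'
#' @param blocks `syntenic_blocks`.
#' @param gA,gB The two genomes.
#' @param annotations Optional CDS annotation table on genome A, from
#'   [read_annotations()] (columns `gene`, `start`, `end`, `strand`,
#'   `part`; 1-based inclusive).
#' @return Data frame of class `snp_records`: `block_id`, `pos_a`, `pos_b`
#'   (0-based), `ref_a`, `alt_b`, `gene`, `cds_pos`, `codon_index`,
#'   `aa_change`.
#' @export
call_snps <- function(blocks, gA, gB, annotations = NULL) {
  b <- as.data.frame(blocks)
  LA <- attr(blocks, "L1"); LB <- attr(blocks, "L2")
  rows <- list(); skipped <- integer(0)
  for (i in seq_len(nrow(b))) {
    if (b$a_span[i] != b$b_span[i]) {
      skipped <- c(skipped, b$block_id[i])
      next
    }
    sa <- extract_interval(gA, b$a_start[i], b$a_span[i])
    inv <- b$orientation[i] == "inverted"
    sb <- extract_interval(gB, b$b_start[i], b$b_span[i],
                           strand = if (inv) "-" else "+")
    ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
    diff <- which(ca != cb & ca != "N" & cb != "N")
    for (p in diff) {
      off <- p - 1L
      pos_a <- circ_norm(b$a_start[i] + off, LA)
      pos_b <- if (!inv) circ_norm(b$b_start[i] + off, LB) else
        circ_norm(b$b_start[i] + b$b_span[i] - 1L - off, LB)
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = b$block_id[i], pos_a = pos_a, pos_b = pos_b,
        ref_a = ca[p], alt_b = cb[p])
    }
  }
  if (length(skipped))
    warning("blocks skipped (span mismatch; alignment refinement needed): ",
            paste(skipped, collapse = ", "))
  snps <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = integer(0), pos_a = numeric(0), pos_b = numeric(0),
               ref_a = character(0), alt_b = character(0))
  snps$gene <- rep(NA_character_, nrow(snps))
  snps$cds_pos <- rep(NA_integer_, nrow(snps))
  snps$codon_index <- rep(NA_integer_, nrow(snps))
  snps$aa_change <- rep(NA_character_, nrow(snps))
  if (!is.null(annotations) && nrow(snps) > 0L && nrow(annotations) > 0L) {
    for (gene in unique(annotations$gene)) {
      ann <- annotations[annotations$gene == gene, , drop = FALSE]
      ann <- ann[order(ann$start), , drop = FALSE]
      strand <- ann$strand[1]
      # CDS base order: 5'->3' on the coding strand
      parts <- if (strand == "+") seq_len(nrow(ann)) else rev(seq_len(nrow(ann)))
      cds_positions <- unlist(lapply(parts, function(pi) {
        p <- ann[pi, ]
        pos <- seq.int(p$start - 1L, p$end - 1L)  # 0-based genome positions
        if (strand == "+") pos else rev(pos)
      }))
      cds_seq <- paste(vapply(cds_positions, function(pp)
        substr(gA$seq, pp + 1L, pp + 1L), character(1)), collapse = "")
      if (strand == "-") cds_seq <- chartr("ACGT", "TGCA", cds_seq)
      hit <- which(snps$pos_a %in% cds_positions)
      for (h in hit) {
        cds_pos <- match(snps$pos_a[h], cds_positions)  # 1-based
        codon_index <- ceiling(cds_pos / 3)
        cp <- (cds_pos - 1L) %% 3L + 1L
        ref_codon <- substr(cds_seq, 3 * codon_index - 2, 3 * codon_index)
        ref_base <- snps$ref_a[h]; alt_base <- snps$alt_b[h]
        if (strand == "-") {
          ref_base <- chartr("ACGT", "TGCA", ref_base)
          alt_base <- chartr("ACGT", "TGCA", alt_base)
        }
        stopifnot(substr(ref_codon, cp, cp) == ref_base)
        alt_codon <- ref_codon
        substr(alt_codon, cp, cp) <- alt_base
        aa_ref <- unname(genetic_code()[ref_codon])
        aa_alt <- unname(genetic_code()[alt_codon])
        snps$gene[h] <- gene
        snps$cds_pos[h] <- cds_pos
        snps$codon_index[h] <- codon_index
        snps$aa_change[h] <- if (identical(aa_ref, aa_alt)) "synonymous" else
          paste0(aa_one(aa_ref), codon_index, aa_one(aa_alt))
      }
    }
  }
  snps <- snps[order(snps$pos_a), , drop = FALSE]
  rownames(snps) <- NULL
  structure(snps, class = c("snp_records", "data.frame"),
            skipped_blocks = skipped)
}

aa_one <- function(aa) if (aa == "*") "*" else aa

#' Read CDS annotations from a GFF3 file
#'
#' Extracts CDS features; the gene name is taken from the `gene`, `Name`,
#' `Parent` or `ID` attribute (first available). Multi-part CDS (introns)
#' are kept as separate parts joined by gene name.
#'
#' @param path GFF3 file path.
#' @return Data frame `gene`, `start`, `end` (1-based inclusive), `strand`,
#'   `part`.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L)
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      part = integer(0)))
  md <- S4Vectors::mcols(gr)
  pick <- function(i) {
    for (f in c("gene", "Name", "Parent", "ID")) {
      if (f %in% colnames(md)) {
        v <- md[[f]][i]
        v <- if (is(v, "List") || is.list(v)) unlist(v)[1] else v
        if (!is.na(v) && length(v) && nzchar(v)) return(as.character(v))
      }
    }
    paste0("cds_", i)
  }
  gene <- vapply(seq_along(gr), pick, character(1))
  df <- data.frame(gene = gene,
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)))
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$part <- stats::ave(seq_len(nrow(df)), df$gene, FUN = seq_along)
  df
}

#' Scan a genome for a motif with mismatches
#'
#' All positions (both strands, wrap-capable on circular genomes) where the
#' motif matches with Hamming distance <= `max_mismatch`.
#'
#' @param g A [circular_genome()].
#' @param motif DNA string.
#' @param max_mismatch Maximum mismatches. Default 0.
#' @return Data frame `start` (0-based forward-strand offset of the
#'   leftmost matched base), `strand`, `mismatches`.
#' @export
scan_motif <- function(g, motif, max_mismatch = 0) {
  motif <- toupper(motif)
  if (nchar(motif) > g$length) stop("motif longer than genome")
  L <- g$length
  circ <- g$topology == "circular"
  fwd <- cpp_motif_scan(g$seq, motif, circ, as.integer(max_mismatch))
  rev <- cpp_motif_scan(g$seq, revcomp(motif), circ, as.integer(max_mismatch))
  out <- rbind(
    if (nrow(fwd)) data.frame(start = fwd$start, strand = "+",
                              mismatches = fwd$mismatches) else NULL,
    if (nrow(rev)) data.frame(start = rev$start, strand = "-",
                              mismatches = rev$mismatches) else NULL)
  if (is.null(out))
    out <- data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write ORFs as GFF3
#' @param orfs An `orf_set`.
#' @param path Output path.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  d <- as.data.frame(orfs)
  L <- attr(orfs, "L")
  gid <- attr(orfs, "genome")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(d))) {
    s <- d$start[i]; e <- s + d$span[i]
    # wrapped ORFs are written as a single feature with end > L, flagged
    writeLines(sprintf("%s\tmitostruct\tORF\t%d\t%d\t.\t%s\t0\tID=%s;aa_len=%d%s",
                       gid, s + 1, e, d$strand[i], d$orf_id[i], d$aa_len[i],
                       if (e > L) ";wraps_origin=true" else ""), con)
  }
  invisible(path)
}
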