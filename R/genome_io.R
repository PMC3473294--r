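#' Circular genome container
#'
#' An immutable container for a single circular (or linear) nucleotide
#' sequence. The sequence is uppercased on construction and any IUPAC
#' ambiguity code other than A/C/G/T is mapped to N (with a message giving
#' the count). Internally all coordinates are 0-based, end-exclusive and
#' wrap-capable; text reports use 1-based inclusive coordinates.
#'
#' @param seq Character scalar, the nucleotide sequence.
#' @param id Identifier for the genome.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `length` and `topology`.
#' @export
circular_genome <- function(seq, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    n_amb <- nchar(gsub("[ACGTN]", "", seq))
    if (grepl("[^ACGTNRYSWKMBDHVU]", seq))
      stop("illegal characters in sequence (not IUPAC nucleotide codes)")
    message(sprintf("mapped %d non-ACGT IUPAC code(s) to N", n_amb))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  structure(list(id = as.character(id), seq = seq, length = nchar(seq),
                 topology = topology),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s), GC %.1f%%\n", x$id,
              format(x$length, big.mark = ","), x$topology,
              100 * gc_content(x)))
  invisible(x)
}

#' @export
length.circular_genome <- function(x) x$length

#' Load a genome from FASTA or GenBank
#'
#' Reads a single-record FASTA or GenBank flat file. Multi-record files are
#' rejected. The record id is taken from the FASTA header (first word) or the
#' GenBank LOCUS line.
#'
#' @param path Path to the file.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return A [circular_genome()].
#' @export
load_genome <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", path)
  if (startsWith(first, ">")) {
    raw <- readLines(path, warn = FALSE)
    body <- raw[!startsWith(raw, ">")]
    if (any(grepl("[^ACGTNRYSWKMBDHVUacgtnryswkmbdhvu \t]", body)))
      stop("illegal characters in FASTA sequence (not IUPAC codes)")
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    if (length(set) > 1L)
      stop("multi-record FASTA not supported; found ", length(set), " records")
    id <- strsplit(names(set)[1], "\\s+")[[1]][1]
    circular_genome(as.character(set[[1]]), id = id, topology = topology)
  } else if (startsWith(first, "LOCUS")) {
    read_genbank(path, topology = topology)
  } else {
    stop("unrecognized format (expected FASTA or GenBank): ", path)
  }
}

# Minimal single-record GenBank flat-file reader (sequence + LOCUS id only);
# none of the pre-installed R packages parse GenBank.
read_genbank <- function(path, topology = "circular") {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines)
  if (length(locus) == 0L) stop("no LOCUS line in GenBank file: ", path)
  if (length(locus) > 1L) stop("multi-record GenBank file not supported")
  id <- strsplit(sub("^LOCUS\\s+", "", lines[locus[1]]), "\\s+")[[1]][1]
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("no ORIGIN section in GenBank file: ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1L
  body <- lines[(ori[1] + 1L):(end - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  if (nchar(seq) == 0L) stop("empty sequence in GenBank file: ", path)
  circular_genome(seq, id = id, topology = topology)
}

#' Write a genome as FASTA
#'
#' @param g A [circular_genome()].
#' @param path Output path.
#' @param width Line width, default 70.
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  x <- Biostrings::DNAStringSet(g$seq)
  names(x) <- g$id
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' GC content
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T); N bases are excluded from the
#' denominator. All-N sequences are an error.
#'
#' @param g A [circular_genome()] or a character scalar.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(g) {
  seq <- if (inherits(g, "circular_genome")) g$seq else toupper(g)
  counts <- table(strsplit(seq, "")[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0L) stop("gc_content undefined: sequence contains no A/C/G/T")
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  as.numeric(gc / acgt)
}

#' Circular interval
#'
#' 0-based, end-exclusive, wrap-capable interval `(start, span)` on a genome.
#' Covered positions are `(start + k) %% length` for `k` in `[0, span)`.
#'
#' @param genome_id Genome identifier.
#' @param start 0-based offset, `0 <= start < L`.
#' @param span Number of bases covered, `1 <= span <= L`.
#' @param strand `"+"` or `"-"`.
#' @param L Genome length (used for validation; optional).
#' @export
circ_interval <- function(genome_id, start, span, strand = "+", L = NULL) {
  start <- as.integer(start); span <- as.integer(span)
  stopifnot(span >= 1L, start >= 0L, strand %in% c("+", "-"))
  if (!is.null(L)) stopifnot(start < L, span <= L)
  structure(list(genome_id = genome_id, start = start, span = span,
                 strand = strand), class = "circ_interval")
}

# --- circular coordinate arithmetic ------------------------------------------

circ_norm <- function(p, L) ((p %% L) + L) %% L

# signed difference a - b on the circle, mapped into (-L/2, L/2]
circ_signed <- function(a, b, L) {
  d <- circ_norm(a - b, L)
  ifelse(d > L / 2, d - L, d)
}

# shortest distance between two positions on the circle
circ_dist <- function(a, b, L) {
  d <- circ_norm(a - b, L)
  pmin(d, L - d)
}

# distance from point p to interval (start, span); 0 if p lies inside
# (endpoints inclusive, since block edges abut gap edges)
circ_point_interval_dist <- function(p, start, span, L) {
  off <- circ_norm(p - start, L)
  ifelse(off <= span, 0, pmin(circ_dist(p, start, L),
                              circ_dist(p, circ_norm(start + span, L), L)))
}

#' Extract the sequence of a circular interval
#'
#' @param g A [circular_genome()].
#' @param start 0-based start.
#' @param span Length in bases (may wrap the origin on circular genomes).
#' @param strand `"+"` or `"-"` (reverse complement).
#' @return Character scalar.
#' @export
extract_interval <- function(g, start, span, strand = "+") {
  L <- g$length
  stopifnot(span >= 1L, span <= L)
  start <- circ_norm(start, L)
  s <- if (start + span <= L) {
    substr(g$seq, start + 1L, start + span)
  } else {
    if (g$topology != "circular")
      stop("interval runs off the end of a linear genome")
    paste0(substr(g$seq, start + 1L, L), substr(g$seq, 1L, start + span - L))
  }
  if (strand == "-") revcomp(s) else s
}

#' Reverse complement of a DNA string
#' @param s Character scalar over A/C/G/T/N.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Rotation-aware genome comparison
#'
#' Two circular genomes are equivalent if one is a rotation of the other
#' (optionally also allowing the reverse-complemented rotations).
#'
#' @param g1,g2 [circular_genome()] objects.
#' @param reverse Also accept reverse-complement rotations? Default FALSE.
#' @export
genomes_equivalent <- function(g1, g2, reverse = FALSE) {
  if (g1$length != g2$length) return(FALSE)
  doubled <- paste0(g2$seq, g2$seq)
  if (grepl(g1$seq, doubled, fixed = TRUE)) return(TRUE)
  reverse && grepl(revcomp(g1$seq), doubled, fixed = TRUE)
}

#' Rotate a circular genome
#'
#' Returns the genome with origin moved to `offset` (0-based).
#' @param g A [circular_genome()].
#' @param offset New origin, 0-based.
#' @export
rotate_genome <- function(g, offset) {
  stopifnot(g$topology == "circular")
  off <- circ_norm(offset, g$length)
  if (off == 0) return(g)
  circular_genome(paste0(substr(g$seq, off + 1L, g$length),
                         substr(g$seq, 1L, off)),
                  id = g$id, topology = "circular")
}

# --- plain-text writers -------------------------------------------------------

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# BED is 0-based half-open; wrapped intervals are split at the origin.
write_bed <- function(chrom, start, span, L, name, path, strand = NULL) {
  if (is.null(strand)) strand <- rep(".", length(start))
  rows <- list()
  for (i in seq_along(start)) {
    s <- circ_norm(start[i], L)
    if (s + span[i] <= L) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + span[i], name = name[i],
        score = 0L, strand = strand[i])
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = L, name = name[i],
        score = 0L, strand = strand[i])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = 0L, end = s + span[i] - L, name = name[i],
        score = 0L, strand = strand[i])
    }
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
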