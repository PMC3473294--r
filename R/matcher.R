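#' Find local near-identical matches between two genomes
#'
#' Deterministic seed-and-extend local matcher: exact k-mer seeds hashed over
#' the doubled circular sequence, ungapped X-drop extension, both strands,
#' circular origin crossed transparently. Identity is defined as
#' matches / alignment columns. In self mode the trivial self-diagonal is
#' excluded and (a,b)/(b,a) mirror duplicates are collapsed.
#'
#' @param g1 Query genome, a [circular_genome()].
#' @param g2 Subject genome; ignored in self mode (defaults to `g1`).
#' @param min_len Minimum alignment length reported (>= `k`).
#' @param min_identity Minimum identity, in (0.5, 1]. When exactly 1, the
#'   X-drop is forced to 0 so reported fragments are maximal exact runs.
#' @param mode `"cross"` (two genomes) or `"self"` (one genome vs itself).
#' @param k Seed length (exact k-mer), default 15.
#' @param xdrop X-drop threshold, default 20.
#' @param mismatch_penalty Extension score is +1 per match and
#'   `-mismatch_penalty` per mismatch; the default 3 keeps extension alive
#'   down to 75% local identity while making chance extension into
#'   unrelated flanking sequence strongly net-negative, so fragment ends
#'   sit at the real homology boundary.
#' @return A data frame of class `match_fragments` with columns `a_start`,
#'   `a_span`, `b_start`, `b_span`, `orientation`, `matches`, `aln_len`,
#'   `identity` (0-based starts, wrap-capable spans). Attributes carry the
#'   genome ids, lengths, topologies and the mode.
#' @export
find_local_matches <- function(g1, g2 = NULL, min_len = 80, min_identity = 0.9,
                               mode = c("cross", "self"), k = 15L,
                               xdrop = 20L, mismatch_penalty = 3L) {
  mode <- match.arg(mode)
  if (mode == "self") g2 <- g1
  stopifnot(inherits(g1, "circular_genome"), inherits(g2, "circular_genome"))
  if (min_len < k)
    stop("min_len (", min_len, ") must be at least the seed length k (", k, ")")
  if (!(min_identity > 0.5 && min_identity <= 1))
    stop("min_identity must be in (0.5, 1]")
  if (g1$length < 1 || g2$length < 1) stop("empty genome")
  if (min_identity == 1) xdrop <- 0L

  circ1 <- g1$topology == "circular"
  circ2 <- g2$topology == "circular"
  L1 <- g1$length; L2 <- g2$length

  fwd <- cpp_scan_matches(g1$seq, g2$seq, circ1, circ2, as.integer(k),
                          min_len, min_identity, as.integer(xdrop),
                          mode == "self", as.integer(mismatch_penalty))
  rc2 <- revcomp(g2$seq)
  rev <- cpp_scan_matches(g1$seq, rc2, circ1, circ2, as.integer(k),
                          min_len, min_identity, as.integer(xdrop), FALSE,
                          as.integer(mismatch_penalty))

  mk <- function(raw, orientation) {
    if (nrow(raw) == 0L)
      return(empty_fragments())
    b_start <- raw$b_start
    if (orientation == "inverted")
      b_start <- circ_norm(L2 - raw$b_start - raw$len, L2)
    data.frame(a_start = circ_norm(raw$a_start, L1), a_span = raw$len,
               b_start = circ_norm(b_start, L2), b_span = raw$len,
               orientation = orientation, matches = raw$matches,
               aln_len = raw$len, identity = raw$matches / raw$len)
  }
  frs <- rbind(mk(fwd, "direct"), mk(rev, "inverted"))

  if (mode == "self" && nrow(frs) > 0L) {
    # drop palindromic self-pairs (both copies the same interval) and
    # collapse (a,b)/(b,a) mirrors to the lexicographically minimal form
    same <- frs$a_start == frs$b_start & frs$a_span == frs$b_span &
      frs$orientation == "inverted"
    frs <- frs[!same, , drop = FALSE]
    swap <- frs$b_start < frs$a_start
    tmp <- frs$a_start[swap]
    frs$a_start[swap] <- frs$b_start[swap]
    frs$b_start[swap] <- tmp
    tmp <- frs$a_span[swap]
    frs$a_span[swap] <- frs$b_span[swap]
    frs$b_span[swap] <- tmp
    frs <- frs[!duplicated(frs[c("a_start", "b_start", "a_span", "b_span",
                                 "orientation")]), , drop = FALSE]
  }

  frs <- frs[order(frs$a_start, frs$b_start), , drop = FALSE]
  rownames(frs) <- NULL
  structure(frs, class = c("match_fragments", "data.frame"),
            genome_a = g1$id, genome_b = g2$id, L1 = L1, L2 = L2,
            circ1 = circ1, circ2 = circ2, mode = mode)
}

empty_fragments <- function() {
  data.frame(a_start = numeric(0), a_span = numeric(0), b_start = numeric(0),
             b_span = numeric(0), orientation = character(0),
             matches = numeric(0), aln_len = numeric(0), identity = numeric(0))
}

frag_attrs <- function(frs) {
  attributes(frs)[c("genome_a", "genome_b", "L1", "L2", "circ1", "circ2",
                    "mode")]
}

restore_frag_attrs <- function(frs, att) {
  attr(frs, "genome_a") <- att$genome_a; attr(frs, "genome_b") <- att$genome_b
  attr(frs, "L1") <- att$L1; attr(frs, "L2") <- att$L2
  attr(frs, "circ1") <- att$circ1; attr(frs, "circ2") <- att$circ2
  attr(frs, "mode") <- att$mode
  class(frs) <- c("match_fragments", "data.frame")
  frs
}

#' Merge collinear match fragments
#'
#' Collinear, same-orientation fragments whose gaps on both genomes are at
#' most `max_gap` (and whose gap sizes agree within `indel_tol`) are merged.
#' Gap columns count as mismatches in the merged identity.
#'
#' @param frs A `match_fragments` data frame (one genome pair).
#' @param max_gap Maximum gap, in bases, on either genome. Default 100.
#' @param indel_tol Maximum allowed difference between the two genomes' gap
#'   sizes (collinearity tolerance). Default 50.
#' @return A merged `match_fragments` data frame.
#' @export
merge_fragments <- function(frs, max_gap = 100, indel_tol = 50) {
  att <- frag_attrs(frs)
  if (is.null(att$L1)) stop("fragments lack genome attributes")
  frs <- as.data.frame(frs)
  if (nrow(frs) < 2L) return(restore_frag_attrs(frs, att))
  L1 <- att$L1; L2 <- att$L2

  gap_a <- function(f, g) {  # gap from end of f to start of g on genome A
    d <- g$a_start - (f$a_start + f$a_span)
    if (att$circ1) circ_signed(g$a_start, f$a_start + f$a_span, L1) else d
  }
  gap_b <- function(f, g) {
    if (f$orientation == "direct") {
      if (att$circ2) circ_signed(g$b_start, f$b_start + f$b_span, L2)
      else g$b_start - (f$b_start + f$b_span)
    } else {
      # inverted: as a advances, b retreats; g lies to the left of f on b
      if (att$circ2) circ_signed(f$b_start, g$b_start + g$b_span, L2)
      else f$b_start - (g$b_start + g$b_span)
    }
  }

  mergeable <- function(f, g) {
    if (f$orientation != g$orientation) return(FALSE)
    ga <- gap_a(f, g); gb <- gap_b(f, g)
    if (is.na(ga) || is.na(gb)) return(FALSE)
    ga <= max_gap && gb <= max_gap && ga > -min(f$a_span, g$a_span) &&
      gb > -min(f$b_span, g$b_span) && abs(ga - gb) <= indel_tol
  }

  do_merge <- function(f, g) {
    ga <- gap_a(f, g); gb <- gap_b(f, g)
    new <- f
    new$a_span <- f$a_span + ga + g$a_span
    new$b_span <- f$b_span + gb + g$b_span
    if (f$orientation == "inverted") new$b_start <- g$b_start
    new$aln_len <- max(new$a_span, new$b_span)
    new$matches <- min(f$matches + g$matches - max(0, -ga),
                       new$aln_len)
    new$identity <- new$matches / new$aln_len
    new
  }

  rows <- split(frs, seq_len(nrow(frs)))
  repeat {
    merged_any <- FALSE
    n <- length(rows)
    i <- 1L
    while (i <= length(rows)) {
      j <- i + 1L
      while (j <= length(rows)) {
        if (mergeable(rows[[i]], rows[[j]])) {
          rows[[i]] <- do_merge(rows[[i]], rows[[j]])
          rows[[j]] <- NULL
          merged_any <- TRUE
        } else if (mergeable(rows[[j]], rows[[i]])) {
          rows[[j]] <- do_merge(rows[[j]], rows[[i]])
          rows[[i]] <- NULL
          merged_any <- TRUE
          j <- i + 1L
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  restore_frag_attrs(out, att)
}

#' Write fragments as a TSV table
#'
#' Columns: `a_start`, `a_span`, `b_start`, `b_span`, `orientation`,
#' `matches`, `aln_len`, `identity` (0-based starts).
#' @param frs A `match_fragments` data frame.
#' @param path Output path.
#' @export
write_fragments_tsv <- function(frs, path) {
  write_tsv(as.data.frame(frs), path)
}
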