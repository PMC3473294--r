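#' Chain match fragments into syntenic blocks
#'
#' Collinear, same-orientation fragments are merged (via [merge_fragments()])
#' and the resulting chains are admitted as syntenic blocks when they are at
#' least `min_block_len` long on *both* genomes and at least
#' `min_block_identity` identical. Per-genome overlaps between admitted
#' blocks (repeat-boundary ambiguity) are resolved by trimming both blocks at
#' the midpoint of the overlap. Block ids are assigned 1..n in genome-A
#' coordinate order.
#'
#' @param frs Cross-mode `match_fragments` between the two genomes.
#' @param min_block_len Minimum block length on each genome. Default 3000.
#' @param min_block_identity Minimum identity (inclusive bound). Default 0.999.
#' @param max_gap Chaining gap tolerance passed to [merge_fragments()].
#' @return A data frame of class `syntenic_blocks` with columns `block_id`,
#'   `a_start`, `a_span`, `b_start`, `b_span`, `orientation`, `identity`.
#' @export
chain_fragments <- function(frs, min_block_len = 3000,
                            min_block_identity = 0.999, max_gap = 100) {
  att <- frag_attrs(frs)
  if (is.null(att$L1)) stop("fragments lack genome attributes")
  if (identical(att$mode, "self"))
    stop("chain_fragments expects cross-mode fragments")
  merged <- merge_fragments(frs, max_gap = max_gap)
  blocks <- as.data.frame(merged)
  keep <- blocks$a_span >= min_block_len & blocks$b_span >= min_block_len &
    blocks$identity >= min_block_identity
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) > 0L) {
    blocks <- trim_overlaps(blocks, att)
    keep <- blocks$a_span >= min_block_len & blocks$b_span >= min_block_len
    blocks <- blocks[keep, , drop = FALSE]
  }
  blocks <- blocks[order(blocks$a_start), , drop = FALSE]
  out <- data.frame(block_id = seq_len(nrow(blocks)),
                    a_start = blocks$a_start, a_span = blocks$a_span,
                    b_start = blocks$b_start, b_span = blocks$b_span,
                    orientation = as.character(blocks$orientation),
                    identity = blocks$identity)
  rownames(out) <- NULL
  structure(out, class = c("syntenic_blocks", "data.frame"),
            genome_a = att$genome_a, genome_b = att$genome_b,
            L1 = att$L1, L2 = att$L2)
}

# Midpoint-trim overlapping blocks, first on genome A coordinates, then on
# genome B; iterate until stable. Trimming one side of the A interval trims
# the corresponding side of the paired B interval (strand-aware).
trim_overlaps <- function(blocks, att) {
  trim_left <- function(row, t) {  # drop t bases from a-left edge
    row$a_start <- circ_norm(row$a_start + t, att$L1)
    row$a_span <- row$a_span - t
    if (row$orientation == "direct") {
      row$b_start <- circ_norm(row$b_start + t, att$L2)
    }
    row$b_span <- row$b_span - t
    row
  }
  trim_right <- function(row, t) {  # drop t bases from a-right edge
    row$a_span <- row$a_span - t
    if (row$orientation == "inverted") {
      row$b_start <- circ_norm(row$b_start + t, att$L2)
    }
    row$b_span <- row$b_span - t
    row
  }
  # analogous trims driven by the B interval
  trim_b_left <- function(row, t) {
    row$b_start <- circ_norm(row$b_start + t, att$L2)
    row$b_span <- row$b_span - t
    if (row$orientation == "direct") row$a_start <- circ_norm(row$a_start + t, att$L1)
    row$a_span <- row$a_span - t
    row
  }
  trim_b_right <- function(row, t) {
    row$b_span <- row$b_span - t
    if (row$orientation == "inverted") row$a_start <- circ_norm(row$a_start + t, att$L1)
    row$a_span <- row$a_span - t
    row
  }

  one_pass <- function(rows, start_col, span_col, L, tl, tr) {
    if (length(rows) < 2L) return(list(rows = rows, changed = FALSE))
    ord <- order(vapply(rows, function(r) r[[start_col]], numeric(1)))
    rows <- rows[ord]
    changed <- FALSE
    n <- length(rows)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (i == j) next
      f <- rows[[i]]; g <- rows[[j]]
      ov <- -circ_signed(g[[start_col]], f[[start_col]] + f[[span_col]], L)
      if (is.na(ov) || ov <= 0) next
      ov <- min(ov, f[[span_col]] - 1, g[[span_col]] - 1)
      if (ov <= 0) next
      t1 <- ceiling(ov / 2); t2 <- ov - t1
      if (t1 > 0) rows[[i]] <- tr(f, t1)
      if (t2 > 0) rows[[j]] <- tl(rows[[j]], t2)
      changed <- TRUE
    }
    list(rows = rows, changed = changed)
  }

  rows <- split(blocks, seq_len(nrow(blocks)))
  for (iter in 1:10) {
    pa <- one_pass(rows, "a_start", "a_span", att$L1, trim_left, trim_right)
    rows <- pa$rows
    pb <- one_pass(rows, "b_start", "b_span", att$L2, trim_b_left, trim_b_right)
    rows <- pb$rows
    if (!pa$changed && !pb$changed) break
  }
  do.call(rbind, rows)
}

#' Signed circular block arrangement of one genome
#'
#' Expresses a genome as the circular order of signed block ids around the
#' circle (+k = direct, -k = inverted, relative to genome A's reference
#' orientation), together with the inter-block gap intervals.
#'
#' @param blocks A `syntenic_blocks` data frame.
#' @param which `"A"` or `"B"`: which genome's arrangement to compute.
#' @return An object of class `block_arrangement`: list with `genome_id`,
#'   `order` (signed integer vector), `gaps` (data frame `start`, `span`,
#'   `after_block`, `before_block`), `L`.
#' @export
block_arrangement <- function(blocks, which = c("A", "B")) {
  which <- match.arg(which)
  L <- if (which == "A") attr(blocks, "L1") else attr(blocks, "L2")
  gid <- if (which == "A") attr(blocks, "genome_a") else attr(blocks, "genome_b")
  b <- as.data.frame(blocks)
  if (nrow(b) == 0L)
    return(structure(list(genome_id = gid, order = integer(0),
                          gaps = data.frame(start = numeric(0), span = numeric(0),
                                            after_block = integer(0),
                                            before_block = integer(0)),
                          L = L), class = "block_arrangement"))
  start <- if (which == "A") b$a_start else b$b_start
  span <- if (which == "A") b$a_span else b$b_span
  ord <- order(start)
  sign <- ifelse(b$orientation == "direct", 1L, -1L)
  signed <- if (which == "A") b$block_id else sign * b$block_id
  # overlap check (precondition)
  st <- start[ord]; sp <- span[ord]; n <- length(ord)
  if (n > 1L) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ov <- -circ_signed(st[j], st[i] + sp[i], L)
      if (ov > 0) stop("blocks overlap on genome ", which,
                       "; resolve overlaps before computing an arrangement")
    }
  }
  gaps <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    gstart <- circ_norm(st[i] + sp[i], L)
    gspan <- if (n == 1L) L - sp[1] else circ_norm(st[j] - gstart, L)
    if (gspan > 0)
      gaps[[length(gaps) + 1L]] <- data.frame(
        start = gstart, span = gspan,
        after_block = abs(signed[ord][i]), before_block = abs(signed[ord][j]))
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(start = numeric(0), span = numeric(0),
               after_block = integer(0), before_block = integer(0))
  structure(list(genome_id = gid, order = as.integer(signed[ord]),
                 gaps = gaps, L = L),
            class = "block_arrangement")
}

#' @export
print.block_arrangement <- function(x, ...) {
  cat(sprintf("<block_arrangement> %s: %s\n", x$genome_id,
              paste(sprintf("%+d", x$order), collapse = " ")))
  invisible(x)
}

#' Format an arrangement as a signed-integer string
#' @param arr A `block_arrangement`.
#' @export
format_arrangement <- function(arr) {
  paste(sprintf("%+d", arr$order), collapse = " ")
}

#' Export fragments or blocks as a dot-plot segment table
#'
#' One row per segment with endpoints on both genomes and an orientation
#' (positive slope = direct). Suitable for plotting with any external viewer.
#'
#' @param x A `match_fragments` or `syntenic_blocks` data frame.
#' @return A data frame `a_start`, `a_end`, `b_start`, `b_end`, `orientation`.
#' @export
export_dotplot <- function(x) {
  d <- as.data.frame(x)
  if (nrow(d) == 0L)
    return(data.frame(a_start = numeric(0), a_end = numeric(0),
                      b_start = numeric(0), b_end = numeric(0),
                      orientation = character(0)))
  data.frame(a_start = d$a_start, a_end = d$a_start + d$a_span,
             b_start = ifelse(d$orientation == "direct", d$b_start,
                              d$b_start + d$b_span),
             b_end = ifelse(d$orientation == "direct", d$b_start + d$b_span,
                            d$b_start),
             orientation = as.character(d$orientation))
}

#' Write syntenic blocks as per-genome BED files and a joint TSV
#' @param blocks A `syntenic_blocks` data frame.
#' @param prefix Output path prefix; writes `<prefix>_A.bed`,
#'   `<prefix>_B.bed`, `<prefix>.tsv`.
#' @export
write_blocks <- function(blocks, prefix) {
  b <- as.data.frame(blocks)
  write_tsv(b, paste0(prefix, ".tsv"))
  if (nrow(b)) {
    write_bed(attr(blocks, "genome_a"), b$a_start, b$a_span,
              attr(blocks, "L1"), paste0("block_", b$block_id),
              paste0(prefix, "_A.bed"), strand = rep("+", nrow(b)))
    write_bed(attr(blocks, "genome_b"), b$b_start, b$b_span,
              attr(blocks, "L2"), paste0("block_", b$block_id),
              paste0(prefix, "_B.bed"),
              strand = ifelse(b$orientation == "direct", "+", "-"))
  }
  invisible(prefix)
}
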