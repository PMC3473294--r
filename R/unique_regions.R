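#' Extract the regions of a genome unique with respect to its partner
#'
#' The unique regions of a genome are the complement of its syntenic-block
#' intervals on the circle, filtered to spans >= `min_report`, labelled with
#' roman numerals in coordinate order and annotated with their flanking
#' blocks. "Unique" means outside every admitted block; sub-threshold
#' similarity to the partner genome is reported as `minor_match_fraction`
#' (coverage by raw match fragments) rather than by shrinking the region.
#'
#' @param g The [circular_genome()] the regions live on.
#' @param blocks `syntenic_blocks` from the pairing of `g` with its partner.
#' @param which `"A"` or `"B"`: which side of the block table `g` is.
#' @param min_report Minimum region span reported. Default 100.
#' @param fragments Optional raw `match_fragments` (same pairing) used to
#'   compute `minor_match_fraction`; 0 when absent.
#' @return Data frame of class `unique_regions`: `region_id` (roman),
#'   `start`, `span`, `flank_left`, `flank_right`, `minor_match_fraction`.
#' @export
extract_unique_regions <- function(g, blocks, which = c("B", "A"),
                                   min_report = 100, fragments = NULL) {
  which <- match.arg(which)
  arr <- block_arrangement(blocks, which = which)
  gaps <- arr$gaps
  empty <- structure(
    data.frame(region_id = character(0), start = numeric(0),
               span = numeric(0), flank_left = integer(0),
               flank_right = integer(0), minor_match_fraction = numeric(0)),
    class = c("unique_regions", "data.frame"), genome = g$id, L = g$length,
    which = which)
  if (nrow(as.data.frame(blocks)) == 0L) {
    # no blocks at all: the whole circle is one unique region
    gaps <- data.frame(start = 0, span = g$length,
                       after_block = NA_integer_, before_block = NA_integer_)
  }
  if (nrow(gaps) == 0L) return(empty)
  gaps <- gaps[gaps$span >= min_report, , drop = FALSE]
  if (nrow(gaps) == 0L) return(empty)
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  frac <- rep(0, nrow(gaps))
  if (!is.null(fragments) && nrow(as.data.frame(fragments)) > 0L) {
    fr <- as.data.frame(fragments)
    fs <- if (which == "A") fr$a_start else fr$b_start
    fp <- if (which == "A") fr$a_span else fr$b_span
    for (i in seq_len(nrow(gaps)))
      frac[i] <- interval_coverage(gaps$start[i], gaps$span[i], fs, fp,
                                   g$length)
  }
  out <- data.frame(region_id = as.character(utils::as.roman(seq_len(nrow(gaps)))),
                    start = gaps$start, span = gaps$span,
                    flank_left = gaps$after_block,
                    flank_right = gaps$before_block,
                    minor_match_fraction = frac)
  rownames(out) <- NULL
  structure(out, class = c("unique_regions", "data.frame"),
            genome = g$id, L = g$length, which = which)
}

# fraction of circular interval (start, span) covered by the union of
# intervals (starts, spans)
interval_coverage <- function(start, span, starts, spans, L) {
  if (length(starts) == 0L) return(0)
  covered <- merged_union_within(start, span, starts, spans, L)
  sum(covered$span) / span
}

# clip intervals to the region, shift to region-relative coordinates,
# merge overlaps; returns data frame (start, span) region-relative
merged_union_within <- function(start, span, starts, spans, L) {
  rel <- list()
  for (i in seq_along(starts)) {
    # interval may wrap; walk it as up to 2 linear pieces in region space
    off <- circ_norm(starts[i] - start, L)
    s <- off; e <- off + spans[i]
    pieces <- list(c(s, e))
    if (e > L) pieces <- list(c(s, L), c(0, e - L))
    for (p in pieces) {
      ps <- max(0, p[1]); pe <- min(span, p[2])
      if (pe > ps) rel[[length(rel) + 1L]] <- c(ps, pe)
    }
  }
  if (length(rel) == 0L)
    return(data.frame(start = numeric(0), span = numeric(0)))
  m <- do.call(rbind, rel)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- out[[length(out)]]
    if (m[i, 1] <= last[2]) {
      out[[length(out)]][2] <- max(last[2], m[i, 2])
    } else out[[length(out) + 1L]] <- m[i, ]
  }
  o <- do.call(rbind, out)
  data.frame(start = o[, 1], span = o[, 2] - o[, 1])
}

#' Mosaic annotation of a unique region against a panel of mitogenomes
#'
#' Runs the local matcher between the region sequence and each panel genome,
#' merges all hits on region coordinates (ignoring orientation and panel
#' identity, as in a black-box coverage plot) and reports the covered
#' fraction.
#'
#' @param region One row of [extract_unique_regions()] output.
#' @param g The genome the region lives on.
#' @param panel List of [circular_genome()] panel members.
#' @param min_hit Minimum hit length. Default 30.
#' @param min_identity Minimum hit identity. Default 0.80.
#' @param k Seed length for the panel search (default 12, shorter than the
#'   main matcher because mosaic fragments are short and diverged).
#' @return List of class `mosaic_annotation`: `region_id`, `hits` (data
#'   frame: panel id, region sub-interval, panel interval, orientation,
#'   identity), `covered` (bases), `coverage` (fraction).
#' @export
mosaic_coverage <- function(region, g, panel, min_hit = 30,
                            min_identity = 0.80, k = 12L) {
  stopifnot(nrow(region) == 1L)
  rg <- circular_genome(extract_interval(g, region$start, region$span),
                        id = paste0(g$id, ":", region$region_id),
                        topology = "linear")
  hits <- list()
  for (p in panel) {
    frs <- as.data.frame(find_local_matches(rg, p, min_len = min_hit,
                                            min_identity = min_identity,
                                            k = k))
    if (nrow(frs))
      hits[[length(hits) + 1L]] <- data.frame(
        panel_id = p$id, region_start = frs$a_start, region_span = frs$a_span,
        panel_start = frs$b_start, panel_span = frs$b_span,
        orientation = frs$orientation, identity = frs$identity)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(panel_id = character(0), region_start = numeric(0),
               region_span = numeric(0), panel_start = numeric(0),
               panel_span = numeric(0), orientation = character(0),
               identity = numeric(0))
  covered <- if (nrow(hits) == 0L) 0 else
    sum(merged_union_within(0, region$span, hits$region_start,
                            hits$region_span, region$span + 1)$span)
  structure(list(region_id = region$region_id, hits = hits,
                 covered = covered, coverage = covered / region$span),
            class = "mosaic_annotation")
}

#' @export
print.mosaic_annotation <- function(x, ...) {
  cat(sprintf("<mosaic_annotation> region %s: %d hit(s), %d/%d bp covered (%.1f%%)\n",
              x$region_id, nrow(x$hits), round(x$covered),
              round(x$covered / max(x$coverage, 1e-12)), 100 * x$coverage))
  invisible(x)
}

#' Detect a nested inverted-repeat integration signature around a region
#'
#' Searches the windows around the two region/block junctions for exact
#' inverted-repeat pairs (one copy near each junction). The longest such
#' pair is the outer signature; the longest pair strictly inside the outer
#' pair is the inner signature. A complete signature (both present, inner
#' strictly inside outer) is the classic footprint of recombination-mediated
#' integration of the region.
#'
#' @param region One row of [extract_unique_regions()] output.
#' @param g The genome the region lives on.
#' @param search_window Bases searched on each side of each junction.
#'   Default 1000.
#' @param min_repeat Minimum exact repeat length. Default 20.
#' @return List of class `integration_signature`: `region_id`, `outer`,
#'   `inner` (each NULL or list with `length`, `copy1_start`, `copy2_start`
#'   in genome coordinates), `complete`.
#' @export
detect_integration_signature <- function(region, g, search_window = 1000,
                                         min_repeat = 20) {
  stopifnot(nrow(region) == 1L)
  L <- g$length
  j1 <- region$start
  j2 <- circ_norm(region$start + region$span, L)
  w <- search_window
  span <- min(2 * w, L)
  s1 <- circ_norm(j1 - w, L); s2 <- circ_norm(j2 - w, L)
  w1 <- circular_genome(extract_interval(g, s1, span), id = "j1",
                        topology = "linear")
  w2 <- circular_genome(extract_interval(g, s2, span), id = "j2",
                        topology = "linear")
  k <- min(15L, as.integer(min_repeat))
  frs <- as.data.frame(find_local_matches(w1, w2, min_len = min_repeat,
                                          min_identity = 1, k = k))
  frs <- frs[frs$orientation == "inverted", , drop = FALSE]
  out <- list(region_id = region$region_id, outer = NULL, inner = NULL,
              complete = FALSE)
  if (nrow(frs)) {
    frs$g1 <- circ_norm(s1 + frs$a_start, L)  # genome coords of copy starts
    frs$g2 <- circ_norm(s2 + frs$b_start, L)
    frs <- frs[order(-frs$aln_len, frs$a_start), , drop = FALSE]
    o <- frs[1, ]
    out$outer <- list(length = o$aln_len, copy1_start = o$g1,
                      copy2_start = o$g2)
    # inner: strictly inside the outer pair, i.e. copy1 strictly right of
    # outer copy1's end (towards the region) and copy2 strictly left of
    # outer copy2's start
    inner <- frs[-1, , drop = FALSE]
    if (nrow(inner)) {
      ok <- inner$a_start >= o$a_start + o$a_span &
        inner$b_start + inner$b_span <= o$b_start
      inner <- inner[ok, , drop = FALSE]
      if (nrow(inner)) {
        i <- inner[1, ]
        out$inner <- list(length = i$aln_len, copy1_start = i$g1,
                          copy2_start = i$g2)
        out$complete <- TRUE
      }
    }
  }
  structure(out, class = "integration_signature")
}

#' @export
print.integration_signature <- function(x, ...) {
  cat(sprintf("<integration_signature> region %s: outer %s bp, inner %s bp (%s)\n",
              x$region_id,
              if (is.null(x$outer)) "-" else x$outer$length,
              if (is.null(x$inner)) "-" else x$inner$length,
              if (x$complete) "complete" else "incomplete"))
  invisible(x)
}
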