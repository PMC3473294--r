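# Breakpoint enumeration and repeat-mediated rearrangement inference.
#
# A circular signed arrangement is summarized by its set of signed
# adjacencies; an adjacency (x, y) and its reverse reading (-y, -x) are the
# same physical junction and are stored in canonical (lexicographically
# minimal) form. The adjacency set is invariant under rotation and global
# flip, so the symmetric difference of two arrangements' adjacency sets is
# empty exactly when the arrangements are equal up to rotation and flip.

canonical_adjacency <- function(x, y) {
  a <- c(x, y); b <- c(-y, -x)
  if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) b else a
}

arrangement_adjacencies <- function(order) {
  n <- length(order)
  if (n == 0L) return(matrix(integer(0), ncol = 2))
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  t(apply(idx, 1, function(ij) canonical_adjacency(order[ij[1]], order[ij[2]])))
}

# The two (block, side) endpoints of an adjacency, sides in genome-A
# reference orientation: "R" = right edge, "L" = left edge.
adjacency_endpoints <- function(x, y) {
  e1 <- c(abs(x), if (x > 0) "R" else "L")
  e2 <- c(abs(y), if (y > 0) "L" else "R")
  list(e1, e2)
}

#' Breakpoints between two block arrangements
#'
#' Symmetric difference of the circular signed-adjacency sets of two
#' arrangements over the same block universe. Empty exactly when the
#' arrangements are equal up to rotation and global flip.
#'
#' @param arrA,arrB [block_arrangement()] objects over the same blocks.
#' @return Data frame of class `breakpoints`: `x`, `y` (canonical signed
#'   adjacency) and `present_in` (`"A only"` / `"B only"`).
#' @export
diff_arrangements <- function(arrA, arrB) {
  if (!identical(sort(abs(arrA$order)), sort(abs(arrB$order))))
    stop("arrangements have different block universes")
  adjA <- arrangement_adjacencies(arrA$order)
  adjB <- arrangement_adjacencies(arrB$order)
  keyA <- apply(adjA, 1, paste, collapse = "|")
  keyB <- apply(adjB, 1, paste, collapse = "|")
  onlyA <- adjA[!(keyA %in% keyB), , drop = FALSE]
  onlyB <- adjB[!(keyB %in% keyA), , drop = FALSE]
  out <- rbind(
    if (nrow(onlyA)) data.frame(x = onlyA[, 1], y = onlyA[, 2],
                                present_in = "A only") else NULL,
    if (nrow(onlyB)) data.frame(x = onlyB[, 1], y = onlyB[, 2],
                                present_in = "B only") else NULL)
  if (is.null(out))
    out <- data.frame(x = integer(0), y = integer(0),
                      present_in = character(0))
  rownames(out) <- NULL
  structure(out, class = c("breakpoints", "data.frame"))
}

# Group breakpoints into clusters sharing a (block, side) edge: one physical
# recombination event changes two (or more) adjacencies that meet at the
# same block edges.
cluster_breakpoints <- function(bps) {
  n <- nrow(bps)
  if (n == 0L) return(integer(0))
  eps <- lapply(seq_len(n), function(i)
    vapply(adjacency_endpoints(bps$x[i], bps$y[i]), paste, character(1),
           collapse = ":"))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (length(intersect(eps[[i]], eps[[j]])) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Genomic coordinate of a block edge. side is in genome-A reference
# orientation; on genome B an inverted block swaps its edges.
edge_coord <- function(blocks, block_id, side, genome, L) {
  b <- blocks[blocks$block_id == block_id, ]
  stopifnot(nrow(b) == 1L)
  if (genome == "A") {
    if (side == "L") b$a_start else circ_norm(b$a_start + b$a_span, L)
  } else {
    flip <- b$orientation == "inverted"
    left <- xor(side == "R", !flip)
    # direct: L -> b_start, R -> b_end; inverted: L -> b_end, R -> b_start
    if ((side == "L" && !flip) || (side == "R" && flip)) b$b_start
    else circ_norm(b$b_start + b$b_span, L)
  }
}

#' Infer repeat-mediated recombination events from breakpoints
#'
#' Breakpoints are clustered by shared block edges (one physical event
#' changes several adjacencies), each cluster is typed, and evidence is
#' sought in the per-genome repeat catalogs and by an exact short-repeat
#' scan of the implicated edge windows. An inversion requires an
#' inverted-orientation pair flanking the inverted block(s); a junction
#' exchange requires a direct pair at the two edges joined. Events are
#' symmetric descriptions: the direction of change is not inferred, and the
#' genome is named only as evidence source.
#'
#' @param bps Breakpoints from [diff_arrangements()].
#' @param blocks The `syntenic_blocks` the arrangements were built from.
#' @param catalogs Named list `list(A = , B = )` of [build_repeat_catalog()]
#'   results (either may be NULL).
#' @param genomes Named list `list(A = , B = )` of the two
#'   [circular_genome()]s (used for the exact short-repeat scan; optional).
#' @param edge_window Distance (bases) within which a repeat copy counts as
#'   "at the edge". Default 500.
#' @param min_exact_repeat Minimum length for the exact short-repeat scan.
#'   Default 10.
#' @param regions Optional `unique_regions` of genome B; clusters flanking a
#'   unique region are labelled `insertion-associated`.
#' @return Data frame of class `recombination_events`: `event_id`, `type`,
#'   `blocks`, `n_breakpoints`, `evidence` (summary string), `confidence`.
#'   Full evidence tables are in `attr(, "evidence")`.
#' @export
infer_events <- function(bps, blocks, catalogs = list(A = NULL, B = NULL),
                         genomes = NULL, edge_window = 500,
                         min_exact_repeat = 10, regions = NULL) {
  empty <- structure(
    data.frame(event_id = integer(0), type = character(0),
               blocks = character(0), n_breakpoints = integer(0),
               evidence = character(0), confidence = character(0)),
    class = c("recombination_events", "data.frame"), evidence = list())
  if (nrow(bps) == 0L) return(empty)
  bl <- as.data.frame(blocks)
  LA <- attr(blocks, "L1"); LB <- attr(blocks, "L2")
  comp <- cluster_breakpoints(bps)
  events <- list(); evtables <- list()
  for (ci in unique(comp)) {
    sub <- bps[comp == ci, , drop = FALSE]
    eps <- unique(do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
      e <- adjacency_endpoints(sub$x[i], sub$y[i])
      data.frame(block = c(e[[1]][1], e[[2]][1]),
                 side = c(e[[1]][2], e[[2]][2]))
    })))
    eps$block <- as.integer(eps$block)
    inv_blocks <- intersect(
      eps$block, bl$block_id[bl$orientation == "inverted"])
    type <- if (length(inv_blocks) > 0) "inversion" else "junction-exchange"
    if (!is.null(regions) && type == "junction-exchange") {
      # only a sizeable region sitting exactly between the joined blocks
      # marks the cluster as insertion-associated; every junction borders
      # some small gap, which proves nothing
      rr <- as.data.frame(regions)
      rr <- rr[rr$span >= 2000, , drop = FALSE]
      joined <- unique(eps$block)
      if (nrow(rr) && any(rr$flank_left %in% joined &
                            rr$flank_right %in% joined))
        type <- "insertion-associated"
    }
    need_orient <- if (type == "inversion") "inverted" else "direct"

    # evidence 1: catalog repeats with copies near two different edges
    ev <- list()
    for (gname in c("A", "B")) {
      cat <- catalogs[[gname]]
      if (is.null(cat) || nrow(cat) == 0L) next
      L <- if (gname == "A") LA else LB
      ecoords <- vapply(seq_len(nrow(eps)), function(i)
        edge_coord(bl, eps$block[i], eps$side[i], gname, L), numeric(1))
      for (r in seq_len(nrow(cat))) {
        if (cat$orientation[r] != need_orient) next
        d1 <- vapply(ecoords, function(p) circ_point_interval_dist(
          p, cat$copy1_start[r], cat$copy1_span[r], L), numeric(1))
        d2 <- vapply(ecoords, function(p) circ_point_interval_dist(
          p, cat$copy2_start[r], cat$copy2_span[r], L), numeric(1))
        ok1 <- which(d1 <= edge_window); ok2 <- which(d2 <= edge_window)
        hit <- FALSE; best <- Inf; be1 <- NA; be2 <- NA
        for (i1 in ok1) for (i2 in ok2) {
          if (i1 == i2) next
          hit <- TRUE
          m <- max(d1[i1], d2[i2])
          if (m < best) { best <- m; be1 <- i1; be2 <- i2 }
        }
        if (hit) {
          ev[[length(ev) + 1L]] <- data.frame(
            source = "catalog", genome = gname, name = cat$name[r],
            orientation = cat$orientation[r], length = cat$length[r],
            dist1 = d1[be1], dist2 = d2[be2],
            edge1 = paste0(eps$block[be1], eps$side[be1]),
            edge2 = paste0(eps$block[be2], eps$side[be2]))
        }
      }
    }

    # evidence 2: exact short-repeat scan of edge-window pairs
    if (!is.null(genomes)) {
      for (gname in c("A", "B")) {
        g <- genomes[[gname]]
        if (is.null(g)) next
        L <- g$length
        ecoords <- vapply(seq_len(nrow(eps)), function(i)
          edge_coord(bl, eps$block[i], eps$side[i], gname, L), numeric(1))
        n_e <- length(ecoords)
        if (n_e < 2) next
        for (i1 in seq_len(n_e - 1)) for (i2 in (i1 + 1):n_e) {
          hits <- exact_window_matches(g, ecoords[i1], ecoords[i2],
                                       edge_window, min_exact_repeat,
                                       need_orient)
          if (nrow(hits)) {
            h <- hits[which.max(hits$aln_len), ]
            ev[[length(ev) + 1L]] <- data.frame(
              source = "exact-scan", genome = gname,
              name = sprintf("exact_%dbp", as.integer(h$aln_len)),
              orientation = need_orient, length = h$aln_len,
              dist1 = h$dist1, dist2 = h$dist2,
              edge1 = paste0(eps$block[i1], eps$side[i1]),
              edge2 = paste0(eps$block[i2], eps$side[i2]))
          }
        }
      }
    }

    ev <- if (length(ev)) do.call(rbind, ev) else
      data.frame(source = character(0), genome = character(0),
                 name = character(0), orientation = character(0),
                 length = numeric(0), dist1 = numeric(0), dist2 = numeric(0),
                 edge1 = character(0), edge2 = character(0))
    # orientation rule holds for every evidence item, mechanically
    stopifnot(all(ev$orientation == need_orient))
    confidence <- if (nrow(ev) == 0L) "unexplained" else
      if (min(pmax(ev$dist1, ev$dist2)) <= 5) "edge-exact" else "within-window"
    blk <- if (type == "inversion") inv_blocks else unique(eps$block)
    events[[length(events) + 1L]] <- data.frame(
      type = type, blocks = paste(sort(blk), collapse = ","),
      n_breakpoints = nrow(sub),
      evidence = if (nrow(ev)) paste(
        sprintf("%s[%s,%s]", ev$name, ev$genome,
                paste0(ev$edge1, "-", ev$edge2)), collapse = ";") else "",
      confidence = confidence)
    evtables[[length(evtables) + 1L]] <- ev
  }
  out <- do.call(rbind, events)
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("recombination_events", "data.frame"),
            evidence = evtables)
}

# Exact common substrings (>= min_len) between the windows around two edge
# coordinates, in the required orientation. Windows are edge +/- w.
exact_window_matches <- function(g, e1, e2, w, min_len, orientation) {
  L <- g$length
  span <- min(2 * w, L)
  s1 <- circ_norm(e1 - w, L); s2 <- circ_norm(e2 - w, L)
  w1 <- circular_genome(extract_interval(g, s1, span), id = "w1",
                        topology = "linear")
  w2 <- circular_genome(extract_interval(g, s2, span), id = "w2",
                        topology = "linear")
  k <- min(15L, as.integer(min_len))
  frs <- suppressMessages(find_local_matches(
    w1, w2, min_len = min_len, min_identity = 1, k = k))
  frs <- as.data.frame(frs)
  frs <- frs[frs$orientation == orientation, , drop = FALSE]
  if (nrow(frs) == 0L)
    return(data.frame(aln_len = numeric(0), dist1 = numeric(0),
                      dist2 = numeric(0)))
  # distance of each copy to its edge (edge sits at offset w inside window)
  data.frame(aln_len = frs$aln_len,
             dist1 = pmax(0, pmin(abs(frs$a_start - w),
                                  abs(frs$a_start + frs$a_span - w))) *
               (frs$a_start > w | frs$a_start + frs$a_span < w),
             dist2 = pmax(0, pmin(abs(frs$b_start - w),
                                  abs(frs$b_start + frs$b_span - w))) *
               (frs$b_start > w | frs$b_start + frs$b_span < w))
}
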