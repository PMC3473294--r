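# Parsimonious master-circle assembly from a contig linkage graph: the
# master circle is the minimum-total-length closed walk that visits every
# contig at least once (and at most `max_visits` times — repeated contigs
# are repeats). Linkages join contig ends ("head" = 5' start, "tail" = 3'
# end); traversing a contig forward enters at head and exits at tail.

#' Contig graph
#'
#' @param contigs Data frame with columns `id`, `seq`, `depth`.
#' @param linkages Data frame with columns `contig1`, `end1` (`"head"` or
#'   `"tail"`), `contig2`, `end2`, `depth`, `overlap` (bases, exact).
#' @return Object of class `contig_graph`.
#' @export
contig_graph <- function(contigs, linkages) {
  stopifnot(all(c("id", "seq", "depth") %in% names(contigs)),
            all(c("contig1", "end1", "contig2", "end2", "depth", "overlap")
                %in% names(linkages)))
  contigs$id <- as.character(contigs$id)
  contigs$length <- nchar(contigs$seq)
  stopifnot(!anyDuplicated(contigs$id), all(contigs$depth >= 0))
  if (nrow(linkages)) {
    stopifnot(all(linkages$contig1 %in% contigs$id),
              all(linkages$contig2 %in% contigs$id),
              all(linkages$end1 %in% c("head", "tail")),
              all(linkages$end2 %in% c("head", "tail")),
              all(linkages$depth >= 0))
    len <- stats::setNames(contigs$length, contigs$id)
    stopifnot(all(linkages$overlap <= pmin(len[linkages$contig1],
                                           len[linkages$contig2])))
  }
  structure(list(contigs = contigs, linkages = linkages),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("<contig_graph> %d contig(s) (%s bp), %d linkage(s)\n",
              nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
              nrow(x$linkages)))
  invisible(x)
}

#' Filter a contig graph before master-circle construction
#'
#' Removes (1) linkages with read depth below `min_link_depth` and (2)
#' putative plastid contigs: contigs matching the plastid panel at >=
#' `plastid_identity` over >= 50% of their length *and* whose depth is
#' below `low_depth_factor` times the median contig depth (true
#' mitochondrial plastid-derived insertions ride at mitochondrial depth and
#' are kept). Removals are reported via message and recorded in attributes.
#' Filtering is idempotent.
#'
#' @param gr A [contig_graph()].
#' @param min_link_depth Default 10.
#' @param plastid_panel Optional list of [circular_genome()]s.
#' @param plastid_identity Default 0.95.
#' @param low_depth_factor Default 0.25.
#' @return Filtered `contig_graph` with attributes `removed_linkages`,
#'   `removed_contigs`.
#' @export
filter_graph <- function(gr, min_link_depth = 10, plastid_panel = NULL,
                         plastid_identity = 0.95, low_depth_factor = 0.25) {
  links <- gr$linkages
  drop_l <- if (nrow(links)) links$depth < min_link_depth else logical(0)
  contigs <- gr$contigs
  drop_c <- rep(FALSE, nrow(contigs))
  if (!is.null(plastid_panel) && length(plastid_panel) && nrow(contigs)) {
    med <- stats::median(contigs$depth)
    for (i in seq_len(nrow(contigs))) {
      if (contigs$depth[i] >= low_depth_factor * med) next
      cg <- circular_genome(contigs$seq[i], id = contigs$id[i],
                            topology = "linear")
      cov <- 0
      for (p in plastid_panel) {
        frs <- as.data.frame(suppressMessages(find_local_matches(
          cg, p, min_len = min(100, contigs$length[i]),
          min_identity = plastid_identity)))
        if (nrow(frs))
          cov <- max(cov, sum(merged_union_within(
            0, contigs$length[i], frs$a_start, frs$a_span,
            contigs$length[i] + 1)$span))
      }
      if (cov >= 0.5 * contigs$length[i]) drop_c[i] <- TRUE
    }
  }
  removed_c <- contigs$id[drop_c]
  if (length(removed_c))
    message("removed ", length(removed_c), " low-depth plastid-like contig(s): ",
            paste(removed_c, collapse = ", "))
  if (any(drop_l))
    message("removed ", sum(drop_l), " linkage(s) below depth ", min_link_depth)
  links <- links[!drop_l, , drop = FALSE]
  links <- links[!(links$contig1 %in% removed_c) &
                   !(links$contig2 %in% removed_c), , drop = FALSE]
  out <- contig_graph(contigs[!drop_c, , drop = FALSE], links)
  attr(out, "removed_linkages") <- sum(drop_l)
  attr(out, "removed_contigs") <- removed_c
  out
}

# adjacency list keyed by "<id>:<end>"
graph_adjacency <- function(gr) {
  adj <- list()
  addedge <- function(adj, from, to_contig, to_end, overlap) {
    adj[[from]] <- rbind(adj[[from]],
                         data.frame(contig = to_contig, end = to_end,
                                    overlap = overlap))
    adj
  }
  for (i in seq_len(nrow(gr$linkages))) {
    l <- gr$linkages[i, ]
    adj <- addedge(adj, paste0(l$contig1, ":", l$end1), l$contig2, l$end2,
                   l$overlap)
    if (!(l$contig1 == l$contig2 && l$end1 == l$end2))
      adj <- addedge(adj, paste0(l$contig2, ":", l$end2), l$contig1, l$end1,
                     l$overlap)
  }
  # deterministic candidate order: by contig id, then end
  for (key in names(adj)) {
    a <- adj[[key]]
    adj[[key]] <- a[order(a$contig, a$end), , drop = FALSE]
  }
  adj
}

#' Build the parsimonious master circle
#'
#' Finds a closed walk through the contig graph visiting every contig at
#' least once and at most `max_visits` times, minimizing the total
#' assembled length (sum of contig lengths over visits minus linkage
#' overlaps along the walk). Ties are broken by fewest total visits, then
#' by lexicographic walk. Exhaustive branch-and-bound search; all
#' co-optimal walks are reported when the minimum is not unique.
#'
#' @param gr A (filtered) [contig_graph()].
#' @param max_visits Per-contig visit cap. Default 3.
#' @return Object of class `master_circle`: `walk` (data frame `contig`,
#'   `orient`), `sequence` (a [circular_genome()]), `visits` (named counts),
#'   `length`, `co_optimal` (list of alternative walks, possibly empty).
#' @export
build_master_circle <- function(gr, max_visits = 3) {
  contigs <- gr$contigs
  n <- nrow(contigs)
  if (n == 0L) stop("empty contig graph")
  len <- stats::setNames(contigs$length, contigs$id)
  adj <- graph_adjacency(gr)
  ids <- sort(contigs$id)
  start_id <- ids[1]

  # obstruction report up front: ends with no linkage, components
  end_keys <- c(paste0(contigs$id, ":head"), paste0(contigs$id, ":tail"))
  dead <- setdiff(end_keys, names(adj))
  comp <- graph_components(contigs$id, gr$linkages)
  if (length(unique(comp)) > 1L || length(dead) > 0L) {
    stop("no covering closed walk can exist: ",
         if (length(unique(comp)) > 1L)
           paste0(length(unique(comp)), " disconnected component(s) [",
                  paste(vapply(split(names(comp), comp), paste, character(1),
                               collapse = "+"), collapse = " | "), "] ")
         else "",
         if (length(dead)) paste0("dead end(s): ",
                                  paste(dead, collapse = ", ")) else "")
  }

  best <- new.env(parent = emptyenv())
  best$len <- Inf; best$visits <- Inf; best$walks <- list()
  max_ov <- if (nrow(gr$linkages)) max(gr$linkages$overlap) else 0

  visits0 <- stats::setNames(integer(n), contigs$id)
  max_steps <- max_visits * n

  consider <- function(walk_c, walk_o, total) {
    nv <- length(walk_c)
    cand <- list(contig = walk_c, orient = walk_o)
    if (total < best$len ||
        (total == best$len && nv < best$visits)) {
      best$len <- total; best$visits <- nv; best$walks <- list(cand)
    } else if (total == best$len && nv == best$visits) {
      best$walks[[length(best$walks) + 1L]] <- cand
    }
  }

  recurse <- function(cur_contig, cur_exit_end, visits, walk_c, walk_o,
                      total) {
    nv <- length(walk_c)
    unvisited <- names(visits)[visits == 0L]
    lower <- total + sum(len[unvisited]) -
      (length(unvisited) + 1L) * max_ov  # valid even with nonzero overlaps
    if (lower > best$len) return(invisible())
    key <- paste0(cur_contig, ":", cur_exit_end)
    cands <- adj[[key]]
    if (is.null(cands)) return(invisible())
    for (ci in seq_len(nrow(cands))) {
      nxt <- cands$contig[ci]; nxt_in <- cands$end[ci]
      ov <- cands$overlap[ci]
      # closing the circle: returning to the start contig's entry end
      if (nxt == start_id && nxt_in == "head" && length(unvisited) == 0L &&
          nv >= 1L) {
        consider(walk_c, walk_o, total - ov)
      }
      if (visits[nxt] >= max_visits || nv >= max_steps) next
      orient <- if (nxt_in == "head") "+" else "-"
      v2 <- visits; v2[nxt] <- v2[nxt] + 1L
      recurse(nxt, if (orient == "+") "tail" else "head", v2,
              c(walk_c, nxt), c(walk_o, orient),
              total + len[nxt] - ov)
    }
    invisible()
  }

  v0 <- visits0; v0[start_id] <- 1L
  recurse(start_id, "tail", v0, start_id, "+", len[start_id])

  if (!is.finite(best$len))
    stop("no covering closed walk exists within max_visits = ", max_visits)

  pick <- order_walks(best$walks)
  walk <- best$walks[[pick[1]]]
  co <- best$walks[pick[-1]]
  seqs <- stats::setNames(contigs$seq, contigs$id)
  sequence <- assemble_walk(walk, seqs, adj)
  visits <- table(factor(walk$contig, levels = contigs$id))
  structure(list(walk = data.frame(contig = walk$contig,
                                   orient = walk$orient),
                 sequence = circular_genome(sequence, id = "master_circle"),
                 visits = visits, length = nchar(sequence),
                 co_optimal = co),
            class = "master_circle")
}

order_walks <- function(walks) {
  keys <- vapply(walks, function(w)
    paste(paste0(w$contig, w$orient), collapse = " "), character(1))
  order(keys)
}

# concatenate oriented contig sequences along the closed walk, trimming
# exact linkage overlaps (mismatched overlap bases are an error)
assemble_walk <- function(walk, seqs, adj) {
  n <- length(walk$contig)
  pieces <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[[walk$contig[i]]]
    pieces[i] <- if (walk$orient[i] == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  out <- pieces[1]
  total_trim_first <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    from_end <- if (walk$orient[i] == "+") "tail" else "head"
    key <- paste0(walk$contig[i], ":", from_end)
    cands <- adj[[key]]
    to_end <- if (walk$orient[j] == "+") "head" else "tail"
    row <- cands[cands$contig == walk$contig[j] & cands$end == to_end, ,
                 drop = FALSE]
    if (nrow(row) == 0L) stop("walk uses a linkage not present in the graph")
    ov <- row$overlap[1]
    if (ov > 0) {
      left <- substr(out, nchar(out) - ov + 1L, nchar(out))
      right <- substr(pieces[j], 1L, ov)
      if (left != right)
        stop("mismatched overlap between ", walk$contig[i], " and ",
             walk$contig[j])
    }
    if (j != 1L) {
      out <- paste0(out, substr(pieces[j], ov + 1L, nchar(pieces[j])))
    } else if (ov > 0) {
      out <- substr(out, 1L, nchar(out) - ov)  # closing overlap
    }
  }
  out
}

graph_components <- function(ids, linkages) {
  comp <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (r in seq_len(nrow(linkages))) {
    a <- find(match(linkages$contig1[r], ids))
    b <- find(match(linkages$contig2[r], ids))
    if (a != b) comp[b] <- a
  }
  stats::setNames(vapply(seq_along(ids), find, numeric(1)), ids)
}

#' Read a contig graph from multi-FASTA + linkage TSV
#'
#' The TSV has columns `contig1`, `end1`, `contig2`, `end2`, `depth`,
#' `overlap`; contig depths are taken from a `depth=<x>` tag in the FASTA
#' header when present, else 1.
#' @param fasta_path Multi-FASTA of contigs.
#' @param linkage_path Linkage TSV.
#' @export
read_contig_graph <- function(fasta_path, linkage_path) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  hdr <- names(set)
  id <- vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1)
  depth <- vapply(hdr, function(h) {
    m <- regmatches(h, regexpr("depth=[0-9.]+", h))
    if (length(m)) as.numeric(sub("depth=", "", m)) else 1
  }, numeric(1))
  contigs <- data.frame(id = id, seq = as.character(set), depth = depth)
  linkages <- utils::read.delim(linkage_path, stringsAsFactors = FALSE)
  contig_graph(contigs, linkages)
}

#' Write a master circle as FASTA + walk TSV
#' @param mc A `master_circle`.
#' @param prefix Output prefix; writes `<prefix>.fasta` and
#'   `<prefix>_walk.tsv`.
#' @export
write_master_circle <- function(mc, prefix) {
  write_genome_fasta(mc$sequence, paste0(prefix, ".fasta"))
  write_tsv(mc$walk, paste0(prefix, "_walk.tsv"))
  invisible(prefix)
}
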