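# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

non_stop_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
}

# circular distance between two positions
cdist <- function(a, b, L) {
  d <- ((a - b) %% L + L) %% L
  pmin(d, L - d)
}

# overlap (bases) of two circular intervals
circ_overlap <- function(s1, sp1, s2, sp2, L) {
  # walk interval 1 as up to two linear pieces, same for 2
  pieces <- function(s, sp) {
    s <- ((s %% L) + L) %% L
    if (s + sp <= L) list(c(s, s + sp)) else list(c(s, L), c(0, s + sp - L))
  }
  tot <- 0
  for (p in pieces(s1, sp1)) for (q in pieces(s2, sp2))
    tot <- tot + max(0, min(p[2], q[2]) - max(p[1], q[1]))
  tot
}

# Map computed blocks onto truth blocks by maximal overlap on genome A.
# Returns index vector: for each truth row, the computed row (or NA).
match_blocks_to_truth <- function(blocks, truth, LA) {
  bl <- as.data.frame(blocks)
  vapply(seq_len(nrow(truth)), function(i) {
    ov <- vapply(seq_len(nrow(bl)), function(j)
      circ_overlap(truth$a_start[i], truth$a_span[i], bl$a_start[j],
                   bl$a_span[j], LA), numeric(1))
    if (length(ov) == 0 || max(ov) <= 0) NA_integer_ else which.max(ov)
  }, integer(1))
}

# Plant repeat pairs into a random background; spec entries are lists with
# pos1, pos2, len, orientation, mm (mismatches planted into copy 2).
plant_repeats <- function(n = 2000, spec, seed) {
  set.seed(seed)
  chars <- strsplit(rand_seq(n), "")[[1]]
  for (s in spec) {
    unit <- rand_seq(s$len)
    copy2 <- strsplit(if (s$orientation == "direct") unit else rc_chr(unit),
                      "")[[1]]
    if (s$mm > 0) {
      at <- sample(seq(5, s$len - 5), s$mm)
      for (p in at) copy2[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                               copy2[p]), 1)
    }
    chars[(s$pos1 + 1):(s$pos1 + s$len)] <- strsplit(unit, "")[[1]]
    chars[(s$pos2 + 1):(s$pos2 + s$len)] <- copy2
  }
  paste(chars, collapse = "")
}

# A small contig graph built directly from a segment layout:
# segments = list of c(name, seq); walk = character vector of segment names
# (repeats appear multiple times). Returns contig_graph + expected length.
graph_from_walk <- function(segments, walk, depth = 36, overlap = 0) {
  seqs <- stats::setNames(vapply(segments, `[[`, character(1), 2),
                          vapply(segments, `[[`, character(1), 1))
  contigs <- data.frame(id = names(seqs), seq = unname(seqs),
                        depth = depth)
  n <- length(walk)
  links <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    data.frame(contig1 = walk[i], end1 = "tail", contig2 = walk[j],
               end2 = "head", depth = depth, overlap = overlap)
  }))
  links <- links[!duplicated(links[c("contig1", "end1", "contig2", "end2")]), ]
  list(graph = contig_graph(contigs, links),
       genome = paste(seqs[walk], collapse = ""))
}
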