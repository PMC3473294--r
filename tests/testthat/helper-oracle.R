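# Independent oracles, deliberately implemented with different algorithms
# than the package: an exhaustive per-diagonal maximal-run scan (vs the C++
# seed-and-extend matcher) and a plain recursive enumeration of closed
# walks (vs the branch-and-bound master-circle search).

rc_chr <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                            collapse = "")

# Best-scoring run on every diagonal of the (linear) comparison s1 vs s2
# under the declared scoring scheme (+1 match, -penalty mismatch; the
# package default is penalty 3); reported if it passes the length/identity
# thresholds. One row per qualifying diagonal.
oracle_diagonal_runs <- function(s1, s2, min_len, min_identity,
                                 penalty = 3) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  out <- list()
  for (d in (-(n2 - 1)):(n1 - 1)) {
    i0 <- max(0, d); j0 <- i0 - d
    len <- min(n1 - i0, n2 - j0)
    if (len < min_len) next
    a <- c1[(i0 + 1):(i0 + len)]; b <- c2[(j0 + 1):(j0 + len)]
    m <- a == b & a != "N" & b != "N"
    v <- ifelse(m, 1, -penalty)
    S <- cumsum(v)
    pre <- c(0, S)                      # prefix sums S[0..len]
    gains <- S - cummin(pre[1:len])
    e <- which.max(gains)
    # ties broken toward the shorter segment (same convention as the
    # package's extension, which only grows on strict improvement)
    q <- max(which(pre[1:e] == min(pre[1:e])))  # segment = q..e (1-based)
    seglen <- e - q + 1
    matches <- sum(m[q:e])
    if (seglen >= min_len && matches / seglen >= min_identity)
      out[[length(out) + 1]] <- data.frame(
        a_start = i0 + q - 1, b_start = j0 + q - 1, len = seglen,
        matches = matches)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a_start = numeric(0), b_start = numeric(0), len = numeric(0),
               matches = numeric(0))
}

# Cross-mode oracle over both strands, fragment table in the package's
# coordinate convention (b on forward strand of s2).
oracle_matches <- function(s1, s2, min_len, min_identity) {
  n2 <- nchar(s2)
  fw <- oracle_diagonal_runs(s1, s2, min_len, min_identity)
  fw$orientation <- rep("direct", nrow(fw))
  rv <- oracle_diagonal_runs(s1, rc_chr(s2), min_len, min_identity)
  if (nrow(rv)) rv$b_start <- n2 - rv$b_start - rv$len
  rv$orientation <- rep("inverted", nrow(rv))
  rbind(fw, rv)
}

# Self-mode oracle: repeat pairs within s (linear), canonicalized like the
# package catalog (copy1_start <= copy2_start), strict thresholds.
oracle_repeats <- function(s, min_len, min_identity) {
  n <- nchar(s)
  fw <- oracle_diagonal_runs(s, s, min_len + 1, min_identity)
  fw <- fw[fw$a_start != fw$b_start, , drop = FALSE]      # self-diagonal
  fw <- fw[fw$a_start < fw$b_start, , drop = FALSE]        # mirror dedupe
  fw$orientation <- rep("direct", nrow(fw))
  rv <- oracle_diagonal_runs(s, rc_chr(s), min_len + 1, min_identity)
  if (nrow(rv)) {
    rv$b_start <- n - rv$b_start - rv$len
    rv <- rv[!(rv$a_start == rv$b_start), , drop = FALSE]  # palindromes
    sw <- rv$b_start < rv$a_start
    tmp <- rv$a_start[sw]; rv$a_start[sw] <- rv$b_start[sw]
    rv$b_start[sw] <- tmp
    rv <- rv[!duplicated(rv[c("a_start", "b_start", "len")]), , drop = FALSE]
  }
  rv$orientation <- rep("inverted", nrow(rv))
  out <- rbind(fw, rv)
  out[out$len > min_len & out$matches / out$len > min_identity, ,
      drop = FALSE]
}

# Brute-force minimum-length covering closed walk (no pruning, no
# tie-breaking): returns the minimal assembled length, or Inf.
oracle_best_walk_len <- function(contigs, linkages, max_visits = 3) {
  ids <- sort(as.character(contigs$id))
  len <- stats::setNames(nchar(contigs$seq), contigs$id)
  edges <- list()
  add <- function(edges, key, to, end, ov) {
    edges[[key]] <- rbind(edges[[key]],
                          data.frame(to = to, end = end, ov = ov))
    edges
  }
  for (r in seq_len(nrow(linkages))) {
    l <- linkages[r, ]
    edges <- add(edges, paste0(l$contig1, ":", l$end1), l$contig2, l$end2,
                 l$overlap)
    if (!(l$contig1 == l$contig2 && l$end1 == l$end2))
      edges <- add(edges, paste0(l$contig2, ":", l$end2), l$contig1, l$end1,
                   l$overlap)
  }
  start <- ids[1]
  best <- Inf
  n <- length(ids)
  recurse <- function(cur, exit_end, visits, total, steps) {
    cand <- edges[[paste0(cur, ":", exit_end)]]
    if (is.null(cand)) return()
    for (ci in seq_len(nrow(cand))) {
      to <- cand$to[ci]; end <- cand$end[ci]; ov <- cand$ov[ci]
      if (to == start && end == "head" && all(visits >= 1))
        best <<- min(best, total - ov)
      if (visits[to] < max_visits && steps < max_visits * n) {
        v2 <- visits; v2[to] <- v2[to] + 1
        recurse(to, if (end == "head") "tail" else "head", v2,
                total + len[to] - ov, steps + 1)
      }
    }
  }
  v0 <- stats::setNames(integer(n), ids); v0[start] <- 1L
  recurse(start, "tail", v0, len[start], 1)
  best
}

# Sliding-window Hamming scan (motif oracle), forward strand, circular.
oracle_motif_scan <- function(seq, motif, max_mismatch) {
  L <- nchar(seq); m <- nchar(motif)
  dbl <- strsplit(paste0(seq, seq), "")[[1]]
  mo <- strsplit(motif, "")[[1]]
  hits <- integer(0); mm <- integer(0)
  for (i in 0:(L - 1)) {
    d <- sum(dbl[(i + 1):(i + m)] != mo)
    if (d <= max_mismatch) { hits <- c(hits, i); mm <- c(mm, d) }
  }
  data.frame(start = hits, mismatches = mm)
}
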