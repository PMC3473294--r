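#' Catalogue repeated sequences within one genome
#'
#' Self-mode matcher output, canonicalized and deduplicated, filtered with
#' the strict thresholds length > `min_len` and identity > `min_identity`
#' (the conventional ">80 bp, >90% homology" definition). Nested/contained
#' pairs are collapsed to the maximal pair. Names "R1".."Rn" are assigned by
#' descending length. For each pair the longest sub-interval at 100%
#' identity is reported alongside the full extent (`perfect_core`), since
#' the biologically active core of a large repeat is often shorter than its
#' >90% extent.
#'
#' @param g A [circular_genome()].
#' @param min_len Strict lower bound on alignment length. Default 80.
#' @param min_identity Strict lower bound on identity. Default 0.90.
#' @param k,xdrop Matcher seed length and X-drop (see [find_local_matches()]).
#' @return A data frame of class `repeat_catalog`: `name`, `copy1_start`,
#'   `copy1_span`, `copy2_start`, `copy2_span`, `orientation`, `length`
#'   (alignment columns), `identity`, `size_class`, `perfect_core`.
#' @export
build_repeat_catalog <- function(g, min_len = 80, min_identity = 0.90,
                                 k = 15L, xdrop = 20L) {
  frs <- find_local_matches(g, mode = "self", min_len = max(min_len, k),
                            min_identity = max(min_identity, 0.5 + 1e-9),
                            k = k, xdrop = xdrop)
  frs <- as.data.frame(frs)
  frs <- frs[frs$aln_len > min_len & frs$identity > min_identity, ,
             drop = FALSE]
  L <- g$length
  if (nrow(frs) == 0L) {
    out <- data.frame(name = character(0), copy1_start = numeric(0),
                      copy1_span = numeric(0), copy2_start = numeric(0),
                      copy2_span = numeric(0), orientation = character(0),
                      length = numeric(0), identity = numeric(0),
                      size_class = character(0), perfect_core = numeric(0))
    return(structure(out, class = c("repeat_catalog", "data.frame"),
                     genome = g$id, L = L))
  }
  frs <- frs[order(-frs$aln_len, frs$a_start, frs$b_start), , drop = FALSE]
  core <- vapply(seq_len(nrow(frs)), function(i) {
    r <- frs[i, ]
    if (r$a_span != r$b_span) return(NA_real_)
    s1 <- extract_interval(g, r$a_start, r$a_span)
    s2 <- extract_interval(g, r$b_start, r$b_span,
                           strand = if (r$orientation == "direct") "+" else "-")
    eq <- strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]]
    longest_run(eq)
  }, numeric(1))
  out <- data.frame(name = paste0("R", seq_len(nrow(frs))),
                    copy1_start = frs$a_start, copy1_span = frs$a_span,
                    copy2_start = frs$b_start, copy2_span = frs$b_span,
                    orientation = as.character(frs$orientation),
                    length = frs$aln_len, identity = frs$identity,
                    size_class = ifelse(frs$aln_len >= 1000, "large", "short"),
                    perfect_core = core)
  out$family <- repeat_families(out, L)
  rownames(out) <- NULL
  structure(out, class = c("repeat_catalog", "data.frame"),
            genome = g$id, L = L)
}

# Pairs whose copies overlap on the genome belong to one multi-copy
# family (>2 copies are emitted as all canonical pairs; the family id ties
# them together).
repeat_families <- function(cat, L) {
  n <- nrow(cat)
  if (n == 0L) return(character(0))
  ivs <- rbind(
    data.frame(pair = seq_len(n), start = cat$copy1_start,
               span = cat$copy1_span),
    data.frame(pair = seq_len(n), start = cat$copy2_start,
               span = cat$copy2_span))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  overlaps <- function(i, j) {
    d <- circ_norm(ivs$start[j] - ivs$start[i], L)
    d < ivs$span[i] || circ_norm(ivs$start[i] - ivs$start[j], L) < ivs$span[j]
  }
  for (i in seq_len(nrow(ivs))) for (j in seq_len(nrow(ivs))) {
    if (j <= i || ivs$pair[i] == ivs$pair[j]) next
    if (overlaps(i, j)) {
      a <- find(ivs$pair[i]); b <- find(ivs$pair[j])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  paste0("F", match(roots, sort(unique(roots))))
}

longest_run <- function(x) {
  if (!any(x)) return(0)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Predict the two sub-genomic circles produced by a large direct repeat
#'
#' Recombination across a pair of direct repeats resolves the master circle
#' into two sub-genomic circles whose sizes always sum to the master length:
#' `size1` is the circular distance from copy1 start to copy2 start and
#' `size2 = L - size1`, so each sub-circle retains exactly one repeat copy.
#' An inverted pair yields an inversion, not two circles, and is an error.
#'
#' @param L Master-circle length in bases.
#' @param pair One row of a `repeat_catalog` (or a list with `copy1_start`,
#'   `copy2_start`, `orientation`).
#' @return Named numeric vector `c(size1, size2)`.
#' @export
predict_subgenomic_circles <- function(L, pair) {
  if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1L)
    pair <- as.list(pair)
  }
  if (!identical(pair$orientation, "direct"))
    stop("recombination across an inverted pair yields an inversion, ",
         "not two sub-genomic circles")
  size1 <- circ_norm(pair$copy2_start - pair$copy1_start, L)
  if (size1 == 0) stop("repeat copies coincide")
  c(size1 = size1, size2 = L - size1)
}

#' Write a repeat catalog as TSV (1-based inclusive coordinates) and BED
#' @param cat A `repeat_catalog`.
#' @param prefix Output prefix; writes `<prefix>.tsv` and `<prefix>.bed`.
#' @export
write_repeat_catalog <- function(cat, prefix) {
  d <- as.data.frame(cat)
  L <- attr(cat, "L")
  rep_1based <- data.frame(
    name = d$name,
    copy1_start = d$copy1_start + 1, copy1_end = d$copy1_start + d$copy1_span,
    copy2_start = d$copy2_start + 1, copy2_end = d$copy2_start + d$copy2_span,
    orientation = d$orientation, length = d$length,
    identity = round(d$identity, 4), size_class = d$size_class,
    perfect_core = d$perfect_core, family = d$family)
  write_tsv(rep_1based, paste0(prefix, ".tsv"))
  if (nrow(d)) {
    write_bed(attr(cat, "genome"),
              c(d$copy1_start, d$copy2_start), c(d$copy1_span, d$copy2_span),
              L, c(paste0(d$name, "_1"), paste0(d$name, "_2")),
              paste0(prefix, ".bed"),
              strand = c(rep("+", nrow(d)),
                         ifelse(d$orientation == "direct", "+", "-")))
  }
  invisible(prefix)
}
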