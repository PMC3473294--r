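# Ground-truthed simulator for pairs of circular mitochondrial genomes.
#
# The simulated world mirrors the structure observed in real crucifer
# mitogenome pairs: a near-identical syntenic backbone (a handful of
# multi-kb blocks), fully diverged inter-block spacers, repeat-mediated
# inversions/translocations whose mediating repeat pairs sit at block edges,
# mosaic unique regions stitched from a donor panel, sparse substitutions
# inside blocks, and (optionally) a nested inverted-repeat integration
# signature around one insertion. Blocks differ by substitutions only
# (indels are not simulated by default); spacers are entirely unrelated
# between the two genomes, so "unique region" truth equals the spacer
# intervals of genome B.

#' Simulation configuration
#'
#' @param ancestor_length Approximate genome length in bases.
#' @param n_blocks Number of syntenic blocks.
#' @param substitution_rate Per-base substitution probability inside blocks.
#'   Default 0.001 (~99.9% block identity).
#' @param gc GC content of generated sequence. Default 0.45.
#' @param spacer_range Range of inter-block spacer lengths. Default 400-1200.
#' @param block_min Minimum planted block length. Default 4000.
#' @param n_inversions,n_translocations Numbers of repeat-mediated events.
#' @param n_insertions Number of mosaic unique-region insertions (each
#'   replaces one genome-B spacer).
#' @param insertion_range Insert length range. Default 3000-15000.
#' @param insertion_sourced_fraction Fraction of each insert drawn from the
#'   donor panel (the rest is unsourced filler). Default 0.8.
#' @param insertion_granularity Donor fragment length range. Default 200-2000.
#' @param integration_signature Plant a nested inverted-repeat signature
#'   (outer `outer_len`, inner `inner_len`) at the edges of the first
#'   insertion? Default FALSE.
#' @param outer_len,inner_len Signature repeat lengths. Defaults 176 and 28.
#' @param event_repeat_len Length of the planted repeat pairs mediating
#'   events. Default 150 (a "short repeat"; kept < 200 so that
#'   repeat-boundary ambiguity stays within +/-100 bp of truth).
#' @param n_cds Number of planted protein-coding genes (distinct blocks).
#' @param cds_aa_range Planted gene length range in amino acids.
#' @param panel_donors,panel_relatedness Donor panel size and per-base
#'   divergence from the ancestor.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(ancestor_length = 200000, n_blocks = 8,
                       substitution_rate = 0.001, gc = 0.45,
                       spacer_range = c(400, 1200), block_min = 4000,
                       n_inversions = 0, n_translocations = 0,
                       n_insertions = 0, insertion_range = c(3000, 15000),
                       insertion_sourced_fraction = 0.8,
                       insertion_granularity = c(200, 2000),
                       integration_signature = FALSE,
                       outer_len = 176, inner_len = 28,
                       event_repeat_len = 150,
                       n_cds = 2, cds_aa_range = c(150, 350),
                       panel_donors = 5, panel_relatedness = 0.15,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_blocks >= 1, substitution_rate >= 0, substitution_rate <= 1,
            panel_relatedness >= 0, panel_relatedness <= 1,
            ancestor_length >= n_blocks * (block_min + spacer_range[2]))
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.45) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(stats::runif(n) < rate)
  if (length(pos) == 0L)
    return(list(seq = seq, pos = integer(0), ref = character(0),
                alt = character(0)))
  chars <- strsplit(seq, "")[[1]]
  ref <- chars[pos]
  bases <- c("A", "C", "G", "T")
  # vectorized draw of a different base: rotate by 1..3 in base order
  alt <- bases[(match(ref, bases) - 1L +
                  sample.int(3L, length(pos), replace = TRUE)) %% 4L + 1L]
  chars[pos] <- alt
  list(seq = paste(chars, collapse = ""), pos = pos, ref = ref, alt = alt)
}

str_insert_at <- function(s, what, at) {  # replace nchar(what) bases at `at` (1-based)
  paste0(substr(s, 1, at - 1), what, substr(s, at + nchar(what), nchar(s)))
}

#' Generate a synthetic genome pair with full ground truth
#'
#' Genome A is the ancestor (blocks interleaved with A-spacers, event
#' repeats planted at the implicated block edges); genome B carries the
#' scripted inversions/translocations, fresh spacers, substituted blocks
#' and mosaic insertions. Same seed, same output, bit for bit.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_pair`: `A`, `B` ([circular_genome()]s),
#'   `truth` (list: `blocks`, `events`, `repeats`, `unique_regions`, `snps`,
#'   `annotations`, `panel`), `config`.
#' @export
generate_genome_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_blocks

  # --- layout -----------------------------------------------------------
  spacerA_len <- sample(cfg$spacer_range[1]:cfg$spacer_range[2], n, TRUE)
  spacerB_len <- sample(cfg$spacer_range[1]:cfg$spacer_range[2], n, TRUE)
  blocks_total <- cfg$ancestor_length - sum(spacerA_len)
  w <- stats::runif(n, 0.5, 1.5)
  extra <- blocks_total - n * cfg$block_min
  stopifnot(extra >= 0)
  block_len <- cfg$block_min + floor(extra * w / sum(w))
  block_len[1] <- block_len[1] + (blocks_total - sum(block_len))

  # --- event targets ----------------------------------------------------
  # One physical event claims a block and (for a translocation) a
  # destination block; targets must be pairwise non-adjacent on the circle
  # so breakpoint clusters stay disjoint and event counts are recoverable
  # exactly. Slots are spread evenly around the circle (feasible whenever
  # slots <= floor(n/2)), then assigned to events in random order.
  n_slots <- cfg$n_inversions + 2L * cfg$n_translocations
  if (n_slots > n %/% 2L)
    stop("events geometrically infeasible: ", n_slots,
         " non-adjacent target blocks needed but only ", n %/% 2L,
         " fit on a circle of ", n, " blocks")
  inv_targets <- integer(0); trans <- list()
  if (n_slots > 0) {
    offset <- sample.int(n, 1) - 1L
    slots <- (offset + round((seq_len(n_slots) - 1L) * n / n_slots)) %% n + 1L
    slots <- sample(slots)  # random assignment of slots to events
    inv_targets <- utils::head(slots, cfg$n_inversions)
    rest <- utils::tail(slots, 2L * cfg$n_translocations)
    if (cfg$n_translocations > 0)
      trans <- lapply(seq_len(cfg$n_translocations), function(t)
        list(x = rest[2 * t - 1L], after = rest[2 * t]))
  }

  # --- sequences --------------------------------------------------------
  blockA <- vapply(block_len, random_dna, character(1), gc = cfg$gc)

  # planted genes inside blocks (interior, both strands)
  ann <- list(); genes <- list()
  if (cfg$n_cds > 0) {
    host <- sample(seq_len(n), min(cfg$n_cds, n))
    for (gi in seq_along(host)) {
      m <- host[gi]
      aa <- sample(cfg$cds_aa_range[1]:cfg$cds_aa_range[2], 1)
      glen <- 3 * aa + 3
      if (glen + 1200 > block_len[m]) next
      non_stop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
      body <- paste(sample(non_stop, aa - 1, TRUE), collapse = "")
      gene_seq <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
      loc <- sample(600:(block_len[m] - glen - 600), 1)  # 0-based block offset
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") gene_seq else revcomp(gene_seq)
      blockA[m] <- str_insert_at(blockA[m], planted, loc + 1)
      genes[[length(genes) + 1L]] <- list(name = sprintf("gene%d", gi),
                                          block = m, offset = loc,
                                          len = glen, strand = strand,
                                          seq = gene_seq)
    }
  }

  # genome-B blocks: ancestor blocks + substitutions
  blockB <- character(n); subs <- vector("list", n)
  for (m in seq_len(n)) {
    mu <- mutate_seq(blockA[m], cfg$substitution_rate)
    blockB[m] <- mu$seq
    subs[[m]] <- mu
  }

  # A spacers with event repeats planted at implicated edges.
  # spacer i follows block i; spacer (m-1 mod n) precedes block m.
  spacerA <- vapply(spacerA_len, random_dna, character(1), gc = cfg$gc)
  prev_spacer <- function(m) (m - 2) %% n + 1
  repeats <- list(); events <- list()
  er <- cfg$event_repeat_len
  for (m in inv_targets) {
    r <- random_dna(er, cfg$gc)
    ps <- prev_spacer(m)
    spacerA[ps] <- str_insert_at(spacerA[ps], r, spacerA_len[ps] - er + 1)
    spacerA[m] <- str_insert_at(spacerA[m], revcomp(r), 1)
    repeats[[length(repeats) + 1L]] <- data.frame(
      name = sprintf("inv_rep_%d", m), orientation = "inverted", length = er,
      copy1_spacer = ps, copy1_off = spacerA_len[ps] - er,
      copy2_spacer = m, copy2_off = 0)
    events[[length(events) + 1L]] <- data.frame(type = "inversion",
                                                blocks = as.character(m))
  }
  for (tr in trans) {
    r <- random_dna(er, cfg$gc)
    # copy near the right edge of destination block, copy near the left
    # edge of the moving block
    spacerA[tr$after] <- str_insert_at(spacerA[tr$after], r, 1)
    ps <- prev_spacer(tr$x)
    spacerA[ps] <- str_insert_at(spacerA[ps], r, spacerA_len[ps] - er + 1)
    repeats[[length(repeats) + 1L]] <- data.frame(
      name = sprintf("trans_rep_%d", tr$x), orientation = "direct",
      length = er, copy1_spacer = tr$after, copy1_off = 0,
      copy2_spacer = ps, copy2_off = spacerA_len[ps] - er)
    events[[length(events) + 1L]] <- data.frame(
      type = "junction-exchange",
      blocks = paste(sort(c(tr$x, tr$after)), collapse = ","))
  }

  # --- genome B order ---------------------------------------------------
  orderB <- seq_len(n)  # signed
  orderB[match(inv_targets, abs(orderB))] <-
    -orderB[match(inv_targets, abs(orderB))]
  for (tr in trans) {
    pos_x <- which(abs(orderB) == tr$x)
    sx <- orderB[pos_x]
    orderB <- orderB[-pos_x]
    pos_c <- which(abs(orderB) == tr$after)
    orderB <- append(orderB, sx, after = pos_c)
  }

  # --- donor panel + insertions ----------------------------------------
  panel <- NULL
  inserts <- list()
  if (cfg$n_insertions > 0) {
    ancestor <- paste(blockA, collapse = "")
    panel <- lapply(seq_len(cfg$panel_donors), function(d) {
      circular_genome(mutate_seq(ancestor, cfg$panel_relatedness)$seq,
                      id = sprintf("donor%d", d))
    })
    ins_spacers <- sample(seq_len(n), cfg$n_insertions)
    for (ii in seq_along(ins_spacers)) {
      len <- sample(cfg$insertion_range[1]:cfg$insertion_range[2], 1)
      sig <- cfg$integration_signature && ii == 1L
      inserts[[ii]] <- build_mosaic_insert(
        len, panel, cfg$insertion_sourced_fraction,
        cfg$insertion_granularity, cfg$gc,
        signature = sig, outer_len = cfg$outer_len,
        inner_len = cfg$inner_len)
      inserts[[ii]]$spacer <- ins_spacers[ii]
    }
  }

  spacerB <- vapply(spacerB_len, random_dna, character(1), gc = cfg$gc)
  ins_at <- vapply(inserts, function(x) x$spacer, integer(1))
  sourced_frac <- stats::setNames(rep(NA_real_, n), seq_len(n))
  has_sig <- stats::setNames(rep(FALSE, n), seq_len(n))
  for (ii in seq_along(inserts)) {
    spacerB[ins_at[ii]] <- inserts[[ii]]$seq
    sourced_frac[ins_at[ii]] <- inserts[[ii]]$sourced_fraction
    has_sig[ins_at[ii]] <- inserts[[ii]]$signature
  }

  # --- emission ---------------------------------------------------------
  a_start <- numeric(n); posA <- 0
  partsA <- character(0)
  for (m in seq_len(n)) {
    a_start[m] <- posA
    partsA <- c(partsA, blockA[m])
    posA <- posA + block_len[m]
    partsA <- c(partsA, spacerA[m])
    posA <- posA + nchar(spacerA[m])
  }
  gA <- circular_genome(paste(partsA, collapse = ""), id = "synthA")

  b_start <- numeric(n); b_orient <- character(n)
  uniq <- list()
  posB <- 0; partsB <- character(0)
  for (j in seq_len(n)) {
    s <- orderB[j]; m <- abs(s)
    b_start[m] <- posB
    b_orient[m] <- if (s > 0) "direct" else "inverted"
    partsB <- c(partsB, if (s > 0) blockB[m] else revcomp(blockB[m]))
    posB <- posB + block_len[m]
    # spacer j follows the j-th emitted block; spacer identity j
    uniq[[j]] <- data.frame(
      start = posB, span = nchar(spacerB[j]),
      after_block = m,
      before_block = abs(orderB[if (j == n) 1L else j + 1L]),
      is_insert = j %in% ins_at,
      sourced_fraction = unname(sourced_frac[as.character(j)]),
      has_signature = unname(has_sig[as.character(j)]))
    partsB <- c(partsB, spacerB[j])
    posB <- posB + nchar(spacerB[j])
  }
  gB <- circular_genome(paste(partsB, collapse = ""), id = "synthB")

  truth_blocks <- data.frame(block_id = seq_len(n), a_start = a_start,
                             a_span = block_len, b_start = b_start,
                             b_span = block_len, orientation = b_orient)

  # planted repeats in A coordinates
  spacerA_start <- a_start + block_len
  rep_df <- if (length(repeats)) do.call(rbind, repeats) else NULL
  if (!is.null(rep_df)) {
    rep_df$copy1_start <- spacerA_start[rep_df$copy1_spacer] + rep_df$copy1_off
    rep_df$copy2_start <- spacerA_start[rep_df$copy2_spacer] + rep_df$copy2_off
  }

  # SNP truth (genome coordinates + effect via planted genes)
  snp_rows <- list()
  gene_by_block <- list()
  for (g in genes) gene_by_block[[as.character(g$block)]] <-
    c(gene_by_block[[as.character(g$block)]], list(g))
  for (m in seq_len(n)) {
    mu <- subs[[m]]
    if (length(mu$pos) == 0L) next
    for (t in seq_along(mu$pos)) {
      off <- mu$pos[t] - 1L  # 0-based offset within block
      pos_a <- a_start[m] + off
      pos_b <- if (b_orient[m] == "direct") b_start[m] + off else
        b_start[m] + block_len[m] - 1L - off
      gene <- NA_character_; cds_pos <- NA_integer_
      codon_index <- NA_integer_; aa_change <- NA_character_
      for (g in gene_by_block[[as.character(m)]]) {
        if (off >= g$offset && off < g$offset + g$len) {
          gene <- g$name
          cds_pos <- if (g$strand == "+") off - g$offset + 1L else
            g$offset + g$len - off
          codon_index <- ceiling(cds_pos / 3)
          cp <- (cds_pos - 1L) %% 3L + 1L
          ref_codon <- substr(g$seq, 3 * codon_index - 2, 3 * codon_index)
          ref_b <- mu$ref[t]; alt_b <- mu$alt[t]
          if (g$strand == "-") {
            ref_b <- chartr("ACGT", "TGCA", ref_b)
            alt_b <- chartr("ACGT", "TGCA", alt_b)
          }
          alt_codon <- ref_codon
          substr(alt_codon, cp, cp) <- alt_b
          aa_r <- unname(Biostrings::GENETIC_CODE[ref_codon])
          aa_a <- unname(Biostrings::GENETIC_CODE[alt_codon])
          aa_change <- if (identical(aa_r, aa_a)) "synonymous" else
            paste0(aa_r, codon_index, aa_a)
        }
      }
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        block_id = m, pos_a = pos_a, pos_b = pos_b, ref_a = mu$ref[t],
        alt_b = mu$alt[t], gene = gene, cds_pos = cds_pos,
        codon_index = codon_index, aa_change = aa_change)
    }
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(block_id = integer(0), pos_a = numeric(0), pos_b = numeric(0),
               ref_a = character(0), alt_b = character(0),
               gene = character(0), cds_pos = integer(0),
               codon_index = integer(0), aa_change = character(0))

  annotations <- if (length(genes)) do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g$name, start = a_start[g$block] + g$offset + 1,
               end = a_start[g$block] + g$offset + g$len,
               strand = g$strand, part = 1L))) else
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               strand = character(0), part = integer(0))

  truth <- list(blocks = truth_blocks,
                events = if (length(events)) do.call(rbind, events) else
                  data.frame(type = character(0), blocks = character(0)),
                repeats = rep_df,
                unique_regions = do.call(rbind, uniq),
                snps = snps,
                annotations = annotations,
                order_b = orderB,
                panel = panel)
  structure(list(A = gA, B = gB, truth = truth, config = cfg),
            class = "sim_pair")
}

build_mosaic_insert <- function(len, panel, sourced_fraction, granularity,
                                gc, signature = FALSE, outer_len = 176,
                                inner_len = 28) {
  fixed <- if (signature) 2 * (outer_len + inner_len) + 102 else 0
  core_len <- len - fixed
  stopifnot(core_len > granularity[1])
  pieces <- character(0); sourced <- numeric(0)
  total <- 0
  while (total < core_len) {
    flen <- sample(granularity[1]:granularity[2], 1)
    flen <- min(flen, core_len - total)
    if (stats::runif(1) < sourced_fraction) {
      p <- panel[[sample(length(panel), 1)]]
      st <- sample(0:(p$length - 1), 1)
      s <- extract_interval(p, st, flen,
                            strand = sample(c("+", "-"), 1))
      pieces <- c(pieces, s); sourced <- c(sourced, flen)
    } else {
      pieces <- c(pieces, random_dna(flen, gc)); sourced <- c(sourced, 0)
    }
    total <- total + flen
  }
  core <- paste(pieces, collapse = "")
  seq <- core
  if (signature) {
    # Separators keep outer and inner from fusing into one exact run, and
    # every base abutting a planted copy is fixed to A so no copy can
    # extend by chance complementarity (A only pairs with T): the planted
    # lengths are recovered exactly.
    outer <- random_dna(outer_len, gc)
    inner <- random_dna(inner_len, gc)
    s1 <- paste0("A", random_dna(48, gc), "A")
    s2 <- paste0("A", random_dna(48, gc), "A")
    if (nchar(core) >= 2) {
      substr(core, 1, 1) <- "A"
      substr(core, nchar(core), nchar(core)) <- "A"
    }
    seq <- paste0("A", outer, s1, inner, core, revcomp(inner), s2,
                  revcomp(outer), "A")
  }
  list(seq = seq, sourced_fraction = sum(sourced) / len,
       signature = signature)
}

#' Generate a panel of related donor genomes
#'
#' Panel members are independent substitution-derived copies of a common
#' ancestor (relatedness = per-base substitution scale; 0 means identical).
#'
#' @param donors Number of panel genomes.
#' @param relatedness Per-base substitution probability from the ancestor.
#' @param seed Integer seed.
#' @param ancestor Optional ancestor sequence (character); generated when
#'   NULL.
#' @param length Ancestor length when generated. Default 150000.
#' @param gc GC content. Default 0.45.
#' @return List of [circular_genome()]s.
#' @export
generate_reference_panel <- function(donors, relatedness, seed,
                                     ancestor = NULL, length = 150000,
                                     gc = 0.45) {
  stopifnot(donors >= 1)
  set.seed(seed)
  if (is.null(ancestor)) ancestor <- random_dna(length, gc)
  lapply(seq_len(donors), function(d)
    circular_genome(mutate_seq(ancestor, relatedness)$seq,
                    id = sprintf("donor%d", d)))
}

#' Generate a contig graph from a genome, with truth walk
#'
#' Cuts the genome at the boundaries of the given direct-repeat pairs and at
#' random points (mean spacing `mean_contig`); repeated regions are emitted
#' once and appear twice in the truth walk, at ~2x depth. Linkage depths are
#' drawn around `depth`.
#'
#' @param g A [circular_genome()].
#' @param mean_contig Mean contig length. Default 4400.
#' @param depth Mean linkage/contig read depth. Default 36.
#' @param seed Integer seed.
#' @param repeat_pairs Optional data frame `copy1_start`, `copy2_start`,
#'   `span` of non-overlapping, non-wrapping direct repeat pairs (both
#'   copies carry identical sequence).
#' @return List of class `sim_contigs`: `graph` (a [contig_graph()]),
#'   `truth` (list: `walk`, `genome_length`).
#' @export
generate_contig_graph <- function(g, mean_contig = 4400, depth = 36, seed = 1,
                                  repeat_pairs = NULL) {
  set.seed(seed)
  L <- g$length
  stopifnot(mean_contig < L)
  # segment boundaries: repeat copy starts/ends, plus random cuts in between
  bounds <- c(0)
  rsegs <- list()
  if (!is.null(repeat_pairs) && nrow(repeat_pairs)) {
    for (i in seq_len(nrow(repeat_pairs))) {
      r <- repeat_pairs[i, ]
      stopifnot(r$copy1_start + r$span <= L, r$copy2_start + r$span <= L)
      bounds <- c(bounds, r$copy1_start, r$copy1_start + r$span,
                  r$copy2_start, r$copy2_start + r$span)
      rsegs[[i]] <- r
    }
  }
  bounds <- sort(unique(circ_norm(bounds, L)))
  # random cuts inside long non-repeat stretches
  segs <- cbind(bounds, c(bounds[-1], L + bounds[1]))
  cuts <- c()
  for (i in seq_len(nrow(segs))) {
    slen <- segs[i, 2] - segs[i, 1]
    ncut <- min(stats::rpois(1, max(0, slen / mean_contig - 1)), slen - 1)
    if (ncut > 0)
      cuts <- c(cuts, circ_norm(segs[i, 1] +
                                  sort(sample(seq_len(slen - 1), ncut)), L))
  }
  bounds <- sort(unique(c(bounds, cuts)))

  # walk the circle segment by segment; identical repeat segments collapse
  # onto one contig
  seg_start <- bounds
  seg_end <- c(bounds[-1], L)
  nseg <- length(seg_start)
  seq_of <- vapply(seq_len(nseg), function(i)
    extract_interval(g, seg_start[i], seg_end[i] - seg_start[i]),
    character(1))
  contig_id <- character(nseg)
  seen <- list()
  cn <- 0
  for (i in seq_len(nseg)) {
    key <- seq_of[i]
    if (!is.null(seen[[key]])) {
      contig_id[i] <- seen[[key]]
    } else {
      cn <- cn + 1
      contig_id[i] <- sprintf("c%03d", cn)
      seen[[key]] <- contig_id[i]
    }
  }
  ids <- unique(contig_id)
  visits <- table(factor(contig_id, levels = ids))
  contigs <- data.frame(
    id = ids,
    seq = vapply(ids, function(id) seq_of[match(id, contig_id)],
                 character(1)),
    depth = round(as.numeric(visits[ids]) * depth *
                    stats::runif(length(ids), 0.9, 1.1)))
  links <- list()
  for (i in seq_len(nseg)) {
    j <- if (i == nseg) 1L else i + 1L
    links[[i]] <- data.frame(
      contig1 = contig_id[i], end1 = "tail",
      contig2 = contig_id[j], end2 = "head",
      depth = max(11, round(stats::rnorm(1, depth, depth / 6))),
      overlap = 0)
  }
  links <- do.call(rbind, links)
  links <- links[!duplicated(links[c("contig1", "end1", "contig2", "end2")]), ]
  gr <- contig_graph(contigs, links)
  structure(list(graph = gr,
                 truth = list(walk = data.frame(contig = contig_id,
                                                orient = "+"),
                              genome_length = L)),
            class = "sim_contigs")
}
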