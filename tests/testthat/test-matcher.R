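test_that("identical genomes give exactly one full-length fragment", {
  g1 <- circular_genome(rand_seq(1000, seed = 1), id = "a")
  g2 <- circular_genome(g1$seq, id = "b")
  fr <- find_local_matches(g1, g2)
  d <- as.data.frame(fr)
  d <- d[d$orientation == "direct", ]
  expect_equal(nrow(d), 1L)
  expect_equal(d$a_span, 1000)
  expect_equal(d$identity, 1)
})

test_that("unrelated sequences yield no fragments", {
  g1 <- circular_genome(rand_seq(400, seed = 2), id = "a")
  g2 <- circular_genome(rand_seq(400, seed = 3), id = "b")
  fr <- find_local_matches(g1, g2, min_len = 80, min_identity = 0.9)
  expect_equal(nrow(fr), 0L)
})

test_that("a planted diverged segment is recovered at oracle endpoints", {
  # 120-bp shared segment carrying 5 substitutions, inside 300-bp strangers
  set.seed(4)
  for (rep in 1:5) {
    seg <- rand_seq(120)
    seg2 <- strsplit(seg, "")[[1]]
    pos <- sample(10:110, 5)
    for (p in pos) seg2[p] <- sample(setdiff(c("A", "C", "G", "T"), seg2[p]), 1)
    s1 <- paste0(rand_seq(90), seg, rand_seq(90))
    s2 <- paste0(rand_seq(120), paste(seg2, collapse = ""), rand_seq(60))
    g1 <- circular_genome(s1, id = "a", topology = "linear")
    g2 <- circular_genome(s2, id = "b", topology = "linear")
    fr <- as.data.frame(find_local_matches(g1, g2, min_len = 80,
                                           min_identity = 0.90))
    expect_gte(nrow(fr), 1L)
    top <- fr[which.max(fr$aln_len), ]
    expect_gte(top$identity, 115 / 120)
    orc <- oracle_matches(s1, s2, 80, 0.90)
    obest <- orc[which.max(orc$len), ]
    expect_lte(abs(top$a_start - obest$a_start), 2)
    expect_lte(abs(top$a_start + top$a_span - (obest$a_start + obest$len)), 2)
    expect_lte(abs(top$b_start - obest$b_start), 2)
  }
})

test_that("cross-mode output is symmetric in its arguments", {
  set.seed(6)
  seg <- rand_seq(200)
  g1 <- circular_genome(paste0(rand_seq(150), seg, rand_seq(150)), id = "a")
  g2 <- circular_genome(paste0(rand_seq(50), revcomp(seg), rand_seq(250)),
                        id = "b")
  f12 <- as.data.frame(find_local_matches(g1, g2))
  f21 <- as.data.frame(find_local_matches(g2, g1))
  swapped <- f21[, c("b_start", "b_span", "a_start", "a_span", "orientation",
                     "matches", "aln_len", "identity")]
  names(swapped) <- names(f12)
  # inverted fragments keep interval starts under the swap
  ord <- function(d) d[order(d$a_start, d$b_start), ]
  expect_equal(ord(f12), ord(swapped), ignore_attr = TRUE)
})

test_that("reverse-complementing genome 2 flips orientation and coordinates", {
  set.seed(7)
  seg <- rand_seq(300)
  g1 <- circular_genome(paste0(rand_seq(100), seg, rand_seq(100)), id = "a")
  g2 <- circular_genome(paste0(rand_seq(200), seg, rand_seq(100)), id = "b")
  g2r <- circular_genome(revcomp(g2$seq), id = "b_rc")
  f <- as.data.frame(find_local_matches(g1, g2))
  fr <- as.data.frame(find_local_matches(g1, g2r))
  expect_equal(nrow(f), nrow(fr))
  L2 <- g2$length
  f$orientation_flipped <- ifelse(f$orientation == "direct", "inverted",
                                  "direct")
  f$b_rc <- (L2 - f$b_start - f$b_span) %% L2
  ord <- function(d, s, o) d[order(d$a_start, d[[s]]), c("a_start", s, o)]
  expect_equal(unname(as.matrix(ord(fr, "b_start", "orientation"))),
               unname(as.matrix(ord(f, "b_rc", "orientation_flipped"))))
})

test_that("fragments cross the circular origin transparently", {
  set.seed(8)
  seg <- rand_seq(400)
  # place the shared segment across the origin of genome 1
  g1 <- circular_genome(paste0(substr(seg, 201, 400), rand_seq(600),
                               substr(seg, 1, 200)), id = "a")
  g2 <- circular_genome(paste0(rand_seq(300), seg, rand_seq(300)), id = "b")
  fr <- as.data.frame(find_local_matches(g1, g2))
  expect_equal(nrow(fr), 1L)
  expect_gte(fr$a_span[1], 395)
  expect_equal(fr$a_start[1], 800, tolerance = 3)
})

test_that("matcher vs oracle on random planted pairs (spot equivalence)", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(200:500, 1)
    seglen <- sample(60:150, 1)
    seg <- rand_seq(seglen)
    inv <- runif(1) < 0.5
    s1 <- paste0(rand_seq(n %/% 2), seg, rand_seq(n %/% 2))
    planted2 <- if (inv) rc_chr(seg) else seg
    s2 <- paste0(rand_seq(n %/% 3), planted2, rand_seq(n %/% 2))
    g1 <- circular_genome(s1, id = "a", topology = "linear")
    g2 <- circular_genome(s2, id = "b", topology = "linear")
    fr <- as.data.frame(find_local_matches(g1, g2, min_len = 50,
                                           min_identity = 0.9, k = 15))
    orc <- oracle_matches(s1, s2, 50, 0.9)
    expect_gte(nrow(fr), 1L)
    top <- fr[which.max(fr$aln_len), ]
    obest <- orc[which.max(orc$len), ]
    expect_equal(top$orientation,
                 if (inv) "inverted" else "direct")
    expect_lte(abs(top$a_start - obest$a_start), 2)
    expect_lte(abs(top$a_span - obest$len), 4)
  }
})

test_that("N bases terminate extension and never match", {
  set.seed(10)
  seg1 <- rand_seq(120); seg2 <- rand_seq(120)
  shared <- paste0(seg1, "NNNNN", seg2)
  g1 <- circular_genome(paste0(rand_seq(100), shared, rand_seq(100)),
                        id = "a", topology = "linear")
  g2 <- circular_genome(paste0(rand_seq(60), shared, rand_seq(140)),
                        id = "b", topology = "linear")
  fr <- as.data.frame(find_local_matches(g1, g2, min_len = 80))
  expect_equal(nrow(fr), 2L)  # split at the N run, not bridged
  expect_true(all(fr$a_span <= 140))
})

test_that("merge_fragments obeys the gap and orientation rules", {
  g1 <- circular_genome(rand_seq(2000, seed = 11), id = "a")
  g2 <- circular_genome(rand_seq(2000, seed = 12), id = "b")
  base <- find_local_matches(g1, g2)  # empty; reuse attributes
  mk <- function(a, b, span, orient = "direct") {
    data.frame(a_start = a, a_span = span, b_start = b, b_span = span,
               orientation = orient, matches = span, aln_len = span,
               identity = 1)
  }
  att <- attributes(base)
  as_frag <- function(df) {
    out <- df
    for (f in c("genome_a", "genome_b", "L1", "L2", "circ1", "circ2", "mode"))
      attr(out, f) <- att[[f]]
    class(out) <- c("match_fragments", "data.frame")
    out
  }
  # abutting fragments merge into one with summed spans
  m <- merge_fragments(as_frag(rbind(mk(0, 0, 100), mk(100, 100, 150))))
  expect_equal(nrow(m), 1L)
  expect_equal(m$a_span, 250)
  # 50-bp gaps on both genomes: merged at max_gap 100, not at 10
  two <- as_frag(rbind(mk(0, 0, 100), mk(150, 150, 100)))
  expect_equal(nrow(merge_fragments(two, max_gap = 100)), 1L)
  expect_equal(nrow(merge_fragments(two, max_gap = 10)), 2L)
  # gap columns count as mismatches in merged identity
  m2 <- merge_fragments(two, max_gap = 100)
  expect_equal(m2$matches, 200)
  expect_equal(m2$aln_len, 250)
  expect_equal(m2$identity, 0.8)
  # direct and inverted fragments never merge
  mix <- as_frag(rbind(mk(0, 0, 100), mk(100, 100, 100, "inverted")))
  expect_equal(nrow(merge_fragments(mix)), 2L)
})

test_that("parameter validation", {
  g <- circular_genome(rand_seq(100, seed = 13))
  expect_error(find_local_matches(g, g, min_len = 10, k = 15), "min_len")
  expect_error(find_local_matches(g, g, min_identity = 0.4), "min_identity")
})
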