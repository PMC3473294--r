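test_that("linkage-depth filtering removes exactly the sub-threshold edges", {
  gw <- graph_from_walk(list(c("a", rand_seq(500, seed = 81)),
                             c("b", rand_seq(400)), c("c", rand_seq(300)),
                             c("d", rand_seq(200)), c("e", rand_seq(100))),
                        c("a", "b", "c", "d", "e"))
  gr <- gw$graph
  expect_equal(nrow(filter_graph(gr)$linkages), 5L)  # all at depth 36
  gr$linkages$depth[3] <- 9
  f <- suppressMessages(filter_graph(gr))
  expect_equal(nrow(f$linkages), 4L)
  # idempotent
  expect_equal(suppressMessages(filter_graph(f))$linkages, f$linkages)
})

test_that("low-depth plastid-like contigs are removed, normal-depth kept", {
  plastid <- circular_genome(rand_seq(20000, seed = 82), id = "plastid")
  pl_piece <- extract_interval(plastid, 5000, 800)
  contigs <- data.frame(
    id = c("c1", "c2", "cp"),
    seq = c(rand_seq(3000), rand_seq(2500), pl_piece),
    depth = c(36, 38, 2))
  links <- data.frame(contig1 = c("c1", "c2", "cp"), end1 = "tail",
                      contig2 = c("c2", "cp", "c1"), end2 = "head",
                      depth = 30, overlap = 0)
  gr <- contig_graph(contigs, links)
  f <- suppressMessages(filter_graph(gr, plastid_panel = list(plastid)))
  expect_equal(sort(f$contigs$id), c("c1", "c2"))
  # same contig at mitochondrial depth survives (plastid-derived insertion)
  contigs$depth[3] <- 35
  f2 <- filter_graph(contig_graph(contigs, links),
                     plastid_panel = list(plastid))
  expect_equal(nrow(f2$contigs), 3L)
})

test_that("a single self-linked contig assembles to itself", {
  s <- rand_seq(1000, seed = 83)
  gr <- contig_graph(data.frame(id = "c1", seq = s, depth = 30),
                     data.frame(contig1 = "c1", end1 = "tail",
                                contig2 = "c1", end2 = "head", depth = 30,
                                overlap = 0))
  mc <- build_master_circle(gr)
  expect_equal(mc$sequence$seq, s)
  expect_equal(nrow(mc$walk), 1L)
})

test_that("a repeat contig is traversed twice, matching brute force", {
  set.seed(84)
  r <- rand_seq(800)
  gw <- graph_from_walk(list(c("s1", rand_seq(4000)), c("r", r),
                             c("s2", rand_seq(3000))),
                        c("s1", "r", "s2", "r"))
  mc <- build_master_circle(gw$graph)
  expect_equal(unname(as.vector(mc$visits[c("s1", "r", "s2")])), c(1, 2, 1))
  expect_equal(mc$length, nchar(gw$genome))
  expect_equal(mc$length,
               oracle_best_walk_len(gw$graph$contigs, gw$graph$linkages))
  expect_true(genomes_equivalent(mc$sequence,
                                 circular_genome(gw$genome, id = "t"),
                                 reverse = TRUE))
})

test_that("assembled length matches brute force on random small graphs", {
  set.seed(85)
  for (rep in 1:10) {
    n_uniq <- sample(3:6, 1)
    segs <- lapply(seq_len(n_uniq), function(i)
      c(paste0("u", i), rand_seq(sample(300:1500, 1))))
    walk <- vapply(segs, `[[`, character(1), 1)
    if (runif(1) < 0.6) {  # insert a repeated contig at two positions
      segs <- c(segs, list(c("rep", rand_seq(sample(200:600, 1)))))
      at <- sort(sample(seq_len(n_uniq), 2))
      walk <- append(walk, "rep", after = at[2])
      walk <- append(walk, "rep", after = at[1] - 1)
    }
    gw <- graph_from_walk(segs, walk)
    mc <- build_master_circle(gw$graph)
    expect_equal(mc$length,
                 oracle_best_walk_len(gw$graph$contigs, gw$graph$linkages),
                 info = paste("rep", rep))
    expect_equal(mc$length, nchar(gw$genome))
  }
})

test_that("simulated contig graphs reassemble the source genome", {
  set.seed(86)
  base <- rand_seq(26000)
  rep2k <- rand_seq(2000)
  gseq <- paste0(substr(base, 1, 10000), rep2k, substr(base, 10001, 20000),
                 rep2k, substr(base, 20001, 26000))
  g <- circular_genome(gseq, id = "toy")
  sc <- generate_contig_graph(g, mean_contig = 4000, depth = 36, seed = 87,
                              repeat_pairs = data.frame(
                                copy1_start = 10000, copy2_start = 22000,
                                span = 2000))
  mc <- build_master_circle(filter_graph(sc$graph))
  expect_equal(mc$length, g$length)
  expect_true(genomes_equivalent(mc$sequence, g, reverse = TRUE))
})

test_that("graph defects are reported, not silently assembled", {
  s <- function(n) rand_seq(n)
  set.seed(88)
  # disconnected components
  contigs <- data.frame(id = c("a", "b", "c", "d"),
                        seq = c(s(500), s(400), s(300), s(200)),
                        depth = 30)
  links <- data.frame(contig1 = c("a", "b", "c", "d"), end1 = "tail",
                      contig2 = c("b", "a", "d", "c"), end2 = "head",
                      depth = 30, overlap = 0)
  expect_error(build_master_circle(contig_graph(contigs, links)),
               "disconnected|component")
  # mismatched overlap bases
  gw <- graph_from_walk(list(c("a", s(500)), c("b", s(400))), c("a", "b"))
  bad <- gw$graph
  bad$linkages$overlap <- 10
  expect_error(build_master_circle(bad), "overlap")
})

test_that("contig graphs round-trip through FASTA + TSV", {
  gw <- graph_from_walk(list(c("a", rand_seq(500, seed = 89)),
                             c("b", rand_seq(400))), c("a", "b"))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  ctg <- gw$graph$contigs
  writeLines(paste0(">", ctg$id, " depth=", ctg$depth, "\n", ctg$seq), fa)
  utils::write.table(gw$graph$linkages, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gr <- read_contig_graph(fa, tsv)
  expect_equal(gr$contigs$seq, ctg$seq)
  expect_equal(gr$contigs$depth, ctg$depth)
  mc <- build_master_circle(gr)
  expect_equal(mc$length, 900)
})
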