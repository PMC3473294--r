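test_that("a self-comparison has no unique regions", {
  g <- circular_genome(rand_seq(10000, seed = 61), id = "g")
  bl <- chain_fragments(find_local_matches(g, g))
  expect_equal(nrow(extract_unique_regions(g, bl, which = "B")), 0L)
})

test_that("a planted insert is recovered within 100 bp", {
  set.seed(62)
  shared1 <- rand_seq(8000); shared2 <- rand_seq(8000)
  insert <- rand_seq(5000)
  gA <- circular_genome(paste0(shared1, rand_seq(500), shared2,
                               rand_seq(500)), id = "A")
  gB <- circular_genome(paste0(shared1, insert, shared2, rand_seq(700)),
                        id = "B")
  bl <- chain_fragments(find_local_matches(gA, gB))
  ur <- extract_unique_regions(gB, bl, which = "B")
  ins <- ur[which.min(abs(ur$span - 5000)), ]
  expect_lte(abs(ins$span - 5000), 100)
  expect_lte(cdist(ins$start, 8000, gB$length), 100)
})

test_that("blocks plus unique regions tile the genome at min_report 1", {
  sp <- generate_genome_pair(sim_config(
    ancestor_length = 90000, n_blocks = 5, substitution_rate = 1e-4,
    n_inversions = 1, seed = 63, n_cds = 0))
  bl <- chain_fragments(find_local_matches(sp$A, sp$B))
  ur <- extract_unique_regions(sp$B, bl, which = "B", min_report = 1)
  expect_equal(sum(bl$b_span) + sum(ur$span), sp$B$length)
})

test_that("mosaic coverage is 0 on an empty panel and tracks construction", {
  sp <- generate_genome_pair(sim_config(
    ancestor_length = 80000, n_blocks = 4, substitution_rate = 1e-4,
    n_insertions = 1, insertion_range = c(4000, 8000),
    insertion_sourced_fraction = 0.7, seed = 64, n_cds = 0))
  bl <- chain_fragments(find_local_matches(sp$A, sp$B))
  ur <- extract_unique_regions(sp$B, bl, which = "B")
  tr <- sp$truth$unique_regions[sp$truth$unique_regions$is_insert, ]
  i <- which.min(cdist(ur$start, tr$start, sp$B$length))
  expect_equal(mosaic_coverage(ur[i, ], sp$B, list())$coverage, 0)
  mc <- mosaic_coverage(ur[i, ], sp$B, sp$truth$panel)
  expect_lte(abs(mc$coverage - tr$sourced_fraction), 0.02)
  # monotone non-decreasing in panel size
  mc2 <- mosaic_coverage(ur[i, ], sp$B, sp$truth$panel[1:2])
  expect_lte(mc2$coverage, mc$coverage + 1e-9)
})

test_that("fully sourced inserts reach coverage 1; unsourced lowers it", {
  panel <- generate_reference_panel(3, relatedness = 0.1, seed = 65,
                                    length = 30000)
  set.seed(66)
  frag <- function(p, n) extract_interval(p, sample(0:(p$length - n), 1), n)
  full <- paste(vapply(1:10, function(i)
    frag(panel[[sample(3, 1)]], 400), character(1)), collapse = "")
  mixed <- paste0(substr(full, 1, 2000), rand_seq(1000),
                  substr(full, 2001, 4000))
  host <- function(region) {
    g <- circular_genome(paste0(rand_seq(3000), region, rand_seq(3000)),
                         id = "h")
    r <- data.frame(region_id = "I", start = 3000, span = nchar(region),
                    flank_left = 1, flank_right = 2,
                    minor_match_fraction = 0)
    mosaic_coverage(r, g, panel)
  }
  expect_equal(host(full)$coverage, 1, tolerance = 0.02)
  m <- host(mixed)
  expect_equal(m$coverage, 4000 / 5000, tolerance = 0.02)
})

test_that("integration signatures are detected exactly when planted", {
  # random flanks: no signature
  g <- circular_genome(rand_seq(20000, seed = 67), id = "g")
  r0 <- data.frame(region_id = "I", start = 8000, span = 4000,
                   flank_left = 1, flank_right = 2,
                   minor_match_fraction = 0)
  s0 <- detect_integration_signature(r0, g)
  expect_false(s0$complete)
  # planted nested inverted pairs recovered at exact lengths
  sp <- generate_genome_pair(sim_config(
    ancestor_length = 80000, n_blocks = 4, substitution_rate = 1e-4,
    n_insertions = 1, integration_signature = TRUE, seed = 68, n_cds = 0))
  bl <- chain_fragments(find_local_matches(sp$A, sp$B))
  ur <- extract_unique_regions(sp$B, bl, which = "B")
  tr <- sp$truth$unique_regions[sp$truth$unique_regions$has_signature, ]
  i <- which.min(cdist(ur$start, tr$start, sp$B$length))
  sig <- detect_integration_signature(ur[i, ], sp$B)
  expect_true(sig$complete)
  expect_equal(sig$outer$length, 176)
  expect_equal(sig$inner$length, 28)
})

test_that("region labels are roman numerals in coordinate order", {
  sp <- generate_genome_pair(sim_config(
    ancestor_length = 90000, n_blocks = 5, substitution_rate = 1e-4,
    seed = 69, n_cds = 0))
  bl <- chain_fragments(find_local_matches(sp$A, sp$B))
  ur <- extract_unique_regions(sp$B, bl, which = "B")
  expect_equal(ur$region_id,
               as.character(utils::as.roman(seq_len(nrow(ur)))))
  expect_true(all(diff(ur$start) > 0))
})
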