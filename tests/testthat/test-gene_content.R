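mk_orf <- function(aa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0("ATG", paste(sample(non_stop_codons(), aa - 1, TRUE), collapse = ""),
         "TAA")
}

test_that("a planted ORF is found at its exact location", {
  set.seed(71)
  orf <- mk_orf(300)
  # a TAG immediately upstream pins the first-ATG rule to the planted start
  g <- circular_genome(paste0(rand_seq(2000), "TAG", orf, rand_seq(2000)),
                       id = "g")
  found <- as.data.frame(find_orfs(g, min_aa = 250))
  found <- found[found$strand == "+", ]
  expect_equal(nrow(found), 1L)
  expect_equal(found$start, 2003)
  expect_equal(found$aa_len, 300)
  expect_equal(substr(found$protein, 1, 1), "M")
  expect_equal(nchar(found$protein), 300)
})

test_that("an ORF across the origin is reported once, wrap-capable", {
  set.seed(72)
  orf <- mk_orf(200)  # 603 bp
  pre <- paste0(rand_seq(1500), "TAA")
  g <- circular_genome(paste0(substr(orf, 301, 603), rand_seq(1200), pre,
                              substr(orf, 1, 300)), id = "g")
  found <- as.data.frame(find_orfs(g, min_aa = 180))
  hit <- found[found$aa_len == 200 & found$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, g$length - 300)
  expect_gt(hit$start + hit$span, g$length)  # wraps
})

test_that("ORF sets are rotation-invariant up to coordinate shift", {
  set.seed(73)
  g <- circular_genome(paste0(rand_seq(1000), "TAG", mk_orf(150),
                              rand_seq(800), "TGA", revcomp(mk_orf(120)),
                              rand_seq(900)), id = "g")
  o1 <- as.data.frame(find_orfs(g, min_aa = 100))
  off <- 777
  o2 <- as.data.frame(find_orfs(rotate_genome(g, off), min_aa = 100))
  expect_equal(nrow(o1), nrow(o2))
  sig <- function(d) d[order(d$aa_len, d$strand), c("aa_len", "strand",
                                                    "protein")]
  expect_equal(sig(o1), sig(o2), ignore_attr = TRUE)
  shifted <- sort((o1$start - off) %% g$length)
  expect_equal(shifted, sort(o2$start))
})

test_that("identical genomes have no unique ORFs; diverged ones do", {
  set.seed(74)
  orfA <- mk_orf(150)
  shared <- paste0(rand_seq(3000), "TAG", mk_orf(120), rand_seq(3000))
  gA <- circular_genome(paste0(shared, "TAG", orfA, rand_seq(1000)),
                        id = "A")
  gB <- circular_genome(paste0(shared, rand_seq(nchar(orfA) + 1003)),
                        id = "B")
  oA <- find_orfs(gA, min_aa = 100); oB <- find_orfs(gB, min_aa = 100)
  same <- compare_orf_sets(oA, oA, gA, gA)
  expect_equal(nrow(same$unique_A), 0L)
  expect_equal(nrow(same$unique_B), 0L)
  diffs <- compare_orf_sets(oA, oB, gA, gB)
  expect_true(any(abs(diffs$unique_A$aa_len - 150) <= 2))
})

test_that("SNP effects reproduce the canonical codon arithmetic", {
  # cds_pos 1010 T>C in codon 337 (CTA Leu) -> CCA Pro, L337P;
  # cds_pos 776 C>T in codon 259 (TCC Ser) -> TTC Phe, S259F;
  # plus a third-position synonymous change
  set.seed(75)
  codons <- sample(non_stop_codons(), 400, TRUE)
  codons[1] <- "ATG"; codons[337] <- "CTA"; codons[259] <- "TCC"
  codons[100] <- "GGC"  # Gly, any third-position change is synonymous
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  gAseq <- paste0(rand_seq(4000), cds, rand_seq(4000))
  ch <- strsplit(gAseq, "")[[1]]
  ch[4000 + 1010] <- "C"; ch[4000 + 776] <- "T"; ch[4000 + 300] <- "T"
  gA <- circular_genome(gAseq, id = "A")
  gB <- circular_genome(paste(ch, collapse = ""), id = "B")
  bl <- chain_fragments(find_local_matches(gA, gB))
  ann <- data.frame(gene = "nad4", start = 4001, end = 4000 + nchar(cds),
                    strand = "+", part = 1L)
  snps <- as.data.frame(call_snps(bl, gA, gB, annotations = ann))
  expect_equal(nrow(snps), 3L)
  expect_equal(snps$aa_change[snps$cds_pos == 1010], "L337P")
  expect_equal(snps$aa_change[snps$cds_pos == 776], "S259F")
  expect_equal(snps$aa_change[snps$cds_pos == 300], "synonymous")
  expect_equal(snps$codon_index, ceiling(snps$cds_pos / 3))
})

test_that("minus-strand CDS SNPs are classified on the coding strand", {
  set.seed(76)
  codons <- sample(non_stop_codons(), 200, TRUE)
  codons[1] <- "ATG"; codons[50] <- "CTA"  # Leu
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  gAseq <- paste0(rand_seq(3000), revcomp(cds), rand_seq(3000))
  # genomic base at CDS position 149 (codon 50, pos 2): on minus strand
  cds_pos <- 149
  gpos <- 3000 + nchar(cds) - cds_pos + 1  # 1-based genomic
  ch <- strsplit(gAseq, "")[[1]]
  expect_equal(ch[gpos], "A")  # complement of coding-strand T
  ch[gpos] <- "G"              # coding strand T>C: CTA->CCA, L50P
  gA <- circular_genome(gAseq, id = "A")
  gB <- circular_genome(paste(ch, collapse = ""), id = "B")
  bl <- chain_fragments(find_local_matches(gA, gB))
  ann <- data.frame(gene = "mirror", start = 3001,
                    end = 3000 + nchar(cds), strand = "-", part = 1L)
  snps <- as.data.frame(call_snps(bl, gA, gB, annotations = ann))
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$cds_pos, cds_pos)
  expect_equal(snps$aa_change, "L50P")
})

test_that("simulated CDS substitutions round-trip through call_snps", {
  sp <- generate_genome_pair(sim_config(
    ancestor_length = 60000, n_blocks = 3, substitution_rate = 2e-3,
    seed = 77, n_cds = 3))
  # divergence here (2e-3) sits above the default 0.999 admission bound;
  # chain with a matching threshold so every planted block is admitted
  bl <- chain_fragments(find_local_matches(sp$A, sp$B),
                        min_block_identity = 0.99)
  snps <- as.data.frame(call_snps(bl, sp$A, sp$B,
                                  annotations = sp$truth$annotations))
  truth <- sp$truth$snps
  truth_cds <- truth[!is.na(truth$gene), ]
  expect_gt(nrow(truth_cds), 0)
  got <- snps[!is.na(snps$gene), ]
  m <- merge(truth_cds, got, by = "pos_a")
  expect_equal(nrow(m), nrow(truth_cds))
  expect_equal(m$aa_change.x, m$aa_change.y)
  expect_equal(m$cds_pos.x, m$cds_pos.y)
  # self-consistency: codon_index == ceil(cds_pos / 3) on every record
  expect_equal(got$codon_index, ceiling(got$cds_pos / 3))
})

test_that("scan_motif finds planted motifs at the stated mismatch budget", {
  set.seed(78)
  motif <- "CTATCAATCTCATAAGAGAAGAAAT"
  g0 <- circular_genome(motif, id = "m")
  hit <- scan_motif(g0, motif, 0)
  expect_true(any(hit$start == 0 & hit$strand == "+" & hit$mismatches == 0))
  # planted with 2 substitutions: found at 2, absent at 1
  mut <- strsplit(motif, "")[[1]]
  mut[5] <- "G"; mut[20] <- "C"
  g <- circular_genome(paste0(rand_seq(2000), paste(mut, collapse = ""),
                              rand_seq(2000)), id = "g")
  h2 <- scan_motif(g, motif, 2)
  expect_true(any(h2$start == 2000 & h2$mismatches == 2))
  h1 <- scan_motif(g, motif, 1)
  expect_false(any(h1$start == 2000))
  # oracle agreement (forward strand) and wrap capability
  orc <- oracle_motif_scan(g$seq, motif, 2)
  expect_setequal(h2$start[h2$strand == "+"], orc$start)
  gw <- circular_genome(paste0(substr(motif, 11, 25), rand_seq(500),
                               substr(motif, 1, 10)), id = "w")
  hw <- scan_motif(gw, motif, 0)
  expect_true(any(hw$start == gw$length - 10))
})
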