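test_that("block p-value is the binomial lower tail", {
  expect_equal(block_p_value(0, 100, 0.05), 0.95^100, tolerance = 1e-12)
  # at the expected count the lower tail is at least ~1/2
  expect_gte(block_p_value(50, 1000, 0.05), 0.5)
  expect_equal(block_p_value(100, 100, 0.05), 1)
  expect_error(block_p_value(5, 100, 0), "background")
  expect_error(block_p_value(200, 100, 0.05), "pair_diffs")
})

test_that("the divergence clock converts as stated and is scale-invariant", {
  expect_equal(date_block(8, 1000), 2e6)        # 0.008 / (2 * 0.2e-8)
  expect_equal(date_block(0, 1000), 0)
  expect_equal(date_block(16, 2000), date_block(8, 1000))
  expect_equal(date_block(8, 1000, mu_year = 0.4e-8), 1e6)
})

test_that("retention filters apply SNP, p-value and sister rules verbatim", {
  blocks <- data.frame(
    scaffold = "s1", start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    pair = c("medius:sibreei", "medius:sibreei", "major:medius",
             "medius:sibreei"),
    n_snps = c(9L, 50L, 50L, 50L),
    p_value = c(1e-9, 1e-5, 1e-9, 1e-9),
    stringsAsFactors = FALSE)
  kept <- filter_blocks(blocks, triplet_params(), species_tree_newick,
                        triplet = c("medius", "major", "sibreei"))
  # 9 SNPs: removed; p = 1e-5: removed; major:medius is the sister pair
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 300)
  expect_error(filter_blocks(blocks, triplet_params(), species_tree_newick,
                             triplet = c("medius", "major", "absent")),
               "absent")
})

test_that("degenerate triplets produce no windows or blocks", {
  # window a multiple of the 3-site tie pattern below, so sums tie exactly
  p <- triplet_params(snp_window = 12, step_snps = 6)
  # identical sequences: no segregating sites
  s <- strrep("ACGT", 500)
  expect_equal(nrow(scan_triplet(s, s, s, p)), 0)
  # mutually equidistant sequences: every window ties, no winner
  n <- 3000
  a <- rep("A", n); b <- rep("A", n); c <- rep("A", n)
  i <- seq(1, n, by = 3)
  b[i] <- "C"                  # A differs from B here, C sides with A
  c[i + 1] <- "G"              # C differs from A and B here
  b[i + 2] <- "T"; c[i + 2] <- "T"   # A differs from both here
  bl <- scan_triplet(paste(a, collapse = ""), paste(b, collapse = ""),
                     paste(c, collapse = ""), p)
  expect_equal(nrow(bl), 0)
  expect_error(scan_triplet("ACGT", "AC", "ACGT", p), "equal length")
})

test_that("a planted donor tract is recovered as a block for the right pair", {
  found <- 0
  for (rep in 1:5) {
    trs <- list(tract_spec("sibreei", "medius", "s1", 150000, 180000,
                           2.5e5, zygosity = "hom"))
    cfg <- sim_config(scaffold_lengths = c(s1 = 4e5), tracts = trs,
                      seed = 700 + rep)
    d <- simulate_dataset(cfg)
    cons <- consensus_sequences(d)
    bl <- triplet_blocks(cons, c("medius", "major", "sibreei"),
                         species_tree = species_tree_newick)
    ms <- bl[bl$pair == "medius:sibreei", , drop = FALSE]
    if (nrow(ms) && any(ms$start < 180000 & ms$end > 150000)) found <- found + 1
    # every retained block is below its pair's background divergence
    bg <- attr(bl, "background")
    if (nrow(bl)) expect_true(all(bl$divergence < bg[bl$pair]))
  }
  expect_gte(found, 5)
})

test_that("null simulations yield almost no retained blocks", {
  n_over <- 0
  for (rep in 1:8) {
    cfg <- sim_config(scaffold_lengths = c(s1 = 1e6), seed = 900 + rep)
    d <- simulate_dataset(cfg)
    cons <- consensus_sequences(d)
    bl <- triplet_blocks(cons, c("medius", "major", "sibreei"),
                         species_tree = species_tree_newick)
    if (nrow(bl) > 1) n_over <- n_over + 1   # > 1 block per 1 Mb
  }
  expect_lte(n_over, 1)
})

test_that("block summaries count pairs and candidate overlap sections", {
  blocks <- data.frame(
    scaffold = c("s1", "s1"), start = c(0, 200), end = c(100, 300),
    pair = "medius:sibreei", n_snps = 20L, pair_diffs = c(2, 3),
    block_len = 100, divergence = c(0.02, 0.03), p_value = 1e-9,
    age_years = c(5e6, 7.5e6), stringsAsFactors = FALSE)
  s0 <- summarize_blocks(blocks[0, ])
  expect_equal(s0$n_blocks, 0)
  cand <- regions(c("s1", "s1"), c(0, 200), c(100, 300))
  s1 <- summarize_blocks(blocks, cand)
  expect_equal(s1$overlap$n_fd_regions_hit, 2L)   # blocks == candidates
  expect_equal(s1$overlap$n_sections, 2L)
  expect_equal(s1$overlap$sections, cand)
  expect_equal(s1$mean_age_years, 6.25e6)
  expect_equal(s1$per_pair$n_blocks, 2L)
  # random interval sets agree with the per-base oracle
  set.seed(13)
  for (i in 1:20) {
    L <- 1000
    b2 <- random_region_set(6, L)
    cand2 <- random_region_set(4, L)
    blocks2 <- data.frame(scaffold = b2$scaffold, start = b2$start,
                          end = b2$end, pair = "x:y", n_snps = 10L,
                          pair_diffs = 1, block_len = 10, divergence = 0.1,
                          p_value = 0, age_years = 1, stringsAsFactors = FALSE)
    s2 <- summarize_blocks(blocks2, cand2)
    expect_equal(s2$overlap$sections, bf_intersect(merge_regions(cand2),
                                                   merge_regions(b2), L))
  }
})
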