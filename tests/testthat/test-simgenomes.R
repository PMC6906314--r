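test_that("configuration invariants are enforced", {
  expect_error(sim_config(c(s1 = -5)), "lengths")
  expect_error(sim_config(c(s1 = 1e5), split_times_gen = c(2, 1, 3, 4)),
               "increasing")
  expect_error(sim_config(c(s1 = 1e5), missing_rate = 1), "missing_rate")
  expect_error(sim_config(c(s1 = 1e5), tracts = list(
    tract_spec("sibreei", "medius", "s1", 0, 2e5, 1e4))), "beyond")
  # admixture older than the donor-recipient divergence is impossible
  expect_error(sim_config(c(s1 = 1e5), tracts = list(
    tract_spec("sibreei", "medius", "s1", 0, 5e4, 5e6))), "younger")
  expect_error(sim_config(c(s1 = 1e5), tracts = list(
    tract_spec("outgroup", "medius", "s1", 0, 5e4, 1e4))), "outgroup")
})

test_that("no tracts means empty truth; same seed means identical output", {
  d <- small_sim()
  expect_equal(nrow(d$truth), 0)
  cfg <- sim_config(scaffold_lengths = c(s1 = 1e5), missing_rate = 0.05,
                    seed = 123)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$haplotypes, d2$haplotypes)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$coverage, d2$coverage)
  d3 <- simulate_dataset(sim_config(scaffold_lengths = c(s1 = 1e5),
                                    missing_rate = 0.05, seed = 124))
  expect_false(identical(d1$genotypes, d3$genotypes))
})

test_that("genotypes are consistent with the haplotypes", {
  d <- small_sim()
  hm <- d$haplotypes[["chr_a"]]
  gt <- d$genotypes[d$genotypes$scaffold == "chr_a", ]
  base <- c("A", "C", "G", "T")
  set.seed(1)
  idx <- sample(nrow(gt), 50)
  for (i in idx) {
    p <- gt$pos[i] + 1
    ref <- gt$ref[i]
    for (k in 1:5) {
      g <- gt[[c("major", "crossleyi", "medius", "sibreei", "outgroup")[k]]][i]
      if (is.na(g)) next
      # genotype is the count of non-reference alleles in the haplotype pair
      have <- sum(base[as.integer(hm[p, c(2 * k - 1, 2 * k)]) + 1] != ref)
      expect_equal(have, g)
    }
  }
  expect_true(all(d$coverage[, -(1:2)] >= 0))
})

test_that("mean pairwise divergence matches the coalescent expectation", {
  # two species split 1e6 generations ago, ancestral Ne 1e5, mu 1e-8, 1 Mb:
  # E[diffs] = L * (2 * T * mu + 4 * Ne * mu) = 24,000
  mu <- 1e-8; L <- 1e6; Tsplit <- 1e6; Ne <- 1e5
  reps <- 20
  diffs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(scaffold_lengths = c(s1 = L),
                      split_times_gen = c(Tsplit, 8e6, 9e6, 1e7),
                      branch_Ne = Ne, mu_gen = mu, seed = 6000 + r)
    d <- simulate_dataset(cfg)
    hm <- d$haplotypes[["s1"]]
    diffs[r] <- sum(hm[, 1] != hm[, 3])   # major hap 1 vs crossleyi hap 1
  }
  # infinite-sites expectation L*(2*T*mu + 4*Ne*mu) = 24,000; the observed
  # count saturates slightly under JC69 multiple hits, so the exact oracle is
  # E_obs = (3/4) L (1 - E[exp(-(8/3) mu T)]), T = Tsplit + Exp(mean 2 Ne)
  cc <- 8 / 3 * mu
  expected <- 0.75 * L * (1 - exp(-cc * Tsplit) / (1 + cc * 2 * Ne))
  expect_equal(expected, L * (2 * Tsplit * mu + 4 * Ne * mu),
               tolerance = 0.03)   # the two oracles agree to a few percent
  # per-replicate sd: coalescent variance across 5-kb blocks + mutation noise
  nblk <- L / 5000
  sd_rep <- sqrt(nblk * (5000 * 2 * mu * 2 * Ne)^2 + expected)
  expect_lt(abs(mean(diffs) - expected), 3 * sd_rep / sqrt(reps))
})

test_that("planted tracts increase donor-recipient identity in-tract", {
  for (r in 1:5) {
    trs <- list(tract_spec("sibreei", "medius", "s1", 100000, 150000,
                           2e5, zygosity = "hom"))
    cfg <- sim_config(scaffold_lengths = c(s1 = 3e5), tracts = trs,
                      seed = 800 + r)
    d <- simulate_dataset(cfg)
    hm <- d$haplotypes[["s1"]]
    med <- hm[, 5]; sib <- hm[, 7]
    inside <- 100001:150000
    div_in <- mean(med[inside] != sib[inside])
    div_out <- mean(med[-inside] != sib[-inside])
    expect_lt(div_in, div_out)
  }
})

test_that("heterozygous tracts touch exactly one recipient haplotype", {
  trs <- list(tract_spec("sibreei", "medius", "s1", 50000, 150000, 2e5))
  cfg <- sim_config(scaffold_lengths = c(s1 = 2e5), tracts = trs, seed = 77)
  d <- simulate_dataset(cfg)
  hm <- d$haplotypes[["s1"]]
  inside <- 50001:150000
  div_h1 <- mean(hm[inside, 5] != hm[inside, 7])  # carrier haplotype vs donor
  div_h2 <- mean(hm[inside, 6] != hm[inside, 7])  # untouched haplotype
  expect_lt(div_h1, div_h2 / 3)
})

test_that("written outputs follow the stated conventions", {
  trs <- list(tract_spec("sibreei", "medius", "scaffold_1", 10000, 50000,
                         2e5))
  cfg <- sim_config(scaffold_lengths = c(scaffold_1 = 6e4), tracts = trs,
                    seed = 15)
  d <- simulate_dataset(cfg)
  out <- file.path(tempdir(), "sim_out")
  files <- write_outputs(d, out)
  bed <- readLines(files[["truth_bed"]])
  expect_match(bed[1], "^scaffold_1\t10000\t50000\t")
  vcf <- readLines(files[["vcf"]])
  expect_equal(vcf[1], "##fileformat=VCFv4.2")
  body <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(body), nrow(d$genotypes))
  # FASTA length equals scaffold length
  fa <- readLines(files[["fasta_medius"]])
  expect_equal(sum(nchar(fa[-1])), 6e4)
  # IUPAC consensus ambiguity codes sit exactly where the haplotypes differ
  cons <- consensus_sequences(d)
  amb <- strsplit(cons[["scaffold_1"]][["medius"]], "")[[1]] %in%
         c("M", "R", "W", "S", "Y", "K")
  hm <- d$haplotypes[["scaffold_1"]]
  expect_equal(which(amb), which(hm[, 5] != hm[, 6]))
  # every biallelic het genotype is an ambiguity code in the consensus
  het_pos <- d$genotypes$pos[d$genotypes$medius == 1] + 1
  expect_true(all(amb[het_pos]))
  # a dataset with zero segregating sites yields a header-only VCF
  cfg0 <- sim_config(scaffold_lengths = c(s1 = 500), mu_gen = 1e-12,
                     seed = 3)
  d0 <- simulate_dataset(cfg0)
  f0 <- write_outputs(d0, file.path(tempdir(), "sim_empty"))
  v0 <- readLines(f0[["vcf"]])
  expect_true(all(startsWith(v0, "#")))
})
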