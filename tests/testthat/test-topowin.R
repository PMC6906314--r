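test_that("allele-sharing distances match a per-site loop", {
  f <- cbind(a = c(0, 0.5, 1), b = c(0, 0.5, 1), c = c(1, 0.5, 0))
  d <- window_distance_matrix(f)
  expect_equal(d["a", "b"], 0)          # identical genotypes
  expect_equal(d["a", "c"], 2 / 3)
  f2 <- cbind(a = c(0, 0), b = c(1, 1))
  expect_equal(window_distance_matrix(f2)["a", "b"], 1)  # opposite homozygotes
  set.seed(3)
  for (i in 1:20) {
    f3 <- matrix(sample(c(0, .5, 1), 40, TRUE), ncol = 4)
    d3 <- window_distance_matrix(f3)
    for (a in 1:3) for (b in (a + 1):4)
      expect_equal(d3[a, b], mean(abs(f3[, a] - f3[, b])))
    expect_equal(d3, t(d3))
    expect_true(all(diag(d3) == 0))
  }
})

# additive distances on a quartet with split {pair1}|{pair2}
.additive_quartet <- function(split, internal, tips) {
  d <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    same_side <- (i %in% split) == (j %in% split)
    d[i, j] <- d[j, i] <- tips[i] + tips[j] + if (same_side) 0 else internal
  }
  d
}

test_that("the four-point condition recovers the generating split", {
  d <- .additive_quartet(c(1, 2), 0.3, rep(0.1, 4))
  expect_equal(nj_quartet(d), "T1")
  expect_equal(nj_quartet(.additive_quartet(c(1, 3), 0.3, rep(0.1, 4))), "T2")
  expect_equal(nj_quartet(.additive_quartet(c(2, 3), 0.3, rep(0.1, 4))), "T3")
  expect_equal(nj_quartet(matrix(1, 4, 4) - diag(4)), "U")   # all equal: tie
  set.seed(11)
  for (i in 1:300) {
    lab <- sample(c("T1", "T2", "T3"), 1)
    split <- switch(lab, T1 = c(1, 2), T2 = c(1, 3), T3 = c(2, 3))
    d <- .additive_quartet(split, runif(1, 0.05, 1), runif(4, 0, 1))
    expect_equal(nj_quartet(d), lab)
  }
})

test_that("windows classify, segment and report fractions that sum to one", {
  wl <- data.frame(scaffold = "s1", start = c(0, 1, 2, 3) * 1e5,
                   end = c(1, 2, 3, 4) * 1e5,
                   n_snps = 100L, label = c("T1", "T1", "T2", "T1"),
                   stringsAsFactors = FALSE)
  seg <- segment_topologies(wl)
  expect_equal(nrow(seg$segments), 3)
  expect_equal(unname(seg$fractions["T1"]), 0.75)
  expect_equal(sum(seg$fractions), 1)
  all1 <- wl; all1$label <- "T1"
  expect_equal(nrow(segment_topologies(all1)$segments), 1)
})

test_that("a null simulation is overwhelmingly concordant", {
  d <- small_sim()
  pt <- polarize(d$genotypes, "outgroup")
  wl <- window_topologies(pt, c("major", "crossleyi", "medius", "sibreei"),
                          win = 5e4)
  expect_equal(sum(wl$end - wl$start), 5e5)   # tiles the genome
  classified <- wl$label != "U"
  expect_gte(mean(wl$label[classified] == "T1"), 0.99)
  seg <- segment_topologies(wl)
  expect_equal(sum(seg$fractions), 1)
})

test_that("planted tracts enrich the matching discordant label in-tract", {
  wins <- 0
  for (rep in 1:5) {
    trs <- list(tract_spec("medius", "crossleyi", "s1", 100000, 200000,
                           2e5, zygosity = "hom"))
    cfg <- sim_config(scaffold_lengths = c(s1 = 4e5), tracts = trs,
                      seed = 500 + rep)
    d <- simulate_dataset(cfg)
    pt <- polarize(d$genotypes, "outgroup")
    wl <- window_topologies(pt, c("major", "crossleyi", "medius", "sibreei"),
                            win = 2e4)
    # tract joins crossleyi (B) and medius (C): the T3 split (B,C)|(A,D)
    in_tract <- wl$start >= 100000 & wl$end <= 200000
    disc_in <- mean(wl$label[in_tract] == "T3")
    disc_out <- mean(wl$label[!in_tract] == "T3")
    if (disc_in > disc_out) wins <- wins + 1
  }
  expect_gte(wins, 4)
})
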