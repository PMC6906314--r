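test_that("site pattern weights match the frequency products", {
  expect_equal(site_pattern_weights(0, 1, 1, 0), list(abba = 1, baba = 0))
  expect_equal(site_pattern_weights(1, 0, 1, 0), list(abba = 0, baba = 1))
  w <- site_pattern_weights(0.5, 0.5, 0.5, 0)
  expect_equal(w$abba, 0.125)
  expect_equal(w$baba, 0.125)
  expect_error(site_pattern_weights(-0.1, 0, 0, 0), "frequencies")
  expect_error(site_pattern_weights(0, 1.2, 0, 0), "frequencies")
})

.mk_ptab <- function(p1, p2, p3, pos = NULL, scaffold = "s1") {
  n <- length(p1)
  data.frame(scaffold = scaffold, pos = if (is.null(pos)) seq_len(n) - 1 else pos,
             p1 = p1, p2 = p2, p3 = p3, stringsAsFactors = FALSE)
}

test_that("Patterson's D matches count arithmetic and is antisymmetric", {
  # 6 pure ABBA sites + 2 pure BABA sites -> D = 0.5
  tab <- .mk_ptab(c(rep(0, 6), rep(1, 2)), c(rep(1, 6), rep(0, 2)), rep(1, 8))
  res <- patterson_d(tab, c("p1", "p2", "p3"))
  expect_equal(res$counts$sum_abba, 6)
  expect_equal(res$counts$sum_baba, 2)
  expect_equal(res$D, 0.5)
  # swapping P1 and P2 flips the sign exactly
  res_sw <- patterson_d(tab, c("p2", "p1", "p3"))
  expect_equal(res_sw$D, -0.5)
  # equal counts -> 0
  tab0 <- .mk_ptab(c(0, 1), c(1, 0), c(1, 1))
  expect_equal(patterson_d(tab0, c("p1", "p2", "p3"))$D, 0)
  expect_error(patterson_d(tab0[0, ], c("p1", "p2", "p3")), "empty")
})

test_that("sites with p3 = 0 carry no weight and are not counted", {
  tab <- .mk_ptab(c(0, 0.5), c(1, 1), c(1, 0))
  res <- patterson_d(tab, c("p1", "p2", "p3"))
  expect_equal(res$counts$n_sites, 1L)
  expect_equal(res$D, 1)
})

test_that("D equals a naive per-site loop on random tables", {
  set.seed(7)
  for (i in 1:100) {
    tab <- random_ptab(sample(20:80, 1))
    res <- patterson_d(tab, c("p1", "p2", "p3"))
    A <- 0; B <- 0
    for (r in seq_len(nrow(tab))) {
      A <- A + (1 - tab$p1[r]) * tab$p2[r] * tab$p3[r]
      B <- B + tab$p1[r] * (1 - tab$p2[r]) * tab$p3[r]
    }
    if (A + B > 0) expect_equal(res$D, (A - B) / (A + B), tolerance = 1e-12)
    expect_true(is.na(res$D) || (res$D >= -1 && res$D <= 1))
  }
})

test_that("adding a pure ABBA site never decreases D", {
  set.seed(8)
  for (i in 1:20) {
    tab <- random_ptab(30)
    d0 <- patterson_d(tab, c("p1", "p2", "p3"))$D
    tab2 <- rbind(tab, .mk_ptab(0, 1, 1, pos = max(tab$pos) + 1))
    d1 <- patterson_d(tab2, c("p1", "p2", "p3"))$D
    if (!is.na(d0)) expect_gte(d1, d0)
  }
})

test_that("jackknife SE matches the delete-one formula on a constructed genome", {
  # 20 blocks of 1 Mb: ten with (abba, baba) = (6, 2), ten with (2, 6)
  parts <- list()
  for (b in 0:19) {
    base <- b * 1e6
    if (b %% 2 == 0)
      parts[[b + 1]] <- .mk_ptab(c(rep(0, 6), rep(1, 2)),
                                 c(rep(1, 6), rep(0, 2)), rep(1, 8),
                                 pos = base + 0:7)
    else
      parts[[b + 1]] <- .mk_ptab(c(rep(0, 2), rep(1, 6)),
                                 c(rep(1, 2), rep(0, 6)), rep(1, 8),
                                 pos = base + 0:7)
  }
  tab <- do.call(rbind, parts)
  res <- jackknife_z(tab, c("p1", "p2", "p3"))
  expect_equal(res$n_blocks, 20L)
  expect_equal(res$D, 0)
  # delete-one estimates are +/- 1/19 of the remaining asymmetry:
  # removing a (6,2) block leaves A=74, B=78 -> D_-i = -4/152
  D_del <- c(rep(-4 / 152, 10), rep(4 / 152, 10))
  SE <- sqrt(19 / 20 * sum((D_del - mean(D_del))^2))
  expect_equal(res$SE, SE, tolerance = 1e-12)
  expect_equal(res$Z, 0)
})

test_that("jackknife flags degenerate cases", {
  # identical blocks -> SE 0, flagged
  parts <- lapply(0:19, function(b)
    .mk_ptab(c(0, 1), c(1, 0), c(1, 1), pos = b * 1e6 + 0:1))
  tab <- do.call(rbind, parts)
  res <- jackknife_z(tab, c("p1", "p2", "p3"))
  expect_true(res$se_zero)
  expect_true(is.infinite(res$Z) || is.nan(res$Z))
  # too few blocks -> error advising larger input
  small <- .mk_ptab(c(0, 1), c(1, 0), c(1, 1))
  expect_error(jackknife_z(small, c("p1", "p2", "p3")), "blocks")
})

test_that("simulated P3->P2 gene flow gives positive D", {
  trs <- list(tract_spec("medius", "crossleyi", "chr_a", 50000, 250000,
                         5e5, zygosity = "hom"))
  cfg <- sim_config(scaffold_lengths = c(chr_a = 3e5), tracts = trs,
                    seed = 99)
  d <- simulate_dataset(cfg)
  pt <- polarize(d$genotypes, "outgroup")
  res <- patterson_d(pt, c("major", "crossleyi", "medius"))
  expect_gt(res$D, 0.2)
})
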