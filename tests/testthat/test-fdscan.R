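test_that("f_d site terms follow the dynamic-donor definition", {
  expect_equal(fd_site_terms(0, 1, 1, 0), list(num = 1, den = 1))
  t2 <- fd_site_terms(0, 0.5, 1, 0)     # pD = 1
  expect_equal(t2$num, 0.5)
  expect_equal(t2$den, 1)
  expect_equal(fd_site_terms(0, 0, 0, 0), list(num = 0, den = 0))
})

test_that("windowed f_d handles pure-signal and undefined windows", {
  # one window of pure (0,1,1,0) sites -> f_d = 1
  tab <- data.frame(scaffold = "s1", pos = seq(0, 39000, by = 1000),
                    p1 = 0, p2 = 1, p3 = 1, stringsAsFactors = FALSE)
  w <- window_fd(tab, c("p1", "p2", "p3"))
  first <- w[w$start == 0, ]
  expect_equal(first$f_d, 1)
  expect_false(first$fd_undefined)
  # balanced ABBA/BABA -> window D = 0 -> f_d zeroed with flag
  tab0 <- data.frame(scaffold = "s1", pos = c(0, 1),
                     p1 = c(0, 1), p2 = c(1, 0), p3 = c(1, 1),
                     stringsAsFactors = FALSE)
  w0 <- window_fd(tab0, c("p1", "p2", "p3"))
  expect_true(all(w0$f_d == 0))
  expect_true(all(w0$fd_undefined))
  expect_error(window_fd(tab0, c("p1", "p2", "p3"), win = 100, step = 300),
               "win")
})

test_that("window sums equal a naive per-site loop", {
  tab <- random_ptab(400, span = 150000, seed = 31)
  w <- window_fd(tab, c("p1", "p2", "p3"), win = 40000, step = 10000)
  for (r in seq_len(nrow(w))) {
    inwin <- tab$pos >= w$start[r] & tab$pos < w$end[r]
    num <- 0; den <- 0; A <- 0; B <- 0
    for (i in which(inwin)) {
      p1 <- tab$p1[i]; p2 <- tab$p2[i]; p3 <- tab$p3[i]
      pd <- max(p2, p3)
      A <- A + (1 - p1) * p2 * p3
      B <- B + p1 * (1 - p2) * p3
      num <- num + (1 - p1) * p2 * p3 - p1 * (1 - p2) * p3
      den <- den + (1 - p1) * pd * pd - p1 * (1 - pd) * pd
    }
    expect_equal(w$n_snps[r], sum(inwin))
    expect_equal(w$sum_num[r], num, tolerance = 1e-12)
    expect_equal(w$sum_den[r], den, tolerance = 1e-12)
    wD <- if (A + B > 0) (A - B) / (A + B) else 0
    expect_equal(w$window_D[r], wD, tolerance = 1e-12)
  }
})

test_that("window masking keeps exactly-30%-failed windows", {
  tab <- data.frame(scaffold = "s1", pos = seq(0, 39999, length.out = 40),
                    p1 = 0, p2 = 1, p3 = 1, stringsAsFactors = FALSE)
  w <- window_fd(tab, c("p1", "p2", "p3"))
  w <- w[w$start == 0, ]
  attr(w, "win") <- 40000; attr(w, "step") <- 10000
  mk_mask <- function(nfail)
    data.frame(scaffold = "s1", pos = tab$pos,
               fail = seq_len(40) <= nfail, stringsAsFactors = FALSE)
  expect_true(apply_window_mask(w, mk_mask(13))$masked[1])   # 32.5% > 30%
  expect_false(apply_window_mask(w, mk_mask(12))$masked[1])  # exactly 30%
  expect_false(apply_window_mask(w, mk_mask(0))$masked[1])
})

test_that("candidate calling takes the top tail with ties and merges", {
  w <- data.frame(scaffold = "s1",
                  start = seq(0, by = 10000, length.out = 10000))
  w$end <- w$start + 40000
  set.seed(5)
  w$f_d <- sample(seq_len(10000)) / 10001   # distinct values
  w$masked <- FALSE
  attr(w, "scaffold_lengths") <- c(s1 = max(w$end))
  cand <- call_candidates(w)
  expect_equal(cand$n_selected, 5L)         # top 0.05% of 10,000 windows
  expect_equal(cand$cutoff_value, sort(w$f_d, decreasing = TRUE)[5])
  # overlapping selected windows merge into one region
  w2 <- data.frame(scaffold = "s1", start = c(0, 10000, 200000),
                   end = c(40000, 50000, 240000),
                   f_d = c(0.9, 0.95, 0.1), masked = FALSE)
  suppressWarnings(c2 <- call_candidates(w2, quantile = 1 / 3,
                                         scaffold_lengths = c(s1 = 3e5)))
  expect_equal(c2$regions, regions("s1", 0, 50000))
  # all masked -> error
  w2$masked <- TRUE
  expect_error(suppressWarnings(call_candidates(w2)), "masked")
})

test_that("null-simulation candidates cover about the top tail fraction", {
  d <- small_sim()
  pt <- polarize(d$genotypes, "outgroup")
  w <- window_fd(pt, c("major", "medius", "sibreei"), win = 10000,
                 step = 10000)
  suppressWarnings(cand <- call_candidates(w, quantile = 0.9))
  frac <- cand$n_selected / nrow(w)
  expect_gte(frac, 0.1 - 0.03)
  expect_lte(frac, 0.1 + 0.05)   # ties can only add windows
})

test_that("planted recent tracts push overlapping windows above background", {
  hits <- 0
  for (rep in 1:5) {
    trs <- list(tract_spec("sibreei", "medius", "s1", 100000, 140000,
                           5e4, zygosity = "hom"))
    cfg <- sim_config(scaffold_lengths = c(s1 = 4e5), tracts = trs,
                      seed = 300 + rep)
    d <- simulate_dataset(cfg)
    pt <- polarize(d$genotypes, "outgroup")
    w <- window_fd(pt, c("major", "medius", "sibreei"))
    over <- w$start < 140000 & w$end > 100000
    if (mean(w$f_d[over]) > mean(w$f_d[!over])) hits <- hits + 1
  }
  expect_gte(hits, 5)
})
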