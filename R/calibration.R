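# Simulation studies used to calibrate and validate the scan: null D/Z
# calibration, f_d and block-age parameter recovery, heterozygosity recovery
# and topology concordance, each run under the study conditions the package
# emulates (four ingroups + outgroup, Ne = 1e5, mu_gen = 0.8e-8, 4 y/gen).

.study_scaffolds <- function(n, bp) stats::setNames(rep(bp, n), paste0("s", seq_len(n)))

#' Null calibration of the genome-wide D statistic
#'
#' Simulates replicate genomes with no gene flow and returns the
#' block-jackknife Z score of Patterson's D for each replicate. Under the
#' null, incomplete lineage sorting makes ABBA and BABA counts symmetric, so
#' |Z| > 3 should be rare.
#'
#' @param n_reps number of replicate genomes (default 200).
#' @param seed base seed; replicate r uses seed + r.
#' @param genome_mb total genome size per replicate in Mb (default 5, as ten
#'   0.5-Mb scaffolds).
#' @param block_span_bp jackknife block span (default 250 kb, giving 20
#'   blocks on the default genome).
#' @return numeric vector of Z scores, one per replicate.
#' @export
calibrate_null_d <- function(n_reps = 200, seed = 1, genome_mb = 5,
                             block_span_bp = 250000) {
  vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(.study_scaffolds(10, genome_mb * 1e5), seed = seed + r)
    d <- simulate_dataset(cfg)
    pt <- polarize(d$genotypes, cfg$outgroup)
    jackknife_z(pt, cfg$species[1:3], block_span_bp = block_span_bp)$Z
  }, 0)
}

#' f_d recovery of a known admixture proportion
#'
#' Plants 25 fixed 40-kb donor tracts (sibreei -> medius, recent admixture)
#' covering 10 percent of a 10-Mb recipient genome, runs the windowed f_d
#' scan, and measures (i) the genome-wide mean f_d, whose expectation is the
#' replaced fraction, and (ii) the fraction of tracts overlapped by a called
#' candidate region when the candidate quantile is matched to the planted
#' fraction.
#'
#' @param n_reps replicates (default 20).
#' @param seed base seed.
#' @return list with \code{mean_fd} (per replicate), \code{recall} (pooled
#'   over replicates), \code{planted_fraction}.
#' @export
recover_fd <- function(n_reps = 20, seed = 1) {
  offsets <- list(c(1e5, 4e5, 7e5), c(2e5, 6e5))  # 3 + 2 tracts alternating
  mean_fd <- numeric(n_reps)
  hit <- 0L; tot <- 0L
  for (r in seq_len(n_reps)) {
    trs <- list()
    for (i in 1:10)
      for (off in offsets[[(i %% 2 == 0) + 1L]])
        trs[[length(trs) + 1L]] <- tract_spec("sibreei", "medius",
                                              paste0("s", i), off,
                                              off + 40000, 1e5,
                                              zygosity = "hom")
    cfg <- sim_config(.study_scaffolds(10, 1e6), tracts = trs,
                      seed = seed + r)
    d <- simulate_dataset(cfg)
    pt <- polarize(d$genotypes, cfg$outgroup)
    w <- window_fd(pt, c("major", "medius", "sibreei"))
    mean_fd[r] <- mean(w$f_d)
    # quantile matched to the planted fraction; the 100-window tail makes the
    # small-genome warning of call_candidates moot here
    cand <- suppressWarnings(call_candidates(w, quantile = 0.90))
    truth <- regions(d$truth$scaffold, d$truth$start, d$truth$end)
    hit <- hit + intersect_regions(truth, cand$regions)$n_a_hit
    tot <- tot + nrow(truth)
  }
  list(mean_fd = mean_fd, recall = hit / tot, planted_fraction = 0.10)
}

#' Block-dating recovery of a known admixture age
#'
#' Plants fixed donor tracts of known age (1.0 My at 4 years per generation),
#' runs the triplet block scan with the retention filters and the divergence
#' clock, and returns the ages of all retained donor-recipient blocks.
#'
#' @param n_reps replicates (default 20).
#' @param seed base seed.
#' @param age_years planted admixture age (default 1e6).
#' @return list with \code{ages} (retained block ages, pooled) and
#'   \code{age_years}.
#' @export
recover_block_age <- function(n_reps = 20, seed = 1, age_years = 1e6) {
  gens <- age_years / 4
  ages <- numeric()
  for (r in seq_len(n_reps)) {
    trs <- list()
    for (i in 1:4)
      for (off in c(1e5, 3e5))
        trs[[length(trs) + 1L]] <- tract_spec("sibreei", "medius",
                                              paste0("s", i), off,
                                              off + 25000, gens,
                                              zygosity = "hom")
    cfg <- sim_config(.study_scaffolds(4, 5e5), tracts = trs, seed = seed + r)
    d <- simulate_dataset(cfg)
    cons <- consensus_sequences(d)
    tree <- sprintf("((((%s,%s),%s),%s),%s);", cfg$species[1],
                    cfg$species[2], cfg$species[3], cfg$species[4],
                    cfg$outgroup)
    bl <- triplet_blocks(cons, c("medius", "major", "sibreei"),
                         species_tree = tree)
    ages <- c(ages, bl$age_years[bl$pair == "medius:sibreei"])
  }
  list(ages = ages, age_years = age_years)
}

#' Heterozygosity recovery against the coalescent expectation
#'
#' Simulates a genome at known Ne and mutation rate and returns the pooled
#' per-sample heterozygosity, whose coalescent expectation is 4 Ne mu.
#'
#' @param seed base seed.
#' @param genome_mb genome size in Mb per replicate (default 5).
#' @param ne diploid effective size (default 1e5).
#' @param n_reps replicate genomes averaged over (default 3; the pooled
#'   estimate of a single 5-Mb genome carries ~5% coalescent noise).
#' @return list with \code{pooled_het} (mean over replicates),
#'   \code{per_rep}, and \code{expected} (= 4 Ne mu).
#' @export
recover_heterozygosity <- function(seed = 1, genome_mb = 5, ne = 1e5,
                                   n_reps = 3) {
  per_rep <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(.study_scaffolds(10, genome_mb * 1e5), branch_Ne = ne,
                      seed = seed + r)
    d <- simulate_dataset(cfg)
    genome_mean_het(window_heterozygosity(d$genotypes, "medius"))$pooled_het
  }, 0)
  cfg0 <- sim_config(c(s = 1e5), branch_Ne = ne)
  list(pooled_het = mean(per_rep), per_rep = per_rep,
       expected = 4 * ne * cfg0$mu_gen)
}

#' Topology concordance on a no-introgression genome
#'
#' Simulates a genome without gene flow, classifies 100-kb windows by quartet
#' topology and returns the fraction of classified windows that match the
#' species tree.
#'
#' @param seed seed.
#' @param genome_mb genome size in Mb (default 5).
#' @return list with \code{concordant_fraction} and \code{n_classified}.
#' @export
topology_concordance <- function(seed = 1, genome_mb = 5) {
  cfg <- sim_config(.study_scaffolds(10, genome_mb * 1e5), seed = seed)
  d <- simulate_dataset(cfg)
  pt <- polarize(d$genotypes, cfg$outgroup)
  wl <- window_topologies(pt, cfg$species)
  cl <- wl$label != "U"
  list(concordant_fraction = mean(wl$label[cl] == "T1"),
       n_classified = sum(cl))
}
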