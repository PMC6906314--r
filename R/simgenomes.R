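#' Specification of a planted introgression tract
#'
#' @param donor,recipient species names (must be distinct members of the
#'   simulated clade; the outgroup can never donate or receive).
#' @param scaffold scaffold name.
#' @param start,end tract interval, 0-based half-open.
#' @param admix_time_gens admixture time in generations before present; must
#'   be younger than the divergence of donor and recipient.
#' @param zygosity \code{"het"} (default; one recipient haplotype carries the
#'   tract) or \code{"hom"} (both haplotypes, i.e. the tract is fixed in the
#'   recipient individual).
#' @return A \code{tract_spec} list.
#' @export
tract_spec <- function(donor, recipient, scaffold, start, end,
                       admix_time_gens, zygosity = c("het", "hom")) {
  zygosity <- match.arg(zygosity)
  if (start < 0 || start >= end) stop("invalid tract interval")
  if (admix_time_gens <= 0) stop("admix_time_gens must be > 0")
  structure(list(donor = donor, recipient = recipient, scaffold = scaffold,
                 start = start, end = end,
                 admix_time_gens = admix_time_gens, zygosity = zygosity),
            class = "tract_spec")
}

#' Simulation configuration for four-ingroup-plus-outgroup genomes
#'
#' Describes the study design emulated by the simulator: a ladder species tree
#' (((A,B),C),D) plus an outgroup, one diploid individual per species,
#' divergence times in generations, per-branch effective sizes, a JC69
#' mutation process, optional introgression tracts, per-site Poisson coverage
#' and missing genotypes. Defaults place the four dwarf-lemur-like species at
#' splits of 2, 3, 4.5 and 7.5 million generations (8, 12, 18 and 30 My at 4
#' years per generation) with Ne = 100,000 on every branch and a
#' per-generation mutation rate of 0.8e-8 — the rates and generation time used
#' throughout the downstream clock and unit conversions.
#'
#' Recombination is emulated by cutting each scaffold into blocks of
#' \code{block_bp}; each block receives an independent coalescent genealogy
#' (free recombination between blocks, complete linkage within).
#'
#' @param scaffold_lengths named numeric vector of scaffold lengths in bp
#'   (unnamed vectors are named scaffold_1, scaffold_2, ...).
#' @param species four ingroup species names in tree order: the two sisters A
#'   and B, then C, then D (the earliest-diverging ingroup).
#' @param outgroup outgroup sample name.
#' @param split_times_gen increasing numeric vector of the four node times in
#'   generations: split(A,B), split(AB,C), split(ABC,D), split(ingroup,
#'   outgroup).
#' @param branch_Ne diploid effective size per branch: either a scalar or a
#'   vector of 9 (five tips A,B,C,D,O then ancestors AB, ABC, ABCD, root).
#' @param mu_gen per-site per-generation mutation rate.
#' @param gen_time_years years per generation.
#' @param tracts list of [tract_spec()] objects.
#' @param coverage_mean expected per-site sequencing depth (Poisson).
#' @param missing_rate fraction of genotype calls set missing, in [0, 1).
#' @param block_bp recombination block length in bp.
#' @param seed integer seed making the whole dataset reproducible.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(scaffold_lengths,
                       species = c("major", "crossleyi", "medius", "sibreei"),
                       outgroup = "outgroup",
                       split_times_gen = c(2e6, 3e6, 4.5e6, 7.5e6),
                       branch_Ne = 1e5,
                       mu_gen = 0.8e-8,
                       gen_time_years = 4,
                       tracts = list(),
                       coverage_mean = 30,
                       missing_rate = 0,
                       block_bp = 5000,
                       seed = 1) {
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- paste0("scaffold_", seq_along(scaffold_lengths))
  if (any(scaffold_lengths <= 0)) stop("scaffold lengths must be > 0")
  if (length(species) != 4 || anyDuplicated(c(species, outgroup)))
    stop("need four distinct ingroup species plus an outgroup")
  if (length(split_times_gen) != 4 || any(diff(split_times_gen) <= 0) ||
      split_times_gen[1] <= 0)
    stop("split_times_gen must be four strictly increasing positive times")
  if (length(branch_Ne) == 1) branch_Ne <- rep(branch_Ne, 9)
  if (length(branch_Ne) != 9 || any(branch_Ne <= 0))
    stop("branch_Ne must be a positive scalar or vector of 9")
  if (mu_gen <= 0) stop("mu_gen must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  cfg <- structure(list(scaffold_lengths = scaffold_lengths, species = species,
                        outgroup = outgroup, split_times_gen = split_times_gen,
                        branch_Ne = branch_Ne, mu_gen = mu_gen,
                        gen_time_years = gen_time_years, tracts = tracts,
                        coverage_mean = coverage_mean,
                        missing_rate = missing_rate, block_bp = block_bp,
                        seed = as.integer(seed)),
                   class = "sim_config")
  for (tr in tracts) .check_tract(tr, cfg)
  cfg
}

# divergence time of two samples under the ladder tree
.divergence_time <- function(cfg, sp1, sp2) {
  all5 <- c(cfg$species, cfg$outgroup)
  i <- match(sp1, all5); j <- match(sp2, all5)
  if (anyNA(c(i, j))) stop("unknown species: ", sp1, " / ", sp2)
  k <- max(i, j)
  if (k == 5) return(cfg$split_times_gen[4])
  if (k == 4) return(cfg$split_times_gen[3])
  if (k == 3) return(cfg$split_times_gen[2])
  cfg$split_times_gen[1]
}

.check_tract <- function(tr, cfg) {
  if (!inherits(tr, "tract_spec")) stop("tracts must be tract_spec objects")
  if (!tr$scaffold %in% names(cfg$scaffold_lengths))
    stop("tract on unknown scaffold: ", tr$scaffold)
  if (tr$end > cfg$scaffold_lengths[[tr$scaffold]])
    stop("tract extends beyond scaffold ", tr$scaffold)
  if (cfg$outgroup %in% c(tr$donor, tr$recipient))
    stop("the outgroup cannot donate or receive tracts")
  if (!all(c(tr$donor, tr$recipient) %in% cfg$species))
    stop("tract donor/recipient must be ingroup species")
  if (tr$donor == tr$recipient) stop("tract donor equals recipient")
  div <- .divergence_time(cfg, tr$donor, tr$recipient)
  if (tr$admix_time_gens >= div)
    stop("tract admixture time (", tr$admix_time_gens,
         ") must be younger than the donor-recipient divergence (", div, ")")
  invisible(tr)
}

#' Simulate a four-ingroup-plus-outgroup diploid dataset
#'
#' Runs the blockwise multispecies coalescent described in [sim_config()]:
#' haplotype sequences evolve under JC69 along per-block genealogies drawn on
#' the fixed species tree; within each introgression tract the recipient
#' haplotype lineage is grafted onto the donor haplotype's ancestral lineage
#' at the admixture time, so the tract's realized age equals its
#' specification. Biallelic SNPs, per-site Poisson coverage and missing
#' genotypes are derived from the haplotypes. Fully reproducible from the
#' config seed.
#'
#' @param config a [sim_config()] object.
#' @return An object of class \code{introscan_sim}: list with
#'   \code{genotypes} (genotype table as in [read_vcf_biallelic()]),
#'   \code{coverage} (site x sample depth matrix with scaffold/pos columns),
#'   \code{haplotypes} (per-scaffold raw matrices, bases coded 0-3),
#'   \code{truth} (tract ground-truth data.frame) and \code{config}.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  all5 <- c(config$species, config$outgroup)
  # tract overlap check per scaffold (one genealogy modification per block)
  tr_df <- .truth_frame(config)
  if (nrow(tr_df) > 1) {
    for (s in unique(tr_df$scaffold)) {
      d <- tr_df[tr_df$scaffold == s, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
        stop("overlapping tracts on scaffold ", s)
    }
  }
  haps <- list()
  geno_parts <- list()
  for (s in names(config$scaffold_lengths)) {
    L <- as.integer(config$scaffold_lengths[[s]])
    trs <- tr_df[tr_df$scaffold == s, , drop = FALSE]
    bk <- sort(unique(c(seq(0L, L, by = as.integer(config$block_bp)), L,
                        trs$start, trs$end)))
    nb <- length(bk) - 1L
    donor_hap <- rep(-1L, nb); rec_sp <- rep(-1L, nb)
    zyg <- rep(1L, nb); ta <- rep(0, nb)
    if (nrow(trs)) {
      mid <- (bk[-length(bk)] + bk[-1]) / 2
      for (ti in seq_len(nrow(trs))) {
        inb <- mid > trs$start[ti] & mid < trs$end[ti]
        donor_hap[inb] <- 2L * (match(trs$donor[ti], all5) - 1L)
        rec_sp[inb] <- match(trs$recipient[ti], all5) - 1L
        zyg[inb] <- if (trs$zygosity[ti] == "hom") 2L else 1L
        ta[inb] <- trs$admix_time_gens[ti]
      }
    }
    hm <- cpp_sim_scaffold(as.integer(bk), config$split_times_gen,
                           config$branch_Ne, config$mu_gen,
                           donor_hap, rec_sp, zyg, ta)
    haps[[s]] <- hm
    snp <- cpp_extract_snps(hm)
    if (length(snp$pos)) geno_parts[[s]] <- snp
  }
  gtcodes <- NULL
  gt <- if (length(geno_parts)) {
    n_per <- vapply(geno_parts, function(x) length(x$pos), 0L)
    g <- data.frame(
      scaffold = rep(names(geno_parts), n_per),
      pos = as.numeric(unlist(lapply(geno_parts, `[[`, "pos"),
                              use.names = FALSE)),
      ref = unlist(lapply(geno_parts, `[[`, "ref"), use.names = FALSE),
      alt = unlist(lapply(geno_parts, `[[`, "alt"), use.names = FALSE),
      n_alleles = unlist(lapply(geno_parts, `[[`, "n_alleles"),
                         use.names = FALSE),
      stringsAsFactors = FALSE)
    gm <- do.call(cbind, lapply(geno_parts, `[[`, "geno"))
    gtcodes <- do.call(cbind, lapply(geno_parts, `[[`, "gtcode"))
    rownames(gtcodes) <- all5
    for (k in seq_along(all5)) g[[all5[k]]] <- gm[k, ]
    g
  } else {
    g <- data.frame(scaffold = character(), pos = numeric(),
                    ref = character(), alt = character(),
                    n_alleles = integer(), stringsAsFactors = FALSE)
    for (sm in all5) g[[sm]] <- integer()
    g
  }
  rownames(gt) <- NULL
  n <- nrow(gt)
  cov <- matrix(rpois(n * 5L, config$coverage_mean), nrow = n, ncol = 5L,
                dimnames = list(NULL, all5))
  if (config$missing_rate > 0 && n) {
    miss <- matrix(runif(n * 5L) < config$missing_rate, nrow = n)
    for (k in seq_along(all5)) gt[[all5[k]]][miss[, k]] <- NA_integer_
  }
  attr(gt, "scaffold_lengths") <- config$scaffold_lengths
  coverage <- cbind(data.frame(scaffold = gt$scaffold, pos = gt$pos,
                               stringsAsFactors = FALSE), as.data.frame(cov))
  structure(list(genotypes = gt, coverage = coverage, haplotypes = haps,
                 gtcodes = gtcodes, truth = tr_df, config = config),
            class = "introscan_sim")
}

.truth_frame <- function(config) {
  trs <- config$tracts
  if (!length(trs))
    return(data.frame(donor = character(), recipient = character(),
                      scaffold = character(), start = numeric(),
                      end = numeric(), admix_time_gens = numeric(),
                      age_years = numeric(), zygosity = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(trs, function(tr)
    data.frame(donor = tr$donor, recipient = tr$recipient,
               scaffold = tr$scaffold, start = tr$start, end = tr$end,
               admix_time_gens = tr$admix_time_gens,
               age_years = tr$admix_time_gens * config$gen_time_years,
               zygosity = tr$zygosity, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
print.introscan_sim <- function(x, ...) {
  cat("Simulated dataset:", length(x$haplotypes), "scaffold(s),",
      format(sum(x$config$scaffold_lengths), big.mark = ","), "bp,",
      nrow(x$genotypes), "biallelic SNPs,", nrow(x$truth),
      "planted tract(s)\n")
  invisible(x)
}

#' Diploid consensus sequences with IUPAC ambiguity codes
#'
#' @param dataset an \code{introscan_sim} object.
#' @return named list (per scaffold) of named character vectors (per sample)
#'   of consensus sequences; heterozygous sites carry IUPAC codes.
#' @export
consensus_sequences <- function(dataset) {
  stopifnot(inherits(dataset, "introscan_sim"))
  all5 <- c(dataset$config$species, dataset$config$outgroup)
  lapply(dataset$haplotypes, function(hm) {
    s <- cpp_consensus(hm)
    names(s) <- all5
    s
  })
}

#' Write a simulated dataset to standard file formats
#'
#' Writes a multi-sample VCF 4.2 of the biallelic SNPs (1-based positions,
#' contig lengths in the header), one IUPAC consensus FASTA per sample, a BED
#' of the true tracts plus a JSON truth sidecar, and a long-format
#' tab-separated coverage table (scaffold, pos0, sample, depth).
#'
#' @param dataset an \code{introscan_sim} object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
write_outputs <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "introscan_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  all5 <- c(cfg$species, cfg$outgroup)
  files <- c()

  # VCF
  vcf_path <- file.path(out_dir, "variants.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=introscan_simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(cfg$scaffold_lengths),
                   as.integer(cfg$scaffold_lengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", all5), collapse = "\t"))
  gt <- dataset$genotypes
  if (nrow(gt)) {
    gcols <- vapply(all5, function(sm) {
      code <- dataset$gtcodes[sm, ]
      out <- paste0(code %/% 8L, "/", code %% 8L)
      out[is.na(gt[[sm]])] <- "./."
      out
    }, character(nrow(gt)))
    body <- paste(gt$scaffold, format(gt$pos + 1, scientific = FALSE,
                                      trim = TRUE),
                  ".", gt$ref, gt$alt, ".", "PASS", ".", "GT",
                  apply(gcols, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), vcf_path)
  files["vcf"] <- vcf_path

  # FASTA per sample
  cons <- consensus_sequences(dataset)
  for (sm in all5) {
    fa <- file.path(out_dir, paste0(sm, ".fa"))
    con <- file(fa, "w")
    for (s in names(cons)) {
      writeLines(paste0(">", s), con)
      seq <- cons[[s]][[sm]]
      starts <- seq(1, nchar(seq), by = 70)
      writeLines(substring(seq, starts, pmin(starts + 69, nchar(seq))), con)
    }
    close(con)
    files[paste0("fasta_", sm)] <- fa
  }

  # truth BED + JSON
  bed <- file.path(out_dir, "truth_tracts.bed")
  tr <- dataset$truth
  writeLines(if (nrow(tr)) {
    sprintf("%s\t%d\t%d\t%s>%s;t=%g;%s", tr$scaffold, as.integer(tr$start),
            as.integer(tr$end), tr$donor, tr$recipient, tr$admix_time_gens,
            tr$zygosity)
  } else character(), bed)
  files["truth_bed"] <- bed
  tj <- file.path(out_dir, "truth_tracts.json")
  jsonlite::write_json(tr, tj, digits = NA)
  files["truth_json"] <- tj

  # coverage TSV, long format
  cv <- dataset$coverage
  cvt <- file.path(out_dir, "coverage.tsv")
  long <- data.frame(
    scaffold = rep(cv$scaffold, length(all5)),
    pos0 = rep(cv$pos, length(all5)),
    sample = rep(all5, each = nrow(cv)),
    depth = as.vector(as.matrix(cv[, all5, drop = FALSE])),
    stringsAsFactors = FALSE)
  write.table(long, cvt, sep = "\t", quote = FALSE, row.names = FALSE)
  files["coverage"] <- cvt
  invisible(files)
}

#' Emit an MSMC2-format output table for a known Ne trajectory
#'
#' Inverse of the coalescent-unit conversion in [convert_units()]: takes a
#' piecewise-constant Ne trajectory in biological units and writes the
#' MSMC2-style table (time_index, left_time_boundary, right_time_boundary,
#' lambda) whose scaled boundaries and lambda values convert back exactly to
#' the input trajectory. Used to build test inputs for the demography stage.
#'
#' @param trajectory data.frame with columns \code{time_years} (left boundary
#'   of each constant piece, first must be 0, strictly increasing) and
#'   \code{Ne}.
#' @param mu_gen per-generation mutation rate.
#' @param gen_time_years years per generation.
#' @param n_segments total number of output segments (>= number of pieces).
#' @param path optional file path; when given the table is written there.
#' @return data.frame with the four MSMC2 columns (invisibly when written).
#' @export
make_msmc_output <- function(trajectory, mu_gen = 0.8e-8, gen_time_years = 4,
                             n_segments = 32, path = NULL) {
  t <- trajectory$time_years; ne <- trajectory$Ne
  if (length(t) < 1 || t[1] != 0 || any(diff(t) <= 0))
    stop("trajectory times must start at 0 and strictly increase")
  if (any(ne <= 0)) stop("Ne must be > 0")
  k <- length(t)
  if (n_segments < k) stop("n_segments must be >= number of trajectory pieces")
  per <- diff(floor(seq(0, n_segments, length.out = k + 1)))  # segments/piece
  left <- c(); lam <- c()
  for (i in seq_len(k)) {
    lo <- t[i]
    hi <- if (i < k) t[i + 1] else NA
    m <- per[i]
    sub <- if (i < k) lo + (hi - lo) * (seq_len(m) - 1) / m
           else if (lo > 0) lo * (1 + (seq_len(m) - 1))
           else (seq_len(m) - 1) * 1000  # flat trajectory: arbitrary spacing
    left <- c(left, sub)
    lam <- c(lam, rep(1 / (2 * mu_gen * ne[i]), m))
  }
  scaled <- left / gen_time_years * mu_gen
  out <- data.frame(time_index = seq_along(left) - 1L,
                    left_time_boundary = scaled,
                    right_time_boundary = c(scaled[-1], Inf),
                    lambda = lam)
  if (!is.null(path)) {
    write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
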