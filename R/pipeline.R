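#' Run the full introgression scan end-to-end
#'
#' Orchestrates simulate (or load) -> polarize -> Patterson's D -> f_d scan ->
#' candidate calling -> triplet block detection and dating -> overlap
#' accounting -> heterozygosity -> topology segmentation -> demography
#' summary -> gene-set enrichment, from one configuration list, writing
#' per-stage TSV/BED outputs and a machine-readable JSON report.
#'
#' @param config a list (or path to a YAML file parsed with
#'   [load_run_config()]) with elements:
#'   \describe{
#'     \item{sim}{arguments for [sim_config()] (simulation-backed run), or}
#'     \item{vcf}{path to a VCF (plus optional \code{coverage} path) for a
#'       data-backed run;}
#'     \item{outgroup}{outgroup sample name;}
#'     \item{pops}{list of (P1, P2, P3) population orders for D and f_d;}
#'     \item{triplets}{list of sample triples for the block scan
#'       (simulation-backed runs only, where consensus sequences exist);}
#'     \item{species_tree}{newick string (derived from \code{sim} when
#'       absent);}
#'     \item{params}{optional overrides: win, step, quantile, max_fail_frac,
#'       block_span_bp, het_win, topo_win, topo_min_snps, and the
#'       [triplet_params()] fields;}
#'     \item{msmc}{optional named vector of MSMC2-format file paths;}
#'     \item{genes}{optional gene table (see [genes_in_regions()]);}
#'     \item{out_dir}{output directory;}
#'     \item{seed}{integer seed.}
#'   }
#' @return An object of class \code{introscan_run}: per-stage summaries, file
#'   manifest with checksums, seed and wall-clock time. The same report is
#'   written as \code{report.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  pget <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  report <- list(seed = config$seed, stages = list())
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data stage -----------------------------------------------------------
  sim <- NULL
  if (!is.null(config$sim)) {
    gt <- stage("data", {
      scfg <- do.call(sim_config, config$sim)
      if (!is.null(config$seed)) scfg$seed <- as.integer(config$seed)
      sim <- simulate_dataset(scfg)
      sim$genotypes
    })
    files <- c(files, write_outputs(sim, file.path(out_dir, "data")))
    outgroup <- config$outgroup %||% sim$config$outgroup
    report$stages$data <- list(source = "simulation",
                               n_snps = nrow(gt),
                               n_tracts = nrow(sim$truth))
  } else if (!is.null(config$vcf)) {
    gt <- stage("data", read_vcf_biallelic(config$vcf,
                                           min_scaffold_len = pget("min_scaffold_len", 1e5)))
    outgroup <- config$outgroup
    report$stages$data <- list(source = config$vcf, n_snps = nrow(gt))
  } else stop("pipeline stage 'data' failed: config needs $sim or $vcf")
  samples <- setdiff(names(gt), c("scaffold", "pos", "ref", "alt", "n_alleles"))
  if (is.null(outgroup) || !outgroup %in% samples)
    stop("pipeline stage 'polarize' failed: outgroup label '",
         outgroup %||% "<missing>", "' not among samples")
  for (ord in config$pops)
    for (lab in ord)
      if (!lab %in% samples)
        stop("pipeline stage 'dstat' failed: population label '", lab,
             "' not among samples")

  # --- polarize -------------------------------------------------------------
  ptab <- stage("polarize", polarize(gt, outgroup))
  report$stages$polarize <- list(n_sites = nrow(ptab))

  # --- Patterson's D ---------------------------------------------------------
  dres <- stage("dstat", lapply(config$pops, function(ord)
    jackknife_z(ptab, ord, block_span_bp = pget("block_span_bp", 1e6))))
  report$stages$dstat <- lapply(dres, function(r)
    list(pops = r$pop_labels, D = r$D, SE = r$SE, Z = r$Z,
         n_blocks = r$n_blocks))

  # --- f_d scan + candidates -------------------------------------------------
  fd_ord <- config$pops[[1]]
  wins <- stage("fdscan", {
    w <- window_fd(ptab, fd_ord, win = pget("win", 40000),
                   step = pget("step", 10000))
    if (!is.null(sim)) {
      msk <- coverage_mask(sim$coverage)
      w <- apply_window_mask(w, msk, pget("max_fail_frac", 0.30))
    }
    w
  })
  cand <- stage("candidates",
                call_candidates(wins, quantile = pget("quantile", 0.9995)))
  fd_path <- file.path(out_dir, "fd_windows.tsv")
  write.table(wins, fd_path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_path <- file.path(out_dir, "fd_candidates.bed")
  writeLines(sprintf("%s\t%d\t%d", cand$regions$scaffold,
                     as.integer(cand$regions$start),
                     as.integer(cand$regions$end)), bed_path)
  files <- c(files, fd_windows = fd_path, fd_candidates = bed_path)
  report$stages$fdscan <- list(n_windows = nrow(wins),
                               n_masked = sum(wins$masked),
                               mean_fd = mean(wins$f_d[!wins$masked]),
                               cutoff = cand$cutoff_value,
                               n_candidate_regions = nrow(cand$regions),
                               candidate_bp = region_span(cand$regions))

  # --- triplet blocks --------------------------------------------------------
  if (!is.null(config$triplets) && !is.null(sim)) {
    tree <- config$species_tree %||%
      sprintf("((((%s,%s),%s),%s),%s);",
              sim$config$species[1], sim$config$species[2],
              sim$config$species[3], sim$config$species[4],
              sim$config$outgroup)
    tp <- triplet_params(snp_window = pget("snp_window", 100),
                         step_snps = pget("step_snps", 50),
                         min_snps = pget("min_snps", 10),
                         max_p = pget("max_p", 1e-6),
                         mu_year = pget("mu_year", 0.2e-8))
    cons <- consensus_sequences(sim)
    blocks <- stage("blocks", {
      bl <- lapply(config$triplets, function(tri)
        triplet_blocks(cons, tri, tp, species_tree = tree))
      do.call(rbind, lapply(seq_along(bl), function(i) {
        b <- bl[[i]]
        if (nrow(b)) b$triplet <- paste(config$triplets[[i]], collapse = ",")
        else b$triplet <- character()
        b
      }))
    })
    bsum <- summarize_blocks(blocks, cand)
    blk_path <- file.path(out_dir, "blocks.tsv")
    write.table(blocks, blk_path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, blocks = blk_path)
    report$stages$blocks <- list(
      n_blocks = bsum$n_blocks, mean_length_bp = bsum$mean_length_bp,
      mean_age_years = bsum$mean_age_years,
      n_fd_regions_hit = bsum$overlap$n_fd_regions_hit,
      n_overlap_sections = bsum$overlap$n_sections)
  }

  # --- heterozygosity --------------------------------------------------------
  het <- stage("heterozygosity", {
    lapply(stats::setNames(nm = setdiff(samples, outgroup)), function(sm) {
      hw <- window_heterozygosity(gt, sm, win = pget("het_win", 1e5))
      genome_mean_het(hw)
    })
  })
  report$stages$heterozygosity <- het

  # --- topology segmentation -------------------------------------------------
  ing <- setdiff(samples, outgroup)
  if (length(ing) == 4) {
    topo <- stage("topology", {
      wl <- window_topologies(ptab, ing, win = pget("topo_win", 1e5),
                              min_snps = pget("topo_min_snps", 50))
      segment_topologies(wl)
    })
    report$stages$topology <- list(fractions = as.list(topo$fractions),
                                   n_segments = nrow(topo$segments))
  }

  # --- demography ------------------------------------------------------------
  if (!is.null(config$msmc)) {
    demo <- stage("demography", {
      lapply(config$msmc, function(path) {
        tr <- convert_units(parse_msmc(path),
                            mu_gen = pget("mu_gen", 0.8e-8),
                            gen_time_years = pget("gen_time_years", 4))
        list(harmonic_mean_ne = harmonic_mean_ne(tr,
               drop_first = pget("drop_first", 5),
               drop_last = pget("drop_last", 5)),
             n_segments = nrow(tr))
      })
    })
    report$stages$demography <- demo
  }

  # --- enrichment ------------------------------------------------------------
  if (!is.null(config$genes)) {
    enr <- stage("enrichment", {
      fl <- genes_in_regions(config$genes, cand$regions)
      ct <- build_contingency(fl)
      c(chi_square_2x2(ct), list(table = ct))
    })
    report$stages$enrichment <- enr[c("chi2", "p", "direction")]
  }

  report$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report$files <- lapply(stats::setNames(nm = names(files)), function(k)
    list(path = unname(files[[k]]), md5 = unname(tools::md5sum(files[[k]]))))
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  structure(list(report = report, out_dir = out_dir), class = "introscan_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML document mirroring the [run_pipeline()] config list. Under
#' \code{sim}, \code{scaffold_lengths} becomes a named numeric vector and
#' each entry of \code{tracts} (fields donor, recipient, scaffold, start,
#' end, admix_time_gens, optional zygosity) is converted to a
#' [tract_spec()].
#'
#' @param path path to a YAML file.
#' @return a config list suitable for [run_pipeline()].
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim)) {
    if (!is.null(cfg$sim$scaffold_lengths))
      cfg$sim$scaffold_lengths <- unlist(cfg$sim$scaffold_lengths)
    if (!is.null(cfg$sim$tracts))
      cfg$sim$tracts <- lapply(cfg$sim$tracts, function(tr)
        do.call(tract_spec, tr))
  }
  if (!is.null(cfg$pops)) cfg$pops <- lapply(cfg$pops, unlist)
  if (!is.null(cfg$triplets)) cfg$triplets <- lapply(cfg$triplets, unlist)
  if (!is.null(cfg$msmc)) cfg$msmc <- unlist(cfg$msmc)
  cfg
}

#' @export
print.introscan_run <- function(x, ...) {
  r <- x$report
  cat("introscan pipeline run (seed ", r$seed %||% NA, ")\n", sep = "")
  cat("  stages:", paste(names(r$stages), collapse = ", "), "\n")
  if (!is.null(r$stages$dstat))
    for (d in r$stages$dstat)
      cat(sprintf("  D(%s) = %.4g (Z = %.2f)\n",
                  paste(d$pops[1:3], collapse = ","), d$D, d$Z))
  if (!is.null(r$stages$fdscan))
    cat(sprintf("  f_d: %d windows, cutoff %.4g, %d candidate regions\n",
                r$stages$fdscan$n_windows, r$stages$fdscan$cutoff,
                r$stages$fdscan$n_candidate_regions))
  if (!is.null(r$stages$blocks))
    cat(sprintf("  blocks: %d retained, mean age %.3g y\n",
                r$stages$blocks$n_blocks, r$stages$blocks$mean_age_years))
  cat(sprintf("  wall clock: %.1f s; outputs in %s\n", r$wall_clock_s,
              x$out_dir))
  invisible(x)
}
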