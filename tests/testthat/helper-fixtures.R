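# Shared fixtures and independent oracles, built in code at test time.

# memoized small null simulation reused across test files
.fixture_env <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(scaffold_lengths = c(chr_a = 3e5, chr_b = 2e5),
                      missing_rate = 0.02, seed = 20240901)
    .fixture_env$sim <- simulate_dataset(cfg)
  }
  .fixture_env$sim
}

# per-base brute-force oracles for interval arithmetic (single scaffold)
bf_union <- function(df, L) {
  covered <- logical(L)
  for (i in seq_len(nrow(df))) covered[(df$start[i] + 1):df$end[i]] <- TRUE
  bf_to_regions(covered, df$scaffold[1])
}
bf_intersect <- function(a, b, L) {
  ca <- logical(L); cb <- logical(L)
  for (i in seq_len(nrow(a))) ca[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) cb[(b$start[i] + 1):b$end[i]] <- TRUE
  bf_to_regions(ca & cb, a$scaffold[1])
}
bf_to_regions <- function(covered, scaffold) {
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(regions())
  regions(rep(scaffold, sum(keep)), starts[keep], ends[keep])
}
random_region_set <- function(n, L, scaffold = "s") {
  s <- sample.int(L - 1, n, replace = TRUE) - 1
  w <- sample.int(max(2, L %/% 5), n, replace = TRUE)
  regions(rep(scaffold, n), s, pmin(s + w, L))
}

# random polarized site table for loop-oracle tests
random_ptab <- function(n, scaffold = "s1", span = 2e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(span, n)) - 1
  tab <- data.frame(scaffold = scaffold, pos = pos,
                    p1 = sample(c(0, .5, 1), n, TRUE),
                    p2 = sample(c(0, .5, 1), n, TRUE),
                    p3 = sample(c(0, .5, 1), n, TRUE),
                    stringsAsFactors = FALSE)
  attr(tab, "scaffold_lengths") <- stats::setNames(span, scaffold)
  tab
}

# write a small VCF from explicit records for io tests
write_test_vcf <- function(path, contigs, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

species_tree_newick <- "((((major,crossleyi),medius),sibreei),outgroup);"
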