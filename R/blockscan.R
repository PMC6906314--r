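# IUPAC nucleotide codes as allele-set bitmasks (A=1, C=2, G=4, T=8).
.iupac_bits <- local({
  b <- integer(256)
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L, W = 9L,
             K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  for (ch in names(codes)) {
    b[utf8ToInt(ch) + 1L] <- codes[[ch]]
    b[utf8ToInt(tolower(ch)) + 1L] <- codes[[ch]]
  }
  b
})

# 2x the per-site distance between two IUPAC allele sets:
# disjoint sets -> 2 (a full difference); identical homozygous -> 0;
# any other overlap (shared allele, or identical heterozygous codes) -> 1,
# i.e. an ambiguous site counts half a difference when the other sequence
# carries one of its alleles.
.d2_table <- local({
  tab <- matrix(0L, 16, 16)
  pc <- vapply(0:15, function(x) sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0), 0L)
  for (x in 1:15) for (y in 1:15) {
    tab[x + 1, y + 1] <- if (bitwAnd(x, y) == 0L) 2L
                         else if (x == y && pc[x + 1] == 1L) 0L
                         else 1L
  }
  tab
})

.seq_codes <- function(s) .iupac_bits[as.integer(charToRaw(s)) + 1L]

#' Parameters of the triplet block scan
#'
#' @param snp_window segregating sites per scan window (default 100).
#' @param step_snps sites the window advances per step (default 50).
#' @param min_snps minimum segregating sites for a retained block (default 10).
#' @param max_p maximum block p-value for retention (default 1e-6).
#' @param mu_year per-year mutation rate for the divergence clock
#'   (default 0.2e-8).
#' @return a \code{triplet_params} list.
#' @export
triplet_params <- function(snp_window = 100, step_snps = 50, min_snps = 10,
                           max_p = 1e-6, mu_year = 0.2e-8) {
  if (min_snps < 1 || max_p <= 0 || max_p >= 1 || snp_window < 2 ||
      step_snps < 1 || step_snps > snp_window)
    stop("invalid triplet scan parameters")
  structure(list(snp_window = snp_window, step_snps = step_snps,
                 min_snps = min_snps, max_p = max_p, mu_year = mu_year),
            class = "triplet_params")
}

#' Scan three aligned sequences for unusually similar pair runs
#'
#' Slides a window of \code{snp_window} segregating sites (advanced by
#' \code{step_snps} sites) along three equal-length aligned sequences,
#' identifies the strictly most similar pair in each window, and fuses
#' maximal runs of consecutive windows won by the same pair into candidate
#' blocks. Block boundaries are refined to the outermost sites in the run at
#' which the pair is identical while the third sequence differs; pairwise
#' differences use the IUPAC half-difference convention for heterozygous
#' consensus codes. Positions where any of the three sequences is masked
#' (codes outside A/C/G/T and the two-allele ambiguity codes, e.g. N) are
#' excluded from counts and from the effective block length.
#'
#' @param seqA,seqB,seqC aligned equal-length sequences (character strings,
#'   IUPAC codes allowed).
#' @param params a [triplet_params()] object.
#' @param labels length-3 character vector naming the sequences.
#' @param scaffold scaffold name recorded in the output.
#' @return data.frame of candidate blocks: scaffold, start, end (0-based
#'   half-open), pair, n_snps, pair_diffs, block_len (valid positions).
#' @export
scan_triplet <- function(seqA, seqB, seqC, params = triplet_params(),
                         labels = c("A", "B", "C"), scaffold = "scaffold") {
  if (nchar(seqA) != nchar(seqB) || nchar(seqA) != nchar(seqC))
    stop("sequences must have equal length")
  ca <- .seq_codes(seqA); cb <- .seq_codes(seqB); cc <- .seq_codes(seqC)
  pc <- vapply(0:15, function(x) sum(bitwAnd(x, c(1L, 2L, 4L, 8L)) > 0), 0L)
  ok <- function(x) pc[x + 1L] >= 1L & pc[x + 1L] <= 2L
  valid <- ok(ca) & ok(cb) & ok(cc)
  d2 <- list(AB = .d2_table[cbind(ca + 1L, cb + 1L)],
             AC = .d2_table[cbind(ca + 1L, cc + 1L)],
             BC = .d2_table[cbind(cb + 1L, cc + 1L)])
  pair_names <- c(paste(labels[1], labels[2], sep = ":"),
                  paste(labels[1], labels[3], sep = ":"),
                  paste(labels[2], labels[3], sep = ":"))
  empty <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), pair = character(), n_snps = integer(),
                      pair_diffs = numeric(), block_len = numeric(),
                      stringsAsFactors = FALSE)
  seg <- valid & (d2$AB | d2$AC | d2$BC)
  segpos <- which(seg)                      # 1-based sequence index
  nseg <- length(segpos)
  sw <- params$snp_window
  if (nseg < sw) return(empty)
  starts <- seq(1L, nseg - sw + 1L, by = params$step_snps)
  wsum <- function(d) {
    cs <- c(0, cumsum(d[segpos]))
    cs[starts + sw] - cs[starts]
  }
  s_ab <- wsum(d2$AB); s_ac <- wsum(d2$AC); s_bc <- wsum(d2$BC)
  smat <- cbind(s_ab, s_ac, s_bc)
  smin <- pmin(s_ab, s_ac, s_bc)
  n_at_min <- (s_ab == smin) + (s_ac == smin) + (s_bc == smin)
  winner <- max.col(-smat, ties.method = "first")
  winner[n_at_min > 1L] <- 0L               # ties: no winning pair
  r <- rle(winner)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  cum_valid <- c(0, cumsum(as.numeric(valid)))
  out <- list()
  for (k in seq_along(r$values)) {
    p <- r$values[k]
    if (p == 0L) next
    dp <- d2[[p]]
    i1 <- starts[run_start[k]]
    i2 <- starts[run_end[k]] + sw - 1L
    span <- segpos[i1:i2]
    # refine boundaries to the maximal-scoring subsegment: sites where the
    # pair is identical (third differs) score +1, pair mismatches score -2,
    # so the low-divergence core is isolated and flanking background trimmed
    sc <- ifelse(dp[span] == 0L, 1, -2)
    cs <- cumsum(sc)
    prev_min <- cummin(c(0, cs[-length(cs)]))
    gain <- cs - prev_min
    if (max(gain) <= 0) next
    hi <- which.max(gain)
    lo <- which.min(c(0, cs[-length(cs)])[seq_len(hi)])  # 1-based: start index
    b0 <- span[lo]; b1 <- span[hi]
    if (b1 <= b0) next
    inside <- span[span >= b0 & span <= b1]
    out[[length(out) + 1L]] <- data.frame(
      scaffold = scaffold, start = b0 - 1, end = b1,
      pair = pair_names[p], n_snps = length(inside),
      pair_diffs = sum(dp[inside]) / 2,
      block_len = cum_valid[b1 + 1L] - cum_valid[b0],
      stringsAsFactors = FALSE)
  }
  blocks <- if (length(out)) do.call(rbind, out) else empty
  attr(blocks, "pair_site_d2") <- d2
  attr(blocks, "valid") <- valid
  attr(blocks, "pair_names") <- pair_names
  blocks
}

#' Probability of a block's similarity under the background divergence
#'
#' One-sided binomial tail: p = P(X <= pair_diffs) for
#' X ~ Binomial(block_len, background_divergence). A small p marks a block
#' whose pair is far more similar than the genome-wide background for that
#' pair. Half-integer difference counts (from IUPAC half-differences) are
#' floored.
#'
#' @param pair_diffs observed differences within the block (may be
#'   half-integer).
#' @param block_len effective block length (valid positions).
#' @param background_divergence genome-wide per-site divergence of the same
#'   pair outside candidate blocks, in (0, 1).
#' @return p-value(s) in [0, 1]; vectorized.
#' @export
block_p_value <- function(pair_diffs, block_len, background_divergence) {
  if (any(background_divergence <= 0) || any(background_divergence >= 1))
    stop("background divergence must be strictly between 0 and 1")
  if (any(pair_diffs < 0) || any(pair_diffs > block_len))
    stop("pair_diffs must be in [0, block_len]")
  pbinom(floor(pair_diffs), block_len, background_divergence)
}

#' Date a block by the divergence clock
#'
#' Converts a block's pair divergence to an age in years:
#' \code{age = (pair_diffs/block_len) / (2 * mu_year)}.
#'
#' @inheritParams block_p_value
#' @param mu_year per-year mutation rate (default 0.2e-8).
#' @return age in years; vectorized.
#' @examples
#' date_block(8, 1000)  # divergence 0.008 -> 2,000,000 years
#' @export
date_block <- function(pair_diffs, block_len, mu_year = 0.2e-8) {
  (pair_diffs / block_len) / (2 * mu_year)
}

# the most closely related pair among three taxa under a species tree
.sister_pair <- function(triplet, species_tree) {
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else ape::read.tree(text = species_tree)
  if (is.null(tree$edge.length))  # topology-only tree: unit branch lengths
    tree$edge.length <- rep(1, nrow(tree$edge))
  miss <- setdiff(triplet, tree$tip.label)
  if (length(miss))
    stop("triplet member(s) not in species tree: ",
         paste(miss, collapse = ", "))
  d <- ape::cophenetic.phylo(tree)[triplet, triplet]
  diag(d) <- Inf
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  sort(triplet[ij])
}

#' Filter candidate blocks by SNP count, significance and sister removal
#'
#' Retains blocks with at least \code{min_snps} segregating sites and a
#' p-value below \code{max_p}, and removes blocks whose pair is the sister
#' pair of the triplet under the species tree (such blocks are the expected
#' signal of shared ancestry, not introgression).
#'
#' @param blocks block data.frame with \code{n_snps}, \code{p_value} and
#'   \code{pair} columns.
#' @param params a [triplet_params()] object.
#' @param species_tree newick string or \code{ape::phylo} of the species.
#' @param triplet the three sequence names scanned.
#' @return the retained blocks.
#' @export
filter_blocks <- function(blocks, params, species_tree, triplet) {
  sis <- paste(.sister_pair(triplet, species_tree), collapse = ":")
  norm_pair <- vapply(strsplit(blocks$pair, ":", fixed = TRUE),
                      function(x) paste(sort(x), collapse = ":"), "")
  keep <- blocks$n_snps >= params$min_snps & blocks$p_value < params$max_p &
          norm_pair != sis
  out <- blocks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full triplet scan: detect, test, date and filter introgressed blocks
#'
#' Runs [scan_triplet()] per scaffold, estimates each pair's genome-wide
#' background divergence from all valid sites outside candidate block spans,
#' attaches binomial p-values, divergence and clock ages, and applies the
#' retention filters of [filter_blocks()].
#'
#' @param sequences named list (per scaffold) of named character vectors (per
#'   sample) of aligned sequences, as from [consensus_sequences()].
#' @param triplet three sample names to scan.
#' @param params a [triplet_params()] object.
#' @param species_tree newick string or \code{ape::phylo}; when supplied,
#'   sister-pair blocks are removed and the SNP/p-value filters applied.
#' @return data.frame of blocks with divergence, p_value and age_years;
#'   background divergences attached as attribute \code{"background"}.
#' @export
triplet_blocks <- function(sequences, triplet, params = triplet_params(),
                           species_tree = NULL) {
  all_blocks <- list()
  d2_sums <- stats::setNames(numeric(3), NULL)
  valid_tot <- numeric(3)
  pair_names <- NULL
  for (s in names(sequences)) {
    seqs <- sequences[[s]]
    miss <- setdiff(triplet, names(seqs))
    if (length(miss))
      stop("sequence(s) missing for scaffold ", s, ": ",
           paste(miss, collapse = ", "))
    bl <- scan_triplet(seqs[[triplet[1]]], seqs[[triplet[2]]],
                       seqs[[triplet[3]]], params, labels = triplet,
                       scaffold = s)
    d2 <- attr(bl, "pair_site_d2"); valid <- attr(bl, "valid")
    pair_names <- attr(bl, "pair_names")
    # background: valid sites outside candidate block spans of any pair
    outside <- valid
    if (nrow(bl))
      for (k in seq_len(nrow(bl))) {
        idx <- (bl$start[k] + 1L):bl$end[k]
        outside[idx] <- FALSE
      }
    for (p in 1:3) {
      d2_sums[p] <- d2_sums[p] + sum(d2[[p]][outside]) / 2
      valid_tot[p] <- valid_tot[p] + sum(outside)
    }
    attr(bl, "pair_site_d2") <- NULL; attr(bl, "valid") <- NULL
    all_blocks[[s]] <- bl
  }
  blocks <- do.call(rbind, all_blocks)
  rownames(blocks) <- NULL
  background <- stats::setNames(d2_sums / pmax(valid_tot, 1), pair_names)
  if (nrow(blocks)) {
    bg <- background[blocks$pair]
    blocks$divergence <- blocks$pair_diffs / blocks$block_len
    blocks$p_value <- block_p_value(blocks$pair_diffs, blocks$block_len, bg)
    blocks$age_years <- date_block(blocks$pair_diffs, blocks$block_len,
                                   params$mu_year)
  } else {
    blocks$divergence <- numeric(); blocks$p_value <- numeric()
    blocks$age_years <- numeric()
  }
  if (!is.null(species_tree))
    blocks <- filter_blocks(blocks, params, species_tree, triplet)
  attr(blocks, "background") <- background
  blocks
}

#' Summarize retained blocks and their overlap with f_d candidates
#'
#' Reports per-pair block counts, mean block length and mean clock age, and —
#' when candidate regions are supplied — how many candidate regions are hit
#' by at least one block and the number of discrete overlapping sections.
#'
#' @param blocks retained block data.frame from [triplet_blocks()].
#' @param fd_candidates optional candidate regions (an
#'   \code{introscan_candidates} object or region data.frame).
#' @return An object of class \code{introscan_block_summary}.
#' @export
summarize_blocks <- function(blocks, fd_candidates = NULL) {
  per_pair <- if (nrow(blocks)) {
    do.call(rbind, lapply(split(blocks, blocks$pair), function(b)
      data.frame(pair = b$pair[1], n_blocks = nrow(b),
                 mean_length_bp = mean(b$end - b$start),
                 mean_age_years = mean(b$age_years),
                 stringsAsFactors = FALSE)))
  } else data.frame(pair = character(), n_blocks = integer(),
                    mean_length_bp = numeric(), mean_age_years = numeric(),
                    stringsAsFactors = FALSE)
  rownames(per_pair) <- NULL
  ov <- NULL
  if (!is.null(fd_candidates)) {
    cand <- if (inherits(fd_candidates, "introscan_candidates"))
      fd_candidates$regions else fd_candidates
    breg <- if (nrow(blocks)) regions(blocks$scaffold, blocks$start, blocks$end)
            else regions()
    if (nrow(cand) && nrow(breg)) {
      ix <- intersect_regions(cand, breg)
      ov <- list(n_fd_regions = nrow(merge_regions(cand)),
                 n_fd_regions_hit = ix$n_a_hit, n_sections = ix$n_sections,
                 sections = ix$sections)
    } else {
      ov <- list(n_fd_regions = nrow(merge_regions(cand)),
                 n_fd_regions_hit = 0L, n_sections = 0L, sections = regions())
    }
  }
  structure(list(n_blocks = nrow(blocks),
                 mean_length_bp = if (nrow(blocks)) mean(blocks$end - blocks$start) else NA_real_,
                 mean_age_years = if (nrow(blocks)) mean(blocks$age_years) else NA_real_,
                 per_pair = per_pair, overlap = ov),
            class = "introscan_block_summary")
}

#' @export
print.introscan_block_summary <- function(x, ...) {
  cat("Introgressed blocks:", x$n_blocks, "retained")
  if (x$n_blocks)
    cat(sprintf("; mean length %.0f bp, mean age %.3g years",
                x$mean_length_bp, x$mean_age_years))
  cat("\n")
  if (nrow(x$per_pair)) print(x$per_pair, row.names = FALSE)
  if (!is.null(x$overlap))
    cat(sprintf("Overlap with f_d candidates: %d of %d regions hit, %d sections\n",
                x$overlap$n_fd_regions_hit, x$overlap$n_fd_regions,
                x$overlap$n_sections))
  invisible(x)
}
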