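#' ABBA and BABA site-pattern weights
#'
#' Frequency-form site weights for the four-taxon test, computed from derived
#' allele frequencies in populations (P1, P2, P3, O):
#' \code{abba = (1-p1) p2 p3 (1-p4)} and \code{baba = p1 (1-p2) p3 (1-p4)}.
#' With single diploids the frequencies are in \{0, 0.5, 1\} and the weights
#' are exact; after outgroup polarization p4 = 0.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in [0, 1]; vectorized.
#' @return list with numeric vectors \code{abba} and \code{baba}.
#' @examples
#' site_pattern_weights(0, 1, 1, 0)   # pure ABBA site
#' @export
site_pattern_weights <- function(p1, p2, p3, p4 = 0) {
  for (p in list(p1, p2, p3, p4))
    if (any(p < 0 | p > 1)) stop("frequencies must be in [0, 1]")
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

#' Genome-wide Patterson's D
#'
#' D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA) over all retained sites
#' of a polarized site table. A genome-wide excess of ABBA sites (D > 0)
#' indicates gene flow between P2 and P3. Sites where P3 carries no derived
#' allele contribute zero weight and are not counted.
#'
#' @param ptab polarized site table from [polarize()].
#' @param pops character vector naming the (P1, P2, P3) frequency columns; an
#'   optional 4th element naming the outgroup is accepted and ignored (the
#'   outgroup's derived frequency is 0 by construction).
#' @return list with \code{counts} (sum_abba, sum_baba, n_sites) and \code{D}
#'   (NaN with a flag when no informative sites).
#' @export
patterson_d <- function(ptab, pops) {
  if (!nrow(ptab)) stop("empty site table")
  pops3 <- pops[1:3]
  if (!all(pops3 %in% names(ptab)))
    stop("population column(s) absent: ",
         paste(setdiff(pops3, names(ptab)), collapse = ", "))
  w <- site_pattern_weights(ptab[[pops3[1]]], ptab[[pops3[2]]],
                            ptab[[pops3[3]]])
  A <- sum(w$abba); B <- sum(w$baba)
  list(counts = list(sum_abba = A, sum_baba = B,
                     n_sites = sum(ptab[[pops3[3]]] > 0)),
       D = if (A + B > 0) (A - B) / (A + B) else NaN)
}

#' Patterson's D with block-jackknife standard error
#'
#' Partitions the genome into contiguous blocks of \code{block_span_bp} per
#' scaffold, computes delete-one-block estimates of D, and reports the
#' jackknife standard error SE = sqrt((m-1)/m * sum_i (D_-i - mean(D_-))^2)
#' and Z = D/SE. Block resampling makes the standard error robust to linkage.
#'
#' @inheritParams patterson_d
#' @param block_span_bp jackknife block span in bp (default 1 Mb).
#' @return An object of class \code{introscan_d}: list with \code{D},
#'   \code{SE}, \code{Z}, \code{n_blocks}, \code{n_sites}, \code{pop_labels},
#'   \code{se_zero} flag.
#' @export
jackknife_z <- function(ptab, pops, block_span_bp = 1e6) {
  d_all <- patterson_d(ptab, pops)
  scaf_id <- match(ptab$scaffold, unique(ptab$scaffold))
  blk <- (scaf_id - 1) * 2^31 + ptab$pos %/% block_span_bp
  w <- site_pattern_weights(ptab[[pops[1]]], ptab[[pops[2]]], ptab[[pops[3]]])
  sums <- rowsum(cbind(w$abba, w$baba), blk)
  A_i <- sums[, 1]; B_i <- sums[, 2]
  m <- nrow(sums)
  if (m < 20)
    stop("only ", m, " non-empty jackknife blocks; need >= 20 ",
         "(use more data or a smaller block_span_bp)")
  A <- sum(A_i); B <- sum(B_i)
  denom <- (A - A_i) + (B - B_i)
  if (any(denom == 0)) stop("a delete-one block leaves no informative sites")
  D_del <- ((A - A_i) - (B - B_i)) / denom
  SE <- sqrt((m - 1) / m * sum((D_del - mean(D_del))^2))
  se_zero <- SE == 0
  Z <- if (se_zero) sign(d_all$D) * Inf else d_all$D / SE
  structure(list(D = d_all$D, SE = SE, Z = Z, n_blocks = m,
                 n_sites = d_all$counts$n_sites,
                 sum_abba = A, sum_baba = B,
                 pop_labels = pops, se_zero = se_zero),
            class = "introscan_d")
}

#' @export
print.introscan_d <- function(x, ...) {
  lab <- x$pop_labels
  cat(sprintf("Patterson's D  (P1=%s, P2=%s, P3=%s)\n", lab[1], lab[2], lab[3]))
  cat(sprintf("  D = %.4g  SE = %.4g  Z = %.3f  (%d blocks, %d sites)\n",
              x$D, x$SE, x$Z, x$n_blocks, x$n_sites))
  if (x$se_zero) cat("  note: jackknife SE is zero; Z reported as +/-Inf\n")
  invisible(x)
}
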