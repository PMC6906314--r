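#' Per-site f_d numerator and denominator terms
#'
#' The f_d admixture-proportion estimator normalizes the ABBA-BABA excess by
#' its maximum under complete introgression with a dynamically chosen donor:
#' \code{num = abba(p1,p2,p3,p4) - baba(p1,p2,p3,p4)} and
#' \code{den = abba(p1,pD,pD,p4) - baba(p1,pD,pD,p4)} with
#' \code{pD = max(p2, p3)} site-wise.
#'
#' @inheritParams site_pattern_weights
#' @return list with numeric vectors \code{num} and \code{den}.
#' @examples
#' fd_site_terms(0, 0.5, 1, 0)  # num = 0.5, den = 1
#' @export
fd_site_terms <- function(p1, p2, p3, p4 = 0) {
  w <- site_pattern_weights(p1, p2, p3, p4)
  pD <- pmax(p2, p3)
  wD <- site_pattern_weights(p1, pD, pD, p4)
  list(num = w$abba - w$baba, den = wD$abba - wD$baba)
}

#' Sliding-window f_d scan
#'
#' Computes f_d = sum(num)/sum(den) and the window D from the same sites in
#' sliding windows of \code{win} bp advanced by \code{step} bp per scaffold.
#' Windows whose D is not positive, or whose denominator is not positive, get
#' f_d = 0 with \code{fd_undefined = TRUE}; windows containing no SNPs are
#' omitted.
#'
#' @inheritParams patterson_d
#' @param win window span in bp (default 40 kb).
#' @param step step size in bp (default 10 kb); must divide \code{win}.
#' @return data.frame of windows: scaffold, start, end, n_snps, sum_num,
#'   sum_den, window_D, f_d, fd_undefined, masked (initialized FALSE).
#' @export
window_fd <- function(ptab, pops, win = 40000, step = 10000) {
  if (win <= 0 || step <= 0 || win < step || win %% step != 0)
    stop("need win >= step > 0 with step dividing win")
  ft <- fd_site_terms(ptab[[pops[1]]], ptab[[pops[2]]], ptab[[pops[3]]])
  w <- site_pattern_weights(ptab[[pops[1]]], ptab[[pops[2]]], ptab[[pops[3]]])
  k <- win %/% step
  out <- lapply(split(seq_len(nrow(ptab)), ptab$scaffold), function(idx) {
    pos <- ptab$pos[idx]
    bin <- pos %/% step
    nb <- max(bin) + 1L
    num_b <- .bin_sum(ft$num[idx], bin, nb)
    den_b <- .bin_sum(ft$den[idx], bin, nb)
    abba_b <- .bin_sum(w$abba[idx], bin, nb)
    baba_b <- .bin_sum(w$baba[idx], bin, nb)
    cnt_b <- .bin_sum(rep(1, length(idx)), bin, nb)
    starts <- (seq_len(nb) - 1L) * step           # window start bins
    num_w <- .runsum(num_b, k); den_w <- .runsum(den_b, k)
    abba_w <- .runsum(abba_b, k); baba_w <- .runsum(baba_b, k)
    n_w <- .runsum(cnt_b, k)
    keep <- n_w > 0
    wD <- ifelse(abba_w + baba_w > 0, (abba_w - baba_w) / (abba_w + baba_w), 0)
    fd <- ifelse(wD > 0 & den_w > 0, num_w / den_w, 0)
    data.frame(scaffold = ptab$scaffold[idx[1]], start = starts[keep],
               end = starts[keep] + win, n_snps = n_w[keep],
               sum_num = num_w[keep], sum_den = den_w[keep],
               window_D = wD[keep], f_d = fd[keep],
               fd_undefined = !(wD[keep] > 0 & den_w[keep] > 0),
               masked = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  attr(out, "win") <- win; attr(out, "step") <- step
  attr(out, "scaffold_lengths") <- attr(ptab, "scaffold_lengths")
  out
}

.bin_sum <- function(x, bin, nb) {
  out <- numeric(nb)
  s <- rowsum(x, bin)
  out[as.integer(rownames(s)) + 1L] <- as.numeric(s)
  out
}

# sum over runs of k consecutive bins, aligned to each possible window start
.runsum <- function(x, k) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  idx_hi <- pmin(seq_len(n) + k - 1L, n)
  cs[idx_hi + 1L] - cs[seq_len(n)]
}

#' Mask f_d windows by coverage-filter failure fraction
#'
#' A window is masked when strictly more than \code{max_fail_frac} of its
#' sites fail the coverage filter; a window at exactly the threshold is kept.
#' Masked windows are excluded from quantile and candidate calling.
#'
#' @param windows window table from [window_fd()].
#' @param mask per-site mask from [coverage_mask()].
#' @param max_fail_frac maximum tolerated failing-site fraction (default 0.30).
#' @return the window table with \code{masked} and \code{fail_frac} updated.
#' @export
apply_window_mask <- function(windows, mask, max_fail_frac = 0.30) {
  win <- attr(windows, "win"); step <- attr(windows, "step")
  fail_frac <- numeric(nrow(windows))
  for (s in unique(windows$scaffold)) {
    wi <- which(windows$scaffold == s)
    ms <- mask[mask$scaffold == s, , drop = FALSE]
    if (!nrow(ms)) next
    bin <- ms$pos %/% step
    nb <- max(bin, windows$start[wi] %/% step) + 1L
    k <- win %/% step
    fail_b <- .bin_sum(as.numeric(ms$fail), bin, nb)
    tot_b <- .bin_sum(rep(1, nrow(ms)), bin, nb)
    fail_w <- .runsum(fail_b, k); tot_w <- .runsum(tot_b, k)
    wstart_bin <- windows$start[wi] %/% step + 1L
    ff <- ifelse(tot_w[wstart_bin] > 0, fail_w[wstart_bin] / tot_w[wstart_bin], 0)
    fail_frac[wi] <- ff
  }
  windows$fail_frac <- fail_frac
  windows$masked <- fail_frac > max_fail_frac
  windows
}

#' Call candidate introgression regions from an f_d scan
#'
#' Takes the top tail of the genome-wide f_d distribution over unmasked
#' windows: the cutoff is the smallest value such that the top
#' \code{(1 - quantile)} fraction of windows (by count, ties kept) lies at or
#' above it. Selected windows are merged and clipped to scaffold ends.
#'
#' @param windows window table from [window_fd()] (optionally masked by
#'   [apply_window_mask()]).
#' @param quantile genome-wide quantile defining the cutoff; the default
#'   0.9995 takes the top 0.05 percent of windows.
#' @param scaffold_lengths named vector of scaffold lengths; defaults to the
#'   lengths carried by the window table.
#' @return An object of class \code{introscan_candidates}: list with
#'   \code{cutoff_value}, \code{regions} (merged, clipped), \code{windows}
#'   (the selected source windows), \code{n_selected}, \code{quantile}.
#' @export
call_candidates <- function(windows, quantile = 0.9995,
                            scaffold_lengths = attr(windows, "scaffold_lengths")) {
  unm <- windows[!windows$masked, , drop = FALSE]
  if (!nrow(unm)) stop("all windows are masked")
  n <- nrow(unm)
  if (n < 2000)
    warning("only ", n, " unmasked windows; an extreme-tail cutoff is ",
            "poorly determined")
  # top-tail count; small epsilon guards the floor against float error
  k <- max(1L, as.integer(floor(n * (1 - quantile) + 1e-9)))
  cutoff <- sort(unm$f_d, decreasing = TRUE)[k]
  sel <- unm[unm$f_d >= cutoff, , drop = FALSE]
  reg <- regions(sel$scaffold, sel$start, sel$end)
  if (!is.null(scaffold_lengths))
    reg <- clip_to_scaffold(reg, scaffold_lengths)
  reg <- merge_regions(reg)
  structure(list(cutoff_value = cutoff, regions = reg, windows = sel,
                 n_selected = nrow(sel), quantile = quantile),
            class = "introscan_candidates")
}

#' @export
print.introscan_candidates <- function(x, ...) {
  cat(sprintf(
    "f_d candidates: cutoff %.4g (quantile %.4f), %d windows -> %d regions, %s bp\n",
    x$cutoff_value, x$quantile, x$n_selected, nrow(x$regions),
    format(region_span(x$regions), big.mark = ",")))
  invisible(x)
}
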