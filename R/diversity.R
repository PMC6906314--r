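#' Sliding-window heterozygosity for one individual
#'
#' Counts heterozygous genotype calls per window and divides by the window
#' span minus the number of missing genotype calls. Positions absent from the
#' genotype table are treated as genotyped homozygous-reference (the usual
#' all-sites assumption for a jointly called VCF). Windows are non-overlapping
#' by default; set \code{step} for overlapping windows.
#'
#' @param gt genotype table (see [read_vcf_biallelic()]).
#' @param sample focal sample name.
#' @param win window span in bp (default 100 kb).
#' @param step window step in bp (default \code{win}: non-overlapping).
#' @param scaffold_lengths named vector of scaffold lengths; defaults to the
#'   lengths carried by the genotype table.
#' @param joint_missing when TRUE a site counts as missing if \emph{any}
#'   sample's call is missing (the cross-species rule); default counts only
#'   the focal sample's missing calls.
#' @return data.frame: scaffold, start, end, span, n_het, n_missing, het
#'   (NA with \code{undefined = TRUE} when a window has no callable sites).
#' @export
window_heterozygosity <- function(gt, sample, win = 100000, step = win,
                                  scaffold_lengths = attr(gt, "scaffold_lengths"),
                                  joint_missing = FALSE) {
  if (win <= 0 || step <= 0 || step > win || win %% step != 0)
    stop("need win >= step > 0 with step dividing win")
  if (!sample %in% names(gt)) stop("sample not present: ", sample)
  if (is.null(scaffold_lengths))
    stop("scaffold_lengths required (none attached to the genotype table)")
  g <- gt[[sample]]
  is_het <- !is.na(g) & g == 1L
  is_mis <- if (joint_missing) {
    samp <- setdiff(names(gt), c("scaffold", "pos", "ref", "alt", "n_alleles"))
    Reduce(`|`, lapply(samp, function(s) is.na(gt[[s]])))
  } else is.na(g)
  k <- win %/% step
  out <- lapply(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    idx <- which(gt$scaffold == s)
    nb <- as.integer((L - 1) %/% step) + 1L
    het_b <- mis_b <- numeric(nb)
    if (length(idx)) {
      bin <- gt$pos[idx] %/% step
      het_b <- .bin_sum(as.numeric(is_het[idx]), bin, nb)
      mis_b <- .bin_sum(as.numeric(is_mis[idx]), bin, nb)
    }
    starts <- (seq_len(nb) - 1L) * step
    n_het <- .runsum(het_b, k); n_mis <- .runsum(mis_b, k)
    span <- pmin(starts + win, L) - starts
    callable <- span - n_mis
    data.frame(scaffold = s, start = starts, end = pmin(starts + win, L),
               span = span, n_het = n_het, n_missing = n_mis,
               het = ifelse(callable > 0, n_het / callable, NA_real_),
               undefined = callable <= 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genome-wide heterozygosity summaries
#'
#' Reports both the unweighted mean of defined windows' heterozygosity and
#' the pooled estimate sum(n_het) / sum(span - n_missing), which weights
#' windows by their callable length and is invariant to window size.
#'
#' @param windows window table from [window_heterozygosity()].
#' @return list with \code{mean_window_het} and \code{pooled_het}.
#' @export
genome_mean_het <- function(windows) {
  ok <- !windows$undefined
  if (!any(ok)) stop("no windows with callable sites")
  list(mean_window_het = mean(windows$het[ok]),
       pooled_het = sum(windows$n_het[ok]) /
                    sum(windows$span[ok] - windows$n_missing[ok]))
}
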