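#' Allele-sharing distance matrix for one window
#'
#' For each pair of individuals, the mean over sites of |f_i - f_j| where f
#' are within-individual alternate (or derived) allele frequencies in
#' \{0, 0.5, 1\}. This p-distance plays the role of the per-region similarity
#' matrix in local-phylogeny segmentation.
#'
#' @param freqs numeric matrix or data.frame of per-site frequencies, one
#'   column per individual (missing values excluded pairwise).
#' @return symmetric distance matrix with zero diagonal.
#' @export
window_distance_matrix <- function(freqs) {
  f <- as.matrix(freqs)
  n <- ncol(f)
  d <- matrix(0, n, n, dimnames = list(colnames(f), colnames(f)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- abs(f[, i] - f[, j])
    d[i, j] <- d[j, i] <- mean(dd, na.rm = TRUE)
  }
  d
}

#' Quartet topology by the four-point condition
#'
#' For four taxa in the fixed order (A, B, C, D), the neighbor-joining split
#' is the pairing \{i,j\}|\{k,l\} minimizing d(i,j) + d(k,l). Labels follow
#' the species-tree reading: T1 = (A,B)|(C,D) (the concordant topology),
#' T2 = (C,A)|(B,D), T3 = (C,B)|(A,D); ties are unresolved (U).
#'
#' @param d 4x4 distance matrix with taxa in order (A, B, C, D).
#' @return one of \code{"T1"}, \code{"T2"}, \code{"T3"}, \code{"U"}.
#' @export
nj_quartet <- function(d) {
  stopifnot(nrow(d) == 4, ncol(d) == 4)
  s <- c(T1 = d[1, 2] + d[3, 4],  # (A,B)|(C,D)
         T2 = d[1, 3] + d[2, 4],  # (A,C)|(B,D)
         T3 = d[2, 3] + d[1, 4])  # (B,C)|(A,D)
  if (sum(s == min(s)) > 1) "U" else names(s)[which.min(s)]
}

#' Windowed quartet-topology classification
#'
#' Classifies non-overlapping windows by the NJ quartet topology of the four
#' ingroup individuals, a transparent surrogate for HMM-based local-phylogeny
#' segmentation: the deliverable is the genome fraction per local
#' relationship, not the HMM itself. Windows with fewer than \code{min_snps}
#' sites are labeled U.
#'
#' @param tab polarized site table or genotype-frequency table with columns
#'   \code{scaffold}, \code{pos} and one frequency column per individual.
#' @param taxa four column names in species-tree order (A, B, C, D): the two
#'   sisters first.
#' @param win window span in bp (default 100 kb).
#' @param min_snps minimum sites to classify a window (default 50).
#' @param scaffold_lengths named vector of scaffold lengths; defaults to the
#'   lengths carried by the table.
#' @return data.frame: scaffold, start, end, n_snps, label.
#' @export
window_topologies <- function(tab, taxa, win = 100000, min_snps = 50,
                              scaffold_lengths = attr(tab, "scaffold_lengths")) {
  if (length(taxa) != 4 || !all(taxa %in% names(tab)))
    stop("taxa must name four frequency columns of the table")
  if (is.null(scaffold_lengths))
    stop("scaffold_lengths required (none attached to the table)")
  f <- as.matrix(tab[, taxa])
  out <- lapply(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    idx <- which(tab$scaffold == s)
    nw <- as.integer((L - 1) %/% win) + 1L
    starts <- (seq_len(nw) - 1L) * win
    labs <- character(nw); nsnp <- integer(nw)
    wof <- if (length(idx)) tab$pos[idx] %/% win + 1L else integer()
    for (wi in seq_len(nw)) {
      rows <- idx[wof == wi]
      nsnp[wi] <- length(rows)
      labs[wi] <- if (length(rows) < min_snps) "U"
                  else nj_quartet(window_distance_matrix(f[rows, , drop = FALSE]))
    }
    data.frame(scaffold = s, start = starts, end = pmin(starts + win, L),
               n_snps = nsnp, label = labs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  out
}

#' Fuse same-topology windows into segments and report genome fractions
#'
#' Consecutive windows of a scaffold carrying the same label are fused into
#' segments; fractions of windowed genome per label (over T1, T2, T3, U, by
#' bp) sum to 1.
#'
#' @param window_labels table from [window_topologies()].
#' @return list with \code{segments} (scaffold, start, end, label, n_windows)
#'   and \code{fractions} (named numeric over T1, T2, T3, U).
#' @export
segment_topologies <- function(window_labels) {
  segs <- lapply(split(window_labels, window_labels$scaffold), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    r <- rle(w$label)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    data.frame(scaffold = w$scaffold[1], start = w$start[lo], end = w$end[hi],
               label = r$values, n_windows = r$lengths,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs[order(names(segs))])
  rownames(segs) <- NULL
  bp <- tapply(window_labels$end - window_labels$start, window_labels$label, sum)
  fractions <- stats::setNames(numeric(4), c("T1", "T2", "T3", "U"))
  fractions[names(bp)] <- bp / sum(bp)
  list(segments = segs, fractions = fractions)
}
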