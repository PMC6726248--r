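# Position weight matrices for splice signals, conservation-window
# summaries, intron length distributions and their two-sample comparison.

#' Build a position weight matrix from aligned sequences
#'
#' Column probabilities are `(count + pseudocount) / (total + 4 *
#' pseudocount)` over `{A,C,G,T}`; `N` contributes nothing to its column.
#' The default pseudocount of 0 reproduces raw-count logos.
#'
#' @param sequences Character vector (or `DNAStringSet`) of equal-length
#'   sequences over `{A,C,G,T,N}`.
#' @param pseudocount Nonnegative pseudocount.
#' @return A 4 x width numeric matrix (rows A, C, G, T) of class `"pwm"`
#'   with attributes `n_sequences` and `pseudocount`.
#' @export
build_pwm <- function(sequences, pseudocount = 0) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("cannot build a PWM from zero sequences")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("PWM input sequences must have equal lengths")
  if (w == 0L) stop("PWM input sequences must be nonempty")
  stopifnot(pseudocount >= 0)
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = bases))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- bases
  totals <- colSums(counts)
  prob <- sweep(counts + pseudocount, 2, totals + 4 * pseudocount, "/")
  structure(prob, class = c("pwm", "matrix"),
            n_sequences = length(sequences), pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM over", ncol(x), "positions from", attr(x, "n_sequences"),
      "sequences (pseudocount", attr(x, "pseudocount"), ")\n")
  print(unclass(x))
  invisible(x)
}

#' Mean conservation score in a window around a signal anchor
#'
#' Arithmetic mean over *scored* positions only within
#' `[pos - upstream, pos + downstream]`; `NaN` when no position in the
#' window is scored.
#'
#' @param track A phastCons-mode `"CoverageTrack"`.
#' @param chrom Chromosome.
#' @param pos Genomic anchor position (1-based).
#' @param upstream,downstream Window half-widths in nt (default 10/10).
#' @return Mean score in \[0, 1\], or `NaN`.
#' @export
conservation_window_mean <- function(track, chrom, pos, upstream = 10L,
                                     downstream = 10L) {
  stopifnot(track$mode == "phastcons")
  from <- max(1L, pos - upstream)
  v <- track_values(track, chrom, from, pos + downstream)
  if (!any(v$scored)) return(NaN)
  mean(v$values[v$scored])
}

#' Conservation windows at the three splice signals of each event
#'
#' For every event, averages phastCons scores in windows anchored on the
#' first intron base (5'ss), the branch A, and the last intron base (3'ss).
#' Anchors honor strand (on minus-strand events the 5'ss anchor is the
#' interval end).
#'
#' @param events Event data.frame with `chrom`, `start`, `end`, `strand`,
#'   `bp_index` (0-based within the oriented intron).
#' @param track phastCons `"CoverageTrack"`.
#' @param half_width Window half-width each side of the anchor (nt).
#' @return data.frame with `cons_5ss`, `cons_bp`, `cons_3ss`.
#' @export
conservation_windows <- function(events, track, half_width = 10L) {
  n <- nrow(events)
  res <- data.frame(cons_5ss = rep(NaN, n), cons_bp = rep(NaN, n),
                    cons_3ss = rep(NaN, n))
  for (i in seq_len(n)) {
    minus <- events$strand[i] == "-"
    p5 <- if (minus) events$end[i] else events$start[i]
    p3 <- if (minus) events$start[i] else events$end[i]
    bp <- events$bp_index[i]
    pbp <- if (is.na(bp)) NA else if (minus) events$end[i] - bp else events$start[i] + bp
    res$cons_5ss[i] <- conservation_window_mean(track, events$chrom[i], p5,
                                                half_width, half_width)
    res$cons_3ss[i] <- conservation_window_mean(track, events$chrom[i], p3,
                                                half_width, half_width)
    if (!is.na(pbp)) {
      res$cons_bp[i] <- conservation_window_mean(track, events$chrom[i], pbp,
                                                 half_width, half_width)
    }
  }
  res
}

#' Histogram of intron lengths
#'
#' Counts per half-open bin `[k*w, (k+1)*w)`.
#'
#' @param lengths Positive integer lengths.
#' @param bin_width Bin width in nt.
#' @return data.frame with `bin_start`, `bin_end`, `count` (empty bins
#'   between occupied ones included).
#' @export
length_histogram <- function(lengths, bin_width = 50L) {
  stopifnot(length(lengths) >= 1L, all(lengths >= 1L), bin_width >= 1L)
  bin <- lengths %/% bin_width
  bins <- seq(0L, max(bin))
  counts <- tabulate(bin + 1L, nbins = max(bin) + 1L)
  data.frame(bin_start = bins * bin_width,
             bin_end = (bins + 1L) * bin_width,
             count = counts)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled data points of the absolute ECDF
#' difference. The p-value uses the asymptotic two-sample Kolmogorov
#' distribution `Q(sqrt(ne) * D)` with effective size
#' `ne = n_a * n_b / (n_a + n_b)`, where
#' `Q(t) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)`.
#'
#' @param a,b Numeric samples (nonempty).
#' @return List with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  pooled <- sort(unique(c(a, b)))
  ea <- vapply(pooled, function(x) mean(a <= x), numeric(1))
  eb <- vapply(pooled, function(x) mean(b <= x), numeric(1))
  D <- max(abs(ea - eb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  t <- sqrt(ne) * D
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  list(D = D, p_value = min(1, max(0, p)))
}

#' Build splice-signal PWMs for a set of events
#'
#' Extracts the oriented 5'ss window (first `w5` intron bases), the
#' branchpoint window (5 nt upstream through 2 nt downstream of the branch
#' A) and the 3'ss window (last `w3` intron bases) of each event and builds
#' one PWM per signal. Events without a branchpoint call contribute to the
#' splice-site PWMs only.
#'
#' @param events Event data.frame (needs `chrom`, `start`, `end`, `strand`,
#'   `bp_index`).
#' @param genome `DNAStringSet`.
#' @param w5,w3 Widths of the 5'ss and 3'ss windows (defaults 6 and 3 nt).
#' @param bp_up,bp_down Branchpoint window flanks (defaults 5 and 2 nt).
#' @param pseudocount PWM pseudocount.
#' @return List with `pwm_5ss`, `pwm_bp`, `pwm_3ss`.
#' @export
signal_pwms <- function(events, genome, w5 = 6L, w3 = 3L, bp_up = 5L,
                        bp_down = 2L, pseudocount = 0) {
  seqs <- intron_sequence(genome, events$chrom, events$start, events$end,
                          events$strand)
  five <- substr(seqs, 1L, w5)
  three <- substr(seqs, nchar(seqs) - w3 + 1L, nchar(seqs))
  has_bp <- !is.na(events$bp_index)
  bp_windows <- vapply(which(has_bp), function(i) {
    branchpoint_window(seqs[i], list(branch_index = events$bp_index[i]),
                       upstream = bp_up, downstream = bp_down)
  }, character(1))
  list(pwm_5ss = build_pwm(five, pseudocount),
       pwm_bp = if (length(bp_windows)) build_pwm(bp_windows, pseudocount) else NULL,
       pwm_3ss = build_pwm(three, pseudocount))
}
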