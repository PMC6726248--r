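# Upstream-ORF detection in 5'UTRs and the contingency analysis relating
# 5'UTR introns to uORF presence.

#' Find upstream ORFs in a 5'UTR sequence
#'
#' Scans every ATG in every frame. In the default strict mode a uORF is
#' called when an in-frame stop codon lies entirely within the UTR and the
#' sense-codon count (ATG through the last sense codon, stop excluded) is at
#' least `min_codons` ("longer than 4 codons"). With
#' `require_stop_in_utr = FALSE`, ATGs whose reading frame runs past the UTR
#' end also count, provided at least `min_codons` sense codons fit within
#' the UTR. Overlapping and nested qualifying ATGs each count as distinct
#' uORFs.
#'
#' @param utr_sequence 5'UTR sequence, transcript orientation, unspliced,
#'   over `{A,C,G,T,N}`.
#' @param min_codons Minimum sense-codon count (default 5).
#' @param require_stop_in_utr Strict mode flag (default `TRUE`).
#' @return data.frame of calls sorted by start: `start` (0-based ATG offset
#'   in the UTR), `frame`, `n_codons`, `stop_offset` (0-based offset of the
#'   stop codon's first base; `NA` in non-strict calls without one).
#' @export
find_uorfs <- function(utr_sequence, min_codons = 5L, require_stop_in_utr = TRUE) {
  seq <- toupper(utr_sequence)
  stopifnot(!grepl("[^ACGTN]", seq))
  len <- nchar(seq)
  empty <- data.frame(start = integer(), frame = integer(),
                      n_codons = integer(), stop_offset = integer())
  if (len < 3L) return(empty)
  m <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  calls <- list()
  for (s in as.integer(m)) {            # 1-based ATG position
    n_sense <- 0L
    stop_off <- NA_integer_
    p <- s
    while (p + 2L <= len) {
      codon <- substr(seq, p, p + 2L)
      if (codon %in% STOP_CODONS) { stop_off <- p - 1L; break }
      n_sense <- n_sense + 1L
      p <- p + 3L
    }
    qualifies <- if (is.na(stop_off)) {
      !require_stop_in_utr && n_sense >= min_codons
    } else {
      n_sense >= min_codons
    }
    if (qualifies) {
      calls[[length(calls) + 1L]] <- data.frame(
        start = s - 1L, frame = (s - 1L) %% 3L,
        n_codons = n_sense, stop_offset = stop_off)
    }
  }
  if (length(calls) == 0L) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$start), , drop = FALSE]
}

#' Select the uORF comparison sets
#'
#' Splits a 5'UTR table into intron-bearing UTRs and the intronless UTRs
#' whose unspliced length falls in the size range of the intron-bearing set
#' (default \[240, 950\] nt, inclusive).
#'
#' @param utrs data.frame with at least `gene`, `length`, `has_intron`.
#' @param range Length-range `c(min, max)` applied to the intronless set.
#' @return List with data.frames `intron_bearing` and `intronless`.
#' @export
select_comparison_set <- function(utrs, range = c(240L, 950L)) {
  stopifnot(all(c("gene", "length", "has_intron") %in% names(utrs)))
  list(intron_bearing = utrs[utrs$has_intron, , drop = FALSE],
       intronless = utrs[!utrs$has_intron &
                           utrs$length >= range[1] & utrs$length <= range[2],
                         , drop = FALSE])
}

#' One-sided Fisher exact test for a 2x2 table
#'
#' Rows: intron-bearing / intronless UTRs; columns: at least one uORF / no
#' uORF. Returns the hypergeometric tail probability of tables at least as
#' extreme as observed toward uORF enrichment in the first row, computed in
#' log space. Degenerate margins give p = 1 by convention.
#'
#' @param a,b,c,d Nonnegative integer cells: `a` intron-bearing with uORF,
#'   `b` intron-bearing without, `c` intronless with uORF, `d` intronless
#'   without.
#' @return The one-sided p-value.
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0L || c1 == 0L || n == 0L || r1 == n || c1 == n) return(1)
  kmax <- min(r1, c1)
  ks <- a:kmax
  logp <- lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1)
  mx <- max(logp)
  exp(mx + log(sum(exp(logp - mx))))
}

#' Are all uORFs of a UTR removed by splicing?
#'
#' `TRUE` iff every uORF's ATG lies within the intron interval: excising
#' the start codon abolishes the uORF, so a uORF straddling the intron's 3'
#' boundary with its ATG inside still counts as removed.
#'
#' @param calls A [find_uorfs()] data.frame.
#' @param intron_interval `c(start, end)` 0-based offsets of the intron
#'   within the UTR (closed interval of removed bases).
#' @return Logical; `TRUE` for a UTR with no uORFs.
#' @export
uorfs_removed_by_splicing <- function(calls, intron_interval) {
  stopifnot(length(intron_interval) == 2L)
  if (nrow(calls) == 0L) return(TRUE)
  all(calls$start >= intron_interval[1] & calls$start <= intron_interval[2])
}

#' uORF contingency analysis over a UTR set
#'
#' Builds the 2x2 table (intron-bearing / intronless x with / without
#' uORFs) over the comparison sets and computes the one-sided Fisher exact
#' p-value for uORF enrichment among intron-bearing UTRs.
#'
#' @param utrs data.frame with `gene`, `sequence`, `length`, `has_intron`,
#'   and (for intron-bearing rows) `intron_start`, `intron_end` (0-based
#'   offsets within the UTR).
#' @param range Intronless length range (see [select_comparison_set()]).
#' @param min_codons Minimum uORF sense codons.
#' @param require_stop_in_utr Strict uORF mode.
#' @return List with `table` (2x2 matrix), `p_value`, and `per_utr`
#'   (data.frame with `gene`, `has_intron`, `n_uorfs`, `all_removed`).
#' @export
uorf_contingency <- function(utrs, range = c(240L, 950L), min_codons = 5L,
                             require_stop_in_utr = TRUE) {
  sets <- select_comparison_set(utrs, range)
  score <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(gene = character(), has_intron = logical(),
                        n_uorfs = integer(), all_removed = logical()))
    }
    res <- lapply(seq_len(nrow(df)), function(i) {
      calls <- find_uorfs(df$sequence[i], min_codons, require_stop_in_utr)
      removed <- if (df$has_intron[i]) {
        uorfs_removed_by_splicing(calls, c(df$intron_start[i], df$intron_end[i]))
      } else NA
      data.frame(gene = df$gene[i], has_intron = df$has_intron[i],
                 n_uorfs = nrow(calls), all_removed = removed)
    })
    do.call(rbind, res)
  }
  per_utr <- rbind(score(sets$intron_bearing), score(sets$intronless))
  with_i <- per_utr[per_utr$has_intron, , drop = FALSE]
  wout_i <- per_utr[!per_utr$has_intron, , drop = FALSE]
  tab <- matrix(c(sum(with_i$n_uorfs > 0), sum(with_i$n_uorfs == 0),
                  sum(wout_i$n_uorfs > 0), sum(wout_i$n_uorfs == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("intron_bearing", "intronless"),
                                c("uorf", "no_uorf")))
  p <- fisher_exact_one_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, p_value = p, per_utr = per_utr)
}
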