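# Junction/intron/exon2 coverage summaries, the three log2 splicing indices,
# their between-condition deltas, percent-spliced, and the transcript-level
# fold-change gate used when reporting.

#' Reporting thresholds for the splicing-change display filter
#'
#' Standard introns are displayed with at least 35 total junction reads,
#' protointrons with at least 50, and only for locations whose total
#' transcript level changes less than `max_fold` between conditions.
#'
#' @param min_reads_standard,min_reads_protointron Junction-read floors.
#' @param max_fold Maximum transcript-level fold change (exclusive).
#' @return A list of class `"DeltaReportParams"`.
#' @export
delta_report_params <- function(min_reads_standard = 35L,
                                min_reads_protointron = 50L,
                                max_fold = 2) {
  stopifnot(min_reads_standard > 0L, min_reads_protointron > 0L, max_fold > 0)
  structure(list(min_reads_standard = as.integer(min_reads_standard),
                 min_reads_protointron = as.integer(min_reads_protointron),
                 max_fold = max_fold),
            class = "DeltaReportParams")
}

#' Minimal intron of an overlap-connected interval cluster
#'
#' Returns the intersection \[max(starts), min(ends)\]: the most downstream
#' start paired with the most upstream end of the overlapping introns.
#' An empty intersection is an error; callers must split such clusters.
#'
#' @param starts,ends Integer vectors of member interval starts/ends
#'   (1-based closed).
#' @return `c(start, end)` of the minimal intron.
#' @export
minimal_intron <- function(starts, ends) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  s <- max(starts); e <- min(ends)
  if (s > e) stop("empty minimal intron: intervals do not all overlap")
  c(start = s, end = e)
}

#' Coverage summary for one intron location in one condition
#'
#' `J` is the junction read count for the condition; `I` is the mean per-base
#' depth across the minimal intron (absent positions count as zero depth);
#' `E2` is the mean depth over the 100 bases of downstream exon immediately
#' past the most downstream 3' splice site, truncated (with a flag) at the
#' transcript boundary.
#'
#' @param chrom Chromosome.
#' @param start,end Minimal-intron interval (1-based closed).
#' @param strand `"+"` or `"-"`.
#' @param track A depth-mode `"CoverageTrack"`.
#' @param J Junction read count for this condition.
#' @param most_downstream_3p Genomic position of the most downstream 3'
#'   splice site among the location's events (defaults to the minimal-intron
#'   boundary).
#' @param exon2_width Downstream exon window width (nt).
#' @param transcript_bounds Optional `c(start, end)` of the host transcript
#'   used to truncate the exon2 window.
#' @return List of class `"CoverageSummary"`: `J`, `I`, `E2`,
#'   `e2_truncated`.
#' @export
coverage_summary <- function(chrom, start, end, strand, track, J,
                             most_downstream_3p = NULL, exon2_width = 100L,
                             transcript_bounds = NULL) {
  stopifnot(track$mode == "depth", end >= start)
  iv <- track_values(track, chrom, start, end)
  I <- mean(iv$values)
  if (is.null(most_downstream_3p)) {
    most_downstream_3p <- if (strand == "-") start else end
  }
  if (strand == "-") {
    e2_to <- most_downstream_3p - 1L
    e2_from <- e2_to - exon2_width + 1L
    if (!is.null(transcript_bounds)) e2_from <- max(e2_from, transcript_bounds[1])
    e2_from_clip <- max(1L, e2_from)
    truncated <- e2_from != e2_to - exon2_width + 1L || e2_from_clip != e2_from
    e2_from <- e2_from_clip
  } else {
    e2_from <- most_downstream_3p + 1L
    e2_to <- e2_from + exon2_width - 1L
    if (!is.null(transcript_bounds)) e2_to <- min(e2_to, transcript_bounds[2])
    truncated <- e2_to != e2_from + exon2_width - 1L
  }
  if (e2_to < e2_from) {
    E2 <- NA_real_; truncated <- TRUE
  } else {
    ev <- track_values(track, chrom, e2_from, e2_to)
    E2 <- mean(ev$values)
  }
  structure(list(J = J, I = I, E2 = E2, e2_truncated = truncated),
            class = "CoverageSummary")
}

#' The three log2 splicing indices
#'
#' `log2(I/E2)`, `log2(J/E2)` and `log2(J/I)`; an index is defined only when
#' both of its terms are strictly positive (no pseudocounts: undefined
#' values propagate as `NA`).
#'
#' @param summary A `"CoverageSummary"` (or list with `J`, `I`, `E2`).
#' @return List of class `"SplicingIndices"`: `intron_exon2`,
#'   `junction_exon2`, `junction_intron`.
#' @export
splicing_indices <- function(summary) {
  l2 <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b) || a <= 0 || b <= 0) {
      NA_real_
    } else log2(a / b)
  }
  structure(list(intron_exon2 = l2(summary$I, summary$E2),
                 junction_exon2 = l2(summary$J, summary$E2),
                 junction_intron = l2(summary$J, summary$I)),
            class = "SplicingIndices")
}

#' Between-condition change in the splice-junction index
#'
#' `log2(J60/I60) - log2(J0/I0)`; positive values indicate increased
#' splicing after treatment. `NA` when either index is undefined.
#'
#' @param t0,t60 `"CoverageSummary"` objects for the two conditions.
#' @return Numeric delta or `NA`.
#' @export
delta_sj_index <- function(t0, t60) {
  i0 <- splicing_indices(t0)$junction_intron
  i60 <- splicing_indices(t60)$junction_intron
  if (is.na(i0) || is.na(i60)) return(NA_real_)
  i60 - i0
}

#' Percent spliced
#'
#' `100 * J / (J + I)`: the bounded splicing-efficiency estimator comparing
#' junction reads with mean intron base coverage. Undefined (`NA`) when
#' `J + I = 0`.
#'
#' @param summary A `"CoverageSummary"` (or list with `J` and `I`).
#' @return Percent in \[0, 100\] or `NA`.
#' @export
percent_spliced <- function(summary) {
  J <- summary$J; I <- summary$I
  if (is.na(J) || is.na(I) || J + I <= 0) return(NA_real_)
  100 * J / (J + I)
}

#' Median-of-ratios size factors
#'
#' For a genes x libraries count matrix, each library's size factor is the
#' median across genes of its counts divided by the per-gene geometric mean,
#' computed over genes with nonzero counts in every library.
#'
#' @param counts Integer matrix, genes in rows, libraries in columns.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  log_counts <- log(counts)
  use <- rowSums(is.finite(log_counts)) == ncol(counts)
  if (!any(use)) stop("no gene has nonzero counts in every library")
  log_geo <- rowMeans(log_counts[use, , drop = FALSE])
  apply(log_counts[use, , drop = FALSE], 2,
        function(lc) exp(median(lc - log_geo)))
}

#' Transcript-level fold change between conditions
#'
#' Normalizes per-gene exonic counts by median-of-ratios size factors, then
#' returns the per-gene ratio of mean normalized t60 counts to mean
#' normalized t0 counts, plus a flag for genes passing the display gate
#' (fold change strictly inside `(1/max_fold, max_fold)`).
#'
#' @param counts Genes x libraries count matrix.
#' @param condition Character vector (`"t0"`/`"t60"`) per column.
#' @param max_fold Gate width (default 2).
#' @return data.frame with `gene`, `fold_change`, `passes`.
#' @export
transcript_fold_change <- function(counts, condition, max_fold = 2) {
  stopifnot(ncol(counts) == length(condition),
            all(condition %in% c("t0", "t60")))
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  m0 <- rowMeans(norm[, condition == "t0", drop = FALSE])
  m60 <- rowMeans(norm[, condition == "t60", drop = FALSE])
  fold <- m60 / m0
  data.frame(gene = if (!is.null(rownames(counts))) rownames(counts)
             else as.character(seq_len(nrow(counts))),
             fold_change = fold,
             passes = is.finite(fold) & fold > 1 / max_fold & fold < max_fold,
             stringsAsFactors = FALSE)
}

#' Quantify splicing at intron locations across two conditions
#'
#' For each location, computes the minimal intron over its member events,
#' per-condition coverage summaries, the three indices, the delta SJ index
#' and percent spliced, plus the display-filter flag from
#' [delta_report_params()].
#'
#' @param locations Location data.frame ([merge_events_to_locations()]),
#'   optionally classified.
#' @param events Event data.frame the locations were built from.
#' @param tracks Named list of depth `"CoverageTrack"`s, names `"t0"`,
#'   `"t60"`.
#' @param condition_of_library Named character vector mapping library ids
#'   (as used in `reads.<lib>` event columns) to conditions.
#' @param is_standard Logical per location: standard-intron (affects the
#'   junction-read display floor).
#' @param report [delta_report_params()].
#' @return data.frame, one row per location, with J/I/E2 per condition, the
#'   indices, `delta_sj`, `percent_spliced_t0`, `percent_spliced_t60` and
#'   `passes_display_filter` (transcript gate not applied here; see
#'   [transcript_fold_change()]).
#' @export
quantify_locations <- function(locations, events, tracks, condition_of_library,
                               is_standard = rep(FALSE, nrow(locations)),
                               report = delta_report_params()) {
  stopifnot(all(c("t0", "t60") %in% names(tracks)))
  lib_cols <- grep("^reads\\.", names(events), value = TRUE)
  libs <- sub("^reads\\.", "", lib_cols)
  stopifnot(all(libs %in% names(condition_of_library)))
  cond <- condition_of_library[libs]
  out <- locations
  for (nm in c("J_t0", "J_t60", "I_t0", "I_t60", "E2_t0", "E2_t60",
               "idx_JI_t0", "idx_JI_t60", "delta_sj",
               "percent_spliced_t0", "percent_spliced_t60")) {
    out[[nm]] <- NA_real_
  }
  out$passes_display_filter <- FALSE
  for (i in seq_len(nrow(locations))) {
    ids <- strsplit(locations$event_ids[i], ",", fixed = TRUE)[[1]]
    mem <- events[events$event_id %in% ids, , drop = FALSE]
    mi <- minimal_intron(mem$start, mem$end)
    strand <- locations$strand[i]
    d3p <- if (strand == "-") min(mem$start) else max(mem$end)
    summaries <- lapply(c(t0 = "t0", t60 = "t60"), function(cd) {
      J <- sum(as.matrix(mem[, lib_cols, drop = FALSE])[, cond == cd, drop = FALSE])
      coverage_summary(locations$chrom[i], mi["start"], mi["end"], strand,
                       tracks[[cd]], J, most_downstream_3p = d3p)
    })
    out$J_t0[i] <- summaries$t0$J; out$J_t60[i] <- summaries$t60$J
    out$I_t0[i] <- summaries$t0$I; out$I_t60[i] <- summaries$t60$I
    out$E2_t0[i] <- summaries$t0$E2; out$E2_t60[i] <- summaries$t60$E2
    out$idx_JI_t0[i] <- splicing_indices(summaries$t0)$junction_intron
    out$idx_JI_t60[i] <- splicing_indices(summaries$t60)$junction_intron
    out$delta_sj[i] <- delta_sj_index(summaries$t0, summaries$t60)
    out$percent_spliced_t0[i] <- percent_spliced(summaries$t0)
    out$percent_spliced_t60[i] <- percent_spliced(summaries$t60)
    floor_i <- if (is_standard[i]) report$min_reads_standard else report$min_reads_protointron
    out$passes_display_filter[i] <- (summaries$t0$J + summaries$t60$J) >= floor_i
  }
  out
}
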