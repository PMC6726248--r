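# Branchpoint search: ordered three-tier degenerate-motif heuristic with
# distance constraints. Motifs use R = A/G, Y = C/T; N in the intron never
# matches. The branch A is the adenosine aligned to the A before the final C
# of the UACUAAC consensus, giving per-motif offsets ACTAA -> 4, RYTRAYR -> 4,
# YTRAY -> 3 (0-based within the motif).

#' Branchpoint search parameters
#'
#' Defaults encode the ordered heuristic used throughout: scan the intron for
#' `ACTAA`, then `RYTRAYR`, then `YTRAY`, stopping at the first tier with a
#' geometrically valid match. A match is valid when the branch A lies at
#' least `min_dist_5p` nt from the intron's 5' end (0-based index >=
#' `min_dist_5p`) and at least `min_dist_3p` nt upstream of the intron's 3'
#' end. Distances are measured from the branch A itself, which keeps the rule
#' independent of motif length.
#'
#' @param min_dist_5p Minimum branch-A distance from the 5' splice site (nt).
#' @param min_dist_3p Minimum branch-A distance to the 3' splice site (nt).
#' @param tiers Ordered character vector of degenerate motifs (IUPAC R/Y
#'   allowed).
#' @param branch_offset Integer 0-based offset of the branch A within each
#'   motif. Each motif must have an A (or R) at its offset.
#' @return A list of class `"BpSearchParams"`.
#' @export
bp_params <- function(min_dist_5p = 45L, min_dist_3p = 7L,
                      tiers = c("ACTAA", "RYTRAYR", "YTRAY"),
                      branch_offset = c(4L, 4L, 3L)) {
  stopifnot(min_dist_5p >= 0L, min_dist_3p >= 0L,
            length(tiers) >= 1L, length(branch_offset) == length(tiers))
  ok_a <- vapply(seq_along(tiers), function(i) {
    substr(tiers[i], branch_offset[i] + 1L, branch_offset[i] + 1L) %in% c("A", "R")
  }, logical(1))
  if (!all(ok_a)) stop("each motif needs A at its branch offset")
  structure(list(min_dist_5p = as.integer(min_dist_5p),
                 min_dist_3p = as.integer(min_dist_3p),
                 tiers = tiers, branch_offset = as.integer(branch_offset)),
            class = "BpSearchParams")
}

#' Single-tier relaxed branchpoint parameters (RYTRAY)
#'
#' Alternative single-tier mode using the relaxed consensus RYURAY (DNA
#' RYTRAY, branch A at offset 4), with the same distance constraints.
#' @inheritParams bp_params
#' @return A `"BpSearchParams"` list.
#' @export
bp_params_relaxed <- function(min_dist_5p = 45L, min_dist_3p = 7L) {
  bp_params(min_dist_5p, min_dist_3p, tiers = "RYTRAY", branch_offset = 4L)
}

degenerate_to_regex <- function(motif) {
  out <- vapply(strsplit(motif, "")[[1]], function(ch) {
    switch(ch, R = "[AG]", Y = "[CT]", A = "A", C = "C", G = "G", T = "T",
           stop("unsupported motif letter: ", ch))
  }, character(1))
  paste0(out, collapse = "")
}

# All (overlapping) 1-based match start positions of a degenerate motif.
motif_match_starts <- function(seq, motif) {
  pat <- paste0("(?=", degenerate_to_regex(motif), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find the best branchpoint in an intron
#'
#' Tiers are scanned in order; within the first tier holding at least one
#' geometrically valid match, the match whose branch A lies closest to the 3'
#' splice site wins. `NULL` is returned when no tier matches (no good match
#' to a branchpoint consensus), including when the intron is too short for
#' any position to satisfy the distance constraints.
#'
#' @param intron_sequence Intron sequence, 5'->3' in transcript orientation,
#'   over `{A,C,G,T,N}`.
#' @param params A [bp_params()] object.
#' @return A list of class `"BranchpointCall"` with `branch_index` (0-based
#'   index of the branch A within the intron), `tier`, `motif` (matched
#'   sequence), `dist5` and `dist3`; or `NULL`.
#' @export
find_branchpoint <- function(intron_sequence, params = bp_params()) {
  stopifnot(is.character(intron_sequence), length(intron_sequence) == 1L)
  seq <- toupper(intron_sequence)
  if (grepl("[^ACGTN]", seq)) stop("intron sequence contains non-ACGTN characters")
  len <- nchar(seq)
  for (t in seq_along(params$tiers)) {
    motif <- params$tiers[t]
    off <- params$branch_offset[t]
    starts <- motif_match_starts(seq, motif)
    if (length(starts) == 0L) next
    branch_idx <- starts - 1L + off               # 0-based branch A index
    valid <- branch_idx >= params$min_dist_5p &
      (len - 1L - branch_idx) >= params$min_dist_3p
    if (!any(valid)) next
    best <- which(valid)[which.max(branch_idx[valid])]
    idx <- branch_idx[best]
    return(structure(list(
      branch_index = idx,
      tier = t,
      motif = substr(seq, starts[best], starts[best] + nchar(motif) - 1L),
      dist5 = idx,
      dist3 = len - 1L - idx
    ), class = "BranchpointCall"))
  }
  NULL
}

#' @export
print.BranchpointCall <- function(x, ...) {
  cat(sprintf("BranchpointCall: branch A at index %d (tier %d, %s), dist5=%d dist3=%d\n",
              x$branch_index, x$tier, x$motif, x$dist5, x$dist3))
  invisible(x)
}

#' Extract the sequence window around a branchpoint
#'
#' Returns the fixed-width `(upstream + 1 + downstream)`-mer around the
#' branch A, N-padded where the window extends past either end of the
#' intron. The default 5/2 window yields the 8-mers used for branchpoint
#' weight matrices.
#'
#' @param intron_sequence Intron sequence (transcript orientation).
#' @param call A `"BranchpointCall"`.
#' @param upstream,downstream Bases flanking the branch A.
#' @return Character string of width `upstream + 1 + downstream`.
#' @export
branchpoint_window <- function(intron_sequence, call, upstream = 5L,
                               downstream = 2L) {
  idx1 <- call$branch_index + 1L              # 1-based
  len <- nchar(intron_sequence)
  from <- idx1 - upstream; to <- idx1 + downstream
  left_pad <- max(0L, 1L - from)
  right_pad <- max(0L, to - len)
  core <- substr(intron_sequence, max(1L, from), min(len, to))
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Find branchpoints for many introns
#'
#' Convenience wrapper returning a data.frame (one row per intron; NA rows
#' for introns without a call).
#'
#' @param sequences Character vector or `DNAStringSet` of intron sequences
#'   (transcript orientation).
#' @param params A [bp_params()] object.
#' @return data.frame with `branch_index`, `tier`, `motif`, `dist5`, `dist3`.
#' @export
find_branchpoints <- function(sequences, params = bp_params()) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  calls <- lapply(sequences, find_branchpoint, params = params)
  data.frame(
    branch_index = vapply(calls, function(x) if (is.null(x)) NA_integer_ else x$branch_index, integer(1)),
    tier = vapply(calls, function(x) if (is.null(x)) NA_integer_ else x$tier, integer(1)),
    motif = vapply(calls, function(x) if (is.null(x)) NA_character_ else x$motif, character(1)),
    dist5 = vapply(calls, function(x) if (is.null(x)) NA_integer_ else x$dist5, integer(1)),
    dist3 = vapply(calls, function(x) if (is.null(x)) NA_integer_ else x$dist3, integer(1)),
    stringsAsFactors = FALSE
  )
}
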