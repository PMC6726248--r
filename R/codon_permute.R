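# Codon-permutation null model for hexamer representation in coding
# sequence. Shuffling the internal codons of each ORF preserves length, GC
# content, codon usage and the encoded protein while partially randomizing
# the nucleotide sequence; comparing extant hexamer counts to this
# background yields per-hexamer depletion/enrichment Z-scores.

all_hexamers <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b6 = bases, b5 = bases, b4 = bases, b3 = bases,
                      b2 = bases, b1 = bases, stringsAsFactors = FALSE)
  sort(paste0(grid$b1, grid$b2, grid$b3, grid$b4, grid$b5, grid$b6))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Load and validate an ORF coding set
#'
#' Reads a FASTA of coding sequences (start codon through stop codon) and
#' applies the ORF validity rules: sequences must start with ATG, end with a
#' stop codon, have length divisible by 3 and at least 9 nt, and contain no
#' internal stop codon. Offending ORFs are excluded with a warning.
#'
#' @param x FASTA path, `DNAStringSet`, or character vector of sequences.
#' @return Named character vector of valid ORF sequences (class `"OrfSet"`).
#' @export
read_orf_set <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
  } else {
    seqs <- toupper(x)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("orf_", seq_along(seqs))
  ok <- rep(TRUE, length(seqs))
  reason <- character(length(seqs))
  len <- nchar(seqs)
  bad_len <- len %% 3L != 0L | len < 9L
  ok[bad_len] <- FALSE; reason[bad_len] <- "length"
  starts <- substr(seqs, 1L, 3L)
  bad_start <- ok & starts != "ATG"
  ok[bad_start] <- FALSE; reason[bad_start] <- "start"
  ends <- substr(seqs, len - 2L, len)
  bad_stop <- ok & !(ends %in% STOP_CODONS)
  ok[bad_stop] <- FALSE; reason[bad_stop] <- "stop"
  internal_stop <- ok & vapply(seqs, function(s) {
    cods <- orf_codons(s)
    any(cods[-c(1L, length(cods))] %in% STOP_CODONS)
  }, logical(1))
  ok[internal_stop] <- FALSE; reason[internal_stop] <- "internal_stop"
  if (any(!ok)) {
    warning(sum(!ok), " ORF(s) excluded (",
            paste(unique(reason[!ok]), collapse = ", "), ")")
  }
  structure(seqs[ok], class = "OrfSet")
}

orf_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Permute the internal codons of one ORF
#'
#' Uniform (Fisher-Yates) shuffle of the codons between the fixed start and
#' stop codons, using the current RNG state. Length, GC content, codon
#' multiset and the encoded amino-acid multiset are invariant.
#'
#' @param orf Coding sequence (character scalar, length divisible by 3).
#' @return Permuted coding sequence.
#' @export
permute_orf <- function(orf) {
  cods <- orf_codons(orf)
  k <- length(cods)
  if (k <= 3L) return(orf)
  internal <- cods[2:(k - 1L)]
  paste0(cods[1L], paste0(internal[sample.int(length(internal))], collapse = ""),
         cods[k], collapse = "")
}

permute_orf_set <- function(orfs) {
  vapply(unclass(orfs), permute_orf, character(1), USE.NAMES = FALSE)
}

#' Count all 4096 hexamers in an ORF set
#'
#' Overlapping occurrences are counted at every offset within each ORF
#' independently (no counting across ORF boundaries), forward strand only.
#'
#' @param orfs `"OrfSet"`, `DNAStringSet`, or character vector.
#' @return Named integer vector over the 4096 hexamers (lexicographic
#'   A < C < G < T order).
#' @export
count_hexamers <- function(orfs) {
  if (!methods::is(orfs, "DNAStringSet")) {
    orfs <- Biostrings::DNAStringSet(as.character(unclass(orfs)))
  }
  m <- Biostrings::oligonucleotideFrequency(orfs, width = 6L)
  counts <- colSums(m)
  counts[order(names(counts))]
}

#' Codon-permutation background for hexamer counts
#'
#' Generates `n_permutations` codon-permuted copies of the ORF set (every
#' ORF permuted independently within each copy) and returns the mean and
#' sample standard deviation (n-1 denominator) of each hexamer's total
#' count. Reproducible given `seed`: permutation `p` runs under the derived
#' seed `seed + p` (a documented counter scheme, so any permutation can be
#' regenerated in isolation).
#'
#' @param orfs An `"OrfSet"` (see [read_orf_set()]).
#' @param n_permutations Number of permuted ORF sets (>= 2).
#' @param seed Master seed.
#' @param keep_counts Keep the per-permutation count matrix (memory:
#'   `n_permutations` x 4096 doubles).
#' @return List with `mean`, `sd` (named over hexamers), `n_permutations`,
#'   and optionally `counts`.
#' @export
permutation_background <- function(orfs, n_permutations = 10000L, seed = 1L,
                                   keep_counts = FALSE) {
  stopifnot(n_permutations >= 2L)
  hex <- all_hexamers()
  sum_x <- setNames(numeric(4096L), hex)
  sum_x2 <- setNames(numeric(4096L), hex)
  counts_mat <- if (keep_counts) {
    matrix(NA_real_, n_permutations, 4096L, dimnames = list(NULL, hex))
  } else NULL
  for (p in seq_len(n_permutations)) {
    set.seed((seed + p) %% .Machine$integer.max)
    cnt <- count_hexamers(permute_orf_set(orfs))
    sum_x <- sum_x + cnt
    sum_x2 <- sum_x2 + cnt^2
    if (keep_counts) counts_mat[p, ] <- cnt
  }
  n <- n_permutations
  mu <- sum_x / n
  var <- pmax(0, (sum_x2 - n * mu^2) / (n - 1))
  list(mean = mu, sd = sqrt(var), n_permutations = n, counts = counts_mat)
}

#' Classify hexamers by embedded stop/start codons
#'
#' A hexamer contains a stop (start) codon when TAA/TAG/TGA (ATG) occurs as
#' a contiguous substring at any of the four offsets.
#'
#' @param hexamers Character vector of 6-mers over `{A,C,G,T}`.
#' @return data.frame with `hexamer`, `contains_stop`, `contains_start`.
#' @export
classify_hexamer <- function(hexamers) {
  stopifnot(all(nchar(hexamers) == 6L))
  has <- function(hex, words) {
    subs <- vapply(1:4, function(o) substr(hex, o, o + 2L), character(1))
    any(subs %in% words)
  }
  data.frame(
    hexamer = hexamers,
    contains_stop = vapply(hexamers, has, logical(1), words = STOP_CODONS),
    contains_start = vapply(hexamers, has, logical(1), words = "ATG"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-hexamer depletion/enrichment Z-scores
#'
#' `Z = (extant - mean) / sd` against the permutation background; `NA` when
#' `sd = 0`. Ranks ascend from the most depleted hexamer (rank 1), ties
#' broken lexicographically.
#'
#' @param extant Named counts from [count_hexamers()] on the extant set.
#' @param background From [permutation_background()].
#' @return data.frame with `hexamer`, `extant`, `mean`, `sd`, `z`, `rank`,
#'   `contains_stop`, `contains_start`.
#' @export
hexamer_zscores <- function(extant, background) {
  hex <- all_hexamers()
  stopifnot(identical(names(extant), hex), identical(names(background$mean), hex))
  z <- ifelse(background$sd > 0, (extant - background$mean) / background$sd,
              NA_real_)
  cls <- classify_hexamer(hex)
  out <- data.frame(hexamer = hex,
                    extant = as.integer(extant),
                    mean = unname(background$mean),
                    sd = unname(background$sd),
                    z = unname(z),
                    stringsAsFactors = FALSE)
  ord <- order(out$z, out$hexamer, na.last = TRUE)
  rank <- integer(4096L)
  rank[ord] <- seq_len(4096L)
  rank[is.na(out$z)] <- NA_integer_
  out$rank <- rank
  out$contains_stop <- cls$contains_stop
  out$contains_start <- cls$contains_start
  out
}

#' Run the full hexamer depletion analysis
#'
#' Counts hexamers in the extant ORF set, builds the codon-permutation
#' background and returns the Z-score table.
#'
#' @param orfs FASTA path or `"OrfSet"`.
#' @param n_permutations Number of permutations.
#' @param seed Master seed.
#' @return The [hexamer_zscores()] data.frame.
#' @export
hexamer_depletion <- function(orfs, n_permutations = 10000L, seed = 1L) {
  if (!methods::is(orfs, "OrfSet")) orfs <- read_orf_set(orfs)
  extant <- count_hexamers(orfs)
  bg <- permutation_background(orfs, n_permutations, seed)
  hexamer_zscores(extant, bg)
}
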