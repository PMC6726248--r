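# Independent oracles and tiny fixture builders shared across the suite.
# Oracles deliberately use different mechanics than the implementation:
# the branchpoint oracle enumerates windows with per-position character-set
# checks (no regex), the KS oracle evaluates both ECDFs at every pooled
# point, the Fisher oracle enumerates all tables with the observed margins.

iupac_sets <- function(motif) {
  lapply(strsplit(motif, "")[[1]], function(ch) {
    switch(ch, R = c("A", "G"), Y = c("C", "T"), ch)
  })
}

# brute-force branchpoint: every window of every tier, distance filters,
# pick (lowest tier, then max branch-A index)
bp_oracle <- function(seq, params = bp_params()) {
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  for (t in seq_along(params$tiers)) {
    sets <- iupac_sets(params$tiers[t])
    m <- length(sets)
    if (len < m) next
    starts <- seq_len(len - m + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_len(m)) {
      ok <- ok & chars[starts + j - 1L] %in% sets[[j]]
    }
    idx <- starts[ok] - 1L + params$branch_offset[t]
    idx <- idx[idx >= params$min_dist_5p & (len - 1L - idx) >= params$min_dist_3p]
    if (length(idx)) {
      return(list(tier = t, branch_index = max(idx)))
    }
  }
  NULL
}

ks_D_oracle <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(x) {
    abs(sum(a <= x) / length(a) - sum(b <= x) / length(b))
  }, numeric(1)))
}

# one-sided Fisher by explicit enumeration of every table with the margins
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0L, c1 - r2):min(r1, c1)
  logp <- lgamma(r1 + 1) - lgamma(ks + 1) - lgamma(r1 - ks + 1) +
    lgamma(r2 + 1) - lgamma(c1 - ks + 1) - lgamma(r2 - (c1 - ks) + 1) -
    (lgamma(r1 + r2 + 1) - lgamma(c1 + 1) - lgamma(r1 + r2 - c1 + 1))
  sum(exp(logp[ks >= a]))
}

count_hexamer_oracle <- function(seqs, hexamer) {
  total <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < 6L) next
    for (i in seq_len(n - 5L)) {
      if (substr(s, i, i + 5L) == hexamer) total <- total + 1L
    }
  }
  total
}

# uORF oracle: translate every ATG suffix (batched) and read off the first
# stop position
uorf_oracle <- function(seq, min_codons = 5L) {
  len <- nchar(seq)
  m <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m)
  tails <- ((len - starts + 1L) %/% 3L) * 3L
  keep <- tails >= 3L
  starts <- starts[keep]; tails <- tails[keep]
  if (length(starts) == 0L) return(integer(0))
  subs <- Biostrings::DNAStringSet(substring(seq, starts, starts + tails - 1L))
  aa <- as.character(Biostrings::translate(subs, if.fuzzy.codon = "X"))
  star <- regexpr("*", aa, fixed = TRUE)
  starts[star > 0 & (star - 1L) >= min_codons] - 1L
}

# tiny single-gene reference: plus- or minus-strand gene with known CDS
# geometry, written as FASTA + GFF3 in a temp dir
write_toy_reference <- function(dir, gene_seq, utr5_len, cds_len, strand = "+",
                                pad = 30L, introns = NULL) {
  chrom_seq <- paste0(strrep("C", pad),
                      if (strand == "-") as.character(Biostrings::reverseComplement(
                        Biostrings::DNAString(gene_seq))) else gene_seq,
                      strrep("G", pad))
  glen <- nchar(gene_seq)
  g2g <- function(s, e) {
    if (strand == "+") c(pad + s, pad + e)
    else c(pad + glen - e + 1L, pad + glen - s + 1L)
  }
  tx <- c(pad + 1L, pad + glen)
  u5 <- g2g(1L, utr5_len)
  cds <- g2g(utr5_len + 1L, utr5_len + cds_len)
  u3 <- g2g(utr5_len + cds_len + 1L, glen)
  fa <- file.path(dir, "toy.fa"); gff <- file.path(dir, "toy.gff3")
  writeLines(c(">chrT", chrom_seq), fa)
  lines <- c("##gff-version 3",
    sprintf("chrT\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=geneA", tx[1], tx[2], strand),
    sprintf("chrT\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=mRNA.geneA;Parent=geneA",
            tx[1], tx[2], strand),
    sprintf("chrT\ttoy\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=mRNA.geneA",
            u5[1], u5[2], strand),
    sprintf("chrT\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tParent=mRNA.geneA",
            cds[1], cds[2], strand),
    sprintf("chrT\ttoy\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=mRNA.geneA",
            u3[1], u3[2], strand))
  if (!is.null(introns)) {
    for (k in seq_len(nrow(introns))) {
      lines <- c(lines, sprintf("chrT\ttoy\tintron\t%d\t%d\t.\t%s\t.\tID=%s",
                                introns$start[k], introns$end[k],
                                introns$strand[k], introns$id[k]))
    }
  }
  writeLines(lines, gff)
  list(fasta = fa, gff = gff, tx = tx, u5 = u5, cds = cds, u3 = u3,
       pad = pad, strand = strand)
}

# minimal junction data.frame in the merged schema used by the caller
toy_junctions <- function(chrom, start, end, strand, reads_by_lib,
                          positions = NA_integer_) {
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   overhang = 30L, stringsAsFactors = FALSE)
  for (lib in names(reads_by_lib)) df[[paste0("reads.", lib)]] <- reads_by_lib[[lib]]
  cnt <- as.matrix(df[, paste0("reads.", names(reads_by_lib)), drop = FALSE])
  df$total_reads <- as.integer(rowSums(cnt))
  df$n_libraries <- as.integer(rowSums(cnt > 0))
  df$positions <- positions
  df
}

random_intron_seq <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
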