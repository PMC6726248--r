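# Synthetic-data generator with planted ground truth. Emulates the
# structure of a two-timepoint (0/60 min rapamycin), two-replicate junction
# and coverage experiment: standard introns spliced at high efficiency
# (~93% median), protointrons at low efficiency (~1% median), splicing
# increasing after treatment, plus one artifact junction per filter class.
# Intron bodies use A-free filler so the planted branchpoint is provably the
# unique motif match; see the methods vignette for what this does and does
# not emulate.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: two conditions
#' (t0, t60) times two replicates at per-condition read depth `depth`;
#' standard-intron efficiencies from Beta(60, 4.5) (median ~0.93);
#' protointron efficiencies from Beta(2, 198) (median ~0.008, floored at
#' `min_efficiency` so that a planted event is detectable at all);
#' treatment multiplies protointron efficiency by `rapamycin_effect` and
#' shrinks the unspliced fraction of standard introns by the same factor.
#'
#' @param seed Master seed; all randomness flows from it via named
#'   substreams (genome, counts, orfs, utrs).
#' @param n_genes Number of genes on the simulated chromosome.
#' @param n_standard Number of genes hosting a standard intron.
#' @param depth Per-condition read depth over transcripts.
#' @param rapamycin_effect Multiplier (> 1) applied at t60.
#' @param min_efficiency Floor on drawn protointron efficiencies.
#' @param std_eff_shape Beta shape parameters for standard-intron
#'   efficiency.
#' @param proto_eff_shape Beta shape parameters for protointron efficiency.
#' @param uorf_rate_intron,uorf_rate_intronless uORF planting probabilities
#'   for the UTR simulator (defaults 1.0 and 38/91).
#' @param n_utr_intron,n_utr_intronless UTR set sizes (defaults 22 and 91).
#' @param orf_n,orf_codons ORF-set simulator sizes (200 ORFs x 300 codons).
#' @param target_hexamer Hexamer targeted by the depletion knob.
#' @param depletion Depletion factor in (0, 1]; 1 = null.
#' @return A list of class `"SimConfig"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 16L, n_standard = 6L,
                       depth = 2000, rapamycin_effect = 3,
                       min_efficiency = 0.003,
                       std_eff_shape = c(60, 4.5),
                       proto_eff_shape = c(2, 198),
                       uorf_rate_intron = 1.0, uorf_rate_intronless = 38 / 91,
                       n_utr_intron = 22L, n_utr_intronless = 91L,
                       orf_n = 200L, orf_codons = 300L,
                       target_hexamer = "ACTAAC", depletion = 1) {
  stopifnot(depth > 0, rapamycin_effect > 0, depletion > 0, depletion <= 1,
            n_genes >= 10L, n_standard >= 1L, n_standard < n_genes)
  structure(as.list(environment()), class = "SimConfig")
}

substream_seed <- function(config, name) {
  offs <- c(genome = 101L, counts = 202L, orfs = 303L, utrs = 404L)
  (config$seed * 1000L + offs[[name]]) %% .Machine$integer.max
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A-free filler cannot contain any branchpoint-tier motif (all require an A
# at the branch offset) nor a stop codon.
afree <- function(n) random_dna(n, c("C", "G", "T"))

# Intron sequence in transcript orientation with a planted tier-1
# branchpoint satisfying the >=45 / >=7 geometry. bp_index is the 0-based
# branch A position.
make_intron_seq <- function(length = 100L, donor = "GTATGT",
                            bp_motif = "TACTAAC", bp_motif_offset = 5L,
                            acceptor = "CAG", bp_gap3 = 12L) {
  stopifnot(length >= 75L)
  # layout: donor | filler1 | bp_motif | filler2 | acceptor
  bp_start <- length - bp_gap3 - nchar(acceptor) - (nchar(bp_motif) - bp_motif_offset) + 1L
  need5 <- 45L - bp_motif_offset  # motif start index floor for bp_index >= 45
  bp_start <- max(bp_start, need5 + nchar(donor) + 1L)
  f1 <- bp_start - nchar(donor) - 1L
  f2 <- length - (bp_start + nchar(bp_motif) - 1L) - nchar(acceptor)
  stopifnot(f1 >= 0L, f2 >= 0L)
  seq <- paste0(donor, afree(f1), bp_motif, afree(f2), acceptor)
  bp_index <- nchar(donor) + f1 + bp_motif_offset  # 0-based
  stopifnot(nchar(seq) == length, substr(seq, bp_index + 1L, bp_index + 1L) == "A")
  list(seq = seq, bp_index = bp_index)
}

proto_donors <- c("GTACGT", "GCATGT", "GTATGA", "GTAAGT", "GTATGG")
proto_bp_motifs <- list(c("AACTAAT", 5L), c("CACTAAT", 5L), c("GACTAAT", 5L),
                        c("TACTAAT", 5L))

random_proto_intron <- function(length = NULL, donors = proto_donors) {
  if (is.null(length)) length <- sample(80:150, 1L)
  bp <- proto_bp_motifs[[sample(length(proto_bp_motifs), 1L)]]
  make_intron_seq(length, donor = sample(donors, 1L),
                  bp_motif = bp[[1]], bp_motif_offset = as.integer(bp[[2]]),
                  acceptor = sample(c("CAG", "AAG"), 1L))
}

# protointron destined for a CDS interior: drawn until no codon-aligned
# (phase 0) window inside it is a stop codon, so it can sit in a reading
# frame without interrupting translation
coding_proto_intron <- function(length) {
  repeat {
    p <- random_proto_intron(length, donors = setdiff(proto_donors, "GTATGA"))
    k <- (length %/% 3L) * 3L
    cods <- substring(p$seq, seq(1L, k - 2L, 3L), seq(3L, k, 3L))
    if (!any(cods %in% STOP_CODONS)) return(p)
  }
}

random_std_intron <- function(length = NULL) {
  if (is.null(length)) {
    length <- if (runif(1) < 0.6) sample(85:140, 1L) else sample(250:420, 1L)
  }
  make_intron_seq(length, donor = "GTATGT", bp_motif = "TACTAAC",
                  bp_motif_offset = 5L, acceptor = sample(c("TAG", "CAG"), 1L))
}

# Overwrite part of a codon string with `insert`, rejecting layouts that put
# a stop codon in frame. at_codon: 1-based codon index where the insert's
# first base lands (phase 0).
embed_in_codons <- function(n_codons, insert, at_codon, tries = 100L) {
  ins_len <- nchar(insert)
  stopifnot((at_codon - 1L) * 3L + ins_len <= n_codons * 3L)
  for (t in seq_len(tries)) {
    cods <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    s <- paste0(cods, collapse = "")
    off <- (at_codon - 1L) * 3L
    s <- paste0(substr(s, 1L, off), insert,
                substr(s, off + ins_len + 1L, nchar(s)))
    body_cods <- orf_codons(s)
    if (!any(body_cods %in% STOP_CODONS)) return(s)
  }
  stop("could not embed sequence without creating an in-frame stop")
}

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$parts <- character(0)
  env$cursor <- 0L
  env
}
emit <- function(builder, seq) {
  start <- builder$cursor + 1L
  builder$parts <- c(builder$parts, seq)
  builder$cursor <- builder$cursor + nchar(seq)
  c(start = start, end = builder$cursor)
}

#' Simulate a genome, annotation and truth table
#'
#' Builds one chromosome carrying `n_genes` genes (5'UTR, CDS with length a
#' multiple of 3 and no internal stops, 3'UTR; both strands), standard
#' introns with canonical signals (GTATGT / TACTAAC / YAG), protointrons
#' with weaker signals planted in all six context categories (non-coding,
#' 5'UTR, 5'UTR^coding, coding, coding^3'UTR, 3'UTR), and one decoy
#' junction per artifact class (CT donor, <3 reads, GAG 3'ss, no
#' branchpoint, single-library jackpot, contiguous-genome mismap copy). All
#' planted branchpoints satisfy the >=45 / >=7 distance geometry.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `annotation`
#'   (`AnnotationSet`), and `truth` (data.frame; one row per planted
#'   feature).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(substream_seed(config, "genome"))
  b <- new_builder()
  chrom <- "chrS"
  genes <- list(); cds_list <- list(); utr5_list <- list(); utr3_list <- list()
  introns <- list(); truth <- list()
  add_truth <- function(...) truth[[length(truth) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  # roles per gene: which protointron context (if any) the gene hosts
  roles <- rep("plain", config$n_genes)
  roles[1:6] <- c("coding_inframe", "coding_frameshift", "utr5",
                  "utr5_coding", "coding_utr3", "utr3")
  roles[7] <- "antisense_host"
  std_genes <- seq(8L, length.out = config$n_standard)
  std_genes <- std_genes[std_genes <= config$n_genes]
  strand_of <- rep(c("+", "-"), length.out = config$n_genes)
  strand_of[1:7] <- c("+", "-", "+", "+", "+", "-", "+")  # exercise both

  gene_sense <- function(i) {
    role <- roles[i]
    utr5_len <- if (role %in% c("utr5", "utr5_coding")) 320L else sample(120:200, 1L)
    utr3_len <- if (role %in% c("utr3", "coding_utr3", "antisense_host")) 300L
                else sample(90:150, 1L)
    n_cod <- sample(150:240, 1L)
    proto <- NULL; std <- NULL
    # sense-relative records: positions within the gene block
    utr5 <- destroy_atgs(random_dna(utr5_len))
    utr3 <- random_dna(utr3_len)
    cds <- paste0("ATG", paste0(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                                collapse = ""), "TAA")
    feat <- list()
    if (role %in% c("coding_inframe", "coding_frameshift")) {
      len <- if (role == "coding_inframe") 99L else 100L
      p <- coding_proto_intron(len)
      at <- sample(30:60, 1L)
      body <- embed_in_codons(n_cod - 2L, p$seq, at)
      cds <- paste0("ATG", body, "TAA")
      off <- 3L + (at - 1L) * 3L           # bases before the insert in CDS
      feat$proto <- list(start = utr5_len + off + 1L,
                         end = utr5_len + off + nchar(p$seq),
                         bp_index = p$bp_index, context = "coding",
                         in_frame = role == "coding_inframe")
    } else if (role == "utr5") {
      p <- random_proto_intron(110L)
      at <- 60L
      utr5 <- paste0(substr(utr5, 1, at), p$seq,
                     substr(utr5, at + nchar(p$seq) + 1L, utr5_len))
      utr5 <- paste0(utr5, strrep("C", utr5_len - nchar(utr5)))
      feat$proto <- list(start = at + 1L, end = at + 110L,
                         bp_index = p$bp_index, context = "5'UTR",
                         in_frame = NA)
    } else if (role == "utr5_coding") {
      # donor in the 5'UTR; the intron's last 45 bases are the gene's own
      # first 15 codons (starting at the ATG), with a branchpoint motif and
      # a CAG acceptor built in without any in-frame stop
      tail45 <- paste0("ATG", afree(25L), "CACTAAT", afree(7L), "CAG")
      stopifnot(!any(orf_codons(tail45) %in% STOP_CODONS))
      cds <- paste0(tail45,
                    paste0(sample(SENSE_CODONS, n_cod - 16L, replace = TRUE),
                           collapse = ""), "TAA")
      head_part <- paste0(sample(setdiff(proto_donors, "GTATGA"), 1L), afree(69L))
      utr5 <- paste0(substr(utr5, 1, utr5_len - 75L), head_part)
      feat$proto <- list(start = utr5_len - 75L + 1L, end = utr5_len + 45L,
                         bp_index = 75L + 28L + 5L,  # branch A of CACTAAT
                         context = "5'UTR^coding", in_frame = NA)
    } else if (role == "coding_utr3") {
      # donor within the last 7 codons; the intron includes the stop codon
      # and runs into the 3'UTR where the branchpoint and acceptor live
      head21 <- paste0("GTATGT", afree(12L), "TAA")
      cds <- paste0("ATG",
                    paste0(sample(SENSE_CODONS, n_cod - 8L, replace = TRUE),
                           collapse = ""), head21)
      tail99 <- paste0(afree(60L), "AACTAAT", afree(29L), "CAG")
      utr3 <- paste0(tail99, substr(utr3, 100L, utr3_len))
      cds_len <- n_cod * 3L
      feat$proto <- list(start = utr5_len + cds_len - 21L + 1L,
                         end = utr5_len + cds_len + 99L,
                         bp_index = 21L + 60L + 5L,  # branch A of AACTAAT
                         context = "coding^3'UTR", in_frame = NA)
    } else if (role == "utr3") {
      p <- random_proto_intron(110L)
      at <- 40L
      utr3 <- paste0(substr(utr3, 1, at), p$seq,
                     substr(utr3, at + 111L, utr3_len))
      utr3 <- paste0(utr3, strrep("C", utr3_len - nchar(utr3)))
      cds_len <- n_cod * 3L
      feat$proto <- list(start = utr5_len + cds_len + at + 1L,
                         end = utr5_len + cds_len + at + 110L,
                         bp_index = p$bp_index, context = "3'UTR",
                         in_frame = NA)
    } else if (role == "antisense_host") {
      # antisense protointron: revcomp of an intron written into the 3'UTR;
      # the junction lies on the opposite strand of this gene
      p <- random_proto_intron(100L)
      at <- 60L
      utr3 <- paste0(substr(utr3, 1, at), revcomp(p$seq),
                     substr(utr3, at + 101L, utr3_len))
      utr3 <- paste0(utr3, strrep("C", utr3_len - nchar(utr3)))
      cds_len <- n_cod * 3L
      feat$antisense <- list(start = utr5_len + cds_len + at + 1L,
                             end = utr5_len + cds_len + at + 100L,
                             bp_index = p$bp_index)
    }
    if (i %in% std_genes) {
      s <- random_std_intron()
      at_codon <- sample(40:80, 1L)
      off <- 3L + (at_codon - 1L) * 3L
      cds <- paste0(substr(cds, 1L, off), s$seq,
                    substr(cds, off + 1L, nchar(cds)))
      feat$std <- list(start = utr5_len + off + 1L,
                       end = utr5_len + off + nchar(s$seq),
                       bp_index = s$bp_index)
    }
    list(seq = paste0(utr5, cds, utr3), utr5_len = utr5_len,
         utr3_len = utr3_len, cds_len_genomic = nchar(cds),
         feat = feat, role = role)
  }

  for (i in seq_len(config$n_genes)) {
    emit(b, random_dna(250L))               # intergenic spacer
    g <- gene_sense(i)
    span <- emit(b, if (strand_of[i] == "-") revcomp(g$seq) else g$seq)
    glen <- nchar(g$seq)
    gid <- sprintf("gene%02d", i)
    # map a sense-relative closed interval to genomic coordinates
    g2g <- function(s, e) {
      if (strand_of[i] == "+") c(span["start"] + s - 1L, span["start"] + e - 1L)
      else c(span["start"] + (glen - e), span["start"] + (glen - s))
    }
    tx <- c(span[["start"]], span[["end"]])
    u5 <- g2g(1L, g$utr5_len)
    cds_iv <- g2g(g$utr5_len + 1L, g$utr5_len + g$cds_len_genomic)
    u3 <- g2g(g$utr5_len + g$cds_len_genomic + 1L, glen)
    genes[[i]] <- data.frame(gene_id = gid, start = tx[1], end = tx[2],
                             strand = strand_of[i])
    utr5_list[[i]] <- data.frame(gene_id = gid, start = u5[1], end = u5[2],
                                 strand = strand_of[i])
    utr3_list[[i]] <- data.frame(gene_id = gid, start = u3[1], end = u3[2],
                                 strand = strand_of[i])
    cds_rows <- data.frame(gene_id = gid, start = cds_iv[1], end = cds_iv[2],
                           strand = strand_of[i])
    if (!is.null(g$feat$std)) {
      iv <- g2g(g$feat$std$start, g$feat$std$end)
      introns[[length(introns) + 1L]] <- data.frame(
        intron_id = paste0("stdint_", gid), start = iv[1], end = iv[2],
        strand = strand_of[i])
      # split CDS around the intron
      cds_rows <- data.frame(gene_id = gid,
                             start = c(cds_iv[1], iv[2] + 1L),
                             end = c(iv[1] - 1L, cds_iv[2]),
                             strand = strand_of[i])
      if (strand_of[i] == "-") cds_rows <- cds_rows[order(cds_rows$start), ]
      add_truth(feature_id = paste0("std_", gid), type = "standard",
                decoy_class = NA_character_, chrom = chrom,
                start = iv[1], end = iv[2], strand = strand_of[i],
                bp_index = g$feat$std$bp_index, context = "coding",
                in_frame = NA, gene_id = gid)
    }
    cds_list[[i]] <- cds_rows
    if (!is.null(g$feat$proto)) {
      iv <- g2g(g$feat$proto$start, g$feat$proto$end)
      add_truth(feature_id = paste0("proto_", gid), type = "protointron",
                decoy_class = NA_character_, chrom = chrom,
                start = iv[1], end = iv[2], strand = strand_of[i],
                bp_index = g$feat$proto$bp_index,
                context = g$feat$proto$context,
                in_frame = g$feat$proto$in_frame, gene_id = gid)
    }
    if (!is.null(g$feat$antisense)) {
      iv <- g2g(g$feat$antisense$start, g$feat$antisense$end)
      add_truth(feature_id = paste0("proto_anti_", gid), type = "protointron",
                decoy_class = NA_character_, chrom = chrom,
                start = iv[1], end = iv[2],
                strand = if (strand_of[i] == "+") "-" else "+",
                bp_index = g$feat$antisense$bp_index, context = "non-coding",
                in_frame = NA, gene_id = NA_character_)
    }
  }

  # intergenic protointron (non-coding context) and the six decoys
  plant_intergenic <- function(seq, bp_index, feature_id, type, decoy_class,
                               extra_copy = NULL) {
    emit(b, random_dna(120L))
    flankL <- random_dna(60L)
    flankR <- random_dna(60L)
    emit(b, flankL)
    iv <- emit(b, seq)
    emit(b, flankR)
    add_truth(feature_id = feature_id, type = type,
              decoy_class = decoy_class, chrom = chrom,
              start = iv[["start"]], end = iv[["end"]], strand = "+",
              bp_index = bp_index, context = "non-coding", in_frame = NA,
              gene_id = NA_character_)
    list(iv = iv, flankL = flankL, flankR = flankR)
  }
  p <- random_proto_intron(105L)
  plant_intergenic(p$seq, p$bp_index, "proto_intergenic", "protointron", NA)

  p <- random_proto_intron(100L)
  donor_decoy <- paste0("CT", substr(p$seq, 3L, 100L))
  plant_intergenic(donor_decoy, p$bp_index, "decoy_donor", "decoy", "donor")

  p <- random_proto_intron(100L)
  plant_intergenic(p$seq, p$bp_index, "decoy_min_reads", "decoy", "min_reads")

  p <- make_intron_seq(100L, donor = "GTATGT", bp_motif = "TACTAAC",
                       bp_motif_offset = 5L, acceptor = "GAG")
  plant_intergenic(p$seq, p$bp_index, "decoy_gag", "decoy", "gag_3ss")

  nobp <- paste0("GTATGT", afree(91L), "CAG")
  stopifnot(is.null(find_branchpoint(nobp)))
  plant_intergenic(nobp, NA_integer_, "decoy_no_bp", "decoy", "no_branchpoint")

  p <- random_proto_intron(100L)
  plant_intergenic(p$seq, p$bp_index, "decoy_jackpot", "decoy", "jackpot")

  p <- random_proto_intron(100L)
  planted <- plant_intergenic(p$seq, p$bp_index, "decoy_mismap", "decoy", "mismap")
  # contiguous copy of the spliced concatenation elsewhere in the genome
  emit(b, random_dna(150L))
  spliced_copy <- paste0(substr(planted$flankL, 41L, 60L),
                         substr(planted$flankR, 1L, 20L))
  emit(b, spliced_copy)
  emit(b, random_dna(250L))

  genome <- Biostrings::DNAStringSet(setNames(paste0(b$parts, collapse = ""), chrom))
  truth <- do.call(rbind, truth)
  ann <- annotation_from_sim(chrom, do.call(rbind, genes),
                             do.call(rbind, cds_list),
                             do.call(rbind, utr5_list),
                             do.call(rbind, utr3_list),
                             if (length(introns)) do.call(rbind, introns) else NULL)
  list(genome = genome, annotation = ann, truth = truth)
}

destroy_atgs <- function(seq) {
  while (TRUE) {
    m <- regexpr("ATG", seq, fixed = TRUE)
    if (m == -1L) return(seq)
    substr(seq, m + 1L, m + 1L) <- "C"
  }
}

annotation_from_sim <- function(chrom, genes, cds, utr5, utr3, introns) {
  mk <- function(df, extra = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    for (nm in setdiff(names(df), c("start", "end", "strand"))) {
      S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
    }
    gr
  }
  g <- mk(genes)
  intron_gr <- if (is.null(introns)) {
    gr <- GenomicRanges::GRanges()
    gr$intron_id <- character(0)
    gr
  } else mk(introns)
  build_annotation_set(g, mk(cds), mk(utr5), mk(utr3), intron_gr)
}

#' Simulate junction tables and coverage tracks from a truth table
#'
#' Draws per-library efficiencies and counts: for a feature with
#' per-condition depth `d` and efficiency `e`, junction reads per replicate
#' library are Poisson(d e / 2), intron per-base depth per condition is
#' Poisson(d (1 - e)), and exonic depth is Poisson(d). Decoys are emitted
#' with their class-specific support pattern (the jackpot decoy appears in
#' exactly one library; the min-reads decoy gets two reads across two
#' libraries). Clean (non-decoy) features have their counts redrawn until
#' detectable (>= 3 reads, >= 2 libraries): the generator emulates the set
#' of *observed* splicing events, which is conditioned on detection.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The same [sim_config()].
#' @return List with `sj_tables` (named list of per-library data.frames in
#'   the junction-table schema), `tracks` (list of depth `"CoverageTrack"`s
#'   `t0`, `t60`), `gene_counts` (genes x libraries exonic count matrix),
#'   `condition_of_library`, and `truth` augmented with per-condition
#'   efficiencies and read totals.
#' @export
simulate_junctions_and_coverage <- function(sim, config = sim_config()) {
  set.seed(substream_seed(config, "counts"))
  truth <- sim$truth
  n <- nrow(truth)
  d <- config$depth
  eff0 <- numeric(n)
  is_std <- truth$type == "standard"
  eff0[is_std] <- rbeta(sum(is_std), config$std_eff_shape[1], config$std_eff_shape[2])
  eff0[!is_std] <- pmax(config$min_efficiency,
                        rbeta(sum(!is_std), config$proto_eff_shape[1],
                              config$proto_eff_shape[2]))
  eff60 <- ifelse(is_std,
                  1 - (1 - eff0) / config$rapamycin_effect,
                  pmin(0.5, eff0 * config$rapamycin_effect))
  libs <- c("t0_r1", "t0_r2", "t60_r1", "t60_r2")
  cond <- c(t0_r1 = "t0", t0_r2 = "t0", t60_r1 = "t60", t60_r2 = "t60")
  J <- matrix(0L, n, 4L, dimnames = list(truth$feature_id, libs))
  for (i in seq_len(n)) {
    cls <- truth$decoy_class[i]
    if (!is.na(cls) && cls == "min_reads") {
      J[i, ] <- c(1L, 1L, 0L, 0L)
    } else if (!is.na(cls) && cls == "jackpot") {
      J[i, ] <- c(25L, 0L, 0L, 0L)
    } else {
      lam <- c(rep(d * eff0[i] / 2, 2), rep(d * eff60[i] / 2, 2))
      repeat {
        draw <- rpois(4L, lam)
        if (sum(draw) >= 3L && sum(draw > 0L) >= 2L) break
      }
      J[i, ] <- draw
    }
  }
  sj_tables <- lapply(libs, function(lib) {
    keep <- J[, lib] > 0L
    data.frame(chrom = truth$chrom[keep], start = truth$start[keep],
               end = truth$end[keep], strand = truth$strand[keep],
               motif_code = 0L,
               annotated = as.integer(truth$type[keep] == "standard"),
               reads = J[keep, lib], multimap_reads = 0L,
               overhang = 30L, library = lib, stringsAsFactors = FALSE)
  })
  names(sj_tables) <- libs

  clen <- nchar(as.character(sim$genome[[1]]))
  chrom <- names(sim$genome)[1]
  mk_track <- function(which_cond) {
    lam <- numeric(clen)
    g <- sim$annotation$genes
    for (k in seq_along(g)) {
      lam[BiocGenerics::start(g)[k]:BiocGenerics::end(g)[k]] <- d
    }
    # local transcription over intergenic features
    inter <- is.na(truth$gene_id)
    for (i in which(inter)) {
      s <- max(1L, truth$start[i] - 150L); e <- min(clen, truth$end[i] + 150L)
      lam[s:e] <- pmax(lam[s:e], d)
    }
    eff <- if (which_cond == "t0") eff0 else eff60
    for (i in seq_len(n)) {
      lam[truth$start[i]:truth$end[i]] <- d * (1 - eff[i])
    }
    pos <- which(lam > 0)
    vals <- numeric(clen)
    vals[pos] <- rpois(length(pos), lam[pos])
    rle <- S4Vectors::Rle(vals)
    structure(list(values = setNames(IRanges::RleList(rle), chrom),
                   scored = setNames(IRanges::RleList(S4Vectors::Rle(vals > -1)), chrom),
                   mode = "depth"),
              class = "CoverageTrack")
  }
  tracks <- list(t0 = mk_track("t0"), t60 = mk_track("t60"))

  gene_ids <- sim$annotation$genes$gene_id
  gene_counts <- matrix(rpois(length(gene_ids) * 4L, d), ncol = 4L,
                        dimnames = list(gene_ids, libs))
  truth$eff_t0 <- eff0
  truth$eff_t60 <- eff60
  truth$reads_total <- as.integer(rowSums(J))
  list(sj_tables = sj_tables, tracks = tracks, gene_counts = gene_counts,
       condition_of_library = cond, truth = truth)
}

#' Simulate an ORF coding set with an optional planted hexamer depletion
#'
#' Draws `orf_n` ORFs of `orf_codons` codons (ATG + uniform sense codons +
#' TAA). With `depletion < 1`, each ORF draw is rejected until its count of
#' the target hexamer is at most `depletion` times that ORF's
#' codon-permutation expectation (estimated by a small per-ORF Monte
#' Carlo); since per-ORF expectations are well below one count, accepted
#' ORFs carry essentially no copies, i.e. realized depletion is at most the
#' nominal factor.
#'
#' @param config A [sim_config()].
#' @return List with `orfs` (an `"OrfSet"`), `target_hexamer`, `depletion`.
#' @export
simulate_orf_set <- function(config = sim_config()) {
  set.seed(substream_seed(config, "orfs"))
  target <- config$target_hexamer
  draw_orf <- function() {
    paste0("ATG", paste0(sample(SENSE_CODONS, config$orf_codons - 2L,
                                replace = TRUE), collapse = ""), "TAA")
  }
  count_target <- function(seq) {
    m <- gregexpr(paste0("(?=", target, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  orfs <- character(config$orf_n)
  for (i in seq_len(config$orf_n)) {
    repeat {
      s <- draw_orf()
      if (config$depletion >= 1) break
      expect <- mean(vapply(1:10, function(...) count_target(permute_orf(s)),
                            numeric(1)))
      if (count_target(s) <= config$depletion * expect) break
    }
    orfs[i] <- s
  }
  names(orfs) <- sprintf("orf%03d", seq_len(config$orf_n))
  list(orfs = structure(orfs, class = "OrfSet"),
       target_hexamer = target, depletion = config$depletion)
}

#' Simulate a 5'UTR set with planted uORFs
#'
#' Generates `n_utr_intron` intron-bearing and `n_utr_intronless` intronless
#' 5'UTRs with unspliced lengths in \[240, 950\] nt. Backgrounds are
#' ATG-free by construction, so uORF presence is exactly the planting
#' outcome: intron-bearing UTRs receive at least one uORF with probability
#' `uorf_rate_intron` (planted inside the intron interval), intronless UTRs
#' with probability `uorf_rate_intronless`.
#'
#' @param config A [sim_config()].
#' @return List with `utrs` (data.frame usable by [uorf_contingency()]) and
#'   `truth_table` (the planted 2x2 matrix).
#' @export
simulate_utr_set <- function(config = sim_config()) {
  set.seed(substream_seed(config, "utrs"))
  make_uorf <- function() {
    k <- sample(4:7, 1L)
    paste0("ATG", paste0(sample(setdiff(SENSE_CODONS, "ATG"), k, replace = TRUE),
                         collapse = ""), "TAA")
  }
  rows <- list()
  planted <- matrix(0L, 2, 2, dimnames = list(c("intron_bearing", "intronless"),
                                              c("uorf", "no_uorf")))
  idx <- 0L
  for (grp in c("intron", "intronless")) {
    n_grp <- if (grp == "intron") config$n_utr_intron else config$n_utr_intronless
    rate <- if (grp == "intron") config$uorf_rate_intron else config$uorf_rate_intronless
    for (j in seq_len(n_grp)) {
      idx <- idx + 1L
      len <- sample(240:950, 1L)
      seq <- destroy_atgs(random_dna(len))
      has_intron <- grp == "intron"
      i_s <- NA_integer_; i_e <- NA_integer_
      if (has_intron) {
        i_s <- sample(20:60, 1L)            # 0-based intron start in UTR
        i_e <- i_s + 99L
      }
      has_uorf <- runif(1) < rate
      if (has_uorf) {
        u <- make_uorf()
        at <- if (has_intron) i_s + 5L else sample(10:(len - nchar(u) - 10L), 1L)
        substr(seq, at + 1L, at + nchar(u)) <- u
        # remove any ATG accidentally created at the splice boundaries
        seq <- keep_only_atg_at(seq, at)
      }
      planted[if (has_intron) 1L else 2L, if (has_uorf) 1L else 2L] <-
        planted[if (has_intron) 1L else 2L, if (has_uorf) 1L else 2L] + 1L
      rows[[idx]] <- data.frame(gene = sprintf("utr%03d", idx), sequence = seq,
                                length = len, has_intron = has_intron,
                                intron_start = i_s, intron_end = i_e,
                                stringsAsFactors = FALSE)
    }
  }
  list(utrs = do.call(rbind, rows), truth_table = planted)
}

# destroy every ATG except the one starting at 0-based offset `keep_at`
keep_only_atg_at <- function(seq, keep_at) {
  repeat {
    m <- gregexpr("(?=ATG)", seq, perl = TRUE)[[1]]
    m <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    bad <- setdiff(m, keep_at)
    if (length(bad) == 0L) return(seq)
    substr(seq, bad[1] + 2L, bad[1] + 2L) <- "C"
  }
}

#' Write a full simulation to disk
#'
#' Emits `genome.fa`, `ann.gff3`, per-library `sj_<lib>.tab`, per-condition
#' `cov_<cond>.bedgraph` and `truth.tsv` under `dir`.
#'
#' @param sim Output of [simulate_genome()].
#' @param reads Output of [simulate_junctions_and_coverage()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "ann.gff3"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  export_annotation_gff3(sim$annotation, paths["annotation"])
  write_results_table(reads$truth, paths["truth"])
  for (lib in names(reads$sj_tables)) {
    p <- file.path(dir, paste0("sj_", lib, ".tab"))
    write_sj_table(reads$sj_tables[[lib]], p)
    paths[paste0("sj_", lib)] <- p
  }
  for (cd in names(reads$tracks)) {
    p <- file.path(dir, paste0("cov_", cd, ".bedgraph"))
    tr <- reads$tracks[[cd]]
    gr <- methods::as(tr$values, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, p, format = "bedGraph")
    paths[paste0("cov_", cd)] <- p
  }
  invisible(paths)
}

export_annotation_gff3 <- function(ann, path) {
  recs <- list()
  g <- ann$genes
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    add <- function(type, start, end, id = NULL, parent = NULL) {
      recs[[length(recs) + 1L]] <<- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(g))[i], type = type,
        start = start, end = end,
        strand = as.character(BiocGenerics::strand(g))[i],
        id = if (is.null(id)) "" else id,
        parent = if (is.null(parent)) "" else parent,
        stringsAsFactors = FALSE)
    }
    add("gene", BiocGenerics::start(g)[i], BiocGenerics::end(g)[i], id = gid)
    mid <- paste0("mRNA.", gid)
    add("mRNA", BiocGenerics::start(g)[i], BiocGenerics::end(g)[i], id = mid,
        parent = gid)
    part <- function(gr_part, type) {
      for (k in seq_along(gr_part)) {
        add(type, BiocGenerics::start(gr_part)[k], BiocGenerics::end(gr_part)[k],
            parent = mid)
      }
    }
    part(ann$utr5[ann$utr5$gene_id == gid], "five_prime_UTR")
    part(ann$cds[[gid]], "CDS")
    part(ann$utr3[ann$utr3$gene_id == gid], "three_prime_UTR")
  }
  for (k in seq_along(ann$introns)) {
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(ann$introns))[k],
      type = "intron",
      start = BiocGenerics::start(ann$introns)[k],
      end = BiocGenerics::end(ann$introns)[k],
      strand = as.character(BiocGenerics::strand(ann$introns))[k],
      id = ann$introns$intron_id[k], parent = "", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  attrs <- ifelse(nzchar(df$id), paste0("ID=", df$id), "")
  attrs <- ifelse(nzchar(df$parent),
                  paste0(attrs, ifelse(nzchar(attrs), ";", ""), "Parent=", df$parent),
                  attrs)
  attrs[!nzchar(attrs)] <- "."
  lines <- paste(df$chrom, "sim", df$type, df$start, df$end, ".", df$strand,
                 ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
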