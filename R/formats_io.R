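#' @import methods
#' @importFrom stats median rbeta rpois runif sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 1-based closed intervals throughout
# (GRanges). STAR SJ.out.tab start/end are the 1-based first and last
# intron base, so they map onto GRanges start/end unchanged. Conversions
# for 0-based formats (BED12, bedGraph) happen only at file boundaries,
# inside rtracklayer.

#' Load a genome from a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped) FASTA file into a named
#' `DNAStringSet`, uppercasing all bases. Any base outside `{A,C,G,T,N}`
#' is an error: the downstream motif and translation machinery assumes a
#' plain nucleotide alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- Biostrings::DNAStringSet(toupper(as.character(genome)))
  freq <- Biostrings::alphabetFrequency(genome)
  foreign <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                          drop = FALSE])
  if (any(foreign > 0)) {
    stop("genome contains bases outside {A,C,G,T,N}: ",
         paste(names(genome)[foreign > 0], collapse = ", "))
  }
  genome
}

#' Chromosome lengths of a loaded genome
#' @param genome A `DNAStringSet` from [read_genome()].
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) setNames(Biostrings::width(genome), names(genome))

#' Parse a STAR-style splice junction table
#'
#' Reads one `SJ.out.tab`-dialect file (9 tab-separated columns: chrom,
#' 1-based intron start, 1-based intron end, strand code 0/1/2, motif code,
#' annotated flag, unique reads, multimapped reads, max overhang) for one
#' library. Multimapped read counts are parsed but never contribute to
#' junction support: repeat-mismapped evidence is exactly what the artifact
#' filters exist to exclude.
#'
#' @param path Path to the junction table.
#' @param library_id Label attributing the unique-read counts to a library.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `"*"` for undefined), `motif_code`, `annotated`,
#'   `reads` (unique reads), `multimap_reads`, `overhang`, `library`.
#' @export
read_sj_table <- function(path, library_id) {
  stopifnot(is.character(library_id), length(library_id) == 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif_code = integer(),
                      annotated = integer(), reads = integer(),
                      multimap_reads = integer(), overhang = integer(),
                      library = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 9L)) {
    bad <- which(nfield != 9L)[1L]
    stop(sprintf("malformed junction table %s: line %d has %d columns, expected 9",
                 path, bad, nfield[bad]))
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed junction table %s: non-integer coordinates", path))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    stop(sprintf("malformed junction table %s: line %d has end < start", path, bad))
  }
  data.frame(
    chrom = m[, 1],
    start = start,
    end = end,
    strand = c("*", "+", "-")[as.integer(m[, 4]) + 1L],
    motif_code = as.integer(m[, 5]),
    annotated = as.integer(m[, 6]),
    reads = as.integer(m[, 7]),
    multimap_reads = as.integer(m[, 8]),
    overhang = as.integer(m[, 9]),
    library = library_id,
    stringsAsFactors = FALSE
  )
}

#' Merge per-library junction tables into one junction set
#'
#' Junctions are keyed by (chrom, start, end, strand); per-library unique
#' read counts become `reads.<library>` columns. `total_reads` sums unique
#' reads over libraries and `n_libraries` counts libraries with nonzero
#' support. An optional `positions` column (distinct duplicate-collapsed
#' alignment positions) may be supplied by programmatic callers; it is `NA`
#' for parsed tables, which carry no such field.
#'
#' @param tables List of data.frames from [read_sj_table()].
#' @return One data.frame, one row per distinct junction.
#' @export
merge_sj_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  all_df <- do.call(rbind, tables)
  libs <- unique(all_df$library)
  key <- paste(all_df$chrom, all_df$start, all_df$end, all_df$strand, sep = "\r")
  uk <- !duplicated(key)
  out <- all_df[uk, c("chrom", "start", "end", "strand", "overhang")]
  rownames(out) <- NULL
  ukey <- key[uk]
  for (lib in libs) {
    cnt <- integer(nrow(out))
    sel <- all_df$library == lib
    idx <- match(key[sel], ukey)
    cnt[idx] <- cnt[idx] + all_df$reads[sel]
    out[[paste0("reads.", lib)]] <- cnt
  }
  cnt_mat <- as.matrix(out[, paste0("reads.", libs), drop = FALSE])
  out$total_reads <- as.integer(rowSums(cnt_mat))
  out$n_libraries <- as.integer(rowSums(cnt_mat > 0))
  out$overhang <- vapply(seq_len(nrow(out)), function(i) {
    max(all_df$overhang[key == ukey[i]])
  }, integer(1))
  out$positions <- NA_integer_
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient junctions and extract terminal dinucleotides
#'
#' For stranded junctions the donor/acceptor dinucleotides are read from the
#' genome in transcript orientation. Strand-undefined junctions (SJ strand
#' code 0) are tried in both orientations; the orientation yielding valid
#' splice-site dinucleotides (donor in `donors`, acceptor `"AG"`) is kept,
#' and junctions valid in both or neither orientation are dropped (flagged
#' ambiguous / unresolvable).
#'
#' @param junctions Merged junction data.frame ([merge_sj_tables()]).
#' @param genome `DNAStringSet` from [read_genome()].
#' @param donors Donor dinucleotides considered valid when resolving strand.
#' @return The junction data.frame with resolved `strand` and added `donor`
#'   and `acceptor` columns; dropped rows are reported via a message.
#' @export
resolve_junction_strands <- function(junctions, genome, donors = c("GT", "GC")) {
  if (nrow(junctions) == 0L) {
    junctions$donor <- character(0); junctions$acceptor <- character(0)
    return(junctions)
  }
  check_junction_bounds(junctions, genome)
  din <- function(strand) {
    first <- extract_genome_seq(genome, junctions$chrom, junctions$start,
                                junctions$start + 1L)
    last <- extract_genome_seq(genome, junctions$chrom, junctions$end - 1L,
                               junctions$end)
    if (strand == "+") list(donor = first, acceptor = last)
    else list(donor = revcomp(last), acceptor = revcomp(first))
  }
  plus <- din("+"); minus <- din("-")
  valid_plus <- plus$donor %in% donors & plus$acceptor == "AG"
  valid_minus <- minus$donor %in% donors & minus$acceptor == "AG"
  strand <- junctions$strand
  undef <- strand == "*"
  strand[undef & valid_plus & !valid_minus] <- "+"
  strand[undef & valid_minus & !valid_plus] <- "-"
  drop <- undef & (valid_plus == valid_minus)
  if (any(drop)) {
    message(sum(drop), " strand-undefined junction(s) dropped (ambiguous or no valid orientation)")
  }
  keep <- !drop
  junctions <- junctions[keep, , drop = FALSE]
  strand <- strand[keep]
  junctions$strand <- strand
  junctions$donor <- ifelse(strand == "+", plus$donor[keep], minus$donor[keep])
  junctions$acceptor <- ifelse(strand == "+", plus$acceptor[keep], minus$acceptor[keep])
  rownames(junctions) <- NULL
  junctions
}

check_junction_bounds <- function(junctions, genome) {
  len <- genome_lengths(genome)
  unknown <- !(junctions$chrom %in% names(len))
  if (any(unknown)) {
    stop("junction on unknown chromosome: ",
         paste(unique(junctions$chrom[unknown]), collapse = ", "))
  }
  over <- junctions$start < 1L | junctions$end > len[junctions$chrom]
  if (any(over)) {
    i <- which(over)[1L]
    stop(sprintf("junction %s:%d-%d outside chromosome bounds",
                 junctions$chrom[i], junctions$start[i], junctions$end[i]))
  }
  short <- junctions$end - junctions$start + 1L < 4L
  if (any(short)) {
    i <- which(short)[1L]
    stop(sprintf("junction %s:%d-%d shorter than 4 nt",
                 junctions$chrom[i], junctions$start[i], junctions$end[i]))
  }
  invisible(TRUE)
}

# Extract genomic subsequences (plus strand, 1-based closed), vectorized.
extract_genome_seq <- function(genome, chrom, start, end) {
  as.character(Biostrings::subseq(genome[chrom], start = start, end = end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Oriented intron sequence (5'->3' in transcript orientation).
intron_sequence <- function(genome, chrom, start, end, strand) {
  s <- extract_genome_seq(genome, chrom, start, end)
  ifelse(strand == "-", revcomp(s), s)
}

#' Load genome and annotation together
#'
#' @param fasta Path to the genome FASTA.
#' @param annotation Path to a GFF3 or BED12 annotation.
#' @param format `"gff3"` or `"bed12"`; guessed from the file extension by
#'   default.
#' @return A list with elements `genome` (`DNAStringSet`) and `annotation`
#'   (see [read_annotation()]).
#' @export
load_reference_bundle <- function(fasta, annotation,
                                  format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  genome <- read_genome(fasta)
  ann <- read_annotation(annotation, format = format, genome = genome)
  list(genome = genome, annotation = ann)
}

#' Read a gene annotation (GFF3 or BED12)
#'
#' GFF3 input uses `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR`,
#' `three_prime_UTR` and `intron` feature types; the standard-intron set is
#' taken from explicit `intron` features when present and otherwise inferred
#' from gaps between exons of the same mRNA. BED12 input defines exons via
#' blockStarts/blockSizes, with `thickStart`/`thickEnd` delimiting the CDS.
#' All coordinates are normalized to 1-based closed `GRanges`.
#'
#' Genes whose assembled CDS length is not a multiple of 3 are flagged
#' (`cds_ok = FALSE`) with a warning and excluded from ORF-level analyses
#' (in-frame classification, CDS translation).
#'
#' @param path Annotation file path.
#' @param format `"auto"`, `"gff3"` or `"bed12"`.
#' @param genome Optional genome (`DNAStringSet`) used to bounds-check
#'   features.
#' @return An object of class `"AnnotationSet"`: a list with `genes`
#'   (GRanges, transcript interval per gene, with `gene_id` and `cds_ok`),
#'   `cds` (GRangesList by gene), `utr5`, `utr3` (GRanges with `gene_id`)
#'   and `introns` (GRanges of standard introns with `intron_id`).
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12"),
                            genome = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    ann <- annotation_from_gff(gr)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ann <- annotation_from_bed12(gr)
  }
  if (!is.null(genome)) {
    len <- genome_lengths(genome)
    for (part in list(ann$genes, ann$introns, ann$utr5, ann$utr3, unlist(ann$cds))) {
      if (length(part) == 0L) next
      chr <- as.character(GenomeInfoDb::seqnames(part))
      if (!all(chr %in% names(len))) stop("annotation feature on unknown chromosome")
      if (any(BiocGenerics::start(part) < 1L | BiocGenerics::end(part) > len[chr])) {
        stop("annotation feature beyond chromosome end")
      }
    }
  }
  bad <- !ann$genes$cds_ok
  if (any(bad)) {
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(ann$genes$gene_id[bad], collapse = ", "),
            "; excluded from ORF-level analyses")
  }
  ann
}

annotation_from_gff <- function(gr) {
  type <- as.character(gr$type)
  get_gene_id <- function(x) {
    id <- if (!is.null(x$gene_id)) x$gene_id else NA_character_
    if (all(is.na(id)) && !is.null(x$Parent)) {
      id <- vapply(x$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
      id <- sub("^(mRNA|transcript)[.:_-]?", "", id)
    }
    if (all(is.na(id)) && !is.null(x$ID)) id <- x$ID
    id
  }
  genes <- gr[type == "gene"]
  gene_ids <- if (!is.null(genes$ID)) genes$ID else get_gene_id(genes)
  mrna <- gr[type == "mRNA"]
  # transcript interval: the mRNA span when present, else the gene span
  tx <- genes
  if (length(mrna) > 0L) {
    mids <- sub("^(mRNA|transcript)[.:_-]?", "",
                vapply(mrna$Parent, function(p) p[[1]], character(1)))
    hit <- match(gene_ids, mids)
    ok <- !is.na(hit)
    tx[ok] <- mrna[hit[ok]]
  }
  out_genes <- GenomicRanges::granges(tx)
  out_genes$gene_id <- gene_ids

  pick <- function(t) {
    x <- gr[type == t]
    g <- GenomicRanges::granges(x)
    g$gene_id <- sub("^(mRNA|transcript)[.:_-]?", "", get_gene_id(x))
    g
  }
  cds <- pick("CDS")
  utr5 <- pick("five_prime_UTR")
  utr3 <- pick("three_prime_UTR")
  introns <- gr[type == "intron"]
  intron_gr <- GenomicRanges::granges(introns)
  intron_gr$intron_id <- if (length(introns) && !is.null(introns$ID)) {
    introns$ID
  } else if (length(introns)) {
    paste0("intron_", seq_along(introns))
  } else character(0)
  if (length(intron_gr) == 0L && length(gr[type == "exon"]) >= 2L) {
    intron_gr <- introns_from_exons(gr[type == "exon"], get_gene_id)
  }
  build_annotation_set(out_genes, cds, utr5, utr3, intron_gr)
}

introns_from_exons <- function(exons, get_gene_id) {
  gid <- get_gene_id(exons)
  spl <- S4Vectors::split(GenomicRanges::granges(exons), gid)
  gaps <- unlist(GenomicRanges::psetdiff(unlist(range(spl)), spl))
  if (length(gaps) == 0L) {
    gaps <- GenomicRanges::GRanges()
  }
  gaps$intron_id <- if (length(gaps)) paste0("intron_", seq_along(gaps)) else character(0)
  gaps
}

annotation_from_bed12 <- function(gr) {
  gene_ids <- if (!is.null(gr$name)) gr$name else paste0("gene_", seq_along(gr))
  genes <- GenomicRanges::granges(gr)
  genes$gene_id <- gene_ids
  cds_list <- list(); utr5_list <- list(); utr3_list <- list(); intr_list <- list()
  for (i in seq_along(gr)) {
    blocks <- gr$blocks[[i]]  # exon blocks relative to chromStart, 1-based in rtracklayer
    chrom <- as.character(GenomeInfoDb::seqnames(gr[i]))
    strand <- as.character(BiocGenerics::strand(gr[i]))
    gstart <- BiocGenerics::start(gr[i])
    ex <- GenomicRanges::GRanges(chrom,
      IRanges::IRanges(gstart + BiocGenerics::start(blocks) - 1L,
                       gstart + BiocGenerics::end(blocks) - 1L), strand)
    thick <- gr$thick[i]
    ts <- BiocGenerics::start(thick); te <- BiocGenerics::end(thick)
    with_id <- function(g) { if (length(g)) g$gene_id <- gene_ids[i]; g }
    cds_list[[i]] <- with_id(IRanges::restrict(ex, start = ts, end = te))
    left <- with_id(IRanges::restrict(ex, end = ts - 1L))
    right <- with_id(IRanges::restrict(ex, start = te + 1L))
    utr5_list[[i]] <- if (strand == "-") right else left
    utr3_list[[i]] <- if (strand == "-") left else right
    intr_list[[i]] <- GenomicRanges::setdiff(range(ex), ex)
  }
  cds <- do.call(c, cds_list)
  utr5 <- do.call(c, utr5_list); utr3 <- do.call(c, utr3_list)
  introns <- do.call(c, intr_list)
  if (length(introns)) introns$intron_id <- paste0("intron_", seq_along(introns))
  else introns <- GenomicRanges::GRanges(intron_id = character(0))
  build_annotation_set(genes, cds, utr5, utr3, introns)
}

build_annotation_set <- function(genes, cds, utr5, utr3, introns) {
  cds_by_gene <- S4Vectors::split(cds, factor(cds$gene_id, levels = genes$gene_id))
  cds_len <- sum(BiocGenerics::width(cds_by_gene))
  genes$cds_ok <- cds_len == 0L | cds_len %% 3L == 0L
  structure(list(genes = genes, cds = cds_by_gene, utr5 = utr5, utr3 = utr3,
                 introns = introns),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", length(x$genes), "genes,",
      length(x$introns), "standard introns\n")
  invisible(x)
}

#' Assemble the coding sequence of a gene
#'
#' Concatenates the CDS intervals in genomic order; on the minus strand the
#' reverse complement of the descending-order concatenation is returned, with
#' CDS phase implicit in the interval boundaries.
#'
#' @param annotation An `AnnotationSet`.
#' @param genome A `DNAStringSet`.
#' @param gene_id Gene identifier.
#' @return Coding sequence as a character string (starts ATG for well-formed
#'   genes).
#' @export
get_cds_sequence <- function(annotation, genome, gene_id) {
  cds <- annotation$cds[[gene_id]]
  if (is.null(cds) || length(cds) == 0L) stop("no CDS for gene ", gene_id)
  cds <- BiocGenerics::sort(cds)
  chrom <- as.character(GenomeInfoDb::seqnames(cds))
  parts <- extract_genome_seq(genome, chrom, BiocGenerics::start(cds),
                              BiocGenerics::end(cds))
  s <- paste(parts, collapse = "")
  if (as.character(BiocGenerics::strand(cds))[1] == "-") s <- revcomp(s)
  s
}

#' Read a bedGraph coverage or conservation track
#'
#' bedGraph intervals (0-based half-open on disk) are expanded to a per-base
#' representation. In `"depth"` mode absent positions mean zero coverage; in
#' `"phastcons"` mode absent positions mean *unscored* and values must lie in
#' \[0, 1\].
#'
#' @param path bedGraph file path.
#' @param mode `"depth"` or `"phastcons"`.
#' @return An object of class `"CoverageTrack"`: list with `values` (RleList
#'   per chromosome), `scored` (logical RleList) and `mode`.
#' @export
read_bedgraph <- function(path, mode = c("depth", "phastcons")) {
  mode <- match.arg(mode)
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(gr, mode = mode)
}

#' Build a CoverageTrack from a scored GRanges
#'
#' @param gr GRanges with a numeric `score` column.
#' @param mode `"depth"` or `"phastcons"`.
#' @param seqlengths Optional named chromosome lengths; defaults to the
#'   maximum covered position per chromosome.
#' @return A `"CoverageTrack"` object.
#' @export
coverage_track <- function(gr, mode = c("depth", "phastcons"), seqlengths = NULL) {
  mode <- match.arg(mode)
  if (mode == "phastcons" && length(gr) &&
      (min(gr$score) < 0 || max(gr$score) > 1)) {
    stop("phastCons scores must lie in [0, 1]")
  }
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  values <- GenomicRanges::coverage(gr, weight = gr$score)
  scored <- GenomicRanges::coverage(gr) > 0
  structure(list(values = values, scored = scored, mode = mode),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack (", x$mode, "): ", length(x$values),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

# Per-base values over a window, honoring the scored mask. Positions beyond
# the stored track are absent (0 in depth mode, unscored in phastcons mode).
track_values <- function(track, chrom, start, end) {
  n <- end - start + 1L
  vals <- numeric(n)
  scored <- logical(n)
  if (chrom %in% names(track$values)) {
    rle <- track$values[[chrom]]
    msk <- track$scored[[chrom]]
    avail <- min(end, length(rle))
    if (avail >= start) {
      idx <- seq_len(avail - start + 1L)
      vals[idx] <- as.numeric(S4Vectors::window(rle, start, avail))
      scored[idx] <- as.logical(S4Vectors::window(msk, start, avail))
    }
  }
  if (track$mode == "depth") scored <- rep(TRUE, n)
  list(values = vals, scored = scored)
}

#' Write a results table as TSV
#'
#' Emits a tab-separated file with header. Coordinates are already 1-based
#' inclusive internally, matching the supplementary-table style of the
#' output. Floating-point columns are rounded to 4 significant digits and
#' rows are ordered deterministically by (chrom, start, end) when those
#' columns exist.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  if (all(c("chrom", "start", "end") %in% names(df)) && nrow(df) > 0) {
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 4)
  }
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results table to ", path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write junctions in the SJ.out.tab dialect
#'
#' Inverse of [read_sj_table()] for one library: used by the synthetic-data
#' generator and for coordinate round-trip checks.
#'
#' @param junctions data.frame with `chrom`, `start`, `end`, `strand`,
#'   `motif_code`, `annotated`, `reads`, `multimap_reads`, `overhang`.
#' @param path Output path.
#' @export
write_sj_table <- function(junctions, path) {
  strand_code <- match(junctions$strand, c("*", "+", "-")) - 1L
  m <- cbind(junctions$chrom, junctions$start, junctions$end, strand_code,
             junctions$motif_code, junctions$annotated, junctions$reads,
             junctions$multimap_reads, junctions$overhang)
  writeLines(apply(m, 1, paste, collapse = "\t"), path)
  invisible(path)
}
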