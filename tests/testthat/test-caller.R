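# A small hand-built genome for filter tests: one valid intron plus decoys,
# each violating exactly one rule.
valid_intron <- function() {
  paste0("GTATGT", strrep("C", 50), "TACTAAC", strrep("C", 34), "CAG")  # 100 nt
}

toy_filter_genome <- function(intron = valid_intron()) {
  set.seed(9021)
  seqs <- paste0(random_intron_seq(40), intron, random_intron_seq(40))
  Biostrings::DNAStringSet(c(chrF = seqs))
}

test_that("each filter fires alone on its designed decoy", {
  g <- toy_filter_genome()
  at <- c(41L, 140L)  # intron occupies [41, 140]
  base <- function(reads) toy_junctions("chrF", at[1], at[2], "+",
                                        list(a = reads[1], b = reads[2]))
  ev <- filter_junctions(base(c(5L, 5L)), g)
  expect_true(ev$accepted)
  expect_equal(ev$reasons, "")
  expect_equal(ev$bp_index, 61L)  # TACTAAC at 0-based 56, branch A offset 5

  ev <- filter_junctions(base(c(1L, 1L)), g)
  expect_equal(ev$reasons, "min_reads")

  ev <- filter_junctions(toy_junctions("chrF", at[1], at[2], "+",
                                       list(a = 10L, b = 0L)), g)
  expect_equal(ev$reasons, "jackpot")
  # two alignment positions rescue a single-library junction
  ev <- filter_junctions(toy_junctions("chrF", at[1], at[2], "+",
                                       list(a = 10L, b = 0L), positions = 2L), g)
  expect_true(ev$accepted)

  # all filters evaluated exhaustively: a junction can fail several at once
  ev <- filter_junctions(toy_junctions("chrF", at[1], at[2], "+",
                                       list(a = 1L, b = 0L)), g)
  expect_setequal(strsplit(ev$reasons, ",")[[1]], c("min_reads", "jackpot"))
})

test_that("donor, acceptor and GAG-context filters read the genome", {
  # CT donor
  g <- toy_filter_genome(paste0("CTATGT", strrep("C", 50), "TACTAAC",
                                strrep("C", 34), "CAG"))
  j <- toy_junctions("chrF", 41L, 140L, "+", list(a = 5L, b = 5L))
  j$donor <- "CT"; j$acceptor <- "AG"
  expect_equal(filter_junctions(j, g)$reasons, "donor")

  # GAG 3' splice site
  g <- toy_filter_genome(paste0("GTATGT", strrep("C", 50), "TACTAAC",
                                strrep("C", 34), "GAG"))
  j <- toy_junctions("chrF", 41L, 140L, "+", list(a = 5L, b = 5L))
  j$donor <- "GT"; j$acceptor <- "AG"
  expect_equal(filter_junctions(j, g)$reasons, "gag_3ss")

  # no branchpoint: A-free intron body
  g <- toy_filter_genome(paste0("GTCTGT", strrep("C", 91), "CAG"))
  j <- toy_junctions("chrF", 41L, 140L, "+", list(a = 5L, b = 5L))
  j$donor <- "GT"; j$acceptor <- "AG"
  expect_equal(filter_junctions(j, g)$reasons, "no_branchpoint")
})

test_that("strand must be resolved and bounds are checked", {
  g <- toy_filter_genome()
  j <- toy_junctions("chrF", 41L, 140L, "*", list(a = 5L, b = 5L))
  expect_error(filter_junctions(j, g), "strand-resolved")
  j <- toy_junctions("chrF", 41L, 9999L, "+", list(a = 5L, b = 5L))
  expect_error(filter_junctions(j, g), "outside chromosome bounds")
})

test_that("contiguous genome match detects planted spliced copies", {
  set.seed(11)
  base <- random_intron_seq(1000)
  up <- substr(base, 81, 100); dn <- substr(base, 201, 220)
  # genome with the spliced 40-mer also planted contiguously at the end
  g1 <- Biostrings::DNAStringSet(c(chr = paste0(base, up, dn)))
  j <- data.frame(chrom = "chr", start = 101L, end = 200L)
  expect_true(contiguous_genome_match(j, g1, flank = 20L))
  # and detected on the minus strand too
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(up, dn))))
  g2 <- Biostrings::DNAStringSet(c(chr = paste0(base, rc)))
  expect_true(contiguous_genome_match(j, g2, flank = 20L))
  # absent from a clean random genome: agree with a substring-search oracle
  g3 <- Biostrings::DNAStringSet(c(chr = base))
  oracle <- grepl(paste0(up, dn), base, fixed = TRUE) ||
    grepl(rc, base, fixed = TRUE)
  expect_identical(contiguous_genome_match(j, g3, flank = 20L), oracle)
  expect_false(oracle)
  # truncated flank at the chromosome start
  j0 <- data.frame(chrom = "chr", start = 6L, end = 105L)
  expect_warning(res <- contiguous_genome_match(j0, g3, flank = 20L),
                 "truncated")
  expect_false(res)
})

test_that("standard-intron overlap separation uses the one-base same-strand rule", {
  intr <- GenomicRanges::GRanges("chr", IRanges::IRanges(100, 200), "+",
                                 intron_id = "i1")
  ann <- structure(list(introns = intr), class = "AnnotationSet")
  ev <- data.frame(chrom = "chr", start = c(100L, 200L, 211L, 150L),
                   end = c(200L, 300L, 300L, 180L),
                   strand = c("+", "+", "+", "-"),
                   event_id = paste0("e", 1:4))
  res <- separate_standard_overlaps(ev, ann)
  expect_equal(res$standard$event_id, c("e1", "e2"))   # identical + 1-base share
  expect_equal(res$protointron$event_id, c("e3", "e4"))  # downstream / antisense
})

test_that("merging forms connected components and is order-independent", {
  ev <- data.frame(chrom = "chr", start = c(100L, 150L, 400L),
                   end = c(200L, 250L, 500L), strand = "+",
                   event_id = c("a", "b", "c"))
  loc <- merge_events_to_locations(ev)
  expect_equal(nrow(loc), 2L)
  expect_equal(loc$start, c(100L, 400L))
  expect_equal(loc$end, c(250L, 500L))
  expect_equal(loc$event_ids[1], "a,b")
  shuffled <- merge_events_to_locations(ev[c(3, 1, 2), ])
  expect_identical(loc, shuffled)
  # same interval, opposite strands: never merged
  ev2 <- data.frame(chrom = "chr", start = 100L, end = 200L,
                    strand = c("+", "-"), event_id = c("p", "m"))
  expect_equal(nrow(merge_events_to_locations(ev2)), 2L)
  # property: location count <= event count; equality iff no two overlap
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    st <- sample(1:500, n, replace = TRUE)
    ev3 <- data.frame(chrom = "chr", start = st,
                      end = st + sample(20:120, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      event_id = paste0("x", seq_len(n)))
    loc3 <- merge_events_to_locations(ev3)
    expect_lte(nrow(loc3), nrow(ev3))
    expect_identical(loc3, merge_events_to_locations(ev3[sample(n), ]))
  }
})

test_that("context classification covers the six categories", {
  dir <- withr::local_tempdir()
  cds <- paste0("ATG", strrep("GGTTCA", 20), "TAA")  # 126 nt
  gene <- paste0(strrep("T", 60), cds, strrep("T", 60))
  ref <- write_toy_reference(dir, gene, 60L, 126L)
  bundle <- load_reference_bundle(ref$fasta, ref$gff)
  pad <- ref$pad
  mk_loc <- function(start, end, strand = "+") {
    data.frame(location_id = "L", chrom = "chrT", strand = strand,
               start = start, end = end, n_events = 1L, event_ids = "e")
  }
  ctx <- function(s, e, strand = "+") {
    classify_context(mk_loc(s, e, strand), bundle$annotation)$context
  }
  expect_equal(ctx(pad + 70, pad + 120), "coding")
  expect_equal(ctx(pad + 10, pad + 50), "5'UTR")
  expect_equal(ctx(pad + 40, pad + 80), "5'UTR^coding")
  expect_equal(ctx(pad + 150, pad + 200), "coding^3'UTR")
  expect_equal(ctx(pad + 190, pad + 230), "3'UTR")
  expect_equal(ctx(pad + 70, pad + 120, "-"), "non-coding")   # antisense
  expect_equal(ctx(5, 20), "non-coding")                      # intergenic
})

test_that("in-frame classification translates the excised CDS", {
  dir <- withr::local_tempdir()
  # CDS: ATG | TAC | 33 x GGT (99-nt block) | ACG | TAA
  block <- strrep("GGT", 33)
  cds <- paste0("ATG", "TAC", block, "ACG", "TAA")
  gene <- paste0(strrep("T", 30), cds, strrep("T", 30))
  ref <- write_toy_reference(dir, gene, 30L, nchar(cds))
  bundle <- load_reference_bundle(ref$fasta, ref$gff)
  loc <- function(s, e) {
    data.frame(location_id = "L", chrom = "chrT", strand = "+", start = s,
               end = e, n_events = 1L, event_ids = "e", context = "coding",
               gene_id = "geneA")
  }
  b0 <- ref$pad + 30L + 6L     # genomic position before the 99-nt block
  # 99-nt excision at a codon boundary: frame preserved, no new stop
  expect_true(is_in_frame(loc(b0 + 1L, b0 + 99L), bundle$annotation,
                          bundle$genome))
  # 100-nt excision: frame shift
  expect_false(is_in_frame(loc(b0 + 1L, b0 + 100L), bundle$annotation,
                           bundle$genome))

  # a 3n excision that fuses T|...|AA into a new in-frame TAA stop:
  # CDS2 = ATG T [99-nt block] AA CGG TAA; excision leaves ATG TAA ...
  dir2 <- withr::local_tempdir()
  cds2 <- paste0("ATG", "T", block, "AA", "CGG", "TAA")
  gene2 <- paste0(strrep("T", 30), cds2, strrep("T", 30))
  ref2 <- write_toy_reference(dir2, gene2, 30L, nchar(cds2))
  bundle2 <- load_reference_bundle(ref2$fasta, ref2$gff)
  s2 <- ref2$pad + 30L + 5L   # genomic position of CDS base 5 (block start)
  expect_false(is_in_frame(loc(s2, s2 + 98L), bundle2$annotation,
                           bundle2$genome))
})
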