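test_that("junction tables parse with exact coordinate conventions", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines("chrI\t1002\t1101\t1\t1\t0\t12\t3\t24", path)
  rec <- read_sj_table(path, "libA")
  expect_equal(rec$chrom, "chrI")
  expect_equal(rec$start, 1002L)   # 1-based first intron base
  expect_equal(rec$end, 1101L)     # 1-based last intron base
  expect_equal(rec$strand, "+")
  expect_equal(rec$reads, 12L)
  expect_equal(rec$multimap_reads, 3L)
  expect_equal(rec$library, "libA")

  writeLines(character(0), path)
  expect_equal(nrow(read_sj_table(path, "libA")), 0L)

  writeLines("chrI\t1002\t1101\t1\t1\t0\t12\t3", path)
  expect_error(read_sj_table(path, "libA"), "line 1.*8 columns")

  writeLines("chrI\t1101\t1002\t1\t1\t0\t12\t3\t24", path)
  expect_error(read_sj_table(path, "libA"), "end < start")
})

test_that("junction coordinates round-trip through write and re-read", {
  path <- withr::local_tempfile(fileext = ".tab")
  df <- data.frame(chrom = c("chrI", "chrII"), start = c(120L, 77L),
                   end = c(260L, 401L), strand = c("+", "-"),
                   motif_code = c(1L, 2L), annotated = c(0L, 1L),
                   reads = c(8L, 15L), multimap_reads = c(0L, 2L),
                   overhang = c(25L, 31L))
  write_sj_table(df, path)
  back <- read_sj_table(path, "lib")
  expect_equal(back[, c("chrom", "start", "end", "strand", "reads")],
               df[, c("chrom", "start", "end", "strand", "reads")])
})

test_that("multimapped reads never contribute to merged support", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines("chrI\t100\t200\t1\t1\t0\t4\t100\t24", path)
  merged <- merge_sj_tables(list(read_sj_table(path, "a"),
                                 read_sj_table(path, "b")))
  expect_equal(merged$total_reads, 8L)
  expect_equal(merged$n_libraries, 2L)
})

test_that("genome loading uppercases and rejects foreign characters", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtN", "ggtt"), fa)
  g <- read_genome(fa)
  expect_equal(as.character(g[["chr1"]]), "ACGTNGGTT")
  expect_equal(genome_lengths(g), c(chr1 = 9L))
})

test_that("strand resolution orients undefined junctions by dinucleotides", {
  fa <- withr::local_tempfile(fileext = ".fa")
  # plus-strand GT...AG junction at 11..20; also a palindromic-ish decoy
  # valid in both orientations at 31..40 (CT..AC = minus GT..AG; GT..AG plus)
  writeLines(c(">c", paste0(strrep("C", 10), "GTCCCCCCAG", strrep("C", 10),
                            "GTCCCCCCAC", strrep("C", 10))), fa)
  g <- read_genome(fa)
  j <- toy_junctions("c", c(11L, 31L), c(20L, 40L), c("*", "*"),
                     list(l1 = c(5L, 5L), l2 = c(5L, 5L)))
  # 31..40 = GT......AC: plus donor GT but acceptor AC -> invalid plus;
  # minus: revcomp(AC..) donor GT, acceptor revcomp(GT) = AC -> invalid
  expect_message(res <- resolve_junction_strands(j, g), "dropped")
  expect_equal(nrow(res), 1L)
  expect_equal(res$strand, "+")
  expect_equal(res$donor, "GT")
  expect_equal(res$acceptor, "AG")
})

test_that("minus-strand donor extraction reverse-complements to GT", {
  fa <- withr::local_tempfile(fileext = ".fa")
  # minus-strand intron at 11..20: genomic CT......AC reads GT......AG on minus
  writeLines(c(">c", paste0(strrep("A", 10), "CTGGGGGGAC", strrep("A", 10))), fa)
  g <- read_genome(fa)
  j <- toy_junctions("c", 11L, 20L, "*", list(l1 = 6L, l2 = 6L))
  res <- resolve_junction_strands(j, g)
  expect_equal(res$strand, "-")
  expect_equal(res$donor, "GT")
  expect_equal(res$acceptor, "AG")
})

test_that("GFF3 annotation loads with file-convention coordinates intact", {
  dir <- withr::local_tempdir()
  # gene: 20 nt 5'UTR, 30 nt CDS, 15 nt 3'UTR
  cds <- "ATGGGTTCAGCTCATAAGGAGCCTGCGTAA"
  gene <- paste0(strrep("T", 20), cds, strrep("T", 15))
  ref <- write_toy_reference(dir, gene, 20L, 30L, strand = "+")
  bundle <- load_reference_bundle(ref$fasta, ref$gff)
  ann <- bundle$annotation
  expect_s3_class(ann, "AnnotationSet")
  expect_equal(ann$genes$gene_id, "geneA")
  expect_equal(BiocGenerics::start(ann$cds[["geneA"]]), ref$cds[1])
  expect_equal(BiocGenerics::end(ann$cds[["geneA"]]), ref$cds[2])
  expect_true(ann$genes$cds_ok)
  expect_equal(get_cds_sequence(ann, bundle$genome, "geneA"), cds)
})

test_that("minus-strand two-exon CDS assembles as reverse complement of descending exons", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  # genomic: exon2 [11,25], intron [26,40], exon1 [41,55] on minus strand
  set.seed(41)
  chrom <- random_intron_seq(70)
  writeLines(c(">chrM", chrom), fa)
  writeLines(c("##gff-version 3",
    "chrM\tt\tgene\t11\t55\t.\t-\t.\tID=gm",
    "chrM\tt\tmRNA\t11\t55\t.\t-\t.\tID=mRNA.gm;Parent=gm",
    "chrM\tt\tCDS\t41\t55\t.\t-\t0\tParent=mRNA.gm",
    "chrM\tt\tCDS\t11\t25\t.\t-\t0\tParent=mRNA.gm"), gff)
  bundle <- load_reference_bundle(fa, gff)
  got <- get_cds_sequence(bundle$annotation, bundle$genome, "gm")
  expected <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0(substr(chrom, 11, 25), substr(chrom, 41, 55)))))
  expect_equal(got, expected)
})

test_that("annotation validation flags bad CDS lengths and out-of-bounds features", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  writeLines(c(">chrZ", strrep("ACGT", 25)), fa)
  writeLines(c("##gff-version 3",
    "chrZ\tt\tgene\t1\t50\t.\t+\t.\tID=gz",
    "chrZ\tt\tCDS\t10\t19\t.\t+\t0\tParent=gz"), gff)  # 10 nt CDS
  expect_warning(ann <- read_annotation(gff, genome = read_genome(fa)),
                 "not divisible by 3")
  expect_false(ann$genes$cds_ok)
  writeLines(c("##gff-version 3",
    "chrZ\tt\tgene\t1\t500\t.\t+\t.\tID=gz"), gff)
  expect_error(read_annotation(gff, genome = read_genome(fa)),
               "beyond chromosome end")
})

test_that("results tables write deterministically and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(chrom = character(), start = integer(), end = integer())
  write_results_table(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only

  df <- data.frame(chrom = c("chrII", "chrI"), start = c(5L, 9L),
                   end = c(10L, 20L), score = c(1.23456789, 2.5),
                   stringsAsFactors = FALSE)
  write_results_table(df, path)
  back <- read_results_table(path)
  expect_equal(back$chrom, c("chrI", "chrII"))  # sorted chrom then start
  expect_equal(back$score, c(2.5, 1.235))       # 4 significant digits
  write_results_table(back, path)
  expect_equal(read_results_table(path), back)  # stable round trip
})

test_that("bedGraph tracks honor depth vs phastCons semantics", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t5\t4", "chr1\t10\t12\t8"), bg)
  depth <- read_bedgraph(bg, "depth")
  v <- protointrons:::track_values(depth, "chr1", 1L, 12L)
  expect_equal(v$values, c(rep(4, 5), rep(0, 5), 8, 8))
  expect_true(all(v$scored))  # absent positions mean zero depth

  writeLines(c("chr1\t0\t2\t0.9", "chr1\t4\t6\t0.1"), bg)
  cons <- read_bedgraph(bg, "phastcons")
  v <- protointrons:::track_values(cons, "chr1", 1L, 6L)
  expect_equal(v$scored, c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(v$values[v$scored], c(0.9, 0.9, 0.1, 0.1))

  writeLines("chr1\t0\t2\t1.5", bg)
  expect_error(read_bedgraph(bg, "phastcons"), "0, 1")
})

test_that("BED12 blocks define exons, CDS and inferred introns", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "g.bed")
  # gene 0-based [10,100); blocks [10,40) and [70,100); thick [21,90)
  writeLines("chr1\t10\t100\tgeneB\t0\t+\t21\t90\t0\t2\t30,30\t0,60", bed)
  ann <- read_annotation(bed, format = "bed12")
  expect_equal(ann$genes$gene_id, "geneB")
  cds <- ann$cds[["geneB"]]
  expect_equal(BiocGenerics::start(cds), c(22L, 71L))
  expect_equal(BiocGenerics::end(cds), c(40L, 90L))
  expect_equal(BiocGenerics::start(ann$introns), 41L)
  expect_equal(BiocGenerics::end(ann$introns), 70L)
})
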