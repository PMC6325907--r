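test_that("FASTA reading uppercases, wraps, and validates the alphabet", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description text",
               "acgtACGTacgt", "ACGT",
               ">chr2", "NNNACGT"), path)
  g <- read_fasta(path)
  expect_s3_class(g, "Genome")
  expect_equal(names(g$sequences), c("chr1", "chr2"))
  expect_equal(g$sequences[["chr1"]], "ACGTACGTACGTACGT")
  expect_equal(g$sequences[["chr2"]], "NNNACGT")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGR"), bad)
  expect_error(read_fasta(bad), "line 2")

  empty_rec <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", ">y", "ACGT"), empty_rec)
  expect_error(read_fasta(empty_rec), "empty sequence")

  headless <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT"), headless)
  expect_error(read_fasta(headless), "line 1")
})

test_that("FASTA write/read round-trips a simulated genome", {
  sim <- sim_genome(sim_config(101, n_chrom = 2, chrom_len = 3000,
                               n_genes = 0L))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$genome, path)
  back <- read_fasta(path)
  expect_identical(back$sequences, sim$genome$sequences)
})

test_that("GFF3 coordinates convert from 1-based closed to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "I\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1;Name=abc-1",
    "I\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=g1",
    "I\tsrc\texon\t101\t140\t.\t+\t.\tID=e1;Parent=t1",
    "I\tsrc\texon\t161\t200\t.\t+\t.\tID=e2;Parent=t1",
    "I\tsrc\tCDS\t111\t140\t.\t+\t.\tID=c1;Parent=t1"), path)
  fs <- read_gff3(path)
  expect_equal(fs$genes$start, 100L)
  expect_equal(fs$genes$end, 200L)
  ex <- fs$features[fs$features$type == "exon", ]
  expect_equal(ex$start, c(100L, 160L))
  introns <- fs$features[fs$features$type == "intron", ]
  expect_equal(nrow(introns), 1L)
  expect_equal(c(introns$start, introns$end), c(140L, 160L))
})

test_that("two transcripts of one gene keep the per-type union", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "I\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1;Name=abc-1",
    "I\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t1;Parent=g1",
    "I\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "I\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=t2;Parent=g1",
    "I\tsrc\texon\t51\t150\t.\t+\t.\tParent=t2"), path)
  fs <- read_gff3(path)
  ex <- fs$features[fs$features$type == "exon", ]
  expect_equal(nrow(ex), 1L)   # overlapping exons merged
  expect_equal(c(ex$start, ex$end), c(0L, 150L))
})

test_that("orphan child features are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "I\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "I\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1",
    "I\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "I\tsrc\texon\t1\t50\t.\t+\t.\tParent=missing"), path)
  expect_warning(fs <- read_gff3(path), "without a known parent")
  expect_equal(nrow(fs$features[fs$features$type == "exon", ]), 1L)
})

test_that("simulated gene models round-trip through GFF3 write and read", {
  sim <- sim_genome(sim_config(7, n_chrom = 2, chrom_len = 6000,
                               n_genes = 2L))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$features, path)
  back <- read_gff3(path)
  expect_equal(back$genes[order(back$genes$gene_id), ]$start,
               sim$truth$genes$start)
  expect_equal(back$genes[order(back$genes$gene_id), ]$end,
               sim$truth$genes$end)
  # per-gene feature spans preserved (intron derivation included)
  for (tp in c("CDS", "intron", "five_prime_UTR", "three_prime_UTR")) {
    a <- sim$features$features
    b <- back$features
    a <- a[a$type == tp, c("gene_id", "start", "end")]
    b <- b[b$type == tp, c("gene_id", "start", "end")]
    expect_equal(a[do.call(order, a), ], b[do.call(order, b), ],
                 ignore_attr = TRUE)
  }
})

test_that("queries resolve via the 1-based browser dialect or gene name", {
  sim <- sim_genome(sim_config(5, n_chrom = 1, chrom_len = 4000,
                               n_genes = 1L))
  iv <- resolve_query(sim$features, sim$genome, "I:101-200")
  expect_equal(c(iv$chrom, iv$start, iv$end), c("I", 100L, 200L),
               ignore_attr = TRUE)
  g <- sim$truth$genes[1, ]
  hit <- resolve_query(sim$features, sim$genome, toupper(g$public_name))
  expect_equal(c(hit$start, hit$end), c(g$start, g$end))
  expect_error(resolve_query(sim$features, sim$genome, "I:200-100"),
               "malformed")
  expect_error(resolve_query(sim$features, sim$genome, "nope-1"),
               "unknown gene")
  expect_error(resolve_query(sim$features, sim$genome, "I:1-99999"),
               "out of bounds")
  expect_error(resolve_query(sim$features, sim$genome, "XX:1-10"),
               "unknown chromosome")
})

test_that("BED export is 0-based half-open and round-trips intervals", {
  guides <- data.frame(chrom = "I", start = 10L, end = 33L, strand = "+",
                       protospacer = strrep("A", 20), pam = "TGG",
                       stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(guides, path)
  line <- readLines(path)
  expect_equal(line, paste0("I\t10\t33\t", strrep("A", 20), "_TGG\t0\t+"))
  back <- read.delim(path, header = FALSE)
  expect_equal(back$V2, guides$start)
  expect_equal(back$V3, guides$end)

  empty <- withr::local_tempfile(fileext = ".bed")
  write_bed(guides[0, ], empty)
  expect_length(readLines(empty), 0L)
})
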