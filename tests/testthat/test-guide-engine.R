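test_that("sequence-level filters match their definitions", {
  expect_equal(gc_fraction("GGGGGGGGGGAAAAAAAAAA"), 0.5)
  expect_equal(gc_fraction(paste0(strrep("G", 4), strrep("A", 16))), 0.2)
  expect_equal(gc_fraction(strrep("A", 20)), 0)
  expect_error(gc_fraction(""), "empty")

  expect_true(has_polyt("ACGTTTTTACG", 5))
  expect_false(has_polyt("TTTTATTTT", 5))
  expect_true(has_polyt("ACT", 1))
  expect_false(has_polyt("ACG", 1))

  expect_true(gg_end(paste0(strrep("A", 18), "GG")))
  expect_false(gg_end(paste0(strrep("A", 18), "GA")))
  expect_error(gg_end("SHORT"), "20 bases")
})

test_that("a single constructed PAM site yields exactly one forward candidate", {
  s <- paste0(strrep("A", 20), "TGG", strrep("A", 7))
  g <- Genome(c(I = s))
  cand <- enumerate_candidates(g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$strand, "+")
  expect_equal(cand$start, 0L)
  expect_equal(cand$protospacer, strrep("A", 20))
  expect_equal(cand$pam, "TGG")
  expect_equal(cand$cut_pos, 17L)

  expect_equal(nrow(enumerate_candidates(Genome(c(I = strrep("A", 50))))),
               0L)
})

test_that("enumeration matches the exhaustive window scan on random sequence", {
  for (seed in c(11, 12)) {
    g <- Genome(c(I = random_seq(1000, seed)), assembly_tag = "fix")
    cand <- enumerate_candidates(g)
    orc <- oracle_enumerate(g)
    expect_identical(cand[names(orc)], orc)
  }
})

test_that("candidates containing N are dropped at enumeration", {
  s <- paste0(strrep("A", 10), "N", strrep("A", 9), "TGG",
              strrep("C", 2), strrep("T", 21), "AGG")
  g <- Genome(c(I = s))
  cand <- enumerate_candidates(g)
  expect_true(all(!grepl("N", paste0(cand$protospacer, cand$pam))))
})

test_that("seed counts reflect planted copies and match the regex oracle", {
  cfg <- sim_config(21, n_chrom = 1, chrom_len = 5000, n_genes = 0L,
                    planted_guides = list(
                      list(copies = 1L),
                      list(copies = 2L, edits = 2L, edit_in_seed = FALSE),
                      list(copies = 2L, edits = 2L, edit_in_seed = TRUE)))
  sim <- sim_genome(cfg)
  idx <- build_seed_index(sim$genome)
  tr <- sim$truth$guides
  originals <- tr[tr$copy == 1L, ]
  counts <- seed_count(idx, originals$protospacer)
  # distal edits leave the seed shared; seed edits make each copy unique
  expect_equal(counts, c(1L, 2L, 1L))
  for (i in seq_len(nrow(originals)))
    expect_equal(counts[i],
                 oracle_seed_count(sim$genome, originals$protospacer[i]))
})

test_that("seed index refuses candidates from another assembly", {
  g1 <- Genome(c(I = random_seq(300, 1)), assembly_tag = "a")
  g2 <- Genome(c(I = random_seq(300, 2)), assembly_tag = "b")
  idx <- build_seed_index(g1)
  expect_error(seed_count(idx, "ACGTACGTACGTACGTACGT", genome = g2),
               "assembly|built on")
})

test_that("genome hit counts see planted near-copies within edit distance 3", {
  cfg <- sim_config(31, n_chrom = 1, chrom_len = 5000, n_genes = 0L,
                    planted_guides = list(
                      list(copies = 1L),
                      list(copies = 2L, edits = 2L)))
  sim <- sim_genome(cfg)
  tr <- sim$truth$guides
  originals <- tr[tr$copy == 1L, ]
  sites <- paste0(originals$protospacer, "NGG")
  hits <- genome_hits(sim$genome, sites)
  expect_equal(hits, c(1L, 2L))
  for (i in seq_len(nrow(originals)))
    expect_equal(hits[i],
                 oracle_genome_hits(sim$genome, originals$protospacer[i],
                                    "NGG", 3L))
})

test_that("cut-site annotation follows the feature priority", {
  genes <- data.frame(
    gene_id = c("gA", "gB"), public_name = c("aaa-1", "bbb-1"),
    chrom = "I", start = c(100L, 150L), end = c(400L, 600L),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  feats <- data.frame(
    gene_id = c("gA", "gB", "gB"),
    type = c("CDS", "intron", "CDS"),
    chrom = "I", start = c(150L, 150L, 450L), end = c(250L, 400L, 550L),
    strand = "+", stringsAsFactors = FALSE)
  fs <- FeatureSet(genes, feats)
  cand <- data.frame(chrom = "I", cut_pos = c(200L, 50L, 300L, 500L))
  ann <- annotate_cut(cand, fs)
  # CDS of gene A beats intron of gene B at 200
  expect_equal(ann$feature, c("CDS", "intergenic", "intron", "CDS"))
  expect_equal(ann$gene, c("aaa-1", NA, "bbb-1", "bbb-1"))
})

test_that("design_guides annotates planted guides and flags the poly-T one", {
  polyt_guide <- paste0("ACGTACGTAC", "TTTTT", "CATGA")
  good <- c("GTACCTGAAGCTTACGATCA", "ATGGCCTTGGACATCCTAGA",
            "CCATGGATCTTAGCGGTACA")
  cfg <- sim_config(41, n_chrom = 1, chrom_len = 9000, n_genes = 1L,
                    planted_guides = c(
                      lapply(good, function(s) list(sequence = s)),
                      list(list(sequence = polyt_guide))))
  sim <- sim_genome(cfg)
  tr <- sim$truth$guides
  lo <- min(tr$start) - 50L
  hi <- max(tr$end) + 50L
  # restrict to one chromosome-wide design call and pick out planted rows
  guides <- design_guides(sim$genome, sim$features,
                          genomic_interval("I", 0L,
                                           chrom_lengths(sim$genome)[[1]]))
  planted <- guides[guides$protospacer %in% c(good, polyt_guide), ]
  expect_equal(nrow(planted), 4L)
  expect_equal(sum(planted$passes), 3L)
  expect_false(planted$passes[planted$protospacer == polyt_guide])
  expect_true(planted$polyT[planted$protospacer == polyt_guide])

  # determinism: identical call, identical bytes
  again <- design_guides(sim$genome, sim$features,
                         genomic_interval("I", 0L,
                                          chrom_lengths(sim$genome)[[1]]))
  expect_identical(guides, again)

  # gg_end constraint returns the GG-ending subset
  gg <- design_guides(sim$genome, sim$features,
                      genomic_interval("I", 0L,
                                       chrom_lengths(sim$genome)[[1]]),
                      require_gg = TRUE)
  expect_equal(gg, guides[guides$gg_end, ], ignore_attr = TRUE)
  expect_true(all(gg$gg_end))
})

test_that("the filter cascade is order-independent and GG never filters", {
  sim <- sim_genome(sim_config(51, n_chrom = 1, chrom_len = 4000,
                               n_genes = 1L))
  guides <- design_guides(sim$genome, sim$features,
                          genomic_interval("I", 0L, 4000L))
  cfg <- filter_config()
  checks <- list(
    gc = guides$gc >= cfg$gc_min & guides$gc <= cfg$gc_max,
    polyt = !guides$polyT,
    seed = guides$seed_count == 1L,
    hits = guides$genome_hits == 1L)
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    acc <- rep(TRUE, nrow(guides))
    for (k in perm) acc <- acc & checks[[k]]
    expect_equal(acc, guides$passes)
  }
  # every passing guide's 23-mer occurs exactly once at edit distance 0
  pass <- guides[guides$passes, ]
  for (i in seq_len(min(5L, nrow(pass)))) {
    site <- paste0(pass$protospacer[i], pass$pam[i])
    n_exact <- 0L
    for (s in c(sim$genome$sequences[[1]],
                revcomp(sim$genome$sequences[[1]]))) {
      m <- gregexpr(paste0("(?=", site, ")"), s, perl = TRUE)[[1]]
      n_exact <- n_exact + sum(m > 0)
    }
    expect_equal(n_exact, 1L)
  }
  # gg_end flag never changes pass status: recompute with flag flipped
  expect_equal(guides$passes,
               with(guides, gc >= 0.2 & gc <= 0.8 & !polyT &
                      seed_count == 1 & genome_hits == 1))
})

test_that("an empty target region gives an empty, well-formed table", {
  g <- Genome(c(I = strrep("A", 2000)))
  tab <- design_guides(g, NULL, genomic_interval("I", 100L, 200L))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("protospacer", "passes", "mfe") %in% names(tab)))
})
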