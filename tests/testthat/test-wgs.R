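make_cohort <- function(parent_depth = 30L, parent_agree = 0.99,
                        sib_agree = 0.99) {
  obs <- rbind(
    data.frame(strain = "parent", chrom = "I", pos = 100L, ref = "A",
               alt = NA, depth = parent_depth, ref_agreement = parent_agree,
               genotype = "ref", stringsAsFactors = FALSE),
    data.frame(strain = "ED01", chrom = "I", pos = 100L, ref = "A",
               alt = "T", depth = 28L, ref_agreement = 0.01,
               genotype = "hom", stringsAsFactors = FALSE),
    data.frame(strain = "ED02", chrom = "I", pos = 100L, ref = "A",
               alt = NA, depth = 25L, ref_agreement = sib_agree,
               genotype = "ref", stringsAsFactors = FALSE))
  cohort_variant_table("parent", c("ED01", "ED02"), obs)
}

test_that("threshold boundaries flip elimination exactly as worded", {
  th <- filter_thresholds()
  # parental depth: 9 eliminated, 10 kept
  expect_equal(nrow(filter_variants(make_cohort(parent_depth = 9L),
                                    "ED01", th)$kept), 0L)
  expect_equal(nrow(filter_variants(make_cohort(parent_depth = 10L),
                                    "ED01", th)$kept), 1L)
  # parental agreement: 0.979 eliminated, 0.98 kept
  expect_equal(nrow(filter_variants(make_cohort(parent_agree = 0.979),
                                    "ED01", th)$kept), 0L)
  expect_equal(nrow(filter_variants(make_cohort(parent_agree = 0.98),
                                    "ED01", th)$kept), 1L)
  # sibling agreement: 0.949 eliminated, 0.95 kept
  expect_equal(nrow(filter_variants(make_cohort(sib_agree = 0.949),
                                    "ED01", th)$kept), 0L)
  expect_equal(nrow(filter_variants(make_cohort(sib_agree = 0.95),
                                    "ED01", th)$kept), 1L)
  # drop reasons are reported
  dr <- filter_variants(make_cohort(parent_agree = 0.5), "ED01", th)$dropped
  expect_equal(dr$reason, "parental_agreement")
  expect_error(filter_variants(make_cohort(), "nope", th), "unknown focal")
})

test_that("kept sets equal the independent re-evaluation on random cohorts", {
  for (seed in c(201, 202, 203)) {
    cfg <- sim_config(seed, n_chrom = 2, chrom_len = 4000, n_genes = 0L,
                      variant_spec = list(n_true = 2L, n_parental = 3L,
                                          n_artifact = 4L), n_edited = 4L)
    sim <- sim_genome(cfg)
    cohort <- sim_cohort_variants(cfg, sim$genome, seed)
    th <- filter_thresholds()
    for (focal in cohort$table$edited_strains) {
      got <- filter_variants(cohort$table, focal, th)$kept
      want <- oracle_filter_kept(cohort$table, focal, th)
      expect_equal(got[c("chrom", "pos")], want[c("chrom", "pos")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("the filter is monotone in all three thresholds", {
  cfg <- sim_config(211, n_chrom = 1, chrom_len = 4000, n_genes = 0L,
                    variant_spec = list(n_true = 2L, n_parental = 2L,
                                        n_artifact = 3L), n_edited = 4L)
  sim <- sim_genome(cfg)
  cohort <- sim_cohort_variants(cfg, sim$genome, 211)
  base <- filter_thresholds(min_parental_depth = 5L,
                            min_parental_agreement = 0.5,
                            min_sibling_agreement = 0.5)
  kept_n <- function(th) nrow(filter_variants(cohort$table, "ED01", th)$kept)
  n_prev <- kept_n(base)
  for (th in list(
    filter_thresholds(min_parental_depth = 20L,
                      min_parental_agreement = 0.5,
                      min_sibling_agreement = 0.5),
    filter_thresholds(min_parental_depth = 20L,
                      min_parental_agreement = 0.99,
                      min_sibling_agreement = 0.5),
    filter_thresholds(min_parental_depth = 20L,
                      min_parental_agreement = 0.99,
                      min_sibling_agreement = 0.99))) {
    n_now <- kept_n(th)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("a parental variant can never surface as strain-specific", {
  cfg <- sim_config(221, n_chrom = 1, chrom_len = 4000, n_genes = 0L,
                    variant_spec = list(n_true = 1L, n_parental = 6L,
                                        n_artifact = 0L), n_edited = 3L)
  sim <- sim_genome(cfg)
  cohort <- sim_cohort_variants(cfg, sim$genome, 221)
  parental_sites <- cohort$truth[cohort$truth$class == "parental",
                                 c("chrom", "pos")]
  for (focal in cohort$table$edited_strains) {
    kept <- filter_variants(cohort$table, focal)$kept
    overlap <- merge(kept, unique(parental_sites), by = c("chrom", "pos"))
    expect_equal(nrow(overlap), 0L)
  }
})

test_that("on-target variants are reported separately, not as off-target", {
  tab <- make_cohort()
  res <- filter_variants(tab, "ED01",
                         target_interval = genomic_interval("I", 50L, 150L))
  expect_equal(nrow(res$kept), 0L)
  expect_equal(nrow(res$on_target), 1L)
})

test_that("variant annotation agrees with guide cut-site annotation", {
  sim <- sim_genome(sim_config(231, n_chrom = 1, chrom_len = 6000,
                               n_genes = 2L))
  pos <- seq(0L, 5999L, by = 37L)
  v <- annotate_variants(data.frame(chrom = "I", pos = pos), sim$features)
  g <- annotate_cut(data.frame(chrom = "I", cut_pos = pos), sim$features)
  expect_equal(v$feature, g$feature)
  expect_equal(v$gene, g$gene)
  expect_true("intergenic" %in% v$feature)
  expect_true("CDS" %in% v$feature)
})

test_that("identical counts give a flat profile and no segments", {
  g <- Genome(c(I = strrep("A", 20000)))
  w <- make_windows(g, 1000L)
  w$count <- rep(50L, nrow(w))
  prof <- cnv_profile(w, w)
  expect_equal(prof$log2_ratio, rep(0, nrow(prof)))
  expect_equal(nrow(call_cnv_segments(prof)), 0L)
})

test_that("common count scaling leaves log2 ratios unchanged", {
  sim <- sim_genome(sim_config(241, n_chrom = 1, chrom_len = 30000,
                               n_genes = 0L))
  cov <- sim_coverage(sim$genome,
                      list(list(chrom = "I", start = 10000L, end = 15000L,
                                ratio = 2)), seed = 241)
  prof <- cnv_profile(cov$strain, cov$parent)
  scaled_s <- cov$strain; scaled_s$count <- scaled_s$count * 7L
  scaled_p <- cov$parent; scaled_p$count <- scaled_p$count * 3L
  prof2 <- cnv_profile(scaled_s, scaled_p)
  expect_equal(prof2$log2_ratio, prof$log2_ratio)
})

test_that("a planted duplication is recovered near log2 of 1", {
  sim <- sim_genome(sim_config(251, n_chrom = 1, chrom_len = 60000,
                               n_genes = 0L))
  span <- list(chrom = "I", start = 20000L, end = 30000L, ratio = 2)
  cov <- sim_coverage(sim$genome, list(span), seed = 251)
  prof <- cnv_profile(cov$strain, cov$parent)
  seg <- call_cnv_segments(prof)
  gain <- seg[seg$direction == "gain", ]
  expect_gte(nrow(gain), 1L)
  big <- gain[which.max(gain$n_windows), ]
  expect_lte(abs(big$mean_log2 - 1), 0.3)
  expect_lte(big$start, 21000L)
  expect_gte(big$end, 29000L)
  # segments merge across a single sub-threshold gap window
  r <- data.frame(chrom = "I", start = seq(0, 9000, by = 1000),
                  end = seq(1000, 10000, by = 1000),
                  log2_ratio = c(0, 1, 1, 0.1, 1, 1, 0, 0, 0, 0))
  segs <- call_cnv_segments(r)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(1000, 6000))
  expect_equal(segs$n_windows, 4L)
})

test_that("zero parental coverage is an error", {
  g <- Genome(c(I = strrep("A", 5000)))
  w <- make_windows(g, 1000L)
  s <- w; s$count <- 10L
  p <- w; p$count <- 0L
  expect_error(cnv_profile(s, p), "zero median coverage")
})

test_that("site tables round-trip through TSV with '.' for unset alleles", {
  obs <- data.frame(strain = c("a", "b"), chrom = "I", pos = c(1L, 2L),
                    ref = c("A", "C"), alt = c(NA, "T"),
                    depth = c(10L, 12L), ref_agreement = c(1, 0.5),
                    genotype = c("ref", "het"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(obs, path)
  expect_true(any(grepl("\t\\.\t", readLines(path))))
  back <- read_site_table(path)
  expect_equal(back, obs)
})
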