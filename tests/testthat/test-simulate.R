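test_that("configuration validation rejects degenerate inputs", {
  expect_error(sim_config(c(chr1 = 0L)), "positive")
  expect_error(sim_config(c(chr1 = 10000L), purity = 0), "purity")
  expect_error(sim_config(c(chr1 = 10000L), purity = 1.2), "purity")
  expect_error(sim_config(c(chr1 = 10000L), insert_mean = 80, read_len = 50),
               "insert_mean")
  expect_error(sim_config(c(chr1 = 10000L),
                          cnv_spec = data.frame(contig = "chr1", start = 2000,
                                                end = 1000, cn = 1)),
               "within their contig")
  # partially overlapping CNV intervals are ambiguous
  expect_error(sim_config(c(chr1 = 10000L),
                          cnv_spec = data.frame(contig = "chr1",
                                                start = c(1000, 3000),
                                                end = c(5000, 8000),
                                                cn = c(1, 0))),
               "nested or disjoint")
  # nested is fine
  expect_s3_class(sim_config(c(chr1 = 10000L),
                             cnv_spec = data.frame(contig = "chr1",
                                                   start = c(1000, 3000),
                                                   end = c(8000, 5000),
                                                   cn = c(1, 0))),
                  "sim_config")
})

test_that("config YAML round-trips", {
  cfg <- sim_config(c(chr1 = 50000L, chr2 = 20000L), seed = 4L,
                    somatic_snv_count = 5L,
                    cnv_spec = data.frame(contig = "chr1", start = 1000,
                                          end = 9000, cn = 1))
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$genome_spec, cfg$genome_spec)
  expect_equal(cfg2$purity, cfg$purity)
  expect_equal(as.data.frame(cfg2$cnv_spec), as.data.frame(cfg$cnv_spec))
})

test_that("reference generation is deterministic with stated lengths", {
  cfg <- sim_config(c(chr1 = 10000L), seed = 7L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  expect_equal(nchar(r1[["chr1"]]), 10000L)
  cfg2 <- sim_config(c(a = 25000L, b = 12000L), seed = 1L)
  r3 <- generate_reference(cfg2)
  expect_equal(unname(nchar(r3)), c(25000L, 12000L))
  # roughly uniform composition
  tab <- table(strsplit(r3[["a"]], "")[[1]])
  expect_true(all(abs(tab / 25000 - 0.25) < 0.02))
  f <- tempfile(fileext = ".fa")
  write_reference_fasta(r3, f)
  expect_identical(read_reference_fasta(f), r3)
})

test_that("planted substitutions follow the Ti/Tv calibration", {
  cfg <- sim_config(c(chr1 = 2000000L), seed = 13L, germline_snp_rate = 0.02)
  ref <- generate_reference(cfg)
  g <- plant_variants(ref, cfg)
  snps <- g$truth$germline_snps
  expect_gt(nrow(snps), 30000)
  r <- titv(snps)
  expect_lt(abs(r - 2.12), 0.08)
  # transition probability 1 leaves no transversions
  cfg2 <- sim_config(c(chr1 = 100000L), seed = 13L, germline_snp_rate = 5e-3,
                     titv_ratio = Inf)
  g2 <- plant_variants(generate_reference(cfg2), cfg2)
  pair <- paste0(g2$truth$germline_snps$ref, g2$truth$germline_snps$alt)
  expect_true(all(pair %in% c("AG", "GA", "CT", "TC")))
})

test_that("truth set records the purity-diluted somatic alt fraction", {
  cfg <- sim_config(c(chr1 = 100000L), seed = 3L, purity = 0.6,
                    germline_snp_rate = 0, somatic_snv_count = 20L)
  g <- plant_variants(generate_reference(cfg), cfg)
  expect_equal(nrow(g$truth$somatic_snvs), 20L)
  expect_true(all(abs(g$truth$somatic_snvs$expected_alt_fraction - 0.3) < 1e-12))
  # no somatic site coincides with a germline site
  cfg2 <- sim_config(c(chr1 = 100000L), seed = 3L, germline_snp_rate = 2e-3,
                     somatic_snv_count = 50L)
  g2 <- plant_variants(generate_reference(cfg2), cfg2)
  expect_length(intersect(paste(g2$truth$somatic_snvs$contig,
                                g2$truth$somatic_snvs$pos),
                          paste(g2$truth$germline_snps$contig,
                                g2$truth$germline_snps$pos)), 0)
})

test_that("read-level simulation hits the requested coverage and is deterministic", {
  sim <- small_pair_sim(seed = 5L, genome = c(chr1 = 1000000L), snp_rate = 0)
  cov_t <- sum(nchar(sim$tumor$seq)) / 1e6
  cov_g <- sum(nchar(sim$germline$seq)) / 1e6
  expect_lt(abs(cov_t - 37) / 37, 0.02)
  expect_lt(abs(cov_g - 40) / 40, 0.02)
  # approximate pair count: coverage * L / (2 * read_len) fragments
  expect_lt(abs(nrow(sim$tumor) / 2 - 37 * 1e6 / 100) / (37 * 1e6 / 100), 0.02)
  sim2 <- small_pair_sim(seed = 5L, genome = c(chr1 = 1000000L), snp_rate = 0)
  expect_identical(as.data.frame(sim$tumor), as.data.frame(sim2$tumor))
})

test_that("homozygous deletions at purity 1 are never sampled in the tumor", {
  cnv <- data.frame(contig = "chr1", start = 40000, end = 60000, cn = 0)
  sim <- small_pair_sim(seed = 8L, genome = c(chr1 = 100000L), purity = 1,
                        cnv_spec = cnv, snp_rate = 0)
  inside <- sim$tumor[start >= 41500 & start + 50 <= 58500]
  expect_equal(nrow(inside), 0L)
  # germline sample unaffected
  g_inside <- sim$germline[start >= 41500 & start + 50 <= 58500]
  expect_gt(nrow(g_inside), 1000)
})

test_that("fusion fragments produce cross-contig mate pairs", {
  fus <- data.frame(contig_a = "chr1", pos_a = 50000, contig_b = "chr2",
                    pos_b = 30000, origin = "somatic")
  sim <- small_pair_sim(seed = 9L, genome = c(chr1 = 100000L, chr2 = 60000L),
                        fusion_spec = fus, snp_rate = 0,
                        background_discordant_rate = 0)
  disc <- sim$tumor[contig != mate_contig]
  expect_gt(nrow(disc), 100)
  expect_true(all(disc$contig %in% c("chr1", "chr2")))
  # reads near the breakpoint, mates near the partner locus
  expect_lt(max(abs(disc[contig == "chr1"]$start - 50000)), 2500)
  expect_lt(max(abs(disc[contig == "chr1"]$mate_start - 30000)), 2500)
  # germline sample carries none of this somatic event
  expect_equal(nrow(sim$germline[contig != mate_contig]), 0L)
})

test_that("oversized read-level requests are refused", {
  cfg <- sim_config(c(chr1 = 1000000L), seed = 1L,
                    mean_coverage_tumor = 20000)
  g <- list(config = cfg)
  class(g) <- "sim_genome"
  expect_error(simulate_mate_pairs(g, "tumor"), "desk-scale")
})

test_that("depth-level simulation matches the Poisson mixture model", {
  cnv <- data.frame(contig = "chr1", start = c(200000, 500000),
                    end = c(400000, 600000), cn = c(0L, 1L))
  cfg <- sim_config(c(chr1 = 1000000L), seed = 11L, purity = 0.6,
                    cnv_spec = cnv)
  tk <- simulate_bin_depths(cfg)
  expect_equal(nrow(tk), 10000L)
  neutral <- tk[start < 200000]
  expect_lt(abs(mean(neutral$tumor) / mean(neutral$germline) - 37 / 40), 0.03)
  # CN 0 at purity 0.6 leaves 40% of diploid tumor signal
  cn0 <- tk[start >= 201000 & start < 399000]
  expect_lt(abs(mean(cn0$tumor) / 37 - 0.4), 0.03)
  # CN 1: log2 of normalized ratio near log2(0.7)
  cn1 <- tk[start >= 501000 & start < 599000]
  expect_lt(abs(log2(mean(cn1$tumor) / 37 / (mean(cn1$germline) / 40)) -
                  log2(0.7)), 0.05)
  expect_identical(as.data.frame(simulate_bin_depths(cfg)), as.data.frame(tk))
  expect_error(simulate_bin_depths(cfg, lambda_tumor = 0), "positive")
})
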