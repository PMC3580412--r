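# independently coded textbook pooled two-proportion z, kept naive on purpose
oracle_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  p <- (k1 + k2) / (n1 + n2)
  if (p == 0 || p == 1) return(0)
  (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

test_that("the strand statistic matches the closed-form oracle", {
  expect_equal(strand_stat(5, 20, 5, 20), 0)
  expect_equal(strand_stat(10, 20, 0, 20), oracle_z(10, 20, 0, 20))
  set.seed(3)
  for (i in 1:100) {
    n1 <- sample(1:60, 1); n2 <- sample(1:60, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(strand_stat(k1, n1, k2, n2), oracle_z(k1, n1, k2, n2),
                 tolerance = 1e-12)
  }
  expect_equal(strand_stat(0, 20, 0, 20), 0)   # pooled p = 0
  expect_equal(strand_stat(20, 20, 20, 20), 0) # pooled p = 1
  expect_error(strand_stat(5, 4, 0, 10), "exceed")
  expect_error(strand_stat(0, 0, 0, 10), "depths")
})

mk_counts <- function(t_alt_f, t_n_f, t_alt_r, t_n_r,
                      g_alt_f = 0L, g_n_f = 20L, g_alt_r = 0L, g_n_r = 20L,
                      contig = "chr1", site = 1000L) {
  data.table::data.table(contig = contig, site = site, ref = "A", alt = "C",
                         t_n_fwd = t_n_f, t_n_rev = t_n_r,
                         t_alt_fwd = t_alt_f, t_alt_rev = t_alt_r,
                         g_n_fwd = g_n_f, g_n_rev = g_n_r,
                         g_alt_fwd = g_alt_f, g_alt_rev = g_alt_r)
}

test_that("somatic calling takes the strand minimum and applies the filters", {
  # 30% alt on both strands at 40x/40x, clean germline: passes defaults
  cc <- call_somatic(mk_counts(6L, 20L, 6L, 20L), strict_params())
  expect_equal(cc$stat, min(cc$stat_fwd, cc$stat_rev))
  expect_equal(cc$stat_fwd, oracle_z(6, 20, 0, 20))
  expect_equal(cc$filter, "pass")
  # germline evidence filter
  g5 <- call_somatic(mk_counts(6L, 20L, 6L, 20L, g_alt_f = 3L, g_alt_r = 2L),
                     strict_params())
  expect_equal(g5$filter, "germline_evidence")
  # alt on one strand only: the minimum rule fails the site
  one <- call_somatic(mk_counts(12L, 20L, 0L, 20L), lenient_params())
  expect_equal(one$stat, 0)
  expect_equal(one$filter, "low_stat")
  # missing tumor strand: no statistic, no call
  miss <- call_somatic(mk_counts(6L, 20L, 0L, 0L), lenient_params())
  expect_true(is.na(miss$stat))
  expect_equal(miss$filter, "low_stat")
})

test_that("strict passes are a subset of lenient passes", {
  set.seed(11)
  tabs <- data.table::rbindlist(lapply(1:400, function(i) {
    nf <- sample(4:40, 1); nr <- sample(4:40, 1)
    mk_counts(sample(0:nf, 1), nf, sample(0:nr, 1), nr,
              g_alt_f = sample(0:3, 1), g_alt_r = sample(0:3, 1),
              site = 1000L + i)
  }))
  s <- call_somatic(tabs, strict_params())
  l <- call_somatic(tabs, lenient_params())
  expect_true(all(s[filter == "pass"]$site %in% l[filter == "pass"]$site))
})

test_that("consensus combines the callers and post-filters lenient-only calls", {
  counts <- data.table::rbindlist(list(
    mk_counts(8L, 20L, 8L, 20L, site = 100L),   # strict-grade signal
    mk_counts(2L, 20L, 1L, 20L, site = 200L),   # lenient-only, balanced-ish
    mk_counts(6L, 10L, 2L, 40L, site = 300L),   # lenient-only, strand-asymmetric
    mk_counts(8L, 20L, 8L, 20L, site = 400L)))  # walker-only (not in solsnp set)
  ws <- call_somatic(counts, strict_params())
  wl <- call_somatic(counts, lenient_params())
  sol <- data.table::data.table(contig = "chr1", site = c(100L, 200L, 300L),
                                ref = "A", alt = "C")
  fin <- consensus_calls(sol, ws, wl)
  expect_true(100L %in% fin$site)                       # strict common call
  expect_false(400L %in% fin$site)                      # intersection rule
  expect_equal(fin[site == 100L]$provenance, "strict")
  if (200L %in% fin$site)
    expect_equal(fin[site == 200L]$provenance, "lenient")
  # asymmetric lenient-only call is removed with a recorded reason
  expect_false(300L %in% fin$site)
  dropped <- attr(fin, "dropped")
  expect_true(300L %in% dropped$site)
  expect_equal(dropped[site == 300L]$post_filter, "strand_asymmetry")
  # indel-proximity post-filter
  fin2 <- consensus_calls(sol, ws, wl,
                          indel_candidates = data.table::data.table(
                            contig = "chr1", start = 203L, end = 207L))
  expect_false(200L %in% fin2$site)
  # inconsistent reference alleles across callers is an error
  sol_bad <- data.table::copy(sol)[site == 100L, ref := "G"]
  expect_error(consensus_calls(sol_bad, ws, wl), "inconsistent reference")
})

test_that("raising thresholds never adds consensus calls", {
  set.seed(19)
  counts <- data.table::rbindlist(lapply(1:300, function(i) {
    nf <- sample(6:40, 1); nr <- sample(6:40, 1)
    mk_counts(sample(0:12, 1), nf, sample(0:12, 1), nr, site = 1000L + i)
  }))
  counts <- counts[t_alt_fwd <= t_n_fwd & t_alt_rev <= t_n_rev]
  sol <- counts[, .(contig, site, ref, alt)]
  base_strict <- strict_params(); base_lenient <- lenient_params()
  fin0 <- consensus_calls(sol, call_somatic(counts, base_strict),
                          call_somatic(counts, base_lenient))
  for (bump in list(c("stat_threshold", 1), c("min_alt_per_strand", 1),
                    c("min_alt_total", 2))) {
    s2 <- base_strict; l2 <- base_lenient
    s2[[bump[1]]] <- s2[[bump[1]]] + as.numeric(bump[2])
    l2[[bump[1]]] <- l2[[bump[1]]] + as.numeric(bump[2])
    fin2 <- consensus_calls(sol, call_somatic(counts, s2),
                            call_somatic(counts, l2), strict = s2, lenient = l2)
    expect_true(all(fin2$site %in% fin0$site))
  }
})

test_that("the end-to-end pipeline finds planted somatic SNVs precisely", {
  sim <- small_pair_sim(seed = 41L, genome = c(chr1 = 150000L), snv = 40L,
                        snp_rate = 5e-4)
  res <- call_somatic_snvs(sim$tumor, sim$germline, sim$ref)
  truth <- paste(sim$genome$truth$somatic_snvs$contig,
                 sim$genome$truth$somatic_snvs$pos)
  wl <- res$walker_lenient[filter == "pass"]
  called <- paste(wl$contig, wl$site)
  expect_gte(mean(truth %in% called), 0.9)
  expect_gte(mean(called %in% truth), 0.95)
  # consensus calls are a subset of the walker lenient passes
  expect_true(all(paste(res$final$contig, res$final$site) %in% called))
  # germline het SNPs are not called somatic
  snp <- paste(sim$genome$truth$germline_snps$contig,
               sim$genome$truth$germline_snps$pos)
  expect_length(intersect(paste(res$final$contig, res$final$site), snp), 0)
})
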