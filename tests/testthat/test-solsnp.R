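test_that("expected pileups keep qualities and split the het pileup", {
  obs <- list(base = c("A", "C", "A", "A"), qual = c(30, 30, 20, 10))
  ep <- expected_pileups(obs, ref = "A", alt = "C")
  expect_equal(ep$hom_ref$base, rep("A", 4))
  expect_equal(ep$het$base, c("A", "A", "C", "C"))
  expect_equal(ep$het$qual, c(30, 30, 20, 10))
  expect_equal(ep$hom_alt$base, rep("C", 4))
  # haploid: two expected pileups only
  expect_named(expected_pileups(obs, "A", "C", ploidy = 1L),
               c("hom_ref", "hom_alt"))
  # degenerate single-observation het: ceiling(1/2) = 1 reference position
  ep1 <- expected_pileups(list(base = "A", qual = 30), "A", "C")
  expect_equal(ep1$het$base, "A")
  expect_true(ep1$het$degenerate)
  expect_error(expected_pileups(obs, "A", "A"), "differ")
})

test_that("KS distance has its boundary and identity values", {
  obs <- list(base = rep("A", 6), qual = rep(30, 6))
  ep <- expected_pileups(obs, "A", "G")
  expect_equal(ks_distance(obs, ep$hom_ref, "A", "G"), 0)
  all_alt <- list(base = rep("G", 6), qual = rep(30, 6))
  expect_equal(ks_distance(all_alt, ep$hom_ref, "A", "G"), 1)
  expect_error(ks_distance(obs, list(base = "A", qual = 30), "A", "G"),
               "equal position counts")
  expect_error(ks_distance(list(base = "A", qual = 0),
                           list(base = "A", qual = 0), "A", "G"),
               "uninformative")
  # symmetry
  o1 <- list(base = c("A", "G", "T"), qual = c(30, 20, 10))
  o2 <- list(base = c("G", "G", "A"), qual = c(15, 30, 25))
  expect_equal(ks_distance(o1, o2, "A", "G"), ks_distance(o2, o1, "A", "G"))
})

test_that("KS distance equals the brute-force cumulative-mass oracle", {
  # exhaustive over category compositions up to 12 observations at Q30,
  # observed vs every expected genotype pileup
  for (n in 1:12) {
    for (k in 0:n) for (m in 0:(n - k)) {
      obs <- list(base = c(rep("A", n - k - m), rep("C", k), rep("T", m)),
                  qual = rep(30, n))
      for (e in expected_pileups(obs, "A", "C")) {
        expect_equal(ks_distance(obs, e, "A", "C"),
                     oracle_ks(obs, e, "A", "C"), tolerance = 1e-12)
      }
    }
  }
  # random mixed-quality cases
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    obs <- list(base = sample(c("A", "C", "G"), n, TRUE),
                qual = sample(c(10, 20, 30, 40), n, TRUE))
    exp <- expected_pileups(obs, "A", "C")[[sample(1:3, 1)]]
    expect_equal(ks_distance(obs, exp, "A", "C"),
                 oracle_ks(obs, exp, "A", "C"), tolerance = 1e-12)
  }
})

test_that("the count-based fast path agrees with the general KS distance", {
  for (n in 1:12) {
    for (k in 0:n) for (m in 0:(n - k)) {
      obs <- list(base = c(rep("A", n - k - m), rep("C", k), rep("T", m)),
                  qual = rep(30, n))
      ep <- expected_pileups(obs, "A", "C")
      triple <- somaticmate:::.ks_triple_counts(n - k - m, k, m)
      expect_equal(unlist(triple),
                   c(hom_ref = ks_distance(obs, ep$hom_ref, "A", "C"),
                     het = ks_distance(obs, ep$het, "A", "C"),
                     hom_alt = ks_distance(obs, ep$hom_alt, "A", "C")),
                   tolerance = 1e-12)
    }
  }
})

test_that("alternative allele choice weighs quality and breaks ties lexicographically", {
  p <- mk_pileup(c("A", "C", "C", "C"), rep(30, 4), c("A", "T"), c(30, 30))
  expect_equal(pick_alt(p, "A"), "C")
  expect_true(is.na(pick_alt(mk_pileup("A", 30, "A", 30), "A")))
  tie <- mk_pileup(c("T", "G"), c(30, 30), character(0), numeric(0))
  expect_equal(pick_alt(tie, "A"), "G")
})

test_that("site calling follows the strand-consensus rules", {
  # clean reference site
  p <- mk_pileup(rep("A", 10), rep(30, 10), rep("A", 10), rep(30, 10))
  call <- call_site(p, "A")
  expect_equal(call$consensus, "hom_ref")
  expect_false(call$variant)
  # strands disagree in consensus mode: no-call
  p2 <- mk_pileup(c(rep("A", 5), rep("C", 5)), rep(30, 10),
                  rep("C", 10), rep(30, 10))
  c2 <- call_site(p2, "A", strand_mode = "consensus")
  expect_true(is.na(c2$consensus))
  expect_false(c2$variant)
  expect_match(c2$no_call_reason, "disagree")
  # same pileup in any mode: variant (both strands variant genotypes)
  c2b <- call_site(p2, "A", strand_mode = "any")
  expect_true(c2b$variant)
  # balanced het on both strands
  p3 <- mk_pileup(c(rep("A", 10), rep("C", 10)), rep(30, 20),
                  c(rep("A", 11), rep("C", 9)), rep(30, 20))
  c3 <- call_site(p3, "A")
  expect_equal(c3$consensus, "het")
  expect_true(c3$variant)
  # distance triple argmin invariant on the emitted call
  expect_equal(names(which.min(c3$fwd$distances)), c3$fwd$genotype)
  expect_true(all(c3$fwd$distances >= 0 & c3$fwd$distances <= 1))
  # depth floor
  c4 <- call_site(mk_pileup(rep("A", 2), rep(30, 2), rep("A", 9), rep(30, 9)),
                  "A", min_strand_depth = 4L)
  expect_true(is.na(c4$consensus))
  expect_match(c4$no_call_reason, "depth")
})

test_that("haploid mode never emits het", {
  set.seed(7)
  for (i in 1:50) {
    nf <- sample(4:15, 1); nr <- sample(4:15, 1)
    p <- mk_pileup(sample(c("A", "C"), nf, TRUE), rep(30, nf),
                   sample(c("A", "C"), nr, TRUE), rep(30, nr))
    call <- call_site(p, "A", ploidy = 1L, strand_mode = "any")
    expect_false(identical(call$fwd$genotype, "het"))
    expect_false(identical(call$rev$genotype, "het"))
  }
})

test_that("genotype concordance with truth is high on deep diploid data", {
  sim <- small_pair_sim(seed = 37L, genome = c(chr1 = 300000L),
                        snp_rate = 1e-3, purity = 0.6,
                        mean_coverage_germline = 45)
  snps <- sim$genome$truth$germline_snps
  calls <- genotype_sites(sim$germline, sim$ref,
                          sites = data.frame(contig = snps$contig,
                                             pos = snps$pos))
  m <- merge(calls, snps, by.x = c("contig", "site"),
             by.y = c("contig", "pos"))
  called <- m[!is.na(consensus)]
  expect_gt(nrow(called), 150)
  concord <- mean(called$consensus == called$genotype &
                    (called$consensus == "hom_ref" | called$alt.x == called$alt.y))
  expect_gte(concord, 0.99)
})
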