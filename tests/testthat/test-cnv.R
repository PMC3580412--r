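test_that("modal depth finds the Poisson mode and rejects empty tracks", {
  set.seed(2)
  x <- rpois(20000, 40)
  expect_lte(abs(modal_depth(x) - 40), 1)
  expect_equal(modal_depth(rep(10, 100)), 10)
  expect_error(modal_depth(numeric(0)), "all-zero")
  expect_error(modal_depth(rep(0, 50)), "all-zero")
})

mk_track <- function(germline, tumor, contig = "chr1", bin = 100L) {
  tk <- data.table::data.table(contig = contig,
                               start = (seq_along(germline) - 1L) * bin,
                               germline = germline, tumor = tumor)
  data.table::setattr(tk, "bin_size", bin)
  tk
}

test_that("normalization and the usable-bin rule follow the mode filter", {
  g <- c(rep(40, 500), 2, 400, 80)
  t <- c(rep(40, 500), 40, 40, 40)
  nt <- normalized_log2(mk_track(g, t))
  expect_equal(nt$g_norm[1], log2(40.5 / 40), tolerance = 1e-9)
  expect_lt(abs(nt$g_norm[1]), 0.02)            # depth at modal: ~0
  expect_false(nt$usable[501])                  # 0.05x the mode
  expect_true(nt$usable[503])                   # 2x the mode
  expect_equal(nt$g_norm[503], log2(80.5 / 40), tolerance = 1e-9)
  expect_lt(abs(nt$g_norm[503] - 1), 0.01)
  expect_error(normalized_log2(mk_track(g, t), modal_germline = 0), "positive")
})

test_that("windowed differences recover planted ratios", {
  # identical tracks: zero everywhere
  g <- rep(40, 1000)
  w0 <- windowed_difference(normalized_log2(mk_track(g, g)))
  expect_true(all(abs(w0$value) < 1e-9))
  # a region at half tumor depth reads ~ -1 (majority neutral keeps modes honest)
  t <- c(rep(40, 700), rep(20, 300))
  w1 <- windowed_difference(normalized_log2(mk_track(rep(40, 1000), t)))
  mid <- w1[start >= 72000 & start < 98000]
  expect_lt(abs(mean(mid$value) - log2(20.5 / 40.5)), 0.02)
  # windows with under half their bins usable are missing
  g2 <- c(rep(40, 100), rep(1, 100), rep(40, 100))
  w2 <- windowed_difference(normalized_log2(mk_track(g2, g2)))
  expect_true(any(is.na(w2$value)))
  expect_true(all(is.na(w2[start >= 10000 & start < 11000]$value)))
})

test_that("depth-level CN=1 at purity 0.6 sits near log2(0.7)", {
  cnv <- data.frame(contig = "chr1", start = 300000, end = 500000, cn = 1L)
  cfg <- sim_config(c(chr1 = 1000000L), seed = 61L, purity = 0.6,
                    cnv_spec = cnv)
  res <- cnv_call(simulate_bin_depths(cfg), departure = 0.4)
  w <- res$windows[start >= 310000 & start < 490000]
  neutral <- res$windows[start < 290000 | start >= 510000]
  # contrast against the neutral level: cancels the half-integer ambiguity of
  # the Poisson mode (P(k-1) = P(k) at integer rates) and the log-Poisson bias
  expect_lt(abs(mean(w$value) - mean(neutral$value) - log2(0.7)), 0.03)
  expect_lt(abs(mean(w$value) - log2(0.7)), 0.08)
})

test_that("segmentation flags, splits states, and stays disjoint", {
  set.seed(5)
  n <- 4000
  g <- rpois(n, 40)
  rel <- rep(1, n)
  rel[1001:1500] <- 0.4   # homozygous loss at purity 0.6
  rel[2001:2500] <- 1.9   # strong gain
  t <- rpois(n, 37 * rel)
  res <- cnv_call(mk_track(g, t), departure = 0.75)
  segs <- res$segments
  expect_gte(nrow(segs), 2L)
  loss <- segs[state == "homozygous_loss"]
  gain <- segs[state %in% c("gain", "amplified")]
  expect_equal(nrow(loss), 1L)
  expect_gte(nrow(gain), 1L)
  # boundaries within 2 windows (4 kb) of the planted breakpoints
  expect_lt(abs(loss$start - 100000), 4000)
  expect_lt(abs(loss$end - 150000), 4000)
  # adjacent loss and gain runs are never merged
  expect_false(any(segs$state == "homozygous_loss" &
                     segs$start < 250000 & segs$end > 200000 & segs$start > 150000))
  # disjoint and sorted
  data.table::setorder(segs, contig, start)
  expect_true(all(segs$end > segs$start))
  expect_true(all(diff(segs$start) >= 0))
  same <- segs$contig[-1] == segs$contig[-nrow(segs)]
  expect_true(all(segs$start[-1][same] >= segs$end[-nrow(segs)][same]))
  # no flagged window at all: empty segment list
  quiet <- cnv_call(mk_track(rpois(3000, 40), rpois(3000, 37)))
  expect_equal(nrow(quiet$segments), 0L)
})

test_that("nested homozygous loss inside a hemizygous deletion is isolated", {
  cnv <- data.frame(contig = "chr10", start = c(1e6, 1.9e6),
                    end = c(3e6, 2.1e6), cn = c(1L, 0L))
  cfg <- sim_config(c(chr10 = 4000000L), seed = 71L, purity = 0.6,
                    cnv_spec = cnv)
  res <- cnv_call(simulate_bin_depths(cfg), departure = 0.4)
  hom <- res$segments[state == "homozygous_loss"]
  expect_equal(nrow(hom), 1L)
  expect_lt(abs(hom$start - 1.9e6), 4000)
  expect_lt(abs(hom$end - 2.1e6), 4000)
  expect_lt(abs(hom$mean - log2(0.4)), 0.15)
})

test_that("whole-chromosome gains appear in the per-chromosome medians", {
  cnv <- data.frame(contig = "chrB", start = 0, end = 1000000, cn = 3L)
  cfg <- sim_config(c(chrA = 3000000L, chrB = 1000000L), seed = 83L,
                    purity = 0.6, cnv_spec = cnv)
  res <- cnv_call(simulate_bin_depths(cfg))
  med <- res$chromosome_medians
  # the between-chromosome contrast cancels modal-depth quantization
  expect_lt(abs(med[contig == "chrB"]$median_diff -
                  med[contig == "chrA"]$median_diff - log2(1.3)), 0.02)
  expect_lt(abs(med[contig == "chrA"]$median_diff), 0.08)
  # below the departure rule: reported by the median summary, not a segment
  expect_equal(nrow(res$segments[contig == "chrB"]), 0L)
})

test_that("the exon scan flags moderate deletions from base coverage", {
  set.seed(9)
  n <- 3000
  g <- rpois(n, 40)
  rel <- rep(1, n); rel[1001:1200] <- 0.5  # CN 1 at purity 1
  t <- rpois(n, 40 * rel)
  track <- mk_track(g, t)
  exons <- data.frame(contig = "chr1",
                      start = c(20000, 101000, 150000, 99000),
                      end = c(21000, 104000, 151000, 101000))
  res <- exon_moderate_deletions(track, exons)
  expect_equal(res[start == 20000]$status, "neutral")
  expect_lt(abs(res[start == 20000]$value), 0.15)
  expect_equal(res[start == 101000]$status, "flagged_loss")
  expect_lt(abs(res[start == 101000]$value - (-1)), 0.15)
  # exon straddling the boundary: intermediate value, 0.75 rule decides
  strad <- res[start == 99000]
  expect_true(strad$value > -1 && strad$value < 0)
  expect_equal(strad$status,
               if (strad$value < -0.75) "flagged_loss" else "neutral")
  # zero-coverage exon reports no data
  g0 <- g; g0[2001:2100] <- 0
  res0 <- exon_moderate_deletions(mk_track(g0, t),
                                  data.frame(contig = "chr1", start = 200100,
                                             end = 209900))
  expect_equal(res0$status, "no_data")
  expect_error(exon_moderate_deletions(track,
                                       data.frame(contig = "chr1", start = 10,
                                                  end = 5)), "invalid exon")
})
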