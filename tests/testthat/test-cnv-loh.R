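test_that("coverage gate: strict normal 10X threshold, inclusive tumor 30X threshold", {
  n <- function(f) coverage_profile("normal", fraction_targets_10x = f)
  t <- function(f) coverage_profile("tumor", fraction_targets_30x = f)
  expect_true(coverage_gate(n(0.96), t(0.91)))
  expect_false(coverage_gate(n(0.94), t(0.99)))
  expect_false(coverage_gate(n(0.95), t(0.99)))   # boundary: strictly greater
  expect_true(coverage_gate(n(0.951), t(0.90)))   # tumor boundary inclusive
  expect_false(coverage_gate(n(0.99), t(0.89)))
})

test_that("segment states partition with an inclusive loss cutoff", {
  segs <- segment_calls(data.frame(
    chrom = "1", start = c(1, 11, 21, 31), end = c(10, 20, 30, 40),
    log2_ratio = c(-0.25, 0, -0.2, 0.3)))
  segs <- call_segment_states(segs)
  expect_equal(segs$state, c("loss", "neutral", "loss", "gain"))
  expect_true(all(table(segs$state) >= 0))  # every segment exactly one state
  expect_false(any(is.na(segs$state)))
})

test_that("relaxing the loss cutoff toward 0 never removes a loss call", {
  set.seed(4)
  segs <- segment_calls(data.frame(chrom = "1",
                                   start = seq(1, 991, 10),
                                   end = seq(10, 1000, 10),
                                   log2_ratio = rnorm(100, -0.1, 0.2)))
  prev <- character()
  for (cutoff in c(-0.4, -0.3, -0.2, -0.1)) {
    losses <- which(call_segment_states(segs, loss_cutoff = cutoff)$state == "loss")
    expect_true(all(prev %in% losses))
    prev <- losses
  }
})

test_that("LOH detection flags strong allelic shift and respects informativeness", {
  segs <- call_segment_states(segment_calls(data.frame(
    chrom = "1", start = c(1, 1001, 2001), end = c(1000, 2000, 3000),
    log2_ratio = c(0, 0, 0))))
  sites <- allelic_sites(data.frame(
    chrom = "1",
    pos = c(seq(10, 990, length.out = 20), seq(1010, 1990, length.out = 20)),
    normal_vaf = 0.5,
    tumor_vaf = c(rep(0.95, 20), rep(0.5, 20))))
  out <- detect_loh(sites, segs)
  expect_equal(out$loh, c(TRUE, FALSE, FALSE))
  expect_true(out$copy_neutral_loh[1])
  expect_equal(out$uninformative, c(FALSE, FALSE, TRUE))
})

test_that("LOH detection is invariant to mirroring tumor VAFs around 0.5", {
  sim <- simulate_ballele_track(simulation_config(seed = 14))
  segs <- call_segment_states(sim$bins)
  a <- detect_loh(sim$sites, segs)
  mirrored <- sim$sites
  mirrored$tumor_vaf <- 1 - mirrored$tumor_vaf
  b <- detect_loh(mirrored, segs)
  expect_equal(a$loh, b$loh)
})

test_that("sites that are homozygous in normal never support LOH", {
  segs <- call_segment_states(segment_calls(data.frame(
    chrom = "1", start = 1, end = 1000, log2_ratio = 0)))
  sites <- allelic_sites(data.frame(chrom = "1", pos = seq(10, 990, 50),
                                    normal_vaf = 0.98, tumor_vaf = 0.98))
  out <- detect_loh(sites, segs)
  expect_false(out$loh)
  expect_true(out$uninformative)
})

test_that("the segmenter merges constant tracks and splits at steps", {
  const <- data.frame(chrom = "1", start = seq(1, 991, 10),
                      end = seq(10, 1000, 10), log2_ratio = 0)
  expect_equal(nrow(simple_segmenter(const)), 1)
  step <- const
  step$log2_ratio <- rep(c(0, -0.5), each = 50)
  segs <- simple_segmenter(step)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start[2], step$start[51])
  expect_equal(segs$log2_ratio, c(0, -0.5))
  shuffled <- const[c(2, 1, 3:100), ]
  expect_error(simple_segmenter(shuffled), "ordered")
})

test_that("a noisy step boundary is recovered within two bins", {
  for (seed in 1:5) {
    set.seed(seed)
    bins <- data.frame(chrom = "1", start = seq(1, 991, 10),
                       end = seq(10, 1000, 10),
                       log2_ratio = rep(c(0, -0.5), each = 50) + rnorm(100, 0, 0.05))
    segs <- simple_segmenter(bins)
    # some boundary within +/- 2 bins of the true step at bin 51
    true_start <- bins$start[51]
    expect_true(any(abs(segs$start - true_start) <= 20))
  }
})

test_that("planted copy-neutral LOH is recovered on the synthetic track", {
  sim <- simulate_ballele_track(simulation_config(seed = 33))
  segs <- call_segment_states(sim$bins)
  out <- detect_loh(sim$sites, segs)
  called <- out[out$copy_neutral_loh, c("chrom", "start", "end")]
  expect_gte(interval_jaccard(called, sim$truth$loh_intervals), 0.9)
})

test_that("planted losses are called loss after segmentation", {
  cfg <- simulation_config(seed = 41, loss_bins = 81:100, loss_log2 = -0.5)
  sim <- simulate_ballele_track(cfg)
  segs <- call_segment_states(simple_segmenter(as.data.frame(sim$bins)))
  loss_iv <- segs[segs$state == "loss", c("chrom", "start", "end")]
  expect_gte(interval_jaccard(loss_iv, sim$truth$loss_intervals), 0.9)
})
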