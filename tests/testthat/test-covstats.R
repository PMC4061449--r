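test_that("bin_depth tiles the contig and averages per actual bin width", {
  b <- bin_depth(depth_track(c(0, 0, 4, 4)), bin_size = 2)
  expect_equal(b$bin_mean_depth, c(0, 4))
  expect_equal(attr(b, "genome_mean_depth"), 2)
  expect_equal(b$normalized, c(0, 2))
  expect_equal(b$bin_start, c(0L, 2L))
  expect_equal(b$bin_end, c(2L, 4L))

  # terminal partial bin retained with its true width
  b2 <- bin_depth(depth_track(rep(1L, 1001)), bin_size = 500)
  expect_equal(nrow(b2), 3)
  expect_equal(b2$bin_end[3] - b2$bin_start[3], 1)

  # constant depth: every bin mean equals the depth, normalized 1
  b3 <- bin_depth(depth_track(rep(10L, 100)), bin_size = 7)
  expect_true(all(b3$bin_mean_depth == 10))
  expect_true(all(b3$normalized == 1))
})

test_that("width-weighted bin means reproduce the genome mean exactly", {
  for (seed in 1:3) {
    d <- wgaqc::simulate_depth(sim_config(seed = seed, genome_length = 2003,
                                          bin_size = 500, mean_depth = 9,
                                          bias_sigma = 0.7))
    b <- bin_depth(d, 150)
    w <- b$bin_end - b$bin_start
    expect_equal(sum(b$bin_mean_depth * w) / sum(w),
                 attr(b, "genome_mean_depth"), tolerance = 1e-9)
  }
})

test_that("breadth counts positions at or above each cutoff", {
  tr <- depth_track(c(0, 1, 5, 9))
  expect_equal(unname(breadth(tr, c(1, 5))), c(75, 50))
  cst <- depth_track(rep(5L, 10))
  expect_equal(unname(breadth(cst, c(1, 5, 6))), c(100, 100, 0))
  expect_error(breadth(tr, 0), ">= 1")
})

test_that("breadth is non-increasing in threshold and permutation-invariant", {
  set.seed(11)
  for (i in 1:5) {
    d <- rpois(1000, 3)
    tr <- depth_track(d)
    br <- breadth(tr, 1:8)
    expect_true(all(diff(br) <= 0))
    expect_equal(breadth(depth_track(sample(d)), 1:8), br)
  }
})

test_that("balance arithmetic matches hand-computed fold variation", {
  a <- fake_bins(c(1, 2))
  b <- fake_bins(c(2, 1))
  rep <- balance(a, b)
  expect_equal(rep$bins$fold_variation, c(2, 2))
  expect_equal(rep$mean_variation, 2)
  expect_equal(rep$pct_within_2fold, 100)
  expect_equal(rep$bins$log2_ratio, c(-1, 1))
  expect_equal(rep$n_excluded_zero_bins, 0)
})

test_that("identical samples are perfectly balanced", {
  tr <- simulate_depth(sim_config(seed = 2, genome_length = 5e4,
                                  mean_depth = 20, bias_sigma = 0.5))
  bn <- bin_depth(tr, 500)
  rep <- balance(bn, bn)
  expect_true(all(rep$bins$fold_variation[rep$bins$included] == 1))
  expect_true(all(rep$bins$log2_ratio[rep$bins$included] == 0))
  expect_equal(rep$pct_within_2fold, 100)
})

test_that("balance is symmetric up to the sign of the log2 ratio", {
  t1 <- simulate_depth(sim_config(seed = 5, genome_length = 5e4,
                                  mean_depth = 15, bias_sigma = 0.8))
  t2 <- simulate_depth(sim_config(seed = 6, genome_length = 5e4,
                                  mean_depth = 40, bias_sigma = 0.3))
  ab <- balance(bin_depth(t1, 500), bin_depth(t2, 500))
  ba <- balance(bin_depth(t2, 500), bin_depth(t1, 500))
  expect_equal(ab$bins$fold_variation, ba$bins$fold_variation)
  expect_equal(ab$pct_within_2fold, ba$pct_within_2fold)
  expect_equal(ab$pct_within_4fold, ba$pct_within_4fold)
  expect_equal(ab$bins$log2_ratio, -ba$bins$log2_ratio)
  expect_gte(ab$pct_within_4fold, ab$pct_within_2fold)
})

test_that("zero bins are excluded from ratio statistics and counted", {
  a <- fake_bins(c(1, 0, 2))
  b <- fake_bins(c(1, 3, 2))
  rep <- balance(a, b)
  expect_equal(rep$n_excluded_zero_bins, 1)
  expect_true(is.na(rep$bins$fold_variation[2]))
  expect_equal(rep$mean_variation, 1)
})

test_that("mismatched binnings are rejected", {
  tr <- depth_track(rep(1L, 1000))
  expect_error(balance(bin_depth(tr, 500), bin_depth(tr, 250)),
               "incompatible")
  expect_error(balance(bin_depth(tr, 500),
                       bin_depth(depth_track(rep(1L, 2000)), 500)),
               "incompatible")
})

test_that("empty or negative depth tracks are rejected", {
  expect_error(depth_track(integer(0)), "empty")
  expect_error(depth_track(c(1, -2)), "non-negative")
})
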