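mixture_draws <- function(n, means, sds, probs, seed) {
  set.seed(seed)
  comp <- sample.int(length(means), n, replace = TRUE, prob = probs)
  rnorm(n, means[comp], sds[comp])
}

test_that("a constant distance gives a single certain peak at that distance", {
  traj <- distance_series_traj(rep(8, 50))
  dist <- distance_distribution(traj, c(1, 2))
  expect_equal(sum(dist$density) * dist$binwidth, 1, tolerance = 1e-9)
  expect_equal(nrow(dist$peaks), 1L)
  expect_equal(dist$peaks$position, 8)
  expect_equal(dist$occupancies$occupancy, 1)
})

test_that("uniform weights and explicit equal weights give identical densities", {
  traj <- distance_series_traj(8 + sin(1:100))
  a <- distance_distribution(traj, c(1, 2))
  w <- mutdyn:::new_frame_weights(1:100, rep(0.37, 100))
  b <- distance_distribution(traj, c(1, 2), weights = w)
  expect_equal(a$density, b$density)
  expect_equal(a$peaks, b$peaks)
})

test_that("a planted bimodal mixture is recovered at its component means", {
  d <- mixture_draws(10000, c(8.3, 16.0), c(0.5, 0.5), c(0.5, 0.5), seed = 61)
  dist <- distance_distribution(distance_series_traj(d), c(1, 2), binwidth = 0.25)
  expect_equal(nrow(dist$peaks), 2L)
  expect_equal(dist$peaks$position, c(8.3, 16.0), tolerance = 0.2 / 8.3)
  expect_equal(dist$occupancies$occupancy, c(0.5, 0.5), tolerance = 0.05)
})

test_that("peak calling handles unimodal, trimodal and limit prominence", {
  uni <- mixture_draws(5000, 10, 0.5, 1, seed = 62)
  d_uni <- distance_distribution(distance_series_traj(uni), c(1, 2), binwidth = 0.25)
  expect_equal(nrow(d_uni$peaks), 1L)
  expect_lt(abs(d_uni$peaks$position - 10), d_uni$binwidth)

  tri <- mixture_draws(9000, c(7.5, 12, 16.5), rep(0.5, 3), rep(1 / 3, 3), seed = 63)
  d_tri <- distance_distribution(distance_series_traj(tri), c(1, 2), binwidth = 0.25)
  expect_equal(nrow(d_tri$peaks), 3L)
  expect_equal(d_tri$peaks$position, c(7.5, 12, 16.5), tolerance = 0.3 / 7.5)

  top_only <- find_peaks(d_tri, min_prominence = 1.0)
  expect_equal(nrow(top_only), 1L)
})

test_that("multi-seed peak recovery holds for well-separated components", {
  for (seed in 1:5) {
    d <- mixture_draws(5000, c(8.3, 16.0), c(0.5, 0.5), c(0.5, 0.5), seed = 630 + seed)
    dist <- distance_distribution(distance_series_traj(d), c(1, 2), binwidth = 0.25)
    expect_equal(nrow(dist$peaks), 2L)
    expect_lt(max(abs(dist$peaks$position - c(8.3, 16.0))), 0.3)
  }
})

test_that("boundary occupancy matches the analytic mixture CDF", {
  traj <- distance_series_traj(rep(c(5, 6), 25))
  expect_equal(state_occupancy(traj, c(1, 2), boundary = 10)$beyond, 0)

  d <- mixture_draws(10000, c(8.3, 16.0), c(0.5, 0.5), c(0.5, 0.5), seed = 64)
  occ <- state_occupancy(distance_series_traj(d), c(1, 2), boundary = 12)
  analytic <- 0.5 * (1 - pnorm(12, 8.3, 0.5)) + 0.5 * (1 - pnorm(12, 16, 0.5))
  expect_lt(abs(occ$beyond - analytic), 0.01)
  expect_equal(occ$beyond + occ$below, 1)
})

test_that("occupancy estimation is unbiased over many replicates", {
  p_beyond <- 0.2
  est <- vapply(1:50, function(seed) {
    d <- mixture_draws(2000, c(8, 16), c(0.5, 0.5), c(1 - p_beyond, p_beyond),
                       seed = 640 + seed)
    state_occupancy(distance_series_traj(d), c(1, 2), boundary = 12)$beyond
  }, numeric(1))
  mc_se <- sd(est) / sqrt(50)
  expect_lt(abs(mean(est) - p_beyond), 2 * mc_se + 1e-12)
})

test_that("population shift reports collapse, matching and total variation", {
  d_bi <- mixture_draws(8000, c(8.3, 16.0), c(0.5, 0.5), c(0.5, 0.5), seed = 65)
  d_uni <- mixture_draws(8000, 15.5, 0.8, 1, seed = 66)
  wt <- distance_distribution(distance_series_traj(d_bi), c(1, 2), binwidth = 0.25)
  mut <- distance_distribution(distance_series_traj(d_uni), c(1, 2), binwidth = 0.25)

  null_shift <- population_shift(wt, wt)
  expect_equal(null_shift$total_variation, 0)
  expect_equal(nrow(null_shift$matched), 2L)
  expect_equal(null_shift$pattern, "stable")

  shift <- population_shift(wt, mut)
  expect_equal(shift$peak_count_change, -1L)
  expect_equal(shift$pattern, "state collapse")
  expect_equal(nrow(shift$matched), 1L)  # 16.0 vs 15.5 within the 1 A tolerance

  # symmetry of total variation
  expect_equal(population_shift(mut, wt)$total_variation, shift$total_variation)

  # disjoint supports
  lo <- distance_distribution(distance_series_traj(rnorm(2000, 5, 0.2)),
                              c(1, 2), binwidth = 0.25)
  hi <- distance_distribution(distance_series_traj(rnorm(2000, 50, 0.2)),
                              c(1, 2), binwidth = 0.25)
  expect_equal(population_shift(lo, hi)$total_variation, 1)
})

test_that("too few frames is an error", {
  expect_error(distance_distribution(distance_series_traj(rep(8, 10)), c(1, 2)),
               "too few frames")
})
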