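triangle_traj <- function(m = 2) {
  # |12| = 5, |13| = 8, |23| = 12
  a <- c(0, 0, 0)
  b <- c(5, 0, 0)
  cx <- (5^2 + 8^2 - 12^2) / (2 * 5)
  cc <- c(cx, sqrt(8^2 - cx^2), 0)
  static_traj(rbind(a, b, cc), m = m)
}

test_that("second shell radius is the doubled-volume radius", {
  expect_equal(second_shell_radius(1), 2^(1 / 3))
  r2 <- second_shell_radius(7.2)
  expect_equal((4 / 3) * pi * r2^3, 2 * (4 / 3) * pi * 7.2^3, tolerance = 1e-12)
  expect_error(second_shell_radius(-1), "positive")
})

test_that("neighbor graph thresholds time-averaged reference distances", {
  traj <- triangle_traj()
  g <- build_neighbor_graph(traj, radius = 9.1)
  expect_equal(g$i, c(1L, 1L))
  expect_equal(g$j, c(2L, 3L))
  expect_equal(g$r_ref, c(5, 8), tolerance = 1e-12)

  expect_equal(nrow(build_neighbor_graph(traj, radius = 0.1)), 0L)
  expect_error(build_neighbor_graph(traj, radius = 0), "positive")
})

test_that("neighbor graph equals an all-pairs brute-force scan on a chain", {
  gen <- generate_pair(synthetic_config(seed = 55, n_frames = 60,
                                        n_shift_pairs = 0, state_pair = NULL,
                                        corr_blocks = NULL, drift = NULL,
                                        pseudo_sidechains = FALSE))
  traj <- superpose_to_first_frame(gen$wt)
  radius <- second_shell_radius(7.2)
  g <- build_neighbor_graph(traj, radius = radius)

  n <- n_residues(traj)
  m <- n_frames(traj)
  expected <- list()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dbar <- mean(vapply(seq_len(m), function(k) {
        sqrt(sum((traj$coords[i, , k] - traj$coords[j, , k])^2))
      }, numeric(1)))
      if (dbar <= radius) expected[[length(expected) + 1L]] <- c(i, j)
    }
  }
  expect_equal(nrow(g), length(expected))
  expect_equal(unname(as.matrix(g[, c("i", "j")])),
               do.call(rbind, expected))
})

test_that("mean distances reproduce hand values and the loop oracle", {
  two <- static_traj(rbind(c(0, 0, 0), c(3, 4, 0)), m = 3)
  g <- build_neighbor_graph(triangle_traj(), radius = 9.1)
  g2 <- structure(tibble::tibble(i = 1L, j = 2L, r_ref = 5),
                  radius = 9.1, n_residues = 2L)
  expect_equal(mean_distances(two, g2)$r_mean, 5)

  # two frames at distances 4 and 6, equal weights
  osc <- distance_series_traj(c(4, 6))
  expect_equal(mean_distances(osc, g2)$r_mean, 5)

  # oscillating pair vs per-frame loop
  d <- 8 + sin(seq_len(40))
  osc2 <- distance_series_traj(d)
  expect_equal(mean_distances(osc2, g2)$r_mean, mean(d), tolerance = 1e-10)
})

test_that("difference map is a null map for identical inputs and antisymmetric", {
  traj <- triangle_traj(m = 4)
  g <- build_neighbor_graph(traj, radius = 9.1)
  md <- mean_distances(traj, g)
  d0 <- delta_matrix(md, md)
  expect_true(all(d0$delta == 0))

  # planted +2 shift on pair (1,3): move residue 3 away from residue 1
  mut <- traj
  u <- (mut$coords[3, , 1] - mut$coords[1, , 1]) / 8
  for (k in seq_len(4)) mut$coords[3, , k] <- mut$coords[3, , k] + 2 * u
  md_mut <- mean_distances(mut, g)
  d1 <- delta_matrix(md, md_mut)
  expect_equal(d1$delta[d1$i == 1 & d1$j == 3], 2, tolerance = 1e-9)
  expect_equal(d1$delta[d1$i == 1 & d1$j == 2], 0, tolerance = 1e-12)

  swapped <- delta_matrix(md_mut, md)
  expect_equal(swapped$delta, -d1$delta)
})

test_that("significant pairs apply both thresholds with direction tags", {
  base <- tibble::tibble(i = 1:4, j = 5:8, r_wt = 8, r_mut = 8,
                         delta = c(3.1, 2.4, -1.5, -1.2))
  out <- significant_pairs(base)
  expect_equal(nrow(out), 2L)
  expect_equal(out$delta, c(3.1, -1.5))
  expect_equal(out$direction, c("apart", "closer"))

  none <- significant_pairs(dplyr::mutate(base, delta = 0))
  expect_equal(nrow(none), 0L)
  expect_error(significant_pairs(base, pos_thresh = -1), "pos_thresh")
})

test_that("planted shifts are recovered exactly with zero false positives", {
  gen <- default_gen()
  wt <- superpose_to_first_frame(gen$wt)
  mut <- superpose_to_first_frame(gen$mut)
  g <- build_neighbor_graph(wt)
  sig <- significant_pairs(delta_matrix(mean_distances(wt, g),
                                        mean_distances(mut, g)))
  key <- function(i, j) paste(i, j, sep = "-")
  expect_setequal(key(sig$i, sig$j),
                  key(gen$truth$shift_pairs$i, gen$truth$shift_pairs$j))
  expect_true(all(sig$direction == "apart"))
})

test_that("per-residue profile equals the loop oracle and respects bounds", {
  gen <- generate_pair(synthetic_config(seed = 56, n_frames = 50,
                                        n_shift_pairs = 0, state_pair = NULL,
                                        corr_blocks = NULL, drift = NULL,
                                        pseudo_sidechains = FALSE,
                                        n_residues = 12))
  wt <- superpose_to_first_frame(gen$wt)
  mut <- superpose_to_first_frame(gen$mut)
  g <- build_neighbor_graph(wt)
  delta <- delta_matrix(mean_distances(wt, g), mean_distances(mut, g))
  prof <- delta_residue_profile(delta, g)
  expect_equal(nrow(prof), 12L)

  for (r in prof$residue) {
    incident <- delta$delta[delta$i == r | delta$j == r]
    if (length(incident) == 0) {
      expect_true(is.na(prof$delta_mean[prof$residue == r]))
      expect_equal(prof$n_neighbors[prof$residue == r], 0L)
    } else {
      expect_equal(prof$delta_mean[prof$residue == r], mean(incident))
      expect_equal(prof$n_neighbors[prof$residue == r], length(incident))
      expect_gte(prof$delta_mean[prof$residue == r], min(incident))
      expect_lte(prof$delta_mean[prof$residue == r], max(incident))
    }
  }

  # zero delta -> zero profile
  zero_prof <- delta_residue_profile(delta_matrix(mean_distances(wt, g),
                                                  mean_distances(wt, g)), g)
  expect_true(all(zero_prof$delta_mean[zero_prof$n_neighbors > 0] == 0))
})

test_that("uniform expansion produces the analytic difference signature", {
  set.seed(57)
  base <- matrix(rnorm(30, sd = 4), 10, 3)
  wt <- static_traj(base, m = 3)
  s <- 1.05
  cen <- colMeans(base)
  mut <- static_traj(sweep(sweep(base, 2, cen), 1, rep(s, 10), "*") +
                       matrix(cen, 10, 3, byrow = TRUE), m = 3)
  g <- build_neighbor_graph(wt, radius = 9.1)
  delta <- delta_matrix(mean_distances(wt, g), mean_distances(mut, g))
  expect_true(all(delta$delta > 0))
  expect_equal(delta$delta, (s - 1) * delta$r_wt, tolerance = 1e-9)
})

test_that("the graph frozen on the reference fixes the analysed pair set", {
  gen <- default_gen()
  wt <- superpose_to_first_frame(gen$wt)
  mut <- superpose_to_first_frame(gen$mut)
  g_ref <- build_neighbor_graph(wt)
  g_mut <- build_neighbor_graph(mut)
  # the mutant's own graph differs, but the delta map is defined on the
  # reference pair set regardless
  expect_false(identical(paste(g_ref$i, g_ref$j), paste(g_mut$i, g_mut$j)))
  delta <- delta_matrix(mean_distances(wt, g_ref), mean_distances(mut, g_ref))
  expect_identical(paste(delta$i, delta$j), paste(g_ref$i, g_ref$j))
})
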