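test_that("plain-table round trip preserves coordinates, labels and times", {
  traj <- random_traj(n = 3, m = 2, seed = 11, condition = "WT")
  tab <- withr::local_tempfile(fileext = ".txt")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_coord_table(traj, tab)
  write_topology_pdb(traj, pdb)

  back <- read_trajectory(pdb, tab, condition = "WT")
  expect_equal(n_residues(back), 3L)
  expect_equal(n_frames(back), 2L)
  expect_equal(back$coords, traj$coords, tolerance = 1e-6)
  expect_equal(back$times, traj$times)

  again <- read_trajectory(pdb, tab, condition = "WT")
  expect_identical(back$coords, again$coords)

  # PDB coordinates are fixed-format with 3 decimals
  frame1 <- read_trajectory(pdb, tab)$coords[, , 1]
  expect_equal(frame1, traj$coords[, , 1], tolerance = 1e-3)
})

test_that("read_trajectory errors on missing files and mismatched tables", {
  traj <- random_traj(n = 4, m = 3, seed = 2)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  tab <- withr::local_tempfile(fileext = ".txt")
  write_topology_pdb(traj, pdb)
  expect_error(read_trajectory("no-such.pdb", tab), "missing")
  # table listing only 3 of the 4 topology residues
  bad <- as_tibble(random_traj(n = 3, m = 3, seed = 2))
  readr::write_delim(bad[, c("frame", "residue", "x", "y", "z")], tab, delim = " ")
  expect_error(read_trajectory(pdb, tab), "mismatch")
})

test_that("superposition removes planted rigid-body motion exactly", {
  set.seed(3)
  ref <- matrix(rnorm(12, sd = 4), 4, 3)
  coords <- array(0, c(4, 3, 5))
  coords[, , 1] <- ref
  for (k in 2:5) {
    moved <- apply_rigid_all_frames(static_traj(ref, m = 1),
                                    angle = 0.3 * k, axis = c(1, k, 2),
                                    translation = c(k, -k, 0.5 * k))
    coords[, , k] <- moved$coords[, , 1]
  }
  traj <- make_traj(coords, aligned = FALSE)
  out <- superpose_to_first_frame(traj)
  expect_true(out$aligned)
  expect_identical(out$coords[, , 1], ref)  # frame 1 untouched
  for (k in 2:5) {
    expect_lt(rmsd_between(out$coords[, , k], ref), 1e-8)
  }
  # idempotence
  twice <- superpose_to_first_frame(out)
  expect_equal(twice$coords, out$coords, tolerance = 1e-10)
})

test_that("superposition is invariant to a rigid pre-transform of the input", {
  traj <- random_traj(n = 6, m = 8, seed = 4, aligned = FALSE)
  a <- superpose_to_first_frame(traj)
  b <- superpose_to_first_frame(apply_rigid_all_frames(traj))
  # both land on their own frame-1; map b's result back onto a's frame 1
  fit <- mutdyn:::kabsch_fit(b$coords[, , 1], a$coords[, , 1])
  for (k in seq_len(8)) {
    expect_lt(rmsd_between(mutdyn:::apply_rigid(b$coords[, , k], fit),
                           a$coords[, , k]), 1e-8)
  }
})

test_that("superposition attains the least-squares optimum per frame", {
  set.seed(5)
  ref <- matrix(rnorm(12, sd = 3), 4, 3)
  mob <- matrix(rnorm(12, sd = 3), 4, 3)
  traj <- make_traj(array(c(ref, mob), c(4, 3, 2)), aligned = FALSE)
  out <- superpose_to_first_frame(traj)
  ours <- rmsd_between(out$coords[, , 2], ref)

  # independent check 1: the field-standard fitter lands on the same optimum
  xyz <- rbind(as.vector(t(ref)), as.vector(t(mob)))
  fitted <- bio3d::fit.xyz(xyz[1, ], xyz, fixed.inds = 1:12, mobile.inds = 1:12)
  theirs <- sqrt(mean(colSums(matrix((fitted[2, ] - xyz[1, ])^2, nrow = 3))))
  expect_equal(ours, theirs, tolerance = 1e-6)

  # independent check 2: no rotation on a coarse grid does better
  expect_lte(ours, grid_min_rmsd(mob, ref, step_deg = 12) + 1e-9)
})

test_that("superposition rejects degenerate reference frames", {
  line <- cbind(0:3, 0, 0)
  traj <- make_traj(array(line, c(4, 3, 2)), aligned = FALSE)
  expect_error(superpose_to_first_frame(traj), "degenerate|collinear")
})

test_that("equilibration slicing removes exactly the early frames", {
  traj <- make_traj(array(rnorm(2 * 3 * 10), c(2, 3, 10)),
                    times = seq(0, 90, by = 10))
  out <- slice_equilibrated(traj, discard_initial = 50)
  expect_equal(n_frames(out), 5L)
  expect_equal(out$times, seq(50, 90, by = 10))

  expect_equal(slice_equilibrated(traj, discard_initial = 0)$coords, traj$coords)
  expect_error(slice_equilibrated(traj, discard_initial = 1e6), "zero frames")

  long <- make_traj(array(rnorm(2 * 3 * 1000), c(2, 3, 1000)),
                    times = seq(0, by = 10, length.out = 1000))
  cut <- slice_equilibrated(long, discard_fraction = 0.1)
  expect_equal(n_frames(cut), 900L)
  expect_gte(min(cut$times), 0.1 * 1000 * 10)
})
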