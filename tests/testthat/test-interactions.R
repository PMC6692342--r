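# minimal atom-detail trajectory: an Asp oxygen and a Lys nitrogen whose
# separation follows `gap` over frames, plus an optional donor-H-acceptor
# triplet with controllable geometry
bridge_traj <- function(gap, hbond_da = NULL, hbond_angle = 180) {
  m <- length(gap)
  n <- 6
  base <- cbind(seq_len(n) * 3.8, 0, 0)
  coords <- array(base, c(n, 3, m))
  residues <- tibble::tibble(index = 1:6,
                             name = c("ASP", "GLY", "LYS", "SER", "GLY", "ASN"))
  info <- tibble::tibble(
    residue = c(1L, 3L, 4L, 4L, 6L),
    atom = c("OD1", "NZ", "OG", "HG", "OD1"),
    element = c("O", "N", "O", "H", "O"),
    role = c("sidechain", "sidechain", "donor", "hydrogen", "acceptor"),
    parent = c(NA, NA, NA, "OG", NA)
  )
  ac <- array(0, c(5, 3, m))
  ac[1, 2, ] <- 5                      # ASP OD1 fixed
  ac[2, 2, ] <- 5 + gap                # LYS NZ at the requested O-N gap
  ac[3, 2, ] <- -5                     # SER OG
  if (!is.null(hbond_da)) {
    theta <- hbond_angle * pi / 180
    # H one Angstrom from the donor; acceptor placed so the D-H...A angle
    # at the hydrogen equals `hbond_angle` and |D-A| is as requested
    ac[4, 2, ] <- -5 + 1               # H straight toward +y
    ac[5, 2, ] <- -5 + 1 - cos(theta) * (hbond_da - 1)
    ac[5, 1, ] <- sin(theta) * (hbond_da - 1)
  } else {
    ac[4, 2, ] <- -5 + 1
    ac[5, 2, ] <- 50                   # acceptor far away
  }
  new_trajectory(coords, residues = residues, times = (seq_len(m) - 1) * 10,
                 atoms = list(info = info, coords = ac), aligned = TRUE)
}

test_that("salt bridges are called by the O-N distance cutoff", {
  close <- detect_salt_bridges(bridge_traj(rep(3.0, 4)))
  expect_equal(nrow(close), 1L)
  expect_equal(close$res_i, 1L)
  expect_equal(close$res_j, 3L)
  expect_equal(close$occupancy, 1)
  expect_equal(close$atoms, "OD1-NZ")

  far <- detect_salt_bridges(bridge_traj(rep(4.5, 4)))
  expect_equal(nrow(far), 0L)
})

test_that("salt-bridge occupancy matches an all-pairs all-frames loop oracle", {
  set.seed(81)
  gap <- c(rep(2.9, 60), rep(5.0, 40))[sample(100)]
  traj <- bridge_traj(gap)
  rec <- detect_salt_bridges(traj)
  expect_equal(rec$occupancy, 0.60)

  # brute-force recomputation from the raw atom coordinates
  o <- traj$atoms$coords[1, , ]
  nz <- traj$atoms$coords[2, , ]
  oracle <- mean(sqrt(colSums((o - nz)^2)) <= 3.2)
  expect_equal(rec$occupancy, oracle)

  # monotonicity in the cutoff
  loose <- detect_salt_bridges(traj, cutoff = 5.5)
  expect_gte(loose$occupancy, rec$occupancy)

  # invariance to duplicating every frame
  dup <- traj
  dup$coords <- dup$coords[, , rep(1:100, 2)]
  dup$atoms$coords <- dup$atoms$coords[, , rep(1:100, 2)]
  dup$times <- seq_len(200)
  expect_equal(detect_salt_bridges(dup)$occupancy, rec$occupancy)
})

test_that("hydrogen bonds require both distance and angle", {
  collinear <- detect_hbonds(bridge_traj(rep(3, 3), hbond_da = 2.9))
  expect_equal(nrow(collinear), 1L)
  expect_equal(collinear$occupancy, 1)
  expect_equal(collinear$atoms, "OG-OD1")

  bent <- detect_hbonds(bridge_traj(rep(3, 3), hbond_da = 2.9, hbond_angle = 90))
  expect_equal(nrow(bent), 0L)

  too_far <- detect_hbonds(bridge_traj(rep(3, 3), hbond_da = 4.2))
  expect_equal(nrow(too_far), 0L)
})

test_that("hydrogen-bond calls match a brute-force triple-loop oracle", {
  set.seed(82)
  m <- 50
  traj <- bridge_traj(rep(3, m), hbond_da = 2.9)
  # jitter all detail atoms so some frames break the criteria
  traj$atoms$coords <- traj$atoms$coords + array(rnorm(5 * 3 * m, sd = 0.4), c(5, 3, m))
  rec <- detect_hbonds(traj)

  info <- traj$atoms$info
  oracle_present <- vapply(seq_len(m), function(k) {
    dpos <- traj$atoms$coords[3, , k]
    hpos <- traj$atoms$coords[4, , k]
    apos <- traj$atoms$coords[5, , k]
    da <- sqrt(sum((dpos - apos)^2))
    v1 <- dpos - hpos
    v2 <- apos - hpos
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    da <= 3.5 && ang >= 150
  }, logical(1))
  if (any(oracle_present)) {
    expect_equal(rec$present[[1]], oracle_present)
    expect_equal(rec$occupancy, mean(oracle_present))
  } else {
    expect_equal(nrow(rec), 0L)
  }
})

test_that("state-conditioned occupancies expose bond/conformation coupling", {
  m <- 100
  state <- rep(c(1L, 2L), each = 50)
  gap <- ifelse(state == 1L, 5.0, 3.0)   # bond exists only in state 2
  traj <- bridge_traj(gap)
  rec <- detect_salt_bridges(traj)

  part <- partition_states(ifelse(state == 1, 0, 10) + rnorm(m, 0, 0.1),
                           rnorm(m, 0, 0.1))
  tl <- interaction_timeline(rec, part)
  by_state <- tl$occupancy[tl$state != "overall"]
  expect_equal(sort(by_state), c(0, 1))
  expect_equal(tl$occupancy[tl$state == "overall"], 0.5)

  overall_only <- interaction_timeline(rec)
  expect_equal(nrow(overall_only), 1L)
  expect_equal(overall_only$state, "overall")
})
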