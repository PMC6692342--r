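#' Cα trajectory container
#'
#' A `ca_trajectory` stores one condition's coordinate time series as an
#' `N x 3 x M` array (N residues, M frames, coordinates in Angstrom), together
#' with 1-based serial residue labels, frame times in picoseconds, a free-text
#' condition tag and an alignment flag.  Optional side-chain atom detail (for
#' salt-bridge / hydrogen-bond calls) rides along in `$atoms`.
#'
#' @param coords numeric `N x 3 x M` array (an `N x 3` matrix is treated as a
#'   single frame).  Units: Angstrom.
#' @param residues optional tibble with columns `index` (1-based serial) and
#'   `name` (three-letter residue name).  Defaults to `1:N` glycines.
#' @param times optional numeric vector of frame times (ps).  Defaults to
#'   `(0:(M-1)) * 10`.
#' @param condition free-text condition tag, e.g. `"WT-GTP"`.
#' @param aligned logical; has rigid-body motion been removed?  Analyses that
#'   require superposed frames check this flag.
#' @param atoms optional atom detail list as built by the synthetic generator:
#'   `list(info = tibble(residue, atom, element, role, parent), coords = A x 3 x M)`.
#'
#' @return An object of class `ca_trajectory`.
#' @export
new_trajectory <- function(coords, residues = NULL, times = NULL,
                           condition = "", aligned = FALSE, atoms = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- dim(coords)[1]
  m <- dim(coords)[3]
  if (n < 2L) abort("a trajectory needs at least 2 residues")
  if (m < 1L) abort("a trajectory needs at least 1 frame")
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (is.null(residues)) {
    residues <- tibble::tibble(index = seq_len(n), name = rep("GLY", n))
  }
  residues <- tibble::as_tibble(residues)
  stopifnot(all(c("index", "name") %in% names(residues)), nrow(residues) == n)
  if (is.null(times)) times <- (seq_len(m) - 1) * 10
  stopifnot(length(times) == m)
  structure(
    list(coords = coords, residues = residues, times = as.numeric(times),
         condition = condition, aligned = isTRUE(aligned), atoms = atoms),
    class = "ca_trajectory"
  )
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ca_trajectory> %s: %d residues x %d frames (%.0f..%.0f ps)%s%s\n",
    if (nzchar(x$condition)) x$condition else "(untagged)",
    n_residues(x), n_frames(x), min(x$times), max(x$times),
    if (x$aligned) ", aligned" else ", unaligned",
    if (!is.null(x$atoms)) sprintf(", %d detail atoms", nrow(x$atoms$info)) else ""
  ))
  invisible(x)
}

#' Number of residues / frames in a trajectory
#' @param traj a [new_trajectory()] object.
#' @return integer count.
#' @export
n_residues <- function(traj) dim(traj$coords)[1]

#' @rdname n_residues
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Long-format view of a trajectory
#'
#' @param x a `ca_trajectory`.
#' @param ... unused.
#' @return A tibble with one row per (frame, residue):
#'   `frame, time, residue, name, x, y, z`.
#' @export
as_tibble.ca_trajectory <- function(x, ...) {
  n <- n_residues(x)
  m <- n_frames(x)
  xs <- as.vector(x$coords[, 1, ])
  ys <- as.vector(x$coords[, 2, ])
  zs <- as.vector(x$coords[, 3, ])
  tibble::tibble(
    frame = rep(seq_len(m), each = n),
    time = rep(x$times, each = n),
    residue = rep(x$residues$index, m),
    name = rep(x$residues$name, m),
    x = xs, y = ys, z = zs
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

## ---- plain-table coordinate dialect -------------------------------------
## One row per (frame, residue): frame, residue, x, y, z, optional time.
## Whitespace- or comma-delimited, header required.

#' Write a trajectory as a plain coordinate table
#'
#' The plain-table dialect has one row per (frame, residue) with columns
#' `frame residue x y z time`, whitespace-delimited with a header line, so
#' tests and small fixtures need no binary formats.
#'
#' @param traj a `ca_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coord_table <- function(traj, path) {
  tab <- as_tibble(traj)[, c("frame", "residue", "x", "y", "z", "time")]
  readr::write_delim(tab, path, delim = " ")
  invisible(path)
}

read_plain_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first, fixed = TRUE)) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tab <- readr::read_table(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("frame", "residue", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    abort(paste0("coordinate table must have columns: ", paste(need, collapse = " ")))
  }
  tab
}

#' Write frame 1 of a trajectory as a PDB topology
#'
#' @param traj a `ca_trajectory`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(traj, path) {
  xyz <- as.vector(t(traj$coords[, , 1]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$residues$index,
                   resid = traj$residues$name,
                   elety = rep("CA", n_residues(traj)),
                   chain = rep("A", n_residues(traj)))
  invisible(path)
}

#' Read a topology + coordinate time series into a trajectory
#'
#' The topology is a PDB file (parsed with bio3d); coordinates come either
#' from a plain coordinate table (see [write_coord_table()]) or from a binary
#' DCD file (extension `.dcd`, read with bio3d).  With the default
#' `"calpha"` selection only Cα atoms are kept, one per residue, in topology
#' order.
#'
#' @param topology_path PDB file.
#' @param coords_path coordinate table or `.dcd` file.
#' @param atom_selection `"calpha"` (default) or `"all"`.
#' @param frame_dt frame spacing in ps, used when the coordinate source
#'   carries no time stamps (default 10 ps, a typical MD saving interval).
#' @param condition condition tag for the result.
#' @return A [new_trajectory()] object.
#' @export
read_trajectory <- function(topology_path, coords_path,
                            atom_selection = c("calpha", "all"),
                            frame_dt = 10, condition = "") {
  atom_selection <- match.arg(atom_selection)
  if (!file.exists(topology_path)) abort(paste0("missing topology file: ", topology_path))
  if (!file.exists(coords_path)) abort(paste0("missing coordinate file: ", coords_path))
  pdb <- bio3d::read.pdb(topology_path)
  sel <- bio3d::atom.select(pdb, if (atom_selection == "calpha") "calpha" else "all",
                            verbose = FALSE)
  if (length(sel$atom) < 2L) abort("atom selection resolves to fewer than 2 atoms")
  at <- pdb$atom[sel$atom, ]
  residues <- tibble::tibble(index = seq_len(nrow(at)), name = at$resid)

  if (grepl("\\.dcd$", coords_path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(coords_path, verbose = FALSE)
    if (ncol(xyz) != 3 * nrow(pdb$atom)) {
      abort("atom-count mismatch between topology and DCD frames")
    }
    xyz <- xyz[, sel$xyz, drop = FALSE]
    m <- nrow(xyz)
    n <- nrow(at)
    coords <- aperm(array(t(xyz), c(3L, n, m)), c(2L, 1L, 3L))
    times <- (seq_len(m) - 1) * frame_dt
  } else {
    tab <- read_plain_table(coords_path)
    n <- nrow(at)
    frames <- sort(unique(tab$frame))
    m <- length(frames)
    tab <- dplyr::arrange(tab, .data$frame, .data$residue)
    if (nrow(tab) != n * m || !all(tab$residue == rep(seq_len(n), m))) {
      abort("atom-count mismatch: every frame must list every topology residue once")
    }
    coords <- array(0, c(n, 3L, m))
    coords[, 1, ] <- tab$x
    coords[, 2, ] <- tab$y
    coords[, 3, ] <- tab$z
    times <- if ("time" %in% names(tab)) {
      tab$time[seq(1L, nrow(tab), by = n)]
    } else {
      (frames - min(frames)) * frame_dt
    }
  }
  new_trajectory(coords, residues = residues, times = times, condition = condition)
}

## ---- rigid-body superposition -------------------------------------------

## Closed-form least-squares rigid fit (Kabsch): rotation + translation
## minimizing RMSD of `mobile` (n x 3) onto `target` (n x 3).
kabsch_fit <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  s <- crossprod(p, q)
  sv <- svd(s)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = rot, mobile_center = cm, target_center = ct)
}

apply_rigid <- function(points, fit) {
  sweep(sweep(points, 2, fit$mobile_center) %*% fit$rotation, 2, fit$target_center, "+")
}

#' Remove rigid-body motion by superposing every frame onto the first
#'
#' Each frame is replaced by the closed-form least-squares rigid transform
#' (Kabsch) of its Cα coordinates onto frame 1; frame 1 is unchanged.  Any
#' side-chain detail atoms are carried through the same per-frame transform.
#'
#' @param traj a `ca_trajectory` with at least 3 non-collinear residues in
#'   frame 1.
#' @return The aligned trajectory (`$aligned` set to `TRUE`).
#' @export
superpose_to_first_frame <- function(traj) {
  ref <- traj$coords[, , 1]
  if (n_residues(traj) < 3L) abort("superposition needs at least 3 residues")
  sv <- svd(sweep(ref, 2, colMeans(ref)))
  if (sv$d[2] < 1e-8) abort("degenerate reference frame: residues are collinear or coincident")
  out <- traj$coords
  atoms <- traj$atoms
  for (m in seq_len(n_frames(traj))[-1]) {
    fit <- kabsch_fit(traj$coords[, , m], ref)
    out[, , m] <- apply_rigid(traj$coords[, , m], fit)
    if (!is.null(atoms)) {
      atoms$coords[, , m] <- apply_rigid(atoms$coords[, , m], fit)
    }
  }
  traj$coords <- out
  traj$atoms <- atoms
  traj$aligned <- TRUE
  traj
}

#' Drop initial non-equilibrated frames
#'
#' Frames with `time < discard_initial` are removed (for example the first
#' 100 ns of a 1 microsecond run, keeping the last 900 ns).  Alternatively
#' `discard_fraction` removes the corresponding fraction of the run length.
#'
#' @param traj a `ca_trajectory`.
#' @param discard_initial duration to discard from the start, in ps.
#' @param discard_fraction fraction of the total duration to discard
#'   (used when `discard_initial` is `NULL`; default 0.1).
#' @return The trimmed trajectory.
#' @export
slice_equilibrated <- function(traj, discard_initial = NULL, discard_fraction = 0.1) {
  if (is.null(discard_initial)) {
    dt <- if (n_frames(traj) > 1) median(diff(traj$times)) else 0
    discard_initial <- discard_fraction * n_frames(traj) * dt
  }
  keep <- traj$times >= discard_initial
  if (!any(keep)) abort("discarding that much leaves zero frames")
  traj$coords <- traj$coords[, , keep, drop = FALSE]
  traj$times <- traj$times[keep]
  if (!is.null(traj$atoms)) {
    traj$atoms$coords <- traj$atoms$coords[, , keep, drop = FALSE]
  }
  traj
}

require_aligned <- function(traj, what) {
  if (!isTRUE(traj$aligned)) {
    abort(paste0(what, " requires an aligned trajectory; run superpose_to_first_frame() first"))
  }
  invisible(traj)
}

## distance series for one residue pair, length M
pair_distance_series <- function(traj, i, j) {
  d <- traj$coords[i, , ] - traj$coords[j, , ]
  if (is.null(dim(d))) d <- matrix(d, nrow = 3L)
  sqrt(colSums(d^2))
}
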