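## Atom detail helpers ------------------------------------------------------
## traj$atoms$info: tibble(residue, atom, element, role, parent)
##   role: "sidechain" (plain side-chain atom), "donor", "hydrogen"
##   (parent = its donor atom name) or "acceptor".
## traj$atoms$coords: A x 3 x M, frame-synchronous with the Calpha coords.

atom_rows <- function(traj, residue, atoms) {
  info <- traj$atoms$info
  which(info$residue == residue & info$atom %in% atoms)
}

ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
HIS_ATOMS <- c("ND1", "NE2")

interaction_record <- function(kind, res_i, res_j, atoms, present) {
  tibble::tibble(kind = kind, res_i = res_i, res_j = res_j, atoms = atoms,
                 occupancy = mean(present), present = list(present))
}

#' Detect salt bridges geometrically over a trajectory
#'
#' A salt bridge between an acidic residue (Asp/Glu) and a basic residue
#' (Lys/Arg, optionally His) is present in a frame iff any acidic side-chain
#' oxygen lies within `cutoff` of any basic side-chain nitrogen.  The default
#' 3.2 Angstrom oxygen-nitrogen cutoff is the widely used convention of the
#' VMD salt-bridge tool.  Requires side-chain atom detail on the trajectory;
#' acidic/basic residues lacking their side-chain atoms are skipped with a
#' warning.
#'
#' @param traj a `ca_trajectory` carrying `$atoms` detail.
#' @param cutoff O-N distance cutoff in Angstrom (default 3.2).
#' @param include_his count histidine as basic (default `FALSE`).
#' @return A tibble of interaction records: `kind, res_i` (acidic),
#'   `res_j` (basic), `atoms`, `occupancy`, and a `present` list-column of
#'   per-frame logicals.  Only pairs with occupancy > 0 are returned.
#' @export
detect_salt_bridges <- function(traj, cutoff = 3.2, include_his = FALSE) {
  if (is.null(traj$atoms)) abort("trajectory has no side-chain atom detail")
  m <- n_frames(traj)
  res <- traj$residues
  basic_atoms <- BASIC_ATOMS
  if (include_his) basic_atoms$HIS <- HIS_ATOMS

  find_group <- function(names_map) {
    out <- list()
    for (k in seq_len(nrow(res))) {
      nm <- res$name[k]
      if (!nm %in% names(names_map)) next
      rows <- atom_rows(traj, res$index[k], names_map[[nm]])
      if (!length(rows)) {
        warn(sprintf("residue %d (%s) lacks side-chain atoms; skipped", res$index[k], nm))
        next
      }
      out[[as.character(res$index[k])]] <- rows
    }
    out
  }
  acidic <- find_group(ACIDIC_ATOMS)
  basic <- find_group(basic_atoms)

  records <- list()
  for (ra in names(acidic)) {
    for (rb in names(basic)) {
      if (ra == rb) next
      best <- rep(Inf, m)
      best_pair <- ""
      for (ia in acidic[[ra]]) {
        for (ib in basic[[rb]]) {
          d <- sqrt(colSums((traj$atoms$coords[ia, , , drop = TRUE] -
                             traj$atoms$coords[ib, , , drop = TRUE])^2))
          if (min(d) < min(best)) {
            best_pair <- paste(traj$atoms$info$atom[ia],
                               traj$atoms$info$atom[ib], sep = "-")
          }
          best <- pmin(best, d)
        }
      }
      present <- best <= cutoff
      if (any(present)) {
        records[[length(records) + 1L]] <- interaction_record(
          "salt-bridge", as.integer(ra), as.integer(rb), best_pair, present)
      }
    }
  }
  if (!length(records)) {
    return(tibble::tibble(kind = character(), res_i = integer(),
                          res_j = integer(), atoms = character(),
                          occupancy = numeric(), present = list()))
  }
  dplyr::bind_rows(records) |> dplyr::arrange(.data$res_i, .data$res_j)
}

#' Detect hydrogen bonds geometrically over a trajectory
#'
#' A bond between a donor heavy atom D (with attached hydrogen H) and an
#' acceptor heavy atom A on a different residue is present in a frame iff
#' the D-A distance is at most `d_cutoff` and the D-H...A angle (at the
#' hydrogen) is at least `angle_cutoff`.  Defaults (3.5 Angstrom, 150
#' degrees) are community-standard geometric criteria.  If no hydrogens are
#' present the call falls back to a distance-only criterion with a warning.
#'
#' @param traj a `ca_trajectory` carrying `$atoms` detail with atoms tagged
#'   `donor`, `hydrogen` (with `parent` naming its donor) and `acceptor`.
#' @param d_cutoff donor-acceptor distance cutoff in Angstrom.
#' @param angle_cutoff donor-hydrogen-acceptor angle cutoff in degrees.
#' @return A tibble of interaction records (see [detect_salt_bridges()]).
#' @export
detect_hbonds <- function(traj, d_cutoff = 3.5, angle_cutoff = 150) {
  if (is.null(traj$atoms)) abort("trajectory has no atom detail")
  info <- traj$atoms$info
  donors <- which(info$role == "donor")
  acceptors <- which(info$role == "acceptor")
  have_h <- any(info$role == "hydrogen")
  if (!have_h) warn("no hydrogens in atom detail; using distance-only criterion")

  records <- list()
  for (id in donors) {
    hrow <- which(info$role == "hydrogen" &
                  info$residue == info$residue[id] &
                  info$parent == info$atom[id])
    for (ia in acceptors) {
      if (info$residue[ia] == info$residue[id]) next
      dvec <- traj$atoms$coords[id, , , drop = TRUE] -
        traj$atoms$coords[ia, , , drop = TRUE]
      dda <- sqrt(colSums(dvec^2))
      present <- dda <= d_cutoff
      if (have_h && length(hrow)) {
        h <- traj$atoms$coords[hrow[1], , , drop = TRUE]
        v1 <- traj$atoms$coords[id, , , drop = TRUE] - h
        v2 <- traj$atoms$coords[ia, , , drop = TRUE] - h
        cosang <- colSums(v1 * v2) /
          (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        present <- present & ang >= angle_cutoff
      }
      if (any(present)) {
        records[[length(records) + 1L]] <- interaction_record(
          "h-bond", info$residue[id], info$residue[ia],
          paste(info$atom[id], info$atom[ia], sep = "-"), present)
      }
    }
  }
  if (!length(records)) {
    return(tibble::tibble(kind = character(), res_i = integer(),
                          res_j = integer(), atoms = character(),
                          occupancy = numeric(), present = list()))
  }
  dplyr::bind_rows(records) |> dplyr::arrange(.data$res_i, .data$res_j)
}

#' Interaction occupancies, overall and per conformational state
#'
#' Joins per-frame interaction presence with a PCA state partition so bond
#' formation can be related to conformational states (e.g. a bond that
#' exists only while the pair occupies its distant state).
#'
#' @param records interaction records from [detect_salt_bridges()] /
#'   [detect_hbonds()].
#' @param states optional [partition_states()] result over the same frames;
#'   omit for overall occupancies only.
#' @return A long tibble `kind, res_i, res_j, atoms, state, occupancy`
#'   where `state` is `"overall"` or the state label.
#' @export
interaction_timeline <- function(records, states = NULL) {
  out <- records |>
    dplyr::select("kind", "res_i", "res_j", "atoms", "occupancy") |>
    dplyr::mutate(state = "overall", .before = "occupancy")
  if (is.null(states)) return(out)
  m <- length(records$present[[1]])
  if (nrow(states$assignments) != m) {
    abort("state partition and interaction records cover different frame counts")
  }
  lab <- states$assignments$state
  per_state <- purrr::map_dfr(seq_len(nrow(records)), function(r) {
    pres <- records$present[[r]]
    purrr::map_dfr(sort(unique(lab)), function(s) {
      tibble::tibble(kind = records$kind[r], res_i = records$res_i[r],
                     res_j = records$res_j[r], atoms = records$atoms[r],
                     state = as.character(s),
                     occupancy = mean(pres[lab == s]))
    })
  })
  dplyr::bind_rows(out, per_state) |>
    dplyr::arrange(.data$res_i, .data$res_j, .data$state)
}
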