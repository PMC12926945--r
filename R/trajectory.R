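# Trajectory container and readers/writers. Frames are stored as an
# (n_frames x n_atoms x 3) array in nm with strictly increasing frame times
# in ps. Multi-model PDB (with per-frame time remarks) and DCD are read;
# multi-model PDB is written.

#' Build a trajectory from frame coordinates
#'
#' @param coords Numeric array of dimension `(n_frames, n_atoms, 3)` in nm,
#'   or a list of `n_atoms x 3` matrices.
#' @param times Frame times in ps, strictly increasing, first >= 0.
#' @param structure The `parch_structure` the frames are congruent with.
#' @param box Optional 3-vector box (nm).
#' @return A `parch_trajectory` object.
#' @export
parch_trajectory <- function(coords, times, structure, box = NULL) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_frames <- dim(coords)[1]
  if (length(times) != n_frames) {
    abort("frame_times length must equal the number of frames")
  }
  if (n_frames == 0) abort("trajectory has no frames")
  if (times[1] < 0) abort("frame times must start at >= 0 ps")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (dim(coords)[2] != nrow(structure)) {
    abort(sprintf(
      "trajectory has %d atoms per frame but structure has %d",
      dim(coords)[2], nrow(structure)
    ))
  }
  structure(
    list(coords = coords, times = as.numeric(times),
         n_atoms = nrow(structure), box = box),
    class = "parch_trajectory"
  )
}

#' @export
print.parch_trajectory <- function(x, ...) {
  cat(sprintf(
    "<parch_trajectory> %d frames x %d atoms | t = %.1f .. %.1f ps\n",
    n_frames(x), x$n_atoms, x$times[1], x$times[n_frames(x)]
  ))
  invisible(x)
}

#' @rdname parch_trajectory
#' @param traj A `parch_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname parch_trajectory
#' @param i Frame index.
#' @return `frame_coords()`: an `n_atoms x 3` matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

TIME_REMARK <- "REMARK 250 PARCH FRAME TIME PS:"

#' Read an annealing trajectory
#'
#' Multi-model PDB files are read with frame times taken from
#' `REMARK 250 PARCH FRAME TIME PS:` records (as written by
#' [write_trajectory()]) or, absent those, from `times`/`frame_interval`.
#' DCD files are read via bio3d with times from `times`/`frame_interval`.
#' XTC is not supported; convert to DCD or multi-model PDB upstream.
#'
#' @param path Trajectory file (`.pdb` multi-model or `.dcd`).
#' @param structure The matching `parch_structure` (atom count is checked).
#' @param times Optional explicit frame times (ps).
#' @param frame_interval Spacing (ps) used to synthesize times when the file
#'   carries none; default 10.
#' @return A `parch_trajectory`.
#' @export
read_trajectory <- function(path, structure, times = NULL,
                            frame_interval = 10) {
  if (!file.exists(path)) abort(paste0("cannot read trajectory: ", path))
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    coords <- xyz_to_array(xyz)
  } else if (grepl("\\.xtc$", path, ignore.case = TRUE)) {
    abort("XTC trajectories are not supported; supply DCD or multi-model PDB")
  } else {
    lines <- readLines(path)
    trem <- lines[startsWith(lines, TIME_REMARK)]
    if (length(trem) > 0 && is.null(times)) {
      times <- as.numeric(trimws(sub(TIME_REMARK, "", trem, fixed = TRUE)))
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    coords <- xyz_to_array(pdb$xyz)
  }
  nf <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(nf) - 1) * frame_interval
  parch_trajectory(coords, times, structure)
}

# bio3d xyz matrix (frames x 3N, Angstrom) -> frames x N x 3 array in nm
xyz_to_array <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  arr <- array(0, dim = c(nf, na, 3))
  for (k in 1:3) arr[, , k] <- xyz[, seq(k, ncol(xyz), by = 3)] / 10
  arr
}

#' Write a trajectory as multi-model PDB
#'
#' Each frame becomes one MODEL block; frame times are stored in
#' `REMARK 250` records so a round-trip through [read_trajectory()]
#' preserves them.
#'
#' @param traj A `parch_trajectory`.
#' @param structure The matching `parch_structure` (atom metadata).
#' @param path Output path (`.pdb`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, structure, path) {
  if (traj$n_atoms != nrow(structure)) {
    abort("trajectory and structure atom counts differ")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s %.4f", TIME_REMARK, traj$times), con)
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(pdb_atom_lines(structure, xyz = frame_coords(traj, i)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
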