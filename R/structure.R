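#' Atom-table structures
#'
#' `tailscope` represents a molecular structure as a plain tibble of atoms
#' with one row per atom and columns:
#'
#' * `name`    -- atom label (`"CA"`, `"N"`, ...)
#' * `element` -- chemical element symbol
#' * `res_seq` -- 1-based residue number
#' * `res_name`-- 3-letter residue code
#' * `chain_id`-- single-character chain identifier
#' * `x`, `y`, `z` -- coordinates in Angstrom
#'
#' `as_structure()` validates a data frame against this contract (finite
#' coordinates, `res_seq >= 1`, unique `(chain_id, res_seq, name)`) and
#' returns it as a tibble carrying a free-text `label` attribute.
#'
#' @param x A data frame with the columns listed above.
#' @param label Free-text label stored as an attribute.
#' @return A tibble of atoms.
#' @export
as_structure <- function(x, label = attr(x, "label") %||% "") {
  cols <- c("name", "element", "res_seq", "res_name", "chain_id", "x", "y", "z")
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    stop("structure is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  s <- tibble::as_tibble(x[, cols])
  if (!all(is.finite(s$x) & is.finite(s$y) & is.finite(s$z))) {
    stop("structure has non-finite coordinates", call. = FALSE)
  }
  if (any(s$res_seq < 1)) {
    stop("residue numbers must be >= 1", call. = FALSE)
  }
  key <- paste(s$chain_id, s$res_seq, s$name)
  if (anyDuplicated(key)) {
    stop(
      "duplicate atom identifier (chain, res_seq, name): ",
      key[which(duplicated(key))[1]],
      call. = FALSE
    )
  }
  attr(s, "label") <- label
  s
}

#' Extract the coordinate matrix of a structure
#'
#' @param s A structure tibble (see [as_structure()]).
#' @return An n_atoms x 3 numeric matrix.
#' @export
structure_coords <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

#' Trajectories
#'
#' A trajectory is a fixed topology (an atom tibble) plus an ordered stack of
#' coordinate frames and a frame spacing `dt` in picoseconds.
#'
#' @param topology Atom tibble shared by every frame.
#' @param coords Numeric array `n_frames x n_atoms x 3`, or a list of
#'   `n_atoms x 3` matrices.
#' @param dt Frame spacing in ps (> 0).
#' @return An object of class `tail_trajectory`.
#' @export
trajectory <- function(topology, coords, dt = 25) {
  topology <- as_structure(topology)
  if (is.list(coords)) {
    n_frames <- length(coords)
    arr <- array(0, dim = c(n_frames, nrow(topology), 3))
    for (i in seq_len(n_frames)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(topology)) {
    stop("frame atom count (", dim(coords)[2], ") does not match topology (",
      nrow(topology), ")",
      call. = FALSE
    )
  }
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 ps", call. = FALSE)
  structure(
    list(topology = topology, coords = coords, dt = dt),
    class = "tail_trajectory"
  )
}

#' @export
print.tail_trajectory <- function(x, ...) {
  cat(
    "<tail_trajectory> ", n_frames(x), " frames x ", nrow(x$topology),
    " atoms, dt = ", x$dt, " ps\n",
    sep = ""
  )
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `tail_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Materialise one frame of a trajectory as a structure
#'
#' @param traj A `tail_trajectory`.
#' @param frame 1-based frame index.
#' @return An atom tibble with that frame's coordinates; its label records
#'   the frame index and simulation time.
#' @export
frame_structure <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  s <- traj$topology
  s$x <- traj$coords[frame, , 1]
  s$y <- traj$coords[frame, , 2]
  s$z <- traj$coords[frame, , 3]
  as_structure(s, label = sprintf("frame %d (t = %g ps)", frame, (frame - 1) * traj$dt))
}

#' Frame coordinates as a matrix
#' @param traj A `tail_trajectory`.
#' @param frame 1-based frame index.
#' @return n_atoms x 3 matrix.
#' @export
frame_coords <- function(traj, frame) {
  traj$coords[frame, , , drop = TRUE]
}

# -- PDB reading ------------------------------------------------------------

# Pre-scan a PDB file: locate MODEL blocks and per-model ATOM/HETATM record
# counts, and fail early (naming the line) on truncated coordinate records.
scan_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records in ", path, " (empty or not a PDB file)",
      call. = FALSE
    )
  }
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad) > 0) {
    stop("malformed ATOM record at line ", bad[1], " of ", path, call. = FALSE)
  }
  coords_txt <- substr(lines[is_atom], 31, 54)
  xyz <- suppressWarnings(matrix(
    as.numeric(c(
      substr(coords_txt, 1, 8), substr(coords_txt, 9, 16),
      substr(coords_txt, 17, 24)
    )),
    ncol = 3
  ))
  if (anyNA(xyz)) {
    bad_line <- which(is_atom)[which(rowSums(is.na(xyz)) > 0)[1]]
    stop("unreadable coordinates at line ", bad_line, " of ", path, call. = FALSE)
  }
  model_starts <- which(substr(rec, 1, 5) == "MODEL")
  if (length(model_starts) == 0) {
    counts <- sum(is_atom)
  } else {
    grp <- findInterval(which(is_atom), model_starts)
    counts <- as.integer(table(factor(grp, levels = seq_along(model_starts))))
  }
  list(n_models = max(1L, length(model_starts)), atom_counts = counts)
}

# Convert a bio3d atom table + one xyz vector into the atom-tibble contract.
bio3d_to_structure <- function(atom, xyz, label) {
  alt <- atom$alt
  bad_alt <- !(is.na(alt) | alt %in% c("", "A"))
  if (any(bad_alt)) {
    stop("unsupported altLoc '", alt[which(bad_alt)[1]],
      "' (only blank or 'A' accepted)",
      call. = FALSE
    )
  }
  elem <- atom$elesy
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", atom$elety), 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  m <- matrix(xyz, ncol = 3, byrow = TRUE)
  as_structure(
    tibble::tibble(
      name = atom$elety,
      element = elem,
      res_seq = as.integer(atom$resno),
      res_name = atom$resid,
      chain_id = ifelse(is.na(atom$chain), " ", atom$chain),
      x = m[, 1], y = m[, 2], z = m[, 3]
    ),
    label = label
  )
}

#' Read one model of a PDB file
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based MODEL index (files without MODEL records are a
#'   single model).
#' @return An atom tibble.
#' @export
read_structure <- function(path, model_index = 1) {
  info <- scan_pdb(path)
  if (model_index < 1 || model_index > info$n_models) {
    stop("model ", model_index, " not found in ", path, " (", info$n_models,
      " model(s) present)",
      call. = FALSE
    )
  }
  pdb <- bio3d::read.pdb(path, multi = info$n_models > 1, verbose = FALSE)
  xyz <- if (info$n_models > 1) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  bio3d_to_structure(pdb$atom, xyz, label = basename(path))
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Each MODEL becomes one frame; the topology is taken from the first model
#' and every model must carry the same number of atoms.
#'
#' @param path Path to a multi-MODEL PDB file.
#' @param dt Frame spacing in ps.
#' @return A `tail_trajectory`.
#' @export
read_trajectory <- function(path, dt = 25) {
  info <- scan_pdb(path)
  if (length(unique(info$atom_counts)) > 1) {
    stop("models in ", path, " are not congruent: atom counts ",
      paste(unique(info$atom_counts), collapse = ", "),
      call. = FALSE
    )
  }
  pdb <- bio3d::read.pdb(path, multi = info$n_models > 1, verbose = FALSE)
  topo <- bio3d_to_structure(
    pdb$atom,
    if (info$n_models > 1) pdb$xyz[1, ] else as.numeric(pdb$xyz),
    label = basename(path)
  )
  n_at <- nrow(topo)
  coords <- array(0, dim = c(info$n_models, n_at, 3))
  for (i in seq_len(info$n_models)) {
    m <- matrix(if (info$n_models > 1) pdb$xyz[i, ] else as.numeric(pdb$xyz),
      ncol = 3, byrow = TRUE
    )
    coords[i, , ] <- m
  }
  trajectory(topo, coords, dt = dt)
}

# -- PDB writing ------------------------------------------------------------

format_pdb_atoms <- function(s) {
  name <- ifelse(nchar(s$name) < 4, sprintf(" %-3s", s$name), s$name)
  sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(s)) %% 100000, name, s$res_name, s$chain_id, s$res_seq,
    s$x, s$y, s$z, 1, 0, s$element
  )
}

#' Write a structure to a PDB file
#' @param s An atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  s <- as_structure(s)
  writeLines(c(format_pdb_atoms(s), "END"), path)
  invisible(path)
}

#' Write a trajectory to a multi-MODEL PDB file
#' @param traj A `tail_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  blocks <- lapply(seq_len(n_frames(traj)), function(i) {
    c(
      sprintf("MODEL     %4d", i),
      format_pdb_atoms(frame_structure(traj, i)),
      "ENDMDL"
    )
  })
  writeLines(c(unlist(blocks), "END"), path)
  invisible(path)
}

# -- Tail extraction and frame arithmetic -----------------------------------

#' Extract the N-terminal tail of a chain
#'
#' Selects the first `n_residues` residues (in residue order) of one chain as
#' an independent single-chain structure -- the operation used to cut the
#' 43-residue H3 N-terminal tail out of a nucleosome core particle.
#'
#' @param s An atom tibble.
#' @param chain_id Chain to cut from.
#' @param n_residues Number of N-terminal residues to keep.
#' @return An atom tibble restricted to those residues.
#' @export
extract_tail <- function(s, chain_id = "A", n_residues = 43) {
  s <- as_structure(s)
  stopifnot(n_residues >= 1)
  ch <- s[s$chain_id == chain_id, ]
  if (nrow(ch) == 0) stop("chain '", chain_id, "' not present", call. = FALSE)
  res <- sort(unique(ch$res_seq))
  if (length(res) < n_residues) {
    stop("chain '", chain_id, "' has only ", length(res), " residues (",
      n_residues, " requested)",
      call. = FALSE
    )
  }
  keep <- res[seq_len(n_residues)]
  out <- ch[ch$res_seq %in% keep, ]
  out <- out[order(out$res_seq), ]
  as_structure(out, label = sprintf(
    "%s chain %s residues %d-%d",
    attr(s, "label") %||% "", chain_id, min(keep), max(keep)
  ))
}

#' Number of saved frames for a simulation length
#'
#' @param duration_ns Simulation length in ns.
#' @param dt_ps Coordinate saving interval in ps.
#' @return `floor(duration_ns * 1000 / dt_ps)`; e.g. a 500-ns run sampled
#'   every 25 ps yields 20000 frames.
#' @export
frame_count <- function(duration_ns, dt_ps) {
  if (!is.numeric(duration_ns) || !is.numeric(dt_ps) ||
    duration_ns <= 0 || dt_ps <= 0) {
    stop("duration and dt must be positive", call. = FALSE)
  }
  as.integer(floor(duration_ns * 1000 / dt_ps))
}
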