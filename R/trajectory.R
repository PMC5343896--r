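## Trajectory containers and structural metrics: Kabsch superposition RMSD,
## radius of gyration, per-residue RMSF, inter-helix distances, salt bridges.

#' Trajectory of atomic coordinates
#'
#' A frames x atoms x 3 coordinate block (nm) with per-atom metadata.
#'
#' @param coords numeric array, `c(n_frames, n_atoms, 3)`, nm. A single
#'   `n_atoms x 3` matrix is promoted to a one-frame trajectory.
#' @param atoms data frame with one row per atom and columns `resno` (residue
#'   number), `resname` (3-letter residue name), `atom` (atom name, e.g.
#'   `"CA"`), `chain`.
#' @param times optional per-frame times, ns.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  .assert_finite(coords, "coords")
  atoms <- as.data.frame(atoms)
  req <- c("resno", "resname", "atom", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("`atoms` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) != dim(coords)[2]) {
    stop("atom metadata rows must equal the atom count", call. = FALSE)
  }
  if (!is.null(times) && length(times) != dim(coords)[1]) {
    stop("`times` must have one entry per frame", call. = FALSE)
  }
  structure(list(coords = coords, atoms = atoms, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d atoms, residues %d-%d\n",
              d[1], d[2], min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Residue range of a helix (or any segment)
#'
#' @param label text label, e.g. `"H3"`.
#' @param from,to inclusive residue-number interval.
#' @return an object of class `helix_range`.
#' @export
helix_range <- function(label, from, to) {
  stopifnot(from <= to)
  structure(list(label = label, from = from, to = to), class = "helix_range")
}

#' Shipped helix-range conventions for the PPARgamma LBD
#'
#' Helix boundaries for the ligand-binding domain in its standard residue
#' numbering: H3 (276-306), H12 (466-477), and the 280-287 subportion of H3.
#' These are conventions, not measurements; reports that use them should echo
#' the ranges employed.
#'
#' @return a named list of [helix_range()] objects: `H3`, `H12`, `sub280_287`.
#' @export
pparg_helix_ranges <- function() {
  list(H3 = helix_range("H3", 276, 306),
       H12 = helix_range("H12", 466, 477),
       sub280_287 = helix_range("280-287", 280, 287))
}

#' Salt-bridge specification
#'
#' @param acidic_resno,acidic_resname residue number and name (`"GLU"` or
#'   `"ASP"`) of the acidic partner.
#' @param basic_resno,basic_resname residue number and name (`"ARG"` or
#'   `"LYS"`) of the basic partner.
#' @param cutoff heavy-atom distance cutoff, nm, below which the bridge
#'   counts as formed (community convention: 0.40 nm).
#' @return an object of class `salt_bridge_spec`.
#' @export
salt_bridge_spec <- function(acidic_resno, acidic_resname,
                             basic_resno, basic_resname, cutoff = 0.40) {
  acidic_resname <- toupper(acidic_resname)
  basic_resname <- toupper(basic_resname)
  if (!acidic_resname %in% c("GLU", "ASP")) {
    stop("acidic residue must be GLU or ASP", call. = FALSE)
  }
  if (!basic_resname %in% c("ARG", "LYS")) {
    stop("basic residue must be ARG or LYS", call. = FALSE)
  }
  structure(list(acidic_resno = acidic_resno, acidic_resname = acidic_resname,
                 basic_resno = basic_resno, basic_resname = basic_resname,
                 cutoff = cutoff),
            class = "salt_bridge_spec")
}

#' Per-frame metric trace
#'
#' @param values per-frame metric values.
#' @param window integer frame indices over which `mean`/`sd` were computed.
#' @return an object of class `metric_trace` with fields `values`, `mean`,
#'   `sd`, `window`.
#' @keywords internal
metric_trace <- function(values, window = seq_along(values)) {
  structure(list(values = values,
                 mean = mean(values[window]),
                 sd = stats::sd(values[window]),
                 window = window),
            class = "metric_trace")
}

#' @export
print.metric_trace <- function(x, ...) {
  cat(sprintf("<metric_trace> %d frames, mean %.4f (sd %.4f) over %d-frame window\n",
              length(x$values), x$mean, x$sd, length(x$window)))
  invisible(x)
}

## Default statistics window: drop the first 1/12 of the frames (the
## equilibration share of a 120 ns run analyzed over its last 110 ns).
.default_window <- function(n_frames) {
  start <- floor(n_frames / 12) + 1L
  seq.int(min(start, n_frames), n_frames)
}

.resolve_window <- function(window, n_frames) {
  if (is.null(window)) .default_window(n_frames) else {
    window <- as.integer(window)
    stopifnot(all(window >= 1L), all(window <= n_frames))
    window
  }
}

## selections -----------------------------------------------------------------

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.select_atoms <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(nrow(traj$atoms)))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.character(selection)) {
    if (length(selection) == 1L && selection == "backbone") {
      return(which(traj$atoms$atom %in% .BACKBONE_ATOMS))
    }
    return(which(traj$atoms$atom %in% selection))
  }
  stop("unsupported selection", call. = FALSE)
}

## superposition --------------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of one coordinate set onto another by the
#' Kabsch algorithm: both sets are centred, the rotation minimizing the
#' residual is obtained from the SVD of the covariance matrix (with the
#' reflection branch excluded), and the RMSD after the transform is reported.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm) with matched rows,
#'   or [trajectory()] objects (first frame used).
#' @param selection optional row indices (or atom-name selection for
#'   trajectories) applied to both sets; default backbone atoms for
#'   trajectories, all rows for matrices.
#' @return a list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% rotation + translation`), `rmsd` (nm) and
#'   `mobile_fitted`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  get_xy <- function(obj) {
    if (inherits(obj, "trajectory")) {
      idx <- if (is.null(selection)) .select_atoms(obj, "backbone")
             else .select_atoms(obj, selection)
      obj$coords[1, idx, , drop = TRUE]
    } else {
      m <- as.matrix(obj)
      if (!is.null(selection) && is.numeric(selection)) m[selection, , drop = FALSE]
      else m
    }
  }
  A <- get_xy(mobile); B <- get_xy(reference)
  if (!is.matrix(A)) A <- matrix(A, ncol = 3)
  if (!is.matrix(B)) B <- matrix(B, ncol = 3)
  if (nrow(A) != nrow(B)) stop("selections differ in atom count", call. = FALSE)
  .kabsch(A, B)
}

.kabsch <- function(A, B) {
  n <- nrow(A)
  if (n < 3L) stop("need at least 3 atoms for superposition", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  ## collinearity check: centred coordinates must span a plane
  sv <- svd(A0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1e-300)) {
    stop("atoms are collinear: superposition underdetermined", call. = FALSE)
  }
  H <- t(A0) %*% B0
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$u %*% diag(c(1, 1, d)) %*% t(dec$v)
  fitted <- A0 %*% R
  rmsd <- sqrt(sum((fitted - B0)^2) / n)
  list(rotation = R,
       translation = cb - as.numeric(ca %*% R),
       rmsd = rmsd,
       mobile_fitted = sweep(fitted, 2, cb, `+`))
}

#' Raw (unsuperposed) RMSD between two coordinate sets
#'
#' @param a,b `n x 3` matrices with matched rows.
#' @return `sqrt(mean(rowSums((a - b)^2)))`, nm.
#' @export
rmsd_raw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Per-frame superposed RMSD trace
#'
#' RMSD of every frame to a reference structure after optimal superposition
#' of the selected atoms.
#'
#' @param traj a [trajectory()].
#' @param reference reference coordinates: an `n x 3` matrix over the selected
#'   atoms, a frame index into `traj`, or `NULL` (first frame).
#' @param selection atom selection (default `"backbone"`: N, CA, C, O).
#' @param window frame indices for the summary statistics; default all frames
#'   after the first 1/12 of the trajectory.
#' @return a [metric_trace] of per-frame RMSD (nm).
#' @export
rmsd_trace <- function(traj, reference = NULL, selection = "backbone",
                       window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .select_atoms(traj, selection)
  if (length(idx) == 0L) stop("selection is empty", call. = FALSE)
  nf <- dim(traj$coords)[1]
  ref <- if (is.null(reference)) {
    traj$coords[1, idx, , drop = TRUE]
  } else if (is.numeric(reference) && length(reference) == 1L) {
    traj$coords[reference, idx, , drop = TRUE]
  } else {
    as.matrix(reference)
  }
  if (!is.matrix(ref)) ref <- matrix(ref, ncol = 3)
  if (nrow(ref) != length(idx)) {
    stop("reference atom count does not match the selection", call. = FALSE)
  }
  vals <- vapply(seq_len(nf), function(f) {
    .kabsch(matrix(traj$coords[f, idx, ], ncol = 3), ref)$rmsd
  }, numeric(1))
  metric_trace(vals, .resolve_window(window, nf))
}

## radius of gyration ---------------------------------------------------------

## rough atomic masses by leading element letter of the atom name
.atom_mass <- function(atom_names) {
  el <- substr(gsub("^[0-9]", "", atom_names), 1, 1)
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}: the
#' mass-weighted RMS distance of the atoms from their centre of mass.
#'
#' @param coords `n x 3` coordinate matrix, nm.
#' @param masses per-atom masses; default unit masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1L) stop("need at least one atom", call. = FALSE)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n)
  M <- sum(masses)
  if (M <= 0) stop("total mass must be positive", call. = FALSE)
  com <- colSums(coords * masses) / M
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / M)
}

#' Radius-of-gyration trace over a trajectory
#'
#' @param traj a [trajectory()].
#' @param masses per-atom masses; by default inferred from atom names
#'   (element lookup on the leading letter).
#' @param window frame indices for the summary statistics (see [rmsd_trace()]).
#' @return a [metric_trace] of per-frame Rg (nm).
#' @export
rg_trace <- function(traj, masses = NULL, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (is.null(masses)) masses <- .atom_mass(traj$atoms$atom)
  vals <- vapply(seq_len(nf), function(f) {
    radius_of_gyration(matrix(traj$coords[f, , ], ncol = 3), masses)
  }, numeric(1))
  metric_trace(vals, .resolve_window(window, nf))
}

## RMSF -----------------------------------------------------------------------

#' Per-residue root mean square fluctuation
#'
#' RMSF of the selected atom (C-alpha by default) of each residue about its
#' window-average position, after superposing every frame in the window onto
#' the window-average structure (computed iteratively: frames are first
#' aligned to the initial frame, averaged, then re-aligned to that average).
#'
#' @param traj a [trajectory()] with at least 10 frames.
#' @param selection atom name used per residue, default `"CA"`.
#' @param window frame indices entering the average; default all frames after
#'   the first 1/12 of the trajectory.
#' @return a data frame with columns `resno` and `rmsf` (nm). Residues in the
#'   trajectory that lack the selected atom appear with `rmsf = NA`.
#' @export
rmsf_per_residue <- function(traj, selection = "CA", window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (nf < 10L) stop("need at least 10 frames for RMSF", call. = FALSE)
  win <- .resolve_window(window, nf)
  idx <- .select_atoms(traj, selection)
  if (length(idx) == 0L) stop("selection is empty", call. = FALSE)

  frames <- lapply(win, function(f) matrix(traj$coords[f, idx, ], ncol = 3))
  ## align to first frame, average, re-align to the average
  ref <- frames[[1]]
  aligned <- lapply(frames, function(m) .kabsch(m, ref)$mobile_fitted)
  avg <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(frames, function(m) .kabsch(m, avg)$mobile_fitted)
  avg <- Reduce(`+`, aligned) / length(aligned)

  dev2 <- Reduce(`+`, lapply(aligned, function(m) rowSums((m - avg)^2))) /
    length(aligned)
  rmsf <- sqrt(dev2)

  all_res <- sort(unique(traj$atoms$resno))
  sel_res <- traj$atoms$resno[idx]
  out <- data.frame(resno = all_res, rmsf = NA_real_)
  out$rmsf[match(sel_res, all_res)] <- rmsf
  out
}

## inter-helix distance -------------------------------------------------------

#' Inter-helix centroid distance trace
#'
#' Per-frame Euclidean distance between the C-alpha centroids of two residue
#' ranges (or, with `method = "closest"`, the minimum C-alpha pair distance).
#'
#' @param traj a [trajectory()].
#' @param a,b [helix_range()] objects.
#' @param method `"centroid"` (default) or `"closest"`.
#' @param window frame indices for the summary statistics.
#' @return a [metric_trace] of per-frame distances (nm).
#' @export
helix_distance <- function(traj, a, b, method = c("centroid", "closest"),
                           window = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(a, "helix_range"), inherits(b, "helix_range"))
  method <- match.arg(method)
  ia <- which(traj$atoms$atom == "CA" &
                traj$atoms$resno >= a$from & traj$atoms$resno <= a$to)
  ib <- which(traj$atoms$atom == "CA" &
                traj$atoms$resno >= b$from & traj$atoms$resno <= b$to)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("helix range resolves to no C-alpha atoms", call. = FALSE)
  }
  nf <- dim(traj$coords)[1]
  vals <- vapply(seq_len(nf), function(f) {
    ca <- matrix(traj$coords[f, ia, ], ncol = 3)
    cb <- matrix(traj$coords[f, ib, ], ncol = 3)
    if (method == "centroid") {
      sqrt(sum((colMeans(ca) - colMeans(cb))^2))
    } else {
      min(sqrt(outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * ca %*% t(cb)))
    }
  }, numeric(1))
  metric_trace(vals, .resolve_window(window, nf))
}

## salt bridges ---------------------------------------------------------------

.ACID_ATOMS <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))
.BASE_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")

#' Salt-bridge distance trace and occupancy
#'
#' Tracks the per-frame minimum heavy-atom distance between the carboxylate
#' oxygens of an acidic residue (GLU: OE1/OE2; ASP: OD1/OD2) and the basic
#' nitrogen group of a basic residue (ARG: NE/NH1/NH2; LYS: NZ), and reports
#' the occupancy: the fraction of frames in the statistics window with a
#' distance below the cutoff. The raw distance trace is always returned, so
#' conclusions need not hinge on the cutoff choice.
#'
#' @param traj a [trajectory()].
#' @param spec a [salt_bridge_spec()].
#' @param window frame indices for statistics and occupancy.
#' @return a [metric_trace] of per-frame minimum distances (nm) with an extra
#'   field `occupancy` in \[0, 1\].
#' @export
salt_bridge_trace <- function(traj, spec, window = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "salt_bridge_spec"))
  find_atoms <- function(resno, resname, wanted) {
    idx <- which(traj$atoms$resno == resno & traj$atoms$atom %in% wanted)
    if (length(idx) == 0L) {
      stop(sprintf("residue %s%d lacks side-chain atoms %s", resname, resno,
                   paste(wanted, collapse = "/")), call. = FALSE)
    }
    idx
  }
  io <- find_atoms(spec$acidic_resno, spec$acidic_resname,
                   .ACID_ATOMS[[spec$acidic_resname]])
  iN <- find_atoms(spec$basic_resno, spec$basic_resname,
                   .BASE_ATOMS[[spec$basic_resname]])
  nf <- dim(traj$coords)[1]
  vals <- vapply(seq_len(nf), function(f) {
    O <- matrix(traj$coords[f, io, ], ncol = 3)
    N <- matrix(traj$coords[f, iN, ], ncol = 3)
    min(sqrt(outer(rowSums(O^2), rowSums(N^2), `+`) - 2 * O %*% t(N)))
  }, numeric(1))
  out <- metric_trace(vals, .resolve_window(window, nf))
  out$occupancy <- mean(vals[out$window] < spec$cutoff)
  out
}

## PDB I/O --------------------------------------------------------------------

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL` block becomes one frame; all models must share the same atom
#' table. Coordinates are converted from Angstrom to nm.
#'
#' @param file path to a PDB file.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  }
  atoms <- data.frame(resno = pdb$atom$resno, resname = pdb$atom$resid,
                      atom = pdb$atom$elety, chain = pdb$atom$chain,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  trajectory(coords, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory"))
  d <- dim(traj$coords)
  xyz <- matrix(NA_real_, d[1], d[2] * 3)
  for (f in seq_len(d[1])) {
    xyz[f, ] <- as.numeric(t(matrix(traj$coords[f, , ], ncol = 3))) * 10
  }
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = traj$atoms$resno, resid = traj$atoms$resname,
                   elety = traj$atoms$atom, chain = traj$atoms$chain)
  invisible(file)
}
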