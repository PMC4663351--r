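#' Build a system topology
#'
#' A topology is the static description of a peptide/bilayer/solvent system:
#' one row per atom with naming, residue and molecule bookkeeping, partial
#' charge, GROMOS-style Lennard-Jones C6/C12 parameters, the implicit-hydrogen
#' count of united atoms, hydrogen-bond donor/acceptor capability, and (for
#' hydrogens) the index of the heavy atom they are bonded to.
#'
#' Internal units throughout the package are nm, ns, kJ/mol, degrees and
#' elementary charges; angstroms appear only at I/O boundaries.
#'
#' @param atoms data.frame with columns `name`, `element`, `resid`, `resname`,
#'   `molid`, `moltype` (one of "peptide", "lipid", "solvent", "ion"),
#'   `charge` (e), `c6` (kJ mol^-1 nm^6), `c12` (kJ mol^-1 nm^12), `nh`
#'   (implicit hydrogens of a united atom), `donor`, `acceptor` (logical),
#'   `bond_to` (integer atom index of the bonded heavy atom, `NA` for heavy
#'   atoms).
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms) {
  required <- c("name", "element", "resid", "resname", "molid", "moltype",
                "charge", "c6", "c12", "nh", "donor", "acceptor", "bond_to")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("topology atoms table lacks columns: ", paste(missing, collapse = ", "))
  atoms <- as.data.frame(atoms)[, required]
  rownames(atoms) <- NULL
  if (!all(is.finite(atoms$charge)))
    stop("non-finite partial charge in topology")
  if (any(atoms$c6 < 0) || any(atoms$c12 < 0))
    stop("LJ C6/C12 parameters must be >= 0")
  bad <- !atoms$moltype %in% c("peptide", "lipid", "solvent", "ion")
  if (any(bad))
    stop("unknown moltype: ", paste(unique(atoms$moltype[bad]), collapse = ", "))
  structure(list(atoms = atoms, natoms = nrow(atoms)), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d molecules\n",
              x$natoms,
              length(unique(paste(x$atoms$molid, x$atoms$resid))),
              length(unique(x$atoms$molid))))
  cat("  moltypes:",
      paste(sprintf("%s=%d", names(table(x$atoms$moltype)),
                    table(x$atoms$moltype)), collapse = " "), "\n")
  invisible(x)
}

#' A single coordinate frame
#'
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box orthorhombic box lengths `c(Lx, Ly, Lz)` in nm.
#' @param time frame time in ns.
#' @return An object of class `"frame"`.
#' @export
make_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have three columns")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive orthorhombic lengths (nm)")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("frame: %d atoms, box %.3f x %.3f x %.3f nm, t = %g ns\n",
              nrow(x$xyz), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' A time-ordered trajectory
#'
#' @param top the `topology` the frames belong to.
#' @param frames list of `frame` objects with strictly increasing times and
#'   atom counts matching `top`.
#' @param stride nominal frame spacing in ns (informational).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(top, frames, stride = NULL) {
  stopifnot(inherits(top, "topology"))
  if (!length(frames)) stop("empty trajectory")
  for (fr in frames) {
    if (!inherits(fr, "frame")) stop("frames must be frame objects")
    if (nrow(fr$xyz) != top$natoms)
      stop(sprintf("frame has %d atoms but topology has %d",
                   nrow(fr$xyz), top$natoms))
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  if (is.null(stride))
    stride <- if (length(times) > 1) times[2] - times[1] else 1
  structure(list(top = top, frames = frames, stride = stride),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  times <- frame_times(x)
  cat(sprintf("trajectory: %d frames, t = %g..%g ns, %d atoms\n",
              length(x$frames), min(times), max(times), x$top$natoms))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Frame times of a trajectory
#' @param traj a `trajectory`.
#' @return numeric vector of times (ns).
#' @export
frame_times <- function(traj) {
  vapply(traj$frames, `[[`, numeric(1), "time")
}

#' An ordered group of atoms
#'
#' @param top the `topology` the indices refer to.
#' @param indices integer atom indices (1-based, ordered, no duplicates).
#' @param label short label used in outputs.
#' @return An object of class `"atom_group"`: an integer vector with
#'   attributes `label` and `natoms` (of the parent topology).
#' @export
atom_group <- function(top, indices, label = "") {
  stopifnot(inherits(top, "topology"))
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 1) || any(indices > top$natoms))
    stop("atom indices out of range")
  if (anyDuplicated(indices)) stop("duplicate atom indices in group")
  structure(indices, label = label, natoms = top$natoms,
            class = "atom_group")
}

#' @export
print.atom_group <- function(x, ...) {
  cat(sprintf("atom_group '%s': %d atoms\n", attr(x, "label"), length(x)))
  invisible(x)
}

group_label <- function(g) {
  lb <- attr(g, "label")
  if (is.null(lb) || !nzchar(lb)) "group" else lb
}

# Atomic numbers of the elements the package meets; united atoms add `nh`
# electrons on top of these.
.element_z <- c(H = 1, C = 6, N = 7, O = 8, NA. = 11, P = 15, S = 16,
                CL = 17, K = 19)

#' Electron count per atom
#'
#' Electrons are counted as the atomic number of the heavy element plus one
#' per implicit hydrogen, the standard united-atom convention (CH2 carries 8,
#' CH3 carries 9).
#'
#' @param top a `topology`.
#' @param indices atom indices (default all).
#' @return numeric vector of electron counts.
#' @export
electron_counts <- function(top, indices = seq_len(top$natoms)) {
  el <- toupper(top$atoms$element[indices])
  el[el == "NA"] <- "NA."
  z <- .element_z[el]
  if (anyNA(z))
    stop("no electron count for element(s): ",
         paste(unique(el[is.na(z)]), collapse = ", "))
  unname(z + top$atoms$nh[indices])
}

#' Merge two systems into one topology and frame
#'
#' Atom and molecule indices of `b` are shifted past those of `a`; residue
#' numbering is per molecule and stays as-is (so a peptide keeps residues
#' 1..n when merged onto a bilayer). The box of `a` is kept.
#'
#' @param top_a,frame_a first system.
#' @param top_b,frame_b second system.
#' @return list with elements `top` and `frame`.
#' @export
merge_systems <- function(top_a, frame_a, top_b, frame_b) {
  at_a <- top_a$atoms
  at_b <- top_b$atoms
  at_b$molid <- at_b$molid + max(at_a$molid)
  at_b$bond_to <- at_b$bond_to + nrow(at_a)
  top <- topology(rbind(at_a, at_b))
  fr <- make_frame(rbind(frame_a$xyz, frame_b$xyz), frame_a$box,
                   frame_a$time)
  list(top = top, frame = fr)
}
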