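#' Read an atom-parameter sidecar
#'
#' The sidecar is a YAML file that supplies, per (residue name, atom name),
#' everything a coordinate file cannot: element (or united-atom class),
#' partial charge (e), GROMOS-style LJ parameters C6 (kJ mol^-1 nm^6) and C12
#' (kJ mol^-1 nm^12), the implicit-hydrogen count of united atoms, and
#' hydrogen-bond donor/acceptor capability. A top-level `moltypes` map assigns
#' each residue name to one of peptide/lipid/solvent/ion.
#'
#' ```yaml
#' moltypes: {LYS: peptide, POPC: lipid, SOL: solvent, NA: ion}
#' atoms:
#'   POPC:
#'     P: {element: P, charge: -1.0, c6: 0.0, c12: 0.0, nh: 0,
#'         donor: false, acceptor: true}
#' ```
#'
#' @param path sidecar file path.
#' @return list with `moltypes` (named character) and `atoms` (nested list).
#' @export
read_sidecar <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$atoms) || is.null(doc$moltypes))
    stop("sidecar must contain 'moltypes' and 'atoms' sections")
  doc$moltypes <- unlist(doc$moltypes)
  doc
}

sidecar_lookup <- function(sidecar, resname, name) {
  rec <- sidecar$atoms[[resname]][[name]]
  if (is.null(rec))
    stop(sprintf("atom '%s' of residue '%s' not found in parameter sidecar",
                 name, resname))
  rec
}

# Assemble the topology atom table from parsed (name, resname, resid) columns
# plus the sidecar. Molecules: consecutive peptide residues form one molecule;
# every lipid/solvent/ion residue is its own molecule.
build_topology <- function(name, resname, resid, sidecar, xyz) {
  n <- length(name)
  moltype <- unname(sidecar$moltypes[resname])
  if (anyNA(moltype)) {
    bad <- unique(resname[is.na(moltype)])
    stop("residue name(s) absent from sidecar moltypes: ",
         paste(bad, collapse = ", "))
  }
  recs <- mapply(function(rn, an) sidecar_lookup(sidecar, rn, an),
                 resname, name, SIMPLIFY = FALSE)
  getf <- function(field, default) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else as.numeric(v)
    }, numeric(1))
  }
  getl <- function(field) {
    vapply(recs, function(r) isTRUE(r[[field]]), logical(1))
  }
  element <- vapply(recs, function(r) as.character(r$element), character(1))

  # molecule ids: break on residue change; merge consecutive peptide residues
  res_break <- c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n])
  res_run <- cumsum(res_break)
  first_of_run <- !duplicated(res_run)
  run_type <- moltype[first_of_run]
  new_mol <- rep(TRUE, max(res_run))
  if (max(res_run) > 1)
    new_mol[-1] <- !(run_type[-1] == "peptide" &
                     run_type[-length(run_type)] == "peptide")
  molid <- cumsum(new_mol)[res_run]

  at <- data.frame(
    name = name, element = element, resid = resid, resname = resname,
    molid = molid, moltype = moltype,
    charge = getf("charge", 0), c6 = getf("c6", 0), c12 = getf("c12", 0),
    nh = getf("nh", 0),
    donor = getl("donor"), acceptor = getl("acceptor"),
    bond_to = NA_integer_, stringsAsFactors = FALSE
  )
  at$bond_to <- infer_h_bonds(at, xyz)
  topology(at)
}

# Attach each explicit hydrogen to the nearest heavy atom of its residue
# (covalent H-X bonds are ~0.1 nm; 0.12 nm is a safe cap).
infer_h_bonds <- function(at, xyz, max_bond = 0.12) {
  bond_to <- rep(NA_integer_, nrow(at))
  h_idx <- which(toupper(at$element) == "H")
  for (i in h_idx) {
    cand <- which(at$resid == at$resid[i] & at$molid == at$molid[i] &
                  toupper(at$element) != "H")
    if (!length(cand)) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
    j <- which.min(d)
    if (d[j] <= max_bond) bond_to[i] <- cand[j]
  }
  bond_to
}

# Box lengths (angstrom) from a PDB CRYST1 record; orthorhombic only.
pdb_cryst1_box <- function(path) {
  ln <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(ln)) stop("PDB lacks a CRYST1 box record")
  ln <- ln[1]
  abc <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                      substr(ln, 25, 33)))
  ang <- as.numeric(c(substr(ln, 34, 40), substr(ln, 41, 47),
                      substr(ln, 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("triclinic box rejected: only orthorhombic boxes are supported")
  abc
}

parse_gro_block <- function(lines) {
  title <- lines[1]
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3) stop("truncated GRO block")
  al <- lines[3:(n + 2)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  xyz <- cbind(as.numeric(substr(al, 21, 28)),
               as.numeric(substr(al, 29, 36)),
               as.numeric(substr(al, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])
  if (length(box) > 3 && any(box[4:length(box)] != 0))
    stop("triclinic box rejected: only orthorhombic boxes are supported")
  box <- box[1:3]
  time <- NA_real_
  m <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
  if (length(m) == 2) time <- as.numeric(m[2])
  list(title = title, n = n, resid = resid, resname = resname,
       name = name, xyz = xyz, box = box, time = time)
}

#' Load a structure file with its parameter sidecar
#'
#' Reads a GRO (nm) or PDB (angstrom, converted to nm on load) structure and
#' joins it with [read_sidecar()] parameters to produce a full topology and
#' one coordinate frame. Atom order is preserved from the file. An atom whose
#' (residue name, atom name) pair is missing from the sidecar is an error
#' naming the atom.
#'
#' @param path structure file (`.gro` or `.pdb`).
#' @param params_path parameter sidecar path (YAML, see [read_sidecar()]).
#' @return list with `top` (topology) and `frame` (frame).
#' @export
load_structure <- function(path, params_path) {
  sidecar <- read_sidecar(params_path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    b <- parse_gro_block(readLines(path))
    top <- build_topology(b$name, b$resname, b$resid, sidecar, b$xyz)
    fr <- make_frame(b$xyz, b$box, if (is.na(b$time)) 0 else b$time)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    xyz <- cbind(a$x, a$y, a$z) / 10  # angstrom -> nm
    box <- pdb_cryst1_box(path)
    top <- build_topology(a$elety, a$resid, a$resno, sidecar, xyz)
    fr <- make_frame(xyz, box / 10, 0)
  } else stop("unsupported structure format: .", ext)
  list(top = top, frame = fr)
}

#' Load a trajectory
#'
#' Multi-frame GRO (concatenated blocks, frame time in the title as `t= <ns>`)
#' or multi-model PDB. Frame atom counts must match the topology; times must
#' be strictly increasing (frames without a time stamp are numbered 0, 1, ...
#' ns).
#'
#' @param path trajectory file (`.gro` or `.pdb`).
#' @param top the `topology` the frames belong to.
#' @return a `trajectory`.
#' @export
load_trajectory <- function(path, top) {
  ext <- tolower(tools::file_ext(path))
  frames <- list()
  if (ext == "gro") {
    lines <- readLines(path)
    pos <- 1L
    while (pos <= length(lines)) {
      if (!nzchar(trimws(lines[pos])) ) { pos <- pos + 1L; next }
      n <- as.integer(trimws(lines[pos + 1]))
      b <- parse_gro_block(lines[pos:(pos + n + 2)])
      if (b$n != top$natoms)
        stop(sprintf("frame has %d atoms but topology has %d", b$n, top$natoms))
      t <- if (is.na(b$time)) length(frames) else b$time
      frames[[length(frames) + 1]] <- make_frame(b$xyz, b$box, t)
      pos <- pos + n + 3L
    }
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    nmodels <- nrow(pdb$xyz)
    box <- pdb_cryst1_box(path)
    for (i in seq_len(nmodels)) {
      xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
      if (nrow(xyz) != top$natoms)
        stop(sprintf("frame has %d atoms but topology has %d",
                     nrow(xyz), top$natoms))
      frames[[i]] <- make_frame(xyz, box / 10, i - 1)
    }
  } else stop("unsupported trajectory format: .", ext)
  if (!length(frames)) stop("empty trajectory")
  trajectory(top, frames)
}

#' Write frames as (multi-frame) GRO
#'
#' Coordinates are written in nm with three decimals, the GRO file precision.
#' Frame times go into the title line as `t= <ns>`.
#'
#' @param path output path.
#' @param top topology providing naming.
#' @param frames a single `frame`, a list of frames, or a `trajectory`.
#' @param title title prefix.
#' @export
write_gro <- function(path, top, frames, title = "bilayerbind system") {
  if (inherits(frames, "trajectory")) frames <- frames$frames
  if (inherits(frames, "frame")) frames <- list(frames)
  at <- top$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(sprintf("%s t= %.6f", title, fr$time), con)
    writeLines(sprintf("%5d", top$natoms), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resid %% 100000, substr(at$resname, 1, 5),
                     substr(at$name, 1, 5), seq_len(top$natoms) %% 100000,
                     fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]),
               con)
  }
  invisible(path)
}

#' Read a lipid chemical-group map
#'
#' YAML mapping group label to the atom names that form it, e.g.
#' `phosphate: [P]`, `ester: [EST1, EST2]`. Returns one `atom_group` per
#' label, restricted to lipid atoms.
#'
#' @param path YAML file path.
#' @param top a `topology`.
#' @return named list of `atom_group`s.
#' @export
read_group_map <- function(path, top) {
  doc <- yaml::read_yaml(path)
  out <- lapply(names(doc), function(lb) {
    select_atoms(top, paste("lipid and name",
                            paste(doc[[lb]], collapse = " ")), label = lb)
  })
  names(out) <- names(doc)
  out
}

#' Write an analysis table as CSV
#'
#' Column names carry their units (e.g. `time_ns`, `elec_kJ_mol`); the single
#' header line is the unit documentation.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_analysis_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
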