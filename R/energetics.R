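#' Nonbonded interaction settings
#'
#' Plain-cutoff Coulomb and Lennard-Jones (no Ewald reciprocal term, no
#' reaction field, no dispersion correction): interaction energies computed
#' here are meant for sign and ranking analyses of peptide-lipid binding, not
#' for reproducing an MD engine's absolute energies.
#'
#' @param coulomb_cutoff Coulomb cutoff (nm, default 1.2).
#' @param lj_cutoff Lennard-Jones cutoff (nm, default 1.4).
#' @param prefactor Coulomb prefactor in kJ mol^-1 nm e^-2 (default
#'   138.935458, i.e. 1/(4 pi eps0) in MD units).
#' @return object of class `"nb_settings"`.
#' @export
nb_settings <- function(coulomb_cutoff = 1.2, lj_cutoff = 1.4,
                        prefactor = 138.935458) {
  if (coulomb_cutoff <= 0 || lj_cutoff <= 0) stop("cutoffs must be positive")
  structure(list(coulomb_cutoff = coulomb_cutoff, lj_cutoff = lj_cutoff,
                 prefactor = prefactor), class = "nb_settings")
}

#' Coulomb pair energy
#'
#' `prefactor * q1 * q2 / r` for `r` below the Coulomb cutoff, exactly zero
#' beyond it.
#'
#' @param r distance(s) in nm (> 0).
#' @param q1,q2 charges in e.
#' @param settings an [nb_settings()].
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
coulomb_pair <- function(r, q1, q2, settings = nb_settings()) {
  if (any(r <= 0)) stop("r must be positive")
  ifelse(r < settings$coulomb_cutoff, settings$prefactor * q1 * q2 / r, 0)
}

#' Lennard-Jones pair energy (C6/C12 form)
#'
#' `c12 / r^12 - c6 / r^6` for `r` below the LJ cutoff, exactly zero beyond
#' it. The C6/C12 parameterisation follows the GROMOS/Berger convention.
#'
#' @param r distance(s) in nm (> 0).
#' @param c6 dispersion coefficient (kJ mol^-1 nm^6).
#' @param c12 repulsion coefficient (kJ mol^-1 nm^12).
#' @param settings an [nb_settings()].
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
lj_pair <- function(r, c6, c12, settings = nb_settings()) {
  if (any(r <= 0)) stop("r must be positive")
  ifelse(r < settings$lj_cutoff, c12 / r^12 - c6 / r^6, 0)
}

#' Cross-group nonbonded interaction energy
#'
#' Sums Coulomb and Lennard-Jones pair energies over all cross pairs of two
#' disjoint groups under minimum-image distances. For pairwise-additive
#' cutoff potentials this equals the total-energy difference
#' U(A+B) - U(A) - U(B), the standard group interaction energy. Cross-pair
#' C6/C12 use geometric-mean combination of the per-atom parameters.
#'
#' @param frame a `frame`.
#' @param group_a,group_b disjoint `atom_group`s.
#' @param top the `topology`.
#' @param settings an [nb_settings()].
#' @return list of class `"energy_decomposition"` with `electrostatic`, `vdw`
#'   and `total` (kJ/mol) and `normalization` ("raw").
#' @export
group_interaction <- function(frame, group_a, group_b, top,
                              settings = nb_settings()) {
  ia <- as.integer(group_a); ib <- as.integer(group_b)
  if (length(intersect(ia, ib))) stop("groups overlap")
  at <- top$atoms
  d <- pair_dist(frame$xyz[ia, , drop = FALSE],
                 frame$xyz[ib, , drop = FALSE], frame$box)
  if (any(d == 0)) stop("coincident atoms across groups (r = 0)")
  qq <- outer(at$charge[ia], at$charge[ib])
  elec <- sum(ifelse(d < settings$coulomb_cutoff,
                     settings$prefactor * qq / d, 0))
  c6 <- outer(sqrt(at$c6[ia]), sqrt(at$c6[ib]))
  c12 <- outer(sqrt(at$c12[ia]), sqrt(at$c12[ib]))
  vdw <- sum(ifelse(d < settings$lj_cutoff, c12 / d^12 - c6 / d^6, 0))
  structure(list(electrostatic = elec, vdw = vdw, total = elec + vdw,
                 normalization = "raw"), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("interaction energy (%s): elec %.4f, vdW %.4f, total %.4f kJ/mol\n",
              x$normalization, x$electrostatic, x$vdw, x$total))
  invisible(x)
}

#' Interaction-energy time series
#'
#' Per-frame electrostatic/van der Waals decomposition of the interaction
#' between two selections, optionally normalized per lipid (divided by the
#' number of lipid molecules in the lipid selection).
#'
#' @param traj a `trajectory`.
#' @param peptide `atom_group` (or any first group).
#' @param lipids `atom_group` of lipid atoms.
#' @param settings an [nb_settings()].
#' @param normalization "raw" or "per_lipid".
#' @return data.frame with `time_ns`, `elec_kJ_mol`, `vdw_kJ_mol`,
#'   `total_kJ_mol`.
#' @export
interaction_timeseries <- function(traj, peptide, lipids,
                                   settings = nb_settings(),
                                   normalization = c("raw", "per_lipid")) {
  normalization <- match.arg(normalization)
  top <- traj$top
  scale <- 1
  if (normalization == "per_lipid") {
    il <- as.integer(lipids)
    nlip <- length(unique(top$atoms$molid[il][top$atoms$moltype[il] == "lipid"]))
    if (nlip == 0) stop("per-lipid normalization with zero lipids")
    scale <- 1 / nlip
  }
  rows <- lapply(traj$frames, function(fr) {
    e <- group_interaction(fr, peptide, lipids, top, settings)
    data.frame(time_ns = fr$time,
               elec_kJ_mol = e$electrostatic * scale,
               vdw_kJ_mol = e$vdw * scale,
               total_kJ_mol = e$total * scale)
  })
  do.call(rbind, rows)
}
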