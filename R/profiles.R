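# Bilayer-level observables: electron density, S_CD, thickness, area per lipid.

#' Electron density profile along the membrane normal
#'
#' Atoms of the group are binned by z relative to the per-frame bilayer
#' center (midplane between the two phosphorus planes, z = 0); each atom
#' contributes its electron count (atomic number plus implicit hydrogens).
#' Density is electrons per bin volume, averaged over frames. The profile
#' integrates to the total electron count of the group.
#'
#' @param traj a `trajectory`.
#' @param group `atom_group` to profile (non-empty).
#' @param phosphorus `atom_group` of lipid phosphorus atoms (defines z = 0).
#' @param bin_width bin width in nm (default 0.05, fixed grid for determinism
#'   across box fluctuations).
#' @return data.frame with `z_nm` (bin centers), `density_e_nm3`; attributes
#'   `bin_width` and `label`.
#' @export
electron_density <- function(traj, group, phosphorus, bin_width = 0.05) {
  if (!length(group)) stop("empty group")
  if (bin_width <= 0) stop("bin width must be positive")
  top <- traj$top
  electrons <- electron_counts(top, as.integer(group))
  zmax <- max(vapply(traj$frames, function(fr) fr$box[3], numeric(1))) / 2
  K <- ceiling(zmax / bin_width) + 1
  breaks <- seq(-K * bin_width, K * bin_width, by = bin_width)
  dens <- numeric(length(breaks) - 1)
  for (fr in traj$frames) {
    ref <- bilayer_reference(fr, phosphorus, phosphorus, top)
    z <- fr$xyz[as.integer(group), 3] - ref$midplane
    z <- z - fr$box[3] * ceiling(z / fr$box[3] - 0.5)
    bin <- findInterval(z, breaks, left.open = TRUE)
    counts <- vapply(seq_along(dens),
                     function(b) sum(electrons[bin == b]), numeric(1))
    dens <- dens + counts / (fr$box[1] * fr$box[2] * bin_width)
  }
  dens <- dens / length(traj$frames)
  out <- data.frame(z_nm = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    density_e_nm3 = dens)
  attr(out, "bin_width") <- bin_width
  attr(out, "label") <- group_label(group)
  out
}

#' Acyl-chain atom indices per lipid
#'
#' Collects, per lipid molecule, the ordered tail carbon atoms whose names
#' are `prefix` followed by a number (e.g. C1, C2, ...).
#'
#' @param top a `topology`.
#' @param prefix tail-carbon name prefix (default "C").
#' @return list of integer vectors, one per lipid, ordered along the chain.
#' @export
acyl_chains <- function(top, prefix = "C") {
  at <- top$atoms
  pat <- paste0("^", prefix, "[0-9]+$")
  idx <- which(at$moltype == "lipid" & grepl(pat, at$name))
  if (!length(idx)) stop("no tail carbons matching '", pat, "' found")
  split_by <- at$molid[idx]
  chains <- split(idx, split_by)
  lapply(chains, function(ch) {
    ch[order(as.integer(sub(paste0("^", prefix), "", at$name[ch])))]
  })
}

# Tetrahedral reconstruction of the two methylene C-H unit vectors of carbon
# r0 from its chain neighbours rm (i-1) and rp (i+1). Returns a 2x3 matrix,
# or NULL for degenerate (collinear) geometry.
ch_vectors_tetrahedral <- function(rm, r0, rp, box) {
  b1 <- wrap_disp(rm - r0, box); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- wrap_disp(rp - r0, box); b2 <- b2 / sqrt(sum(b2^2))
  u <- -(b1 + b2)
  v <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-10 || nv < 1e-10) return(NULL)
  u <- u / nu; v <- v / nv
  half <- 54.7356103 * pi / 180  # half the tetrahedral H-C-H angle
  rbind(cos(half) * u + sin(half) * v,
        cos(half) * u - sin(half) * v)
}

#' Acyl-chain order parameter S_CD
#'
#' S_CD = 0.5 <3 cos^2 theta - 1>, with theta the angle between each C-H bond
#' vector and the bilayer normal (z), averaged over the C-H vectors of the
#' carbon, over lipids and over frames. For united-atom chains the two
#' methylene hydrogens are reconstructed assuming ideal tetrahedral geometry
#' from the two chain neighbours; terminal carbons, which lack both
#' neighbours, are reported absent (not zero). Explicit-hydrogen mode uses the
#' hydrogens bonded to each carbon instead.
#'
#' @param traj a `trajectory`.
#' @param chains list of ordered tail-carbon atom index vectors, one per
#'   lipid (see [acyl_chains()]); each chain needs >= 3 carbons for
#'   reconstruction.
#' @param hydrogens "reconstructed" or "explicit".
#' @param peptide optional `atom_group`; with `near_cutoff`, restricts the
#'   average to lipids whose minimum heavy-atom distance to any peptide
#'   non-hydrogen atom is below the cutoff (nm) in that frame.
#' @param near_cutoff lipid-inclusion cutoff in nm (default `NULL`: all
#'   lipids).
#' @return data.frame with `carbon` (position along the chain), `scd`,
#'   `n_samples`.
#' @export
order_parameter <- function(traj, chains,
                            hydrogens = c("reconstructed", "explicit"),
                            peptide = NULL, near_cutoff = NULL) {
  hydrogens <- match.arg(hydrogens)
  if (any(vapply(chains, length, integer(1)) < 3) &&
      hydrogens == "reconstructed")
    stop("reconstruction needs chains of at least 3 carbons")
  top <- traj$top
  el <- toupper(top$atoms$element)
  ncarb <- max(vapply(chains, length, integer(1)))
  s_sum <- numeric(ncarb)
  s_n <- integer(ncarb)
  pep_heavy <- if (!is.null(peptide))
    as.integer(peptide)[el[as.integer(peptide)] != "H"] else NULL
  for (fr in traj$frames) {
    use <- rep(TRUE, length(chains))
    if (!is.null(near_cutoff) && !is.null(pep_heavy)) {
      use <- vapply(chains, function(ch) {
        molid <- top$atoms$molid[ch[1]]
        lat <- which(top$atoms$molid == molid & el != "H")
        d <- pair_dist(fr$xyz[lat, , drop = FALSE],
                       fr$xyz[pep_heavy, , drop = FALSE], fr$box)
        min(d) < near_cutoff
      }, logical(1))
    }
    for (ch in chains[use]) {
      n <- length(ch)
      for (j in seq_len(n)) {
        hvecs <- NULL
        if (hydrogens == "explicit") {
          hs <- which(!is.na(top$atoms$bond_to) &
                      top$atoms$bond_to == ch[j] & el == "H")
          if (length(hs)) {
            hvecs <- wrap_disp(fr$xyz[hs, , drop = FALSE] -
                               matrix(fr$xyz[ch[j], ], length(hs), 3,
                                      byrow = TRUE), fr$box)
            hvecs <- hvecs / sqrt(rowSums(hvecs^2))
          }
        } else if (j > 1 && j < n) {
          hvecs <- ch_vectors_tetrahedral(fr$xyz[ch[j - 1], ],
                                          fr$xyz[ch[j], ],
                                          fr$xyz[ch[j + 1], ], fr$box)
        }
        if (is.null(hvecs)) next
        cz2 <- hvecs[, 3]^2
        s_sum[j] <- s_sum[j] + sum(0.5 * (3 * cz2 - 1))
        s_n[j] <- s_n[j] + nrow(hvecs)
      }
    }
  }
  present <- s_n > 0
  data.frame(carbon = which(present), scd = s_sum[present] / s_n[present],
             n_samples = s_n[present])
}

#' Closed-form S_CD of an ideal tilted all-trans chain
#'
#' For an ideal all-trans zigzag chain every C-H vector is perpendicular to
#' the chain axis, so a chain tilted by `tilt` from the membrane normal with
#' uniformly distributed azimuth has S_CD = 0.5 (3 sin^2(tilt) / 2 - 1).
#'
#' @param tilt chain tilt from the bilayer normal, degrees.
#' @return S_CD value.
#' @export
scd_ideal_chain <- function(tilt) {
  0.5 * (3 * sin(tilt * pi / 180)^2 / 2 - 1)
}

#' Phosphorus-to-phosphorus membrane thickness
#'
#' Mean z of the upper-leaflet phosphorus atoms minus that of the lower
#' leaflet, averaged over frames. With `cutoff`, only lipids whose minimum
#' lateral (xy, minimum-image) heavy-atom distance to any peptide
#' non-hydrogen atom is below the cutoff are included (local thickness of the
#' membrane column under the peptide); a 3D distance would empty the distal
#' leaflet at small cutoffs for any surface-bound peptide. Leaflet membership
#' always comes from the full bilayer.
#'
#' @param traj a `trajectory`.
#' @param phosphorus `atom_group` of lipid phosphorus atoms.
#' @param peptide optional `atom_group` (required with `cutoff`).
#' @param cutoff lipid-inclusion cutoff in nm, or `NULL` for all lipids.
#' @return list of class `"thickness_result"`: `thickness_nm`, `cutoff_nm`
#'   (NA when global), `lipid_count` (mean included lipids per frame).
#' @export
membrane_thickness <- function(traj, phosphorus, peptide = NULL,
                               cutoff = NULL) {
  top <- traj$top
  el <- toupper(top$atoms$element)
  if (!is.null(cutoff) && is.null(peptide))
    stop("local thickness needs a peptide group")
  pep_heavy <- if (!is.null(peptide))
    as.integer(peptide)[el[as.integer(peptide)] != "H"] else NULL
  th <- numeric(length(traj$frames))
  nlip <- numeric(length(traj$frames))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    ref <- bilayer_reference(fr, phosphorus,
                             if (is.null(peptide)) phosphorus else peptide,
                             top)
    idx <- as.integer(phosphorus)
    keep <- rep(TRUE, length(idx))
    if (!is.null(cutoff)) {
      flat <- fr$xyz; flat[, 3] <- 0  # lateral distances only
      keep <- vapply(idx, function(p) {
        molid <- top$atoms$molid[p]
        lat <- which(top$atoms$molid == molid & el != "H")
        d <- pair_dist(flat[lat, , drop = FALSE],
                       flat[pep_heavy, , drop = FALSE], fr$box)
        min(d) < cutoff
      }, logical(1))
    }
    leaf <- ref$leaflet[as.character(top$atoms$molid[idx])]
    z <- unwrap_z(fr$xyz[idx, 3], fr$box[3], ref$midplane)
    up <- keep & leaf == "upper"
    lo <- keep & leaf == "lower"
    if (!any(up) || !any(lo))
      stop("a leaflet has no lipids within the cutoff; use a larger cutoff")
    th[f] <- mean(z[up]) - mean(z[lo])
    nlip[f] <- sum(keep)
  }
  structure(list(thickness_nm = mean(th),
                 cutoff_nm = if (is.null(cutoff)) NA_real_ else cutoff,
                 lipid_count = mean(nlip)),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("P-P thickness: %.4f nm (%s, %.1f lipids)\n", x$thickness_nm,
              if (is.na(x$cutoff_nm)) "global"
              else sprintf("cutoff %.2f nm", x$cutoff_nm), x$lipid_count))
  invisible(x)
}

#' Area per lipid
#'
#' Time average of the lateral box area divided by the number of lipids per
#' leaflet.
#'
#' @param traj a `trajectory`.
#' @param lipids_per_leaflet lipid count of one leaflet (> 0).
#' @return area per lipid in nm^2.
#' @export
area_per_lipid <- function(traj, lipids_per_leaflet) {
  if (lipids_per_leaflet <= 0) stop("lipids_per_leaflet must be positive")
  mean(vapply(traj$frames, function(fr) fr$box[1] * fr$box[2], numeric(1))) /
    lipids_per_leaflet
}
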