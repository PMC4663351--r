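# Helix-axis fitting, rotational phase, and the four-class binding
# orientation (Fa/Fb/Fc/Fd) of a membrane-bound amphipathic helix.

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(a[1]^2 * C + c,       a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c,       a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c),
         3, 3, byrow = TRUE)
}

# Azimuth (degrees in [0, 360)) of vector v about `axis`, measured from the
# downward reference (-z projected off the axis), increasing by right-hand
# rule about the axis.
axis_azimuth <- function(v, axis) {
  dref <- c(0, 0, -1) - sum(c(0, 0, -1) * axis) * axis
  nd <- sqrt(sum(dref^2))
  if (nd < 1e-8) stop("helix axis is (nearly) vertical: azimuth undefined")
  dref <- dref / nd
  w <- c(axis[2] * dref[3] - axis[3] * dref[2],
         axis[3] * dref[1] - axis[1] * dref[3],
         axis[1] * dref[2] - axis[2] * dref[1])
  vperp <- v - sum(v * axis) * axis
  (atan2(sum(vperp * w), sum(vperp * dref)) * 180 / pi) %% 360
}

#' Fit the helix axis of the core helical region
#'
#' Least-squares line through the C-alpha atoms of the chosen residue range
#' (default the core helix, residues 8-19); the axis sign points from lower
#' to higher residue index. Also records, for each residue in the range, the
#' azimuth of its side-chain centroid about the axis (measured from the
#' downward direction, right-hand rule).
#'
#' @param frame a `frame`.
#' @param peptide `atom_group` of the peptide.
#' @param top the `topology`.
#' @param residue_range residues used for the fit (default 8:19; >= 4
#'   C-alphas required).
#' @return object of class `"helix_frame"`: list with `axis` (unit vector),
#'   `point` (nm), `residue_range`, and `azimuth` (named numeric, degrees,
#'   per residue in range).
#' @export
fit_helix_axis <- function(frame, peptide, top, residue_range = 8:19) {
  at <- top$atoms
  idx <- as.integer(peptide)
  # sequential unwrap along the chain: each atom is placed by minimum image
  # relative to its predecessor, so molecules longer than half the box stay
  # contiguous (an anchor-based unwrap would fold them)
  xyz_all <- unwrap_chain(frame, idx)
  ca_rows <- which(at$name[idx] == "CA" & at$resid[idx] %in% residue_range)
  if (length(ca_rows) < 4)
    stop("need at least 4 C-alpha atoms to fit a helix axis")
  ca_rows <- ca_rows[order(at$resid[idx][ca_rows])]
  xyz <- xyz_all[ca_rows, , drop = FALSE]

  # Axis estimate from cross products of bond-vector differences: on a
  # regular helix the differences d_i point radially, so every d_i x d_j
  # (sign-aligned) points along the axis -- exact for ideal helices of any
  # turn count, where a principal-component line is biased by the phase
  # distribution of the C-alphas.
  d <- diff(diff(xyz))
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  a_adj <- c(0, 0, 0)
  for (i in seq_len(nrow(d) - 1))
    a_adj <- a_adj + cross3(d[i, ], d[i + 1, ])
  axis <- c(0, 0, 0)
  for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
    cij <- cross3(d[i, ], d[j, ])
    axis <- axis + sign(sum(cij * a_adj)) * cij
  }
  na <- sqrt(sum(axis^2))
  if (na < 1e-10) {
    # degenerate (near-collinear) geometry: least-squares line fallback
    sv <- svd(sweep(xyz, 2, colMeans(xyz)))
    axis <- sv$v[, 1]
  } else axis <- axis / na

  circle_ctr <- function(axis) {
    e1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(axis, e1)
    ctr0 <- colMeans(xyz)
    rel <- sweep(xyz, 2, ctr0)
    uv <- cbind(rel %*% e1, rel %*% e2)
    A <- cbind(2 * uv[, 1], 2 * uv[, 2], 1)
    cc <- tryCatch(qr.solve(A, rowSums(uv^2)),
                   error = function(e) c(0, 0, 0))
    ctr0 + cc[1] * e1 + cc[2] * e2
  }
  # cylinder refinement: jointly adjust axis direction and a point on the
  # axis to minimise the variance of the C-alpha-to-axis distances (zero for
  # an ideal helix, so the exact estimate above is a fixed point)
  b1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  b1 <- b1 - sum(b1 * axis) * axis; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cross3(axis, b1)
  ctr <- circle_ctr(axis)
  obj <- function(p) {
    a <- axis + p[1] * b1 + p[2] * b2
    a <- a / sqrt(sum(a^2))
    pt <- ctr + p[3] * b1 + p[4] * b2
    rel <- sweep(xyz, 2, pt)
    perp <- rel - (rel %*% a) %*% t(a)
    stats::var(sqrt(rowSums(perp^2)))
  }
  fit <- stats::optim(c(0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 500))
  axis <- axis + fit$par[1] * b1 + fit$par[2] * b2
  axis <- axis / sqrt(sum(axis^2))
  ctr <- circle_ctr(axis)
  if (sum(axis * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) axis <- -axis

  # side-chain centroids from the unwrapped coordinates
  az <- rep(NA_real_, length(residue_range))
  names(az) <- residue_range
  if (abs(axis[3]) < 0.999) {  # azimuths are undefined for a vertical axis
    el <- toupper(at$element[idx])
    for (i in seq_along(residue_range)) {
      rows <- which(at$resid[idx] == residue_range[i] & el != "H" &
                      !(at$name[idx] %in% .mainchain_names))
      if (!length(rows)) next
      r <- colMeans(xyz_all[rows, , drop = FALSE])
      az[i] <- axis_azimuth(r - ctr, axis)
    }
  }
  structure(list(axis = unname(axis), point = unname(ctr),
                 residue_range = residue_range, azimuth = az),
            class = "helix_frame")
}

#' Rotational phase of the bound helix
#'
#' The phase psi is the azimuth, about the fitted helix axis and measured
#' from the downward (membrane-ward) direction with the right-hand rule, of
#' the anchor face: the mean radial direction of the anchor residues'
#' side-chain centroids (default R11/F15/S19, so the orientation with those
#' side chains membrane-facing has psi = 0). The depth-weighted radial
#' resultant sum(max(0, zbar - z_i) u_i) over the core residues gates the
#' computation: a flat depth profile has no membrane-facing asymmetry and is
#' an error.
#'
#' @param helixframe a `helix_frame` from [fit_helix_axis()].
#' @param depths a [depth_profile()] for the same frame
#'   (phosphorus-plane convention).
#' @param anchor_residues residues defining the reference face (default
#'   c(11, 15, 19)).
#' @param max_axis_tilt maximum allowed angle (degrees) between the axis and
#'   the membrane plane (default 60).
#' @return psi in degrees [0, 360), with attribute `asymmetry` (normalized
#'   depth-weighted resultant length in [0, 1]).
#' @export
rotational_phase <- function(helixframe, depths,
                             anchor_residues = c(11, 15, 19),
                             max_axis_tilt = 60) {
  axis <- helixframe$axis
  if (abs(axis[3]) > sin(max_axis_tilt * pi / 180))
    stop("helix axis is tilted more than ", max_axis_tilt,
         " degrees out of the membrane plane")
  az <- helixframe$azimuth
  rr <- as.integer(names(az))
  z <- depths$z_sidechain_nm[match(rr, depths$resid)]
  ok <- !is.na(az) & !is.na(z)
  w <- pmax(0, mean(z[ok]) - z[ok])
  if (sum(w) <= 0)
    stop("no membrane-facing asymmetry: flat side-chain depth profile")
  th <- az[ok] * pi / 180
  asym <- sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)

  miss <- setdiff(anchor_residues, rr[!is.na(az)])
  if (length(miss))
    stop("anchor residue(s) outside the fitted range: ",
         paste(miss, collapse = ", "))
  tha <- az[as.character(anchor_residues)] * pi / 180
  psi <- (atan2(mean(sin(tha)), mean(cos(tha))) * 180 / pi) %% 360
  attr(psi, "asymmetry") <- asym
  psi
}

.class_order <- c("Fd", "Fa", "Fb", "Fc")

#' Map a rotational phase to its orientation class
#'
#' Quadrants anchored at Fd = 0 degrees with boundaries at 45, 135, 225 and
#' 315 degrees; successive +90 degree rotations advance the class cyclically
#' Fd -> Fa -> Fb -> Fc.
#'
#' @param psi phase in degrees.
#' @return class label.
#' @export
phase_class <- function(psi) {
  .class_order[(floor(((psi + 45) %% 360) / 90) %% 4) + 1]
}

#' Classify the binding orientation over an analysis window
#'
#' Computes the rotational phase for every frame of the window (default the
#' last 20 ns), combines them by circular mean, and assigns one of the four
#' orientation classes. A peptide with no residue within the adsorption
#' threshold in any window frame is reported "unbound". Confidence is the
#' circular resultant length of the per-frame phases.
#'
#' @param traj a `trajectory`.
#' @param peptide `atom_group` of the peptide.
#' @param phosphorus `atom_group` of lipid phosphorus atoms.
#' @param window_ns analysis window, counted back from the final frame
#'   (default 20 ns).
#' @param residue_range core helix residues for the axis fit (default 8:19).
#' @param anchor_residues reference-face residues (default c(11, 15, 19)).
#' @param z_threshold adsorption threshold (nm above the proximal phosphorus
#'   plane, default 0.3).
#' @return object of class `"orientation_result"`: list with `psi` (degrees),
#'   `class` ("Fa"/"Fb"/"Fc"/"Fd"/"unbound"), `window_ns`, `confidence`,
#'   `n_frames`.
#' @export
classify_orientation <- function(traj, peptide, phosphorus, window_ns = 20,
                                 residue_range = 8:19,
                                 anchor_residues = c(11, 15, 19),
                                 z_threshold = 0.3) {
  times <- frame_times(traj)
  sel <- which(times >= max(times) - window_ns)
  top <- traj$top
  psis <- numeric(0)
  bound <- FALSE
  for (f in sel) {
    fr <- traj$frames[[f]]
    ref <- bilayer_reference(fr, phosphorus, peptide, top)
    ct <- residue_centroids(fr, peptide, top, "whole")
    if (min(ref_depth(ct$xyz[, 3], ref, "phosphorus_plane")) < z_threshold)
      bound <- TRUE
    hf <- fit_helix_axis(fr, peptide, top, residue_range)
    dp <- depth_profile(fr, peptide, ref, top, "phosphorus_plane")
    psis <- c(psis, as.numeric(rotational_phase(hf, dp, anchor_residues)))
  }
  if (!bound)
    return(structure(list(psi = NA_real_, class = "unbound",
                          window_ns = window_ns, confidence = NA_real_,
                          n_frames = length(sel)),
                     class = "orientation_result"))
  th <- psis * pi / 180
  psi <- (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
  conf <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  structure(list(psi = psi, class = phase_class(psi), window_ns = window_ns,
                 confidence = conf, n_frames = length(sel)),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  if (x$class == "unbound") {
    cat("orientation: unbound\n")
  } else {
    cat(sprintf("orientation: %s (psi = %.1f deg, confidence %.3f, %d frames)\n",
                x$class, x$psi, x$confidence, x$n_frames))
  }
  invisible(x)
}

#' Build the four rotated initial states
#'
#' Places the helical peptide above the bilayer with its helix axis parallel
#' to the membrane plane and the anchor residue's side chain pointing at the
#' membrane in the 0-degree state, at a minimum peptide-lipid heavy-atom
#' distance of at least `separation`; the other states rotate the peptide by
#' the requested angles about its helix axis (right-hand rule). The
#' construction is deterministic.
#'
#' @param peptide_sys list with `top` and `frame` of the peptide alone.
#' @param bilayer_sys list with `top` and `frame` of the bilayer alone.
#' @param separation minimum peptide-bilayer heavy-atom distance (nm,
#'   default 1.4).
#' @param rotations rotation angles in degrees (default c(0, 90, 180, 270)).
#' @param anchor_residue residue whose side chain points at the membrane in
#'   the unrotated state (default 1).
#' @param residue_range residues for the axis fit (default 8:19).
#' @return named list ("S(0)", "S(90)", ...) of merged systems, each a list
#'   with `top` and `frame`.
#' @export
build_initial_states <- function(peptide_sys, bilayer_sys, separation = 1.4,
                                 rotations = c(0, 90, 180, 270),
                                 anchor_residue = 1, residue_range = 8:19) {
  ptop <- peptide_sys$top; pfr <- peptide_sys$frame
  btop <- bilayer_sys$top; bfr <- bilayer_sys$frame
  box <- bfr$box
  el_b <- toupper(btop$atoms$element)
  bil_heavy <- which(el_b != "H")
  el_p <- toupper(ptop$atoms$element)
  pep_heavy_local <- which(el_p != "H")

  hf <- fit_helix_axis(pfr, atom_group(ptop, seq_len(ptop$natoms), "peptide"),
                       ptop, residue_range)
  # rotate the helix axis onto +x
  xyz <- sweep(pfr$xyz, 2, hf$point)
  tgt <- c(1, 0, 0)
  cr <- c(hf$axis[2] * tgt[3] - hf$axis[3] * tgt[2],
          hf$axis[3] * tgt[1] - hf$axis[1] * tgt[3],
          hf$axis[1] * tgt[2] - hf$axis[2] * tgt[1])
  ncr <- sqrt(sum(cr^2))
  if (ncr > 1e-10) {
    ang <- atan2(ncr, sum(hf$axis * tgt)) * 180 / pi
    xyz <- xyz %*% t(rotation_matrix(cr / ncr, ang))
  } else if (sum(hf$axis * tgt) < 0) {
    xyz <- xyz %*% t(rotation_matrix(c(0, 0, 1), 180))
  }
  # point the anchor residue's side chain straight down
  pgroup <- atom_group(ptop, seq_len(ptop$natoms), "peptide")
  fr0 <- make_frame(xyz, box + max(abs(xyz)) * 2 + 1, 0)  # huge box: no wrap
  sc <- residue_centroids(fr0, pgroup, ptop, "sidechain")
  i <- match(anchor_residue, sc$resid)
  if (is.na(i) || anyNA(sc$xyz[i, ]))
    stop("anchor residue has no side-chain centroid")
  az <- axis_azimuth(sc$xyz[i, ] - c(sum(sc$xyz[i, ] * tgt), 0, 0), tgt)
  xyz <- xyz %*% t(rotation_matrix(tgt, -az))

  top_bil_z <- max(bfr$xyz[bil_heavy, 3])
  out <- list()
  for (rot in rotations) {
    xr <- xyz %*% t(rotation_matrix(tgt, rot))
    shift <- c(box[1] / 2, box[2] / 2,
               top_bil_z + separation - min(xr[pep_heavy_local, 3]))
    xr <- sweep(xr, 2, shift, `+`)
    if (max(xr[pep_heavy_local, 3]) > box[3] + top_bil_z - separation ||
        max(xr[pep_heavy_local, 3]) > box[3])
      stop("bilayer box too small to satisfy the separation")
    m <- merge_systems(btop, bfr, ptop, make_frame(xr, box, 0))
    d <- pair_dist(m$frame$xyz[bil_heavy, , drop = FALSE],
                   m$frame$xyz[btop$natoms + pep_heavy_local, , drop = FALSE],
                   box)
    if (min(d) < separation)
      stop("bilayer box too small to satisfy the separation")
    out[[sprintf("S(%d)", as.integer(rot))]] <- m
  }
  out
}

#' Orientation table over multiple runs
#'
#' Classifies each run and tabulates initial state against final orientation
#' class, with class frequencies over the bound runs.
#'
#' @param runs list of `trajectory` objects.
#' @param labels initial-state name per run (same length as `runs`).
#' @param peptide_expr,phosphorus_expr selection strings evaluated on each
#'   run's topology.
#' @param ... passed to [classify_orientation()].
#' @return list with `table` (data.frame: initial_state, run, class, psi_deg,
#'   confidence), `frequencies` (named numeric over bound runs) and
#'   `n_unbound`.
#' @export
orientation_table <- function(runs, labels, peptide_expr = "peptide",
                              phosphorus_expr = "lipid and name P", ...) {
  if (!length(runs)) stop("need at least one run")
  stopifnot(length(labels) == length(runs))
  rows <- lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]
    pep <- select_atoms(tr$top, peptide_expr)
    phos <- select_atoms(tr$top, phosphorus_expr)
    res <- classify_orientation(tr, pep, phos, ...)
    data.frame(initial_state = labels[i], run = i, class = res$class,
               psi_deg = res$psi, confidence = res$confidence)
  })
  tab <- do.call(rbind, rows)
  bound <- tab$class != "unbound"
  freq <- if (any(bound)) {
    t <- table(factor(tab$class[bound], levels = .class_order))
    as.numeric(t) / sum(bound)
  } else numeric(4)
  names(freq) <- .class_order
  list(table = tab, frequencies = freq, n_unbound = sum(!bound))
}
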