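# Depth coordinates, leaflet assignment, closest-residue timelines, contacts.

# Unwrap a z column on the periodic circle so a set of atoms that straddles
# the z boundary becomes contiguous: fold each z into the window of length Lz
# centred on `center`.
unwrap_z <- function(z, Lz, center) {
  center + (z - center) - Lz * ceiling((z - center) / Lz - 0.5)
}

# Robust circular centre of a z distribution (atan2 of the mean phase).
circular_z_center <- function(z, Lz) {
  th <- 2 * pi * z / Lz
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * Lz / (2 * pi)
}

#' Leaflet assignment and the phosphorus reference planes
#'
#' Establishes the depth convention every membrane analysis uses: lipid
#' phosphorus atoms are unwrapped across the periodic z boundary, split into
#' an upper and a lower leaflet, and the mean phosphorus z of each leaflet
#' plus the bilayer midplane are recorded. The proximal leaflet is the one
#' whose mean phosphorus plane lies nearest the peptide centroid.
#'
#' @param frame a `frame`.
#' @param phosphorus `atom_group` of the lipid phosphorus atoms (>= 2).
#' @param peptide `atom_group` of the peptide.
#' @param top the `topology` (for per-lipid molecule ids).
#' @return object of class `"bilayer_ref"`: list with `upper_z`, `lower_z`,
#'   `midplane` (nm, unwrapped convention), `proximal` ("upper"/"lower"),
#'   `leaflet` (named character vector by lipid molid) and `Lz`.
#' @export
bilayer_reference <- function(frame, phosphorus, peptide, top) {
  if (length(phosphorus) < 2) stop("need at least two phosphorus atoms")
  Lz <- frame$box[3]
  zP_raw <- frame$xyz[phosphorus, 3]
  ctr <- circular_z_center(zP_raw, Lz)
  zP <- unwrap_z(zP_raw, Lz, ctr)
  mid0 <- mean(zP)
  upper <- zP > mid0
  lower <- zP < mid0
  if (!any(upper) || !any(lower))
    stop("all phosphorus atoms lie in one leaflet: bilayer reference is degenerate")
  upper_z <- mean(zP[upper])
  lower_z <- mean(zP[zP <= mid0])
  # atoms exactly at the midplane count as lower; recompute cleanly
  lower_z <- mean(zP[!upper])
  midplane <- (upper_z + lower_z) / 2

  leaflet <- ifelse(upper, "upper", "lower")
  names(leaflet) <- as.character(top$atoms$molid[phosphorus])

  pep_z <- mean(unwrap_z(frame$xyz[peptide, 3], Lz, midplane))
  proximal <- if (abs(pep_z - upper_z) <= abs(pep_z - lower_z)) "upper" else "lower"
  structure(list(upper_z = upper_z, lower_z = lower_z, midplane = midplane,
                 proximal = proximal, leaflet = leaflet, Lz = Lz),
            class = "bilayer_ref")
}

#' @export
print.bilayer_ref <- function(x, ...) {
  cat(sprintf("bilayer_ref: P planes %.3f / %.3f nm, midplane %.3f nm, proximal %s\n",
              x$upper_z, x$lower_z, x$midplane, x$proximal))
  invisible(x)
}

# Signed depth of absolute z values relative to the chosen reference plane.
# Positive z is the water side of the proximal leaflet, so a peptide residue
# buried below the phosphorus plane has negative depth.
ref_depth <- function(z, ref, convention = c("phosphorus_plane", "bilayer_center")) {
  convention <- match.arg(convention)
  plane <- switch(convention,
                  phosphorus_plane = if (ref$proximal == "upper") ref$upper_z else ref$lower_z,
                  bilayer_center = ref$midplane)
  d <- (z - plane) - ref$Lz * ceiling((z - plane) / ref$Lz - 0.5)
  if (ref$proximal == "lower") d <- -d
  d
}

.mainchain_names <- c("N", "CA", "C", "O")

# Per-residue centroid coordinates of a peptide group. Atoms of each residue
# are unwrapped relative to the residue's first atom before averaging, so
# box-wrapped peptides do not corrupt centroids. part: mainchain (N, CA, C, O),
# sidechain (remaining heavy atoms), ca, or whole (all heavy atoms).
residue_centroids <- function(frame, peptide, top,
                              part = c("whole", "mainchain", "sidechain", "ca")) {
  part <- match.arg(part)
  at <- top$atoms
  idx <- as.integer(peptide)
  keep <- toupper(at$element[idx]) != "H"
  idx <- switch(part,
    whole = idx[keep],
    mainchain = idx[keep & at$name[idx] %in% .mainchain_names],
    sidechain = idx[keep & !(at$name[idx] %in% .mainchain_names) &
                      !(toupper(at$element[idx]) == "H")],
    ca = idx[at$name[idx] == "CA"])
  resids <- sort(unique(at$resid[as.integer(peptide)]))
  out <- matrix(NA_real_, length(resids), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(resids)) {
    ai <- idx[at$resid[idx] == resids[i]]
    if (!length(ai)) next
    xyz <- frame$xyz[ai, , drop = FALSE]
    anchor <- xyz[1, ]
    for (k in 1:3) {
      L <- frame$box[k]
      xyz[, k] <- anchor[k] + (xyz[, k] - anchor[k]) -
        L * ceiling((xyz[, k] - anchor[k]) / L - 0.5)
    }
    out[i, ] <- colMeans(xyz)
  }
  list(resid = resids, xyz = out)
}

#' Per-residue depth profile
#'
#' z-position of each peptide residue's mainchain centroid, side-chain
#' centroid and C-alpha atom relative to the proximal phosphorus plane
#' (`"phosphorus_plane"`) or the bilayer midplane (`"bilayer_center"`).
#' Positive values are on the water side.
#'
#' @param frame a `frame`.
#' @param peptide `atom_group` of the peptide.
#' @param ref a `bilayer_ref` for the same frame.
#' @param top the `topology`.
#' @param convention depth reference plane.
#' @return data.frame with columns `resid`, `z_mainchain_nm`,
#'   `z_sidechain_nm`, `z_ca_nm`; attribute `convention`.
#' @export
depth_profile <- function(frame, peptide, ref, top,
                          convention = c("phosphorus_plane", "bilayer_center")) {
  convention <- match.arg(convention)
  mc <- residue_centroids(frame, peptide, top, "mainchain")
  sc <- residue_centroids(frame, peptide, top, "sidechain")
  ca <- residue_centroids(frame, peptide, top, "ca")
  df <- data.frame(
    resid = mc$resid,
    z_mainchain_nm = ref_depth(mc$xyz[, 3], ref, convention),
    z_sidechain_nm = ref_depth(sc$xyz[, 3], ref, convention),
    z_ca_nm = ref_depth(ca$xyz[, 3], ref, convention)
  )
  attr(df, "convention") <- convention
  df
}

#' Residue closest to the bilayer surface
#'
#' The residue whose centroid z (relative to the proximal phosphorus plane)
#' is smallest; ties go to the lower residue index.
#'
#' @inheritParams depth_profile
#' @param part which atoms define the centroid.
#' @return integer residue index.
#' @export
closest_residue <- function(frame, peptide, ref, top,
                            part = c("whole", "mainchain", "sidechain")) {
  part <- match.arg(part)
  ct <- residue_centroids(frame, peptide, top, part)
  z <- ref_depth(ct$xyz[, 3], ref, "phosphorus_plane")
  ct$resid[which.min(z)]  # which.min takes the first (lowest index) on ties
}

#' Count atomic contacts between two groups
#'
#' Number of heavy-atom (non-hydrogen) pairs across the two groups with
#' minimum-image distance strictly below `cutoff`. The groups must not
#' overlap.
#'
#' @param frame a `frame`.
#' @param group_a,group_b `atom_group`s.
#' @param top the `topology`.
#' @param cutoff contact cutoff in nm (default 0.45, a common literature
#'   convention; the underlying papers rarely state one).
#' @return integer count.
#' @export
contact_count <- function(frame, group_a, group_b, top, cutoff = 0.45) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(intersect(as.integer(group_a), as.integer(group_b))))
    stop("contact groups overlap")
  el <- toupper(top$atoms$element)
  a <- as.integer(group_a)[el[as.integer(group_a)] != "H"]
  b <- as.integer(group_b)[el[as.integer(group_b)] != "H"]
  if (!length(a) || !length(b)) return(0L)
  d <- pair_dist(frame$xyz[a, , drop = FALSE], frame$xyz[b, , drop = FALSE],
                 frame$box)
  sum(d < cutoff)
}

#' Per-residue adsorption timeline
#'
#' A residue counts as adsorbed at the first time its centroid depth stays
#' below `z_threshold` (relative to the proximal phosphorus plane) for at
#' least `dwell` nanoseconds without interruption. The initiating region is
#' the one containing the earliest-adsorbing residue.
#'
#' @param traj a `trajectory`.
#' @param peptide `atom_group` of the peptide.
#' @param phosphorus `atom_group` of the lipid phosphorus atoms.
#' @param part which atoms define the residue centroid.
#' @param z_threshold adsorption depth threshold in nm above the proximal
#'   phosphorus plane (default 0.3).
#' @param dwell minimum sustained time below threshold in ns (default 1).
#' @param nterm_range residue indices forming the N-terminal region (default
#'   1:19; the remainder is the C-terminal region).
#' @return list with `times` (data.frame `resid`, `first_time_ns`, NA where a
#'   residue never adsorbs), `region` ("N-terminal", "C-terminal" or "none"),
#'   `first_residue` and `first_time_ns`.
#' @export
adsorption_report <- function(traj, peptide, phosphorus,
                              part = c("whole", "mainchain", "sidechain"),
                              z_threshold = 0.3, dwell = 1,
                              nterm_range = 1:19) {
  part <- match.arg(part)
  times <- frame_times(traj)
  if (max(times) - min(times) < dwell)
    stop("trajectory is shorter than the dwell time")
  top <- traj$top
  resids <- sort(unique(top$atoms$resid[as.integer(peptide)]))
  below <- matrix(FALSE, length(traj$frames), length(resids))
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    ref <- bilayer_reference(fr, phosphorus, peptide, top)
    ct <- residue_centroids(fr, peptide, top, part)
    below[f, ] <- ref_depth(ct$xyz[, 3], ref, "phosphorus_plane") < z_threshold
  }
  first_time <- rep(NA_real_, length(resids))
  for (r in seq_along(resids)) {
    runs <- rle(below[, r])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      if (times[ends[k]] - times[starts[k]] >= dwell) {
        first_time[r] <- times[starts[k]]
        break
      }
    }
  }
  if (all(is.na(first_time))) {
    region <- "none"; first_res <- NA_integer_; ft <- NA_real_
  } else {
    i <- which.min(first_time)  # earliest; first index on ties
    first_res <- resids[i]
    ft <- first_time[i]
    region <- if (first_res %in% nterm_range) "N-terminal" else "C-terminal"
  }
  list(times = data.frame(resid = resids, first_time_ns = first_time),
       region = region, first_residue = first_res, first_time_ns = ft)
}
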