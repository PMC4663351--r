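# Synthetic systems with analytic ground truth: idealized bilayers, ideal
# alpha-helical peptides, planted hydrogen bonds, and scripted adsorption /
# rotation kinematics. Scripted kinematics only -- no forces, no dynamics.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic bilayer specification
#'
#' Defines an idealized planar two-leaflet bilayer: lipids on a lateral grid
#' whose box area realizes the target area per lipid exactly, phosphorus
#' planes at plus/minus half the target thickness (plus per-lipid z jitter),
#' headgroup pseudo-sites at fixed offsets from the phosphorus plane
#' (positive = toward water), and one all-trans zigzag acyl chain per lipid
#' tilted from the membrane normal. Chain tilt and zigzag azimuths are
#' deterministically stratified over lipids so orientational averages are
#' exact, with per-lipid tilt optionally drawn from a normal distribution.
#'
#' @param lipids_per_leaflet lipids per leaflet (default 64, a 2 x 64
#'   bilayer).
#' @param apl target area per lipid in nm^2 (default 0.616, a typical
#'   fluid-phase phosphatidylcholine value).
#' @param thickness target phosphorus-to-phosphorus thickness in nm (default
#'   3.67, a typical neat phosphatidylcholine bilayer).
#' @param jitter headgroup z-jitter standard deviation in nm (default 0.1).
#' @param offsets named z-offsets (nm) of the head/ester pseudo-sites
#'   relative to the phosphorus plane, positive toward water; the default
#'   choline above phosphate above ester is the phosphatidylcholine layering.
#'   Setting the head offset to ~0 gives phosphatidylglycerol-like layering.
#' @param style "POPC" (choline head site, +1/-1 choline/phosphate charges,
#'   choline neither donor nor acceptor) or "POPG" (glycerol head site with a
#'   hydroxyl hydrogen: donor and acceptor; lipid net charge -1).
#' @param tail_carbons carbons per acyl chain (default 12).
#' @param tilt_mean,tilt_sd chain-tilt distribution (degrees from the
#'   membrane normal; default fixed 30 degrees).
#' @param z_margin water gap above each leaflet (nm, default 3).
#' @param n_frames,stride frames to generate and their spacing (ns).
#' @param dimple optional `list(depth=, radius=)` (nm): a Gaussian local
#'   thinning of both leaflets centred in the box, emulating a peptide-induced
#'   dimple.
#' @param seed RNG seed.
#' @return object of class `"bilayer_spec"`.
#' @export
bilayer_spec <- function(lipids_per_leaflet = 64, apl = 0.616,
                         thickness = 3.67, jitter = 0.1,
                         offsets = c(head = 0.10, phosphate = 0,
                                     ester = -0.25),
                         style = c("POPC", "POPG"), tail_carbons = 12,
                         tilt_mean = 30, tilt_sd = 0, z_margin = 3,
                         n_frames = 1, stride = 1, dimple = NULL, seed = 1) {
  style <- match.arg(style)
  stopifnot(lipids_per_leaflet >= 1, apl > 0, thickness > 0, jitter >= 0,
            tail_carbons >= 3, n_frames >= 1)
  structure(list(lipids_per_leaflet = lipids_per_leaflet, apl = apl,
                 thickness = thickness, jitter = jitter, offsets = offsets,
                 style = style, tail_carbons = tail_carbons,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 z_margin = z_margin, n_frames = n_frames, stride = stride,
                 dimple = dimple, seed = seed), class = "bilayer_spec")
}

# Lennard-Jones parameters on the Berger united-atom scale.
.lj_c <- list(C = c(5.9e-3, 2.1e-5), O = c(2.4e-3, 1.5e-6),
              N = c(2.4e-3, 2.3e-6), P = c(9.2e-3, 2.2e-5), H = c(0, 0),
              S = c(9.9e-3, 1.3e-5))

.lipid_atom_row <- function(name, element, resid, resname, molid, charge,
                            nh, donor, acceptor, bond_to = NA_integer_) {
  lj <- .lj_c[[element]]
  data.frame(name = name, element = element, resid = resid,
             resname = resname, molid = molid, moltype = "lipid",
             charge = charge, c6 = lj[1], c12 = lj[2], nh = nh,
             donor = donor, acceptor = acceptor, bond_to = bond_to,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic bilayer
#'
#' Realizes a [bilayer_spec()]: identical specs and seeds give bit-identical
#' output. The returned ground-truth record holds every generator target so
#' analyses can be checked against construction values.
#'
#' @param spec a `bilayer_spec`.
#' @return list with `top` (topology), `traj` (trajectory) and `truth`
#'   (list: `box`, `apl`, `thickness`, `upper_z`, `lower_z`, `midplane`,
#'   `scd` = the closed-form order parameter of the tilt distribution,
#'   `tilt_deg` per lipid).
#' @export
generate_bilayer <- function(spec) {
  with_seed(spec$seed, generate_bilayer_impl(spec))
}

generate_bilayer_impl <- function(spec) {
  npl <- spec$lipids_per_leaflet
  L <- sqrt(npl * spec$apl)
  nx <- ceiling(sqrt(npl))
  ny <- ceiling(npl / nx)
  Lz <- spec$thickness + 2 * spec$z_margin
  mid <- Lz / 2
  head_name <- if (spec$style == "POPC") "CHO" else "GLY"
  head_charge <- if (spec$style == "POPC") 1 else 0
  resname <- spec$style

  nlip <- 2 * npl
  tilts <- spec$tilt_mean + if (spec$tilt_sd > 0)
    stats::rnorm(nlip, 0, spec$tilt_sd) else numeric(nlip)
  # stratified per leaflet (identical sets in both) so the leaflets are
  # exact mirrors and orientational averages are exact, not sampled
  tilt_az <- 360 * ((seq_len(nlip) - 1) %% npl) / npl  # chain-tilt azimuth
  zig_az <- 180 * ((seq_len(nlip) - 1) %% npl) / npl   # zigzag-plane azimuth

  bond_len <- 0.153
  half_ccc <- (180 - 111) / 2 * pi / 180  # bond angle 111 deg
  d_ax <- bond_len * cos(half_ccc)
  h_pp <- bond_len * sin(half_ccc) / 2

  rows <- list(); coord0 <- list()
  molid <- 0
  for (leaflet in c("upper", "lower")) {
    for (i in seq_len(npl)) {
      molid <- molid + 1
      gx <- ((i - 1) %% nx + 0.5) * (L / nx)
      gy <- ((i - 1) %/% nx + 0.5) * (L / ny)
      # every lipid is built in upper-leaflet form; lower-leaflet lipids are
      # reflected about the midplane afterwards, bit-exactly, so densities
      # are symmetric about z = 0 by construction
      zP <- mid + spec$thickness / 2
      if (!is.null(spec$dimple)) {
        r2 <- (gx - L / 2)^2 + (gy - L / 2)^2
        zP <- zP - spec$dimple$depth *
          exp(-r2 / (2 * spec$dimple$radius^2))
      }
      tau <- tilts[molid] * pi / 180
      alpha <- tilt_az[molid] * pi / 180
      a_hat <- c(sin(tau) * cos(alpha), sin(tau) * sin(alpha), -cos(tau))
      e1 <- c(-sin(alpha), cos(alpha), 0)
      e2 <- c(a_hat[2] * e1[3] - a_hat[3] * e1[2],
              a_hat[3] * e1[1] - a_hat[1] * e1[3],
              a_hat[1] * e1[2] - a_hat[2] * e1[1])
      gam <- zig_az[molid] * pi / 180
      p_hat <- cos(gam) * e1 + sin(gam) * e2

      at <- list(); xyz <- list()
      add <- function(row, pos) {
        at[[length(at) + 1]] <<- row
        xyz[[length(xyz) + 1]] <<- pos
      }
      add(.lipid_atom_row(head_name, if (spec$style == "POPC") "N" else "O",
                          molid, resname, molid, head_charge, 3,
                          donor = spec$style == "POPG",
                          acceptor = spec$style == "POPG"),
          c(gx, gy, zP + spec$offsets[["head"]]))
      if (spec$style == "POPG")
        add(.lipid_atom_row("HG", "H", molid, resname, molid, 0, 0,
                            FALSE, FALSE, bond_to = 1L),
            c(gx, gy, zP + spec$offsets[["head"]] + 0.1))
      add(.lipid_atom_row("P", "P", molid, resname, molid, -1, 0,
                          FALSE, TRUE),
          c(gx, gy, zP + spec$offsets[["phosphate"]]))
      add(.lipid_atom_row("EST1", "O", molid, resname, molid, 0, 0,
                          FALSE, TRUE),
          c(gx - 0.1, gy, zP + spec$offsets[["ester"]]))
      add(.lipid_atom_row("EST2", "O", molid, resname, molid, 0, 0,
                          FALSE, TRUE),
          c(gx + 0.1, gy, zP + spec$offsets[["ester"]]))
      start <- c(gx, gy, zP + spec$offsets[["ester"]] - 0.1)
      for (k in seq_len(spec$tail_carbons)) {
        pos <- start + k * d_ax * a_hat + ((-1)^k) * h_pp * p_hat
        add(.lipid_atom_row(paste0("C", k), "C", molid, resname, molid, 0,
                            if (k == spec$tail_carbons) 3 else 2,
                            FALSE, FALSE), pos)
      }
      block <- do.call(rbind, at)
      # bond_to was local to the lipid block; shift to global indices
      off <- sum(vapply(rows, nrow, integer(1)))
      block$bond_to <- block$bond_to + off
      rows[[molid]] <- block
      co <- do.call(rbind, xyz)
      if (leaflet == "lower") co[, 3] <- 2 * mid - co[, 3]
      coord0[[molid]] <- co
    }
  }
  atoms <- do.call(rbind, rows)
  top <- topology(atoms)
  base_xyz <- do.call(rbind, coord0)

  natoms_per_lipid <- vapply(coord0, nrow, integer(1))
  lipid_of_atom <- rep(seq_len(nlip), natoms_per_lipid)
  frames <- lapply(seq_len(spec$n_frames), function(f) {
    xyz <- base_xyz
    if (spec$jitter > 0) {
      dz <- stats::rnorm(nlip, 0, spec$jitter)
      xyz[, 3] <- xyz[, 3] + dz[lipid_of_atom]
    }
    make_frame(xyz, c(L, L, Lz), (f - 1) * spec$stride)
  })
  scd_true <- mean(scd_ideal_chain(tilts))
  list(top = top, traj = trajectory(top, frames, spec$stride),
       truth = list(box = c(L, L, Lz), apl = spec$apl,
                    thickness = spec$thickness,
                    upper_z = mid + spec$thickness / 2,
                    lower_z = mid - spec$thickness / 2, midplane = mid,
                    scd = scd_true, tilt_deg = tilts, seed = spec$seed))
}

# --- peptide ---------------------------------------------------------------

.hiapp_sequence <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.sc_charge <- c(K = 1, R = 1, D = -1, E = -1)
.sc_donor <- c("S", "T", "Y", "N", "Q", "K", "R", "H", "W", "C")
.sc_acceptor <- c("S", "T", "Y", "N", "Q", "D", "E", "H")

#' Synthetic helical peptide specification
#'
#' An ideal alpha-helix (default rise 0.15 nm and twist 100 degrees per
#' residue) with a reduced per-residue geometry: backbone N, CA, C, O sites
#' near the helix radius, an amide hydrogen on N, and the side chain as a
#' single radial stub site (plus a polar hydrogen for donor-capable side
#' chains). Charges: Lys/Arg side chains +1, Asp/Glu -1, the N-terminus +1,
#' the C-terminus amidated (neutral).
#'
#' The rotational phase `phase` places the mean side-chain direction of the
#' `anchor_residues` at that azimuth, measured from straight down, so
#' `phase = 0` is the orientation with the anchor face membrane-facing.
#'
#' @param sequence one-letter sequence (default the 37-residue human amylin
#'   sequence).
#' @param rise,twist helix rise (nm) and twist (degrees) per residue.
#' @param helix_range residues treated as helical (default 5:28; the reduced
#'   geometry places all residues on the ideal helix and this range is
#'   bookkeeping for axis fits).
#' @param stub side-chain stub length beyond the helix radius (nm).
#' @param phase rotational phase of the anchor face in degrees (default 0).
#' @param anchor_residues residues defining the reference face (default
#'   c(11, 15, 19)).
#' @param seed RNG seed (reserved; the construction is deterministic).
#' @return object of class `"peptide_spec"`.
#' @export
peptide_spec <- function(sequence = .hiapp_sequence, rise = 0.15,
                         twist = 100, helix_range = 5:28, stub = 0.25,
                         phase = 0, anchor_residues = c(11, 15, 19),
                         seed = 1) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(.aa3))
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  if (any(!helix_range %in% seq_along(letters1)))
    stop("helix_range outside the sequence")
  structure(list(sequence = sequence, rise = rise, twist = twist,
                 helix_range = helix_range, stub = stub, phase = phase,
                 anchor_residues = anchor_residues, seed = seed),
            class = "peptide_spec")
}

circ_mean_deg <- function(x) {
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
}

#' Generate a synthetic helical peptide
#'
#' Builds the ideal helix of a [peptide_spec()] with its axis along +x,
#' centred at the origin. Deterministic.
#'
#' @param spec a `peptide_spec`.
#' @return list with `top`, `frame` (in a 10 nm cube, centred), and `truth`
#'   (list: `axis`, `phase`, `net_charge`, `azimuth` per residue).
#' @export
generate_peptide <- function(spec) {
  letters1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(letters1)
  Rh <- 0.23
  theta0 <- spec$phase - circ_mean_deg(spec$twist * spec$anchor_residues)
  theta <- (spec$twist * seq_len(n) + theta0) %% 360
  # azimuth convention: direction(theta) = (0, sin, -cos) about the +x axis
  raddir <- cbind(0, sin(theta * pi / 180), -cos(theta * pi / 180))
  xs <- (seq_len(n) - (n + 1) / 2) * spec$rise

  rows <- list(); xyz <- list()
  for (i in seq_len(n)) {
    aa <- letters1[i]
    rn <- .aa3[[aa]]
    lj <- function(el) .lj_c[[el]]
    base <- c(xs[i], 0, 0) + Rh * raddir[i, ]
    idx0 <- sum(vapply(rows, nrow, integer(1)))
    at <- list(); pos <- list()
    add <- function(name, el, charge, nh, donor, acceptor, p,
                    bond_to = NA_integer_) {
      at[[length(at) + 1]] <<- data.frame(
        name = name, element = el, resid = i, resname = rn, molid = 1,
        moltype = "peptide", charge = charge, c6 = lj(el)[1],
        c12 = lj(el)[2], nh = nh, donor = donor, acceptor = acceptor,
        bond_to = if (is.na(bond_to)) NA_integer_ else bond_to + idx0,
        stringsAsFactors = FALSE)
      pos[[length(pos) + 1]] <<- p
    }
    nterm <- i == 1
    has_bb_h <- aa != "P"
    add("N", "N", if (nterm) 1 else 0, if (nterm) 3 else 0,
        donor = has_bb_h || nterm, acceptor = FALSE,
        base + c(-0.06, 0, 0))
    if (has_bb_h)
      add("H", "H", 0, 0, FALSE, FALSE,
          base + c(-0.06, 0, 0) + 0.1 * raddir[i, ], bond_to = 1L)
    add("CA", "C", 0, 1, FALSE, FALSE, base)
    add("C", "C", 0, 0, FALSE, FALSE, base + c(0.06, 0, 0))
    add("O", "O", 0, 0, FALSE, TRUE, base + c(0.08, 0, 0) + 0.02 * raddir[i, ])
    sc_i <- length(at) + 1L
    add("SC", "C", if (aa %in% names(.sc_charge)) .sc_charge[[aa]] else 0, 3,
        donor = aa %in% .sc_donor, acceptor = aa %in% .sc_acceptor,
        c(xs[i], 0, 0) + (Rh + spec$stub) * raddir[i, ])
    if (aa %in% .sc_donor)
      add("HS", "H", 0, 0, FALSE, FALSE,
          c(xs[i], 0, 0) + (Rh + spec$stub + 0.1) * raddir[i, ],
          bond_to = sc_i)
    rows[[i]] <- do.call(rbind, at)
    xyz[[i]] <- do.call(rbind, pos)
  }
  atoms <- do.call(rbind, rows)
  top <- topology(atoms)
  coords <- do.call(rbind, xyz)
  fr <- make_frame(sweep(coords, 2, c(-5, -5, -5)), c(10, 10, 10), 0)
  list(top = top, frame = fr,
       truth = list(axis = c(1, 0, 0), phase = spec$phase %% 360,
                    center = c(5, 5, 5),
                    net_charge = sum(atoms$charge),
                    azimuth = stats::setNames(theta, seq_len(n)),
                    seed = spec$seed))
}

# --- scripted trajectories -------------------------------------------------

#' Scripted-trajectory specification
#'
#' Rigid-body peptide kinematics over a synthetic bilayer: piecewise-linear
#' schedules for the depth of the N-terminal and C-terminal ends of the helix
#' axis (nm relative to the proximal phosphorus plane), a rotation schedule
#' for the phase about the helix axis, and an optional hydrogen-bond planting
#' schedule (bonds per frame per lipid group, planted by placing group
#' acceptor atoms at ideal geometry: D-A 0.30 nm, H-A 0.20 nm, angle 180
#' degrees). Defaults emulate a C-terminal-first adsorption: the C-terminal
#' end reaches the surface at 12 ns, the N-terminal end at 50 ns.
#'
#' @param n_frames number of frames (default 60).
#' @param stride frame spacing in ns (default 1).
#' @param z_nterm,z_cterm keyframe data.frames with columns `time` (ns) and
#'   `z` (nm above the proximal phosphorus plane) for the two helix ends;
#'   values are linearly interpolated (rule 2 outside the range).
#' @param psi keyframe data.frame (`time`, `psi` in degrees) for the
#'   rotational phase.
#' @param plant_hbonds named counts of hydrogen bonds to plant per frame per
#'   lipid group (names from `phosphate`, `ester`, `head`), e.g.
#'   `c(phosphate = 5)`.
#' @param seed RNG seed.
#' @return object of class `"script_spec"`.
#' @export
script_spec <- function(n_frames = 60, stride = 1,
                        z_nterm = data.frame(time = c(0, 49, 50),
                                             z = c(2, 2, 0.15)),
                        z_cterm = data.frame(time = c(0, 11, 12),
                                             z = c(2, 2, 0.15)),
                        psi = data.frame(time = 0, psi = 0),
                        plant_hbonds = NULL, seed = 1) {
  stopifnot(n_frames >= 1, stride > 0)
  structure(list(n_frames = n_frames, stride = stride, z_nterm = z_nterm,
                 z_cterm = z_cterm, psi = psi, plant_hbonds = plant_hbonds,
                 seed = seed), class = "script_spec")
}

interp_sched <- function(df, col, t) {
  if (nrow(df) == 1) return(rep(df[[col]], length(t)))
  stats::approx(df$time, df[[col]], xout = t, rule = 2)$y
}

#' Generate a scripted peptide-bilayer trajectory
#'
#' Assembles the bilayer and peptide of the given specs and moves the peptide
#' rigid-body frame by frame per the script: rotation about its helix axis,
#' then a tilt so the two helix ends track their depth schedules. The ground
#' truth record carries, per frame, the true phase, the per-residue centroid
#' depth (construction arithmetic relative to the true proximal phosphorus
#' plane), the planted hydrogen-bond counts, and the true per-residue
#' first-adsorption times under a threshold/dwell rule.
#'
#' @param bspec a [bilayer_spec()] (zero jitter recommended for exact ground
#'   truth).
#' @param pspec a [peptide_spec()].
#' @param script a [script_spec()].
#' @param z_threshold,dwell the adsorption rule used for the ground-truth
#'   first-adsorption times (defaults 0.3 nm / 1 ns).
#' @return list with `top`, `traj` and `truth` (list: `psi` per frame,
#'   `planted` counts per group per frame, `z_residue` matrix
#'   frame x residue, `first_adsorption_ns` per residue, `region`,
#'   `upper_z`).
#' @export
generate_scripted_trajectory <- function(bspec, pspec, script,
                                         z_threshold = 0.3, dwell = 1) {
  with_seed(script$seed,
            generate_scripted_impl(bspec, pspec, script, z_threshold, dwell))
}

generate_scripted_impl <- function(bspec, pspec, script, z_threshold, dwell) {
  bil <- generate_bilayer_impl(bspec)
  pep <- generate_peptide(pspec)
  nb <- bil$top$natoms
  merged <- merge_systems(bil$top, bil$traj$frames[[1]], pep$top, pep$frame)
  top <- merged$top
  at <- top$atoms
  box <- bil$truth$box
  upper_z <- bil$truth$upper_z

  pep_local <- sweep(pep$frame$xyz, 2, pep$truth$center)  # axis on x, origin
  n_res <- max(pep$top$atoms$resid)
  helix_len <- (n_res - 1) * pspec$rise
  times <- (seq_len(script$n_frames) - 1) * script$stride
  zN <- interp_sched(script$z_nterm, "z", times)
  zC <- interp_sched(script$z_cterm, "z", times)
  psi_t <- interp_sched(script$psi, "psi", times)
  if (min(c(zN, zC)) < bspec$offsets[["ester"]])
    stop("script would embed the peptide inside the lipid tail region")

  # planting bookkeeping: acceptor atoms per group in the upper leaflet,
  # peptide backbone donors (N with H) from the C-terminal end inward
  plant <- script$plant_hbonds
  group_atoms <- list()
  if (!is.null(plant)) {
    nm_map <- c(phosphate = "P", ester = "EST1", head = "CHO")
    for (g in names(plant)) {
      idx <- which(at$moltype == "lipid" & at$name == nm_map[[g]] &
                   seq_len(nrow(at)) <= nb)
      idx <- idx[bil$traj$frames[[1]]$xyz[idx, 3] > bil$truth$midplane]
      if (plant[[g]] > length(idx))
        stop("not enough '", g, "' acceptor atoms to plant")
      group_atoms[[g]] <- idx
    }
  }
  pep_at <- pep$top$atoms
  donor_heavy <- which(pep_at$name == "N" & pep_at$donor)
  donor_h <- vapply(donor_heavy, function(d)
    which(!is.na(pep_at$bond_to) & pep_at$bond_to == d)[1], integer(1))
  keep <- !is.na(donor_h)
  donor_heavy <- rev(donor_heavy[keep]); donor_h <- rev(donor_h[keep])

  pep_heavy_local <- which(toupper(pep_at$element) != "H")
  frames <- vector("list", script$n_frames)
  z_res <- matrix(NA_real_, script$n_frames, n_res)
  planted <- matrix(0L, script$n_frames, length(group_atoms),
                    dimnames = list(NULL, names(group_atoms)))
  for (f in seq_len(script$n_frames)) {
    xyz <- if (length(bil$traj$frames) >= f) bil$traj$frames[[f]]$xyz
           else bil$traj$frames[[length(bil$traj$frames)]]$xyz
    # rotate the peptide about its axis, then tilt about y to hit the
    # end-depth schedule, then translate over the box centre
    p <- pep_local %*% t(rotation_matrix(c(1, 0, 0), psi_t[f]))
    beta <- atan2(zN[f] - zC[f], helix_len) * 180 / pi
    p <- p %*% t(rotation_matrix(c(0, 1, 0), beta))
    ctr_z <- upper_z + (zN[f] + zC[f]) / 2
    p <- sweep(p, 2, c(box[1] / 2, box[2] / 2, ctr_z), `+`)
    full <- rbind(xyz, p)

    # plant hydrogen bonds: move group acceptors onto ideal D-H...A geometry
    gi <- 0
    for (g in names(group_atoms)) {
      k <- plant[[g]]
      if (k < 1) next
      for (j in seq_len(k)) {
        gi <- gi + 1
        d <- donor_heavy[(gi - 1) %% length(donor_heavy) + 1]
        h <- donor_h[(gi - 1) %% length(donor_h) + 1]
        u <- full[nb + h, ] - full[nb + d, ]
        u <- u / sqrt(sum(u^2))
        full[group_atoms[[g]][j], ] <- full[nb + d, ] + 0.30 * u
      }
      planted[f, g] <- k
    }
    frames[[f]] <- make_frame(full, box, times[f])

    # construction-side residue centroid depths (heavy atoms)
    for (r in seq_len(n_res)) {
      ai <- pep_heavy_local[pep_at$resid[pep_heavy_local] == r]
      z_res[f, r] <- mean(p[ai, 3]) - upper_z
    }
  }

  first_ads <- rep(NA_real_, n_res)
  for (r in seq_len(n_res)) {
    runs <- rle(z_res[, r] < z_threshold)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (runs$values[k] && times[ends[k]] - times[starts[k]] >= dwell) {
        first_ads[r] <- times[starts[k]]; break
      }
    }
  }
  region <- if (all(is.na(first_ads))) "none" else {
    r0 <- which.min(first_ads)
    if (r0 <= 19) "N-terminal" else "C-terminal"
  }

  list(top = top, traj = trajectory(top, frames, script$stride),
       truth = list(psi = (pspec$phase + psi_t) %% 360, planted = planted,
                    z_residue = z_res, first_adsorption_ns = first_ads,
                    region = region, upper_z = upper_z,
                    bilayer = bil$truth, peptide = pep$truth))
}
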