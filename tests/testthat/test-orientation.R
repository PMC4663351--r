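pep_group <- function(top) atom_group(top, seq_len(top$natoms), "peptide")

test_that("the helix axis of an ideal helix is recovered exactly", {
  p <- generate_peptide(peptide_spec())
  hf <- fit_helix_axis(p$frame, pep_group(p$top), p$top)
  expect_equal(hf$axis, c(1, 0, 0), tolerance = 1e-6)
  # equivariance: rotating the helix 30 degrees about z rotates the axis
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  fr2 <- make_frame(p$frame$xyz %*% t(R) + 3, c(20, 20, 20))
  hf2 <- fit_helix_axis(fr2, pep_group(p$top), p$top)
  expect_equal(as.numeric(hf2$axis), as.numeric(R %*% hf$axis),
               tolerance = 1e-6)
  expect_error(fit_helix_axis(p$frame, pep_group(p$top), p$top,
                              residue_range = 8:10), "4 C-alpha")
})

test_that("jittered helices recover the axis within 5 degrees over 100 seeds", {
  p <- generate_peptide(peptide_spec())
  for (seed in 1:100) {
    set.seed(seed)
    fr <- p$frame
    fr$xyz <- fr$xyz + matrix(rnorm(length(fr$xyz), 0, 0.02),
                              ncol = 3)
    hf <- fit_helix_axis(fr, pep_group(p$top), p$top)
    ang <- acos(min(1, abs(sum(hf$axis * c(1, 0, 0))))) * 180 / pi
    expect_lt(ang, 5)
  }
})

# a depth profile for a free helix, measured against a virtual plane above
free_depths <- function(p, plane = 8) {
  data.frame(resid = 1:37, z_mainchain_nm = NA_real_,
             z_sidechain_nm = residue_sidechain_z(p, plane),
             z_ca_nm = NA_real_)
}

residue_sidechain_z <- function(p, plane) {
  top <- p$top
  idx <- which(top$atoms$name == "SC")
  z <- rep(NA_real_, 37)
  z[top$atoms$resid[idx]] <- p$frame$xyz[idx, 3] - plane
  z
}

test_that("rotational phase anchors Fd at zero and rotates equivariantly", {
  p <- generate_peptide(peptide_spec(phase = 0))
  hf <- fit_helix_axis(p$frame, pep_group(p$top), p$top)
  psi0 <- rotational_phase(hf, free_depths(p))
  expect_lt(min(abs(c(as.numeric(psi0), 360 - as.numeric(psi0)))), 2)
  for (d in c(90, 180, 270)) {
    p2 <- generate_peptide(peptide_spec(phase = d))
    hf2 <- fit_helix_axis(p2$frame, pep_group(p2$top), p2$top)
    psi <- as.numeric(rotational_phase(hf2, free_depths(p2)))
    delta <- (psi - as.numeric(psi0) - d) %% 360
    expect_lt(min(delta, 360 - delta), 2)
    expect_equal(phase_class(psi), c(`90` = "Fa", `180` = "Fb",
                                     `270` = "Fc")[[as.character(d)]])
  }
})

test_that("a flat side-chain depth profile has no defined phase", {
  p <- generate_peptide(peptide_spec())
  hf <- fit_helix_axis(p$frame, pep_group(p$top), p$top)
  dp <- free_depths(p)
  dp$z_sidechain_nm <- 0.5
  expect_error(rotational_phase(hf, dp), "asymmetry")
})

test_that("a near-vertical helix axis is rejected for phase analysis", {
  p <- generate_peptide(peptide_spec())
  # rotate the helix axis from x onto z
  R <- matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  fr <- make_frame(p$frame$xyz %*% t(R) + 5, c(20, 20, 20))
  hf <- fit_helix_axis(fr, pep_group(p$top), p$top)
  expect_error(rotational_phase(hf, free_depths(p)), "tilted")
})

test_that("scripted bound trajectories classify into the scripted class", {
  classes <- c(`0` = "Fd", `90` = "Fa", `180` = "Fb", `270` = "Fc")
  for (ph in names(classes)) {
    st <- generate_scripted_trajectory(
      bilayer_spec(lipids_per_leaflet = 16, jitter = 0, seed = 17),
      peptide_spec(phase = as.numeric(ph)),
      script_spec(n_frames = 4, z_nterm = data.frame(time = 0, z = 0.15),
                  z_cterm = data.frame(time = 0, z = 0.15), seed = 17))
    res <- classify_orientation(st$traj, select_atoms(st$top, "peptide"),
                                select_atoms(st$top, "lipid and name P"),
                                window_ns = 3)
    expect_equal(res$class, classes[[ph]])
    dpsi <- (res$psi - as.numeric(ph)) %% 360
    expect_lt(min(dpsi, 360 - dpsi), 2)
    expect_gt(res$confidence, 0.99)
  }
})

test_that("rotating a bound helix advances psi and the class cyclically", {
  st <- generate_scripted_trajectory(
    bilayer_spec(lipids_per_leaflet = 16, jitter = 0, seed = 18),
    peptide_spec(phase = 0),
    script_spec(n_frames = 3, z_nterm = data.frame(time = 0, z = 0.15),
                z_cterm = data.frame(time = 0, z = 0.15), seed = 18))
  top <- st$top
  pep <- select_atoms(top, "peptide")
  phos <- select_atoms(top, "lipid and name P")
  base <- classify_orientation(st$traj, pep, phos, window_ns = 2)
  hf <- fit_helix_axis(st$traj$frames[[1]], pep, top)
  order_from <- function(cl) {
    cyc <- c("Fd", "Fa", "Fb", "Fc")
    which(cyc == cl)
  }
  for (d in c(90, 180, 270)) {
    frames <- lapply(st$traj$frames, function(fr) {
      xyz <- fr$xyz
      ip <- as.integer(pep)
      rel <- sweep(xyz[ip, , drop = FALSE], 2, hf$point)
      xyz[ip, ] <- sweep(rel %*% t(bilayerbind:::rotation_matrix(hf$axis, d)),
                         2, hf$point, `+`)
      make_frame(xyz, fr$box, fr$time)
    })
    tr2 <- trajectory(top, frames)
    res <- classify_orientation(tr2, pep, phos, window_ns = 2)
    dpsi <- (res$psi - base$psi - d) %% 360
    expect_lt(min(dpsi, 360 - dpsi), 2)
    expect_equal(order_from(res$class) - 1,
                 (order_from(base$class) - 1 + d / 90) %% 4)
  }
})

test_that("a desorbed peptide is reported unbound", {
  st <- generate_scripted_trajectory(
    bilayer_spec(lipids_per_leaflet = 16, jitter = 0, seed = 19),
    peptide_spec(),
    script_spec(n_frames = 3, z_nterm = data.frame(time = 0, z = 2),
                z_cterm = data.frame(time = 0, z = 2), seed = 19))
  res <- classify_orientation(st$traj, select_atoms(st$top, "peptide"),
                              select_atoms(st$top, "lipid and name P"),
                              window_ns = 2)
  expect_equal(res$class, "unbound")
})

test_that("initial states satisfy separation, determinism and 90-degree steps", {
  bil <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 64, jitter = 0,
                                       z_margin = 4, seed = 20))
  pep <- generate_peptide(peptide_spec())
  states <- build_initial_states(list(top = pep$top, frame = pep$frame),
                                 list(top = bil$top,
                                      frame = bil$traj$frames[[1]]))
  expect_named(states, c("S(0)", "S(90)", "S(180)", "S(270)"))
  el <- function(top) toupper(top$atoms$element)
  for (s in states) {
    nb <- bil$top$natoms
    d <- bilayerbind:::pair_dist(
      s$frame$xyz[seq_len(nb), , drop = FALSE][el(bil$top) != "H", ],
      s$frame$xyz[nb + which(el(pep$top) != "H"), , drop = FALSE],
      s$frame$box)
    expect_gte(min(d), 1.4 - 1e-9)
  }
  # deterministic
  states2 <- build_initial_states(list(top = pep$top, frame = pep$frame),
                                  list(top = bil$top,
                                       frame = bil$traj$frames[[1]]))
  expect_identical(states$`S(90)`$frame$xyz, states2$`S(90)`$frame$xyz)
  # phase steps of 90 degrees between successive states
  psi_of <- function(s) {
    top <- s$top
    pg <- select_atoms(top, "peptide")
    hf <- fit_helix_axis(s$frame, pg, top)
    sc <- bilayerbind:::residue_centroids(s$frame, pg, top, "sidechain")
    dp <- data.frame(resid = sc$resid, z_mainchain_nm = NA_real_,
                     z_sidechain_nm = sc$xyz[, 3] - max(sc$xyz[, 3]) - 0.1,
                     z_ca_nm = NA_real_)
    as.numeric(rotational_phase(hf, dp))
  }
  p0 <- psi_of(states$`S(0)`)
  for (d in c(90, 180, 270)) {
    dd <- (psi_of(states[[sprintf("S(%d)", d)]]) - p0 - d) %% 360
    expect_lt(min(dd, 360 - dd), 2)
  }
})

test_that("the orientation table reproduces scripted per-run classes", {
  # twelve short runs scripted to end in a fixed class pattern
  pattern <- data.frame(
    state = rep(c("S(0)", "S(90)", "S(180)", "S(270)"), each = 3),
    cls = c("Fb", "Fd", "Fd", "Fa", "Fd", "Fb",
            "Fa", "Fb", "Fc", "Fd", "Fc", "Fb"))
  psi_for <- c(Fd = 0, Fa = 90, Fb = 180, Fc = 270)
  runs <- lapply(seq_len(nrow(pattern)), function(i) {
    st <- generate_scripted_trajectory(
      bilayer_spec(lipids_per_leaflet = 8, jitter = 0, seed = 100 + i),
      peptide_spec(phase = psi_for[[pattern$cls[i]]]),
      script_spec(n_frames = 3, z_nterm = data.frame(time = 0, z = 0.15),
                  z_cterm = data.frame(time = 0, z = 0.15), seed = 100 + i))
    st$traj
  })
  tab <- orientation_table(runs, pattern$state, window_ns = 2)
  expect_equal(tab$table$class, pattern$cls)
  expect_equal(tab$n_unbound, 0)
  expect_equal(sum(tab$frequencies), 1)
  expect_equal(as.numeric(tab$frequencies["Fd"]), 4 / 12)
})
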