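test_that("a single fixed atom gives the textbook density value", {
  s <- slab_system(npl = 16, half = 1.835, box = c(5, 5, 8), pep_z = 5)
  # one oxygen-like atom (8 electrons) fixed 1 nm above the midplane
  at <- rbind(s$top$atoms[seq_len(32), ],
              toy_atoms(1, name = "OW", element = "O", moltype = "solvent",
                        resname = "SOL", molid = 33L))
  top <- topology(at)
  xyz <- rbind(s$frame$xyz[seq_len(32), ], c(2.5, 2.5, 5))  # midplane is 4
  traj <- trajectory(top, list(make_frame(xyz, c(5, 5, 8))))
  grp <- select_atoms(top, "solvent", label = "water")
  prof <- electron_density(traj, grp, select_atoms(top, "lipid and name P"),
                          bin_width = 0.1)
  nz <- prof[prof$density_e_nm3 > 0, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$density_e_nm3, 8 / (5 * 5 * 0.1))
  expect_equal(nz$z_nm, 0.95, tolerance = 0.051)  # the bin containing z = 1
})

test_that("electron density integrates to the group's total electrons", {
  set.seed(808)
  sys <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 16, jitter = 0.08,
                                       n_frames = 2, seed = 12))
  phos <- select_atoms(sys$top, "lipid and name P")
  for (k in 1:20) {
    bw <- runif(1, 0.02, 0.3)
    expr <- sample(c("lipid and name P", "lipid and name CHO",
                     "lipid and name EST1 EST2", "lipid and name C1 C2 C3",
                     "lipid"), 1)
    grp <- select_atoms(sys$top, expr)
    prof <- electron_density(sys$traj, grp, phos, bin_width = bw)
    box <- sys$traj$frames[[1]]$box
    integral <- sum(prof$density_e_nm3) * box[1] * box[2] * bw
    expect_equal(integral, sum(electron_counts(sys$top, as.integer(grp))),
                 tolerance = 1e-9)
  }
  expect_error(electron_density(sys$traj, atom_group(sys$top, integer(0)),
                                phos), "empty")
})

test_that("a symmetric synthetic bilayer gives a symmetric density profile", {
  sys <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 64, jitter = 0,
                                       seed = 13))
  phos <- select_atoms(sys$top, "lipid and name P")
  prof <- electron_density(sys$traj, select_atoms(sys$top, "lipid"), phos,
                           bin_width = 0.1)
  flipped <- prof$density_e_nm3[rev(seq_len(nrow(prof)))]
  expect_equal(prof$density_e_nm3, flipped, tolerance = 1e-9)
  # headgroup layering: phosphate peak further out than ester
  pP <- electron_density(sys$traj, select_atoms(sys$top, "lipid and name P"),
                         phos, bin_width = 0.1)
  pE <- electron_density(sys$traj,
                         select_atoms(sys$top, "lipid and name EST1 EST2"),
                         phos, bin_width = 0.1)
  peak <- function(p) abs(p$z_nm[which.max(p$density_e_nm3)])
  expect_gt(peak(pP), peak(pE))
})

test_that("S_CD reproduces the closed forms at 0, 90 and the magic angle", {
  # chain of three carbons along x with two explicit hydrogens on the middle
  build <- function(hdir) {
    at <- rbind(toy_atoms(3, name = c("C1", "C2", "C3"),
                          resid = 1L, molid = 1L),
                toy_atoms(2, name = c("H1", "H2"), element = "H",
                          resid = 1L, molid = 1L, bond_to = 2L))
    top <- topology(at)
    xyz <- rbind(c(1, 1, 1), c(1.15, 1, 1), c(1.3, 1, 1),
                 c(1.15, 1, 1) + 0.1 * hdir,
                 c(1.15, 1, 1) - 0.1 * hdir)
    traj <- trajectory(top, list(make_frame(xyz, c(5, 5, 5))))
    order_parameter(traj, list(1:3), hydrogens = "explicit")
  }
  expect_equal(build(c(0, 0, 1))$scd, 1.0, tolerance = 1e-9)
  expect_equal(build(c(0, 1, 0))$scd, -0.5, tolerance = 1e-9)
  magic <- acos(1 / sqrt(3))
  expect_equal(build(c(sin(magic), 0, cos(magic)))$scd, 0, tolerance = 1e-9)
})

test_that("isotropic C-H orientations average to |S_CD| < 0.01", {
  set.seed(909)
  n <- 1e5
  hdir <- matrix(rnorm(3 * n), n)
  hdir <- hdir / sqrt(rowSums(hdir^2))
  at <- rbind(toy_atoms(3, name = c("C1", "C2", "C3"), resid = 1L,
                        molid = 1L),
              toy_atoms(n, name = paste0("H", seq_len(n)), element = "H",
                        resid = 1L, molid = 1L, bond_to = 2L))
  top <- topology(at)
  xyz <- rbind(c(2, 2, 2), c(2.15, 2, 2), c(2.3, 2, 2),
               matrix(c(2.15, 2, 2), n, 3, byrow = TRUE) + 0.1 * hdir)
  traj <- trajectory(top, list(make_frame(xyz, c(5, 5, 5))))
  prof <- order_parameter(traj, list(1:3), hydrogens = "explicit")
  expect_lt(abs(prof$scd[prof$carbon == 2]), 0.01)
})

test_that("tetrahedral reconstruction recovers the generator's tilt target", {
  magic_deg <- acos(1 / sqrt(3)) * 180 / pi
  sys <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 16, jitter = 0,
                                       tilt_mean = magic_deg, tilt_sd = 0,
                                       seed = 14))
  prof <- order_parameter(sys$traj, acyl_chains(sys$top))
  expect_true(all(abs(prof$scd) < 1e-6))
  # terminal carbons (no reconstruction neighbours) are absent, not zero
  expect_false(1 %in% prof$carbon)
  expect_false(12 %in% prof$carbon)
  for (tilt in c(20, 40)) {
    s2 <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 16, jitter = 0,
                                        tilt_mean = tilt, tilt_sd = 0,
                                        seed = 14))
    p2 <- order_parameter(s2$traj, acyl_chains(s2$top))
    expect_equal(p2$scd, rep(scd_ideal_chain(tilt), nrow(p2)),
                 tolerance = 1e-9)
  }
})

test_that("S_CD stays within its mathematical bounds on arbitrary chains", {
  set.seed(111)
  sys <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 8, jitter = 0.1,
                                       tilt_mean = 30, tilt_sd = 15,
                                       n_frames = 3, seed = 15))
  prof <- order_parameter(sys$traj, acyl_chains(sys$top))
  expect_true(all(prof$scd >= -0.5 - 1e-12 & prof$scd <= 1 + 1e-12))
})

test_that("thickness recovers the slab construction and the cutoff identity", {
  s <- slab_system(npl = 16, half = 1.835, box = c(4, 4, 8), pep_z = 6)
  traj <- trajectory(s$top, list(s$frame))
  th <- membrane_thickness(traj, s$phos)
  expect_equal(th$thickness_nm, 3.67)
  # cutoff = none equals a cutoff larger than the box
  th_inf <- membrane_thickness(traj, s$phos, s$pep, cutoff = 50)
  expect_equal(th_inf$thickness_nm, th$thickness_nm)
  expect_error(membrane_thickness(traj, s$phos, s$pep, cutoff = 1e-3),
               "larger cutoff")
})

test_that("a local dimple thins the membrane only at small cutoffs", {
  sys <- generate_bilayer(bilayer_spec(lipids_per_leaflet = 64, jitter = 0,
                                       dimple = list(depth = 0.4,
                                                     radius = 0.8),
                                       seed = 16))
  box <- sys$truth$box
  # marker peptide atom over the dimple centre
  pep_at <- toy_atoms(1, name = "CA", moltype = "peptide", resname = "ALA")
  m <- merge_systems(sys$top, sys$traj$frames[[1]], topology(pep_at),
                     make_frame(matrix(c(box[1] / 2, box[2] / 2,
                                         sys$truth$upper_z + 0.5), 1), box))
  traj <- trajectory(m$top, list(m$frame))
  phos <- select_atoms(m$top, "lipid and name P")
  pep <- select_atoms(m$top, "peptide")
  t1 <- membrane_thickness(traj, phos, pep, cutoff = 1)
  t3 <- membrane_thickness(traj, phos, pep, cutoff = 3)
  tg <- membrane_thickness(traj, phos)
  expect_lt(t1$thickness_nm, t3$thickness_nm)
  expect_lt(abs(t3$thickness_nm - tg$thickness_nm) / tg$thickness_nm, 0.01)
  expect_lt(t1$lipid_count, t3$lipid_count)
})

test_that("area per lipid is the lateral box area over the leaflet count", {
  at <- toy_atoms(1, name = "P", element = "P")
  top <- topology(at)
  mk <- function(Lx, Ly, t) make_frame(matrix(c(1, 1, 1), 1),
                                       c(Lx, Ly, 8), t)
  traj <- trajectory(top, list(mk(6.2, 6.2, 0)))
  expect_equal(area_per_lipid(traj, 64), 0.600625)
  # constant box: zero variance across frames; doubling both lengths
  # quadruples the value
  traj2 <- trajectory(top, list(mk(6.2, 6.2, 0), mk(6.2, 6.2, 1)))
  expect_equal(area_per_lipid(traj2, 64), 0.600625)
  traj4 <- trajectory(top, list(mk(12.4, 12.4, 0)))
  expect_equal(area_per_lipid(traj4, 64), 4 * 0.600625)
  expect_error(area_per_lipid(traj, 0), "positive")
})
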