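# Small systems built in code for the unit tests.

# Atom-table builder with sensible defaults; any column can be overridden.
toy_atoms <- function(n, ...) {
  at <- data.frame(
    name = paste0("X", seq_len(n)), element = "C", resid = 1L,
    resname = "TOY", molid = 1L, moltype = "lipid", charge = 0,
    c6 = 0, c12 = 0, nh = 0, donor = FALSE, acceptor = FALSE,
    bond_to = NA_integer_, stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) at[[k]] <- over[[k]]
  at
}

# A flat two-leaflet phosphorus slab: npl P atoms per leaflet on a grid at
# z = mid +/- half, plus one marker "peptide" atom above the upper plane.
slab_system <- function(npl = 16, half = 1.835, box = c(4, 4, 8),
                        pep_z = 6) {
  grid <- expand.grid(x = seq_len(ceiling(sqrt(npl))),
                      y = seq_len(ceiling(sqrt(npl))))[seq_len(npl), ]
  xy <- cbind(grid$x * box[1] / (ceiling(sqrt(npl)) + 1),
              grid$y * box[2] / (ceiling(sqrt(npl)) + 1))
  xyz <- rbind(cbind(xy, box[3] / 2 + half),
               cbind(xy, box[3] / 2 - half),
               c(box[1] / 2, box[2] / 2, pep_z))
  at <- rbind(
    toy_atoms(2 * npl, name = "P", element = "P",
              resid = seq_len(2 * npl), molid = seq_len(2 * npl),
              resname = "LIP"),
    toy_atoms(1, name = "CA", moltype = "peptide", resname = "ALA",
              molid = 2L * npl + 1L))
  top <- topology(at)
  list(top = top, frame = make_frame(xyz, box),
       phos = select_atoms(top, "lipid and name P"),
       pep = select_atoms(top, "peptide"))
}

# Random charged/LJ atoms in a periodic box, split into two groups.
random_energy_system <- function(n_a = 30, n_b = 30, box = c(3, 3, 3)) {
  n <- n_a + n_b
  at <- toy_atoms(n,
                  charge = stats::runif(n, -1, 1),
                  c6 = stats::runif(n, 0, 8e-3),
                  c12 = stats::runif(n, 0, 3e-5),
                  resid = seq_len(n), molid = seq_len(n))
  top <- topology(at)
  xyz <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
               stats::runif(n, 0, box[3]))
  list(top = top, frame = make_frame(xyz, box),
       a = atom_group(top, seq_len(n_a), "A"),
       b = atom_group(top, n_a + seq_len(n_b), "B"))
}

# Random donors (each with one hydrogen at 0.1 nm) and acceptors in a box.
random_hbond_system <- function(n_d = 20, n_a = 50, box = c(2, 2, 2)) {
  nd2 <- 2 * n_d
  at <- rbind(
    toy_atoms(nd2,
              name = rep(c("N", "H"), n_d),
              element = rep(c("N", "H"), n_d),
              donor = rep(c(TRUE, FALSE), n_d),
              resid = rep(seq_len(n_d), each = 2),
              molid = rep(seq_len(n_d), each = 2),
              moltype = "peptide", resname = "GLN",
              bond_to = as.integer(rbind(NA, seq(1, nd2, by = 2)))),
    toy_atoms(n_a, name = "O", element = "O", acceptor = TRUE,
              resid = n_d + seq_len(n_a), molid = n_d + seq_len(n_a),
              resname = "LIP"))
  top <- topology(at)
  xyz <- matrix(0, nd2 + n_a, 3)
  dpos <- cbind(stats::runif(n_d, 0, box[1]), stats::runif(n_d, 0, box[2]),
                stats::runif(n_d, 0, box[3]))
  hdir <- matrix(stats::rnorm(3 * n_d), n_d)
  hdir <- hdir / sqrt(rowSums(hdir^2))
  xyz[seq(1, nd2, 2), ] <- dpos
  xyz[seq(2, nd2, 2), ] <- dpos + 0.1 * hdir
  xyz[nd2 + seq_len(n_a), ] <- cbind(stats::runif(n_a, 0, box[1]),
                                     stats::runif(n_a, 0, box[2]),
                                     stats::runif(n_a, 0, box[3]))
  list(top = top, frame = make_frame(xyz, box),
       donors = atom_group(top, seq_len(nd2), "donors"),
       acceptors = atom_group(top, nd2 + seq_len(n_a), "acceptors"))
}

# A three-site D-H-A triple at exact geometry, for criterion edge cases.
dha_system <- function(d_da = 0.30, d_dh = 0.10, angle = 180,
                       box = c(5, 5, 5)) {
  at <- toy_atoms(3, name = c("N", "H", "O"), element = c("N", "H", "O"),
                  donor = c(TRUE, FALSE, FALSE),
                  acceptor = c(FALSE, FALSE, TRUE),
                  resid = c(1L, 1L, 2L), molid = c(1L, 1L, 2L),
                  bond_to = c(NA_integer_, 1L, NA_integer_))
  top <- topology(at)
  # D at origin-ish, H along +x; A placed so that the D-H...A angle at H is
  # `angle` and |D-A| = d_da
  th <- (180 - angle) * pi / 180
  # solve |HA| from the triangle D-H-A with |DH| = d_dh and angle at H
  # between H->D (-x) and H->A: interior angle at H is `angle`
  # place A = H + r*(cos(angle_from_+x), sin, 0) with angle measured from +x
  # direction continuing away from D: angle at H between (D-H) and (A-H) is
  # `angle`, so A-H makes (180 - angle) with +x.
  ha_dir <- c(cos(th), sin(th), 0)
  # choose r so that |D-A| = d_da
  # D = (0,0,0), H = (d_dh,0,0), A = H + r*ha_dir
  # |A|^2 = (d_dh + r cos th)^2 + (r sin th)^2 = d_da^2
  cc <- c(d_dh^2 - d_da^2, 2 * d_dh * cos(th), 1)
  r <- (-cc[2] + sqrt(cc[2]^2 - 4 * cc[3] * cc[1])) / 2
  xyz <- rbind(c(1, 1, 1),
               c(1 + d_dh, 1, 1),
               c(1 + d_dh, 1, 1) + r * ha_dir)
  list(top = top, frame = make_frame(xyz, box),
       donors = atom_group(top, 1:2, "D"),
       acceptors = atom_group(top, 3L, "A"), r_ha = r)
}
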