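# Independent brute-force oracles. These use their own minimum-image
# arithmetic and plain loops, deliberately sharing no code with the package.

owrap <- function(d, L) d - L * round(d / L)

odist <- function(p, q, box) {
  sqrt(sum(owrap(p - q, box)^2))
}

# O(N^2) contact count over non-hydrogen atoms.
oracle_contacts <- function(frame, ia, ib, top, cutoff) {
  el <- toupper(top$atoms$element)
  ia <- ia[el[ia] != "H"]; ib <- ib[el[ib] != "H"]
  n <- 0L
  for (i in ia) for (j in ib) {
    if (odist(frame$xyz[i, ], frame$xyz[j, ], frame$box) < cutoff)
      n <- n + 1L
  }
  n
}

# Exhaustive (D, H, A) triple loop under the geometric criterion.
oracle_hbonds <- function(frame, donors, acceptors, top, d_da = 0.35,
                          d_ha = 0.25, angle_min = 150) {
  at <- top$atoms
  el <- toupper(at$element)
  dh <- donors[at$donor[donors] & el[donors] != "H"]
  ac <- acceptors[at$acceptor[acceptors] & el[acceptors] != "H"]
  hits <- 0L
  for (d in dh) {
    hs <- which(!is.na(at$bond_to) & at$bond_to == d & el == "H")
    for (h in hs) for (a in ac) {
      if (a == d) next
      if (odist(frame$xyz[d, ], frame$xyz[a, ], frame$box) >= d_da) next
      if (odist(frame$xyz[h, ], frame$xyz[a, ], frame$box) >= d_ha) next
      vhd <- owrap(frame$xyz[d, ] - frame$xyz[h, ], frame$box)
      vha <- owrap(frame$xyz[a, ] - frame$xyz[h, ], frame$box)
      ang <- acos(max(-1, min(1, sum(vhd * vha) /
                                sqrt(sum(vhd^2) * sum(vha^2))))) * 180 / pi
      if (ang > angle_min) hits <- hits + 1L
    }
  }
  hits
}

# Brute-force cross-group pair sum with geometric-mean LJ combination.
oracle_energy <- function(frame, ia, ib, top, rc_c = 1.2, rc_lj = 1.4,
                          kq = 138.935458) {
  at <- top$atoms
  elec <- 0; vdw <- 0
  for (i in ia) for (j in ib) {
    r <- odist(frame$xyz[i, ], frame$xyz[j, ], frame$box)
    if (r < rc_c) elec <- elec + kq * at$charge[i] * at$charge[j] / r
    if (r < rc_lj) {
      c6 <- sqrt(at$c6[i] * at$c6[j]); c12 <- sqrt(at$c12[i] * at$c12[j])
      vdw <- vdw + c12 / r^12 - c6 / r^6
    }
  }
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

# Total energy of a set of atoms (all internal pairs), for the
# U(A+B) - U(A) - U(B) additivity identity.
oracle_total_energy <- function(frame, idx, top, ...) {
  e <- 0
  if (length(idx) < 2) return(0)
  for (k in seq_along(idx)) for (l in seq_len(k - 1)) {
    p <- oracle_energy(frame, idx[k], idx[l], top, ...)
    e <- e + p$total
  }
  e
}
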