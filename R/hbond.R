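#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triple counts as a hydrogen bond when the
#' donor-acceptor heavy-atom distance is below `d_da`, the hydrogen-acceptor
#' distance is below `d_ha`, and the D-H...A angle (vertex at the hydrogen)
#' exceeds `angle_min`. Defaults are the widely used 0.35 nm / 0.25 nm / 150
#' degrees geometric criterion. Note the angle vertex: some MD tools use the
#' donor-vertex convention instead, so exact parity with those is not implied.
#'
#' @param d_da max donor-acceptor distance (nm).
#' @param d_ha max hydrogen-acceptor distance (nm).
#' @param angle_min min D-H...A angle (degrees, in (0, 180]).
#' @return object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(d_da = 0.35, d_ha = 0.25, angle_min = 150) {
  if (d_da <= 0 || d_ha <= 0) stop("criterion distances must be positive")
  if (angle_min <= 0 || angle_min > 180) stop("angle must be in (0, 180]")
  structure(list(d_da = d_da, d_ha = d_ha, angle_min = angle_min),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in a frame
#'
#' Donor-capable heavy atoms of `donors` are paired with their bonded
#' hydrogens (the topology's `bond_to` column); every (D, H, A) triple with an
#' acceptor-capable heavy atom of `acceptors` that satisfies all three
#' conditions of the criterion simultaneously, under minimum-image distances,
#' yields one record. A donor-capable heavy atom with no attached hydrogen is
#' an error naming the atom.
#'
#' @param frame a `frame`.
#' @param donors `atom_group` providing donors (heavy atoms with the sidecar's
#'   donor flag; their hydrogens are taken from the topology).
#' @param acceptors `atom_group` providing acceptors (acceptor flag).
#' @param top the `topology`.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `time_ns`, `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `donor_resid`, `acceptor_resid`.
#' @export
detect_hbonds <- function(frame, donors, acceptors, top,
                          criterion = hbond_criterion()) {
  at <- top$atoms
  el <- toupper(at$element)
  d_heavy <- as.integer(donors)[at$donor[as.integer(donors)] &
                                el[as.integer(donors)] != "H"]
  acc <- as.integer(acceptors)[at$acceptor[as.integer(acceptors)] &
                               el[as.integer(acceptors)] != "H"]
  empty <- data.frame(time_ns = numeric(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      donor_resid = integer(0), acceptor_resid = integer(0))
  if (!length(d_heavy) || !length(acc)) return(empty)

  xa <- frame$xyz[acc, , drop = FALSE]
  recs <- vector("list", 0)
  for (d in d_heavy) {
    hs <- which(!is.na(at$bond_to) & at$bond_to == d & el == "H")
    if (!length(hs))
      stop(sprintf("donor atom %d (%s %s%d) has no attached hydrogen",
                   d, at$name[d], at$resname[d], at$resid[d]))
    a_ok <- acc != d
    if (!any(a_ok)) next
    dDA <- pair_dist(frame$xyz[d, , drop = FALSE],
                     xa[a_ok, , drop = FALSE], frame$box)[1, ]
    cand <- which(dDA < criterion$d_da)
    if (!length(cand)) next
    a_idx <- acc[a_ok][cand]
    for (h in hs) {
      hd <- min_image_vector(frame$xyz[h, ], frame$xyz[d, ], frame$box)
      ha <- min_image_vector(matrix(frame$xyz[h, ], length(a_idx), 3,
                                    byrow = TRUE),
                             frame$xyz[a_idx, , drop = FALSE], frame$box)
      dHA <- sqrt(rowSums(ha^2))
      ok <- dHA < criterion$d_ha
      if (!any(ok)) next
      cosang <- (ha[ok, , drop = FALSE] %*% hd) /
        (dHA[ok] * sqrt(sum(hd^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      hit <- a_idx[ok][ang > criterion$angle_min]
      if (length(hit))
        recs[[length(recs) + 1]] <- data.frame(
          time_ns = frame$time, donor = d, hydrogen = h, acceptor = hit,
          donor_resid = at$resid[d], acceptor_resid = at$resid[hit])
    }
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Hydrogen bonds between peptide residues and lipid chemical groups
#'
#' Per-frame hydrogen-bond counts between each peptide residue and each lipid
#' chemical group (e.g. choline, phosphate, ester), averaged over the analysis
#' window. Both directions (peptide as donor and as acceptor) are counted by
#' default.
#'
#' @param traj a `trajectory`.
#' @param peptide `atom_group` of the peptide.
#' @param group_map named list of lipid `atom_group`s; the labels must not
#'   overlap.
#' @param criterion an [hbond_criterion()].
#' @param direction which donor directions to include.
#' @param frames frame indices forming the analysis window (default all).
#' @return data.frame: one row per peptide residue, one column per group label
#'   with the mean count per frame, plus `resid`.
#' @export
hbonds_by_lipid_group <- function(traj, peptide, group_map,
                                  criterion = hbond_criterion(),
                                  direction = c("both", "peptide_donor",
                                                "peptide_acceptor"),
                                  frames = seq_along(traj$frames)) {
  direction <- match.arg(direction)
  if (!length(frames)) stop("empty trajectory window")
  labels <- names(group_map)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("group_map must be a named list")
  for (i in seq_along(group_map))
    for (j in seq_len(i - 1))
      if (length(intersect(as.integer(group_map[[i]]),
                           as.integer(group_map[[j]]))))
        stop(sprintf("lipid groups '%s' and '%s' overlap",
                     labels[i], labels[j]))
  top <- traj$top
  resids <- sort(unique(top$atoms$resid[as.integer(peptide)]))
  acc <- matrix(0, length(resids), length(labels),
                dimnames = list(NULL, labels))
  for (f in frames) {
    fr <- traj$frames[[f]]
    for (g in seq_along(group_map)) {
      if (direction %in% c("both", "peptide_donor")) {
        hb <- detect_hbonds(fr, peptide, group_map[[g]], top, criterion)
        if (nrow(hb)) {
          t1 <- table(factor(hb$donor_resid, levels = resids))
          acc[, g] <- acc[, g] + as.numeric(t1)
        }
      }
      if (direction %in% c("both", "peptide_acceptor")) {
        hb <- detect_hbonds(fr, group_map[[g]], peptide, top, criterion)
        if (nrow(hb)) {
          t2 <- table(factor(hb$acceptor_resid, levels = resids))
          acc[, g] <- acc[, g] + as.numeric(t2)
        }
      }
    }
  }
  out <- data.frame(resid = resids, acc / length(frames))
  names(out) <- c("resid", labels)
  out
}
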