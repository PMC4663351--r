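#' Minimum-image displacement vector
#'
#' Displacement from `a` to `b` under orthorhombic periodic boundaries, each
#' component folded into (-L/2, L/2].
#'
#' @param a,b points (length-3 numeric, nm), or matrices with one point per
#'   row (recycled against each other).
#' @param box orthorhombic box lengths (nm).
#' @return displacement vector(s), same shape as the inputs.
#' @export
min_image_vector <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, nrow = NROW(b), ncol = 3, byrow = TRUE)
    b <- if (is.matrix(b)) b else matrix(b, nrow = NROW(a), ncol = 3, byrow = TRUE)
    b - a
  } else b - a
  wrap_disp(d, box)
}

# Fold displacement components into (-L/2, L/2]. The half-open convention
# keeps exactly +L/2 (not -L/2) so the boundary case is deterministic.
wrap_disp <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) {
      L <- box[k]
      d[, k] <- d[, k] - L * ceiling(d[, k] / L - 0.5)
    }
  } else {
    d <- d - box * ceiling(d / box - 0.5)
  }
  d
}

# Sequential unwrap of a connected chain of atoms: atom k is placed by
# minimum image relative to atom k-1, so molecules longer than half the box
# stay contiguous. Valid whenever consecutive atoms are closer than L/2.
unwrap_chain <- function(frame, idx) {
  xyz <- frame$xyz[idx, , drop = FALSE]
  if (nrow(xyz) < 2) return(xyz)
  steps <- wrap_disp(diff(xyz), frame$box)
  out <- xyz
  out[-1, ] <- matrix(out[1, ], nrow(xyz) - 1, 3, byrow = TRUE) +
    apply(steps, 2, cumsum)
  out
}

# All minimum-image distances between the rows of xa and xb
# (length(a) x length(b) matrix). Vectorized per coordinate.
pair_dist <- function(xa, xb, box) {
  na <- nrow(xa); nb <- nrow(xb)
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], `-`)
    dk <- dk - box[k] * ceiling(dk / box[k] - 0.5)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
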