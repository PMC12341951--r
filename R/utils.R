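# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimum-image pairwise distances with x,y periodicity
#'
#' Distances between two coordinate sets under minimum-image convention in
#' the membrane plane (x, y); z is treated as non-periodic (the membrane
#' normal is not replicated in any analysis).
#'
#' @param a,b numeric matrices (n x 3 and m x 3), coordinates in Angstrom.
#' @param box numeric length-3 orthorhombic box lengths in Angstrom.
#' @return n x m matrix of distances in Angstrom.
#' @keywords internal
pair_distances_xy_periodic <- function(a, b, box) {
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, length(box) == 3L, all(box > 0))
  dx <- outer(a[, 1L], b[, 1L], "-")
  dx <- dx - box[1L] * round(dx / box[1L])
  dy <- outer(a[, 2L], b[, 2L], "-")
  dy <- dy - box[2L] * round(dy / box[2L])
  dz <- outer(a[, 3L], b[, 3L], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

# Wrap in-plane coordinates into [0, box).
wrap_xy <- function(coords, box) {
  coords[, 1L] <- coords[, 1L] %% box[1L]
  coords[, 2L] <- coords[, 2L] %% box[2L]
  coords
}

# Derived sub-stream seed: fixed offsets keep independent random components
# (lipid jitter, protein kinematics, surfacing events) from reshuffling one
# another when frame counts change. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919) %% 2147483647)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Signed dihedral angle (degrees, IUPAC convention, in (-180, 180]) from four
# points given as rows of a 4 x 3 matrix.
dihedral_angle <- function(p) {
  b1 <- p[2L, ] - p[1L, ]
  b2 <- p[3L, ] - p[2L, ]
  b3 <- p[4L, ] - p[3L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# Circular difference in degrees, result in [0, 180].
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

# Rotation matrices about the lab axes (degrees).
rotation_matrix <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3L, 3L, byrow = TRUE),
    y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3L, 3L, byrow = TRUE),
    z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3L, 3L, byrow = TRUE))
}
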