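#' Crystallographic unit cell
#'
#' Constructs a unit cell from the six standard cell parameters and
#' precomputes the orthogonalization matrix (PDB convention: `a` along x,
#' `b` in the xy plane) together with its inverse, so that fractional and
#' orthogonal (Cartesian, in angstroms) coordinates can be interconverted
#' cheaply.
#'
#' @param a,b,c Cell edge lengths in angstroms; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; each in (0, 180).
#' @return An object of class `unit_cell` with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the cell `volume` in cubic angstroms, the
#'   3x3 orthogonalization matrix `orth` and its inverse `frac`.
#' @examples
#' cell <- unit_cell(20, 30, 40)
#' x <- orthogonalize(cell, c(0.25, 0.5, 0.1))
#' fractionalize(cell, x)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(!is.finite(c(a, b, c, alpha, beta, gamma))))
    stop("unit cell parameters must be finite")
  if (any(c(a, b, c) <= 0))
    stop("unit cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("unit cell angles do not define a positive cell volume")
  vol <- a * b * c * sqrt(vfac)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, vol / (a * b * sg)), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = vol, orth = orth, frac = solve(orth)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

cells_compatible <- function(c1, c2, tol = 0.05) {
  all(abs(c(c1$a - c2$a, c1$b - c2$b, c1$c - c2$c)) < tol * max(c1$a, c1$b, c1$c)) &&
    all(abs(c(c1$alpha - c2$alpha, c1$beta - c2$beta, c1$gamma - c2$gamma)) < 1)
}

#' Convert fractional coordinates to orthogonal angstroms
#'
#' @param cell A [unit_cell()].
#' @param x Fractional coordinates: length-3 vector or n x 3 matrix.
#' @return Orthogonal coordinates with the same shape as `x`.
#' @export
orthogonalize <- function(cell, x) {
  if (is.matrix(x)) t(cell$orth %*% t(x)) else as.numeric(cell$orth %*% x)
}

#' Convert orthogonal angstrom coordinates to fractional
#'
#' @inheritParams orthogonalize
#' @param x Orthogonal coordinates: length-3 vector or n x 3 matrix.
#' @export
fractionalize <- function(cell, x) {
  if (is.matrix(x)) t(cell$frac %*% t(x)) else as.numeric(cell$frac %*% x)
}

#' Resolution (d-spacing) of Miller indices
#'
#' Computes d = 1/|B h| where B is the transpose inverse of the
#' orthogonalization matrix, i.e. the reciprocal-space vector length.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer Miller indices: length-3 vector or n x 3 matrix.
#' @return d-spacings in angstroms (Inf for the (0,0,0) index).
#' @export
d_spacing <- function(cell, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  # reciprocal vector for row h is h %*% frac (frac = inverse orth matrix)
  s <- sqrt(rowSums((hkl %*% cell$frac)^2))
  d <- ifelse(s == 0, Inf, 1 / s)
  if (length(d) == 1) d <- as.numeric(d)
  d
}
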