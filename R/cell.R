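#' Crystallographic unit cell
#'
#' Construct a unit cell from edge lengths (Angstrom) and angles (degrees),
#' precomputing the orthogonalization matrix (fractional -> Cartesian, PDB
#' convention: a along x, b in the xy plane), its inverse, and the cell
#' volume.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; each in (0, 180).
#' @return An object of class \code{xtal_cell} with elements \code{a, b, c,
#'   alpha, beta, gamma}, \code{orth} (3x3 fractional-to-Cartesian matrix),
#'   \code{frac} (its inverse) and \code{volume} (Angstrom^3).
#' @examples
#' cl <- unit_cell(40, 50, 60, 90, 95, 90)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  edges <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(edges)) || any(edges <= 0))
    stop("unit cell edges must be positive and finite")
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("degenerate unit cell: angles are not realizable")
  v <- sqrt(v)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0, c * v / sg
  ), nrow = 3, byrow = TRUE)
  cell <- list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    orth = orth, frac = solve(orth), volume = a * b * c * v
  )
  class(cell) <- "xtal_cell"
  cell
}

#' @export
print.xtal_cell <- function(x, ...) {
  cat(sprintf("P1 unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert fractional coordinates to Cartesian (Angstrom)
#'
#' @param cell An \code{xtal_cell}.
#' @param xyz Numeric matrix (n x 3) or length-3 vector of fractional
#'   coordinates.
#' @return Matrix (n x 3) of Cartesian coordinates.
#' @export
frac_to_orth <- function(cell, xyz) {
  xyz <- rbind3(xyz)
  t(cell$orth %*% t(xyz))
}

#' Convert Cartesian coordinates (Angstrom) to fractional
#'
#' @inheritParams frac_to_orth
#' @param xyz Numeric matrix (n x 3) or length-3 vector of Cartesian
#'   coordinates.
#' @export
orth_to_frac <- function(cell, xyz) {
  xyz <- rbind3(xyz)
  t(cell$frac %*% t(xyz))
}

rbind3 <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  storage.mode(xyz) <- "double"
  xyz
}

cells_equal <- function(c1, c2, tol = 1e-4) {
  all(abs(c(c1$a - c2$a, c1$b - c2$b, c1$c - c2$c,
            c1$alpha - c2$alpha, c1$beta - c2$beta, c1$gamma - c2$gamma)) < tol)
}

#' Minimum-image Cartesian distances under periodic boundaries
#'
#' Distances between one reference point and a set of points, with each
#' difference vector wrapped to the nearest periodic image in fractional
#' space before orthogonalization. Exact for displacements shorter than
#' half the shortest cell width (the only regime used here).
#'
#' @param cell An \code{xtal_cell}.
#' @param x0 Length-3 Cartesian reference point.
#' @param xyz n x 3 Cartesian points.
#' @return Numeric vector of n distances (Angstrom).
#' @export
min_image_dist <- function(cell, x0, xyz) {
  d_frac <- orth_to_frac(cell, sweep(rbind3(xyz), 2, as.numeric(x0)))
  d_frac <- d_frac - round(d_frac)
  d_orth <- frac_to_orth(cell, d_frac)
  sqrt(rowSums(d_orth^2))
}
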