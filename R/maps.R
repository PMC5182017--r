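new_density_map <- function(values, cell) {
  stopifnot(length(dim(values)) == 3, all(dim(values) >= 2))
  m <- mean(values)
  map <- list(values = values, cell = cell,
              grid = dim(values),
              mean = m,
              sigma = sqrt(mean((values - m)^2)))  # population sd
  class(map) <- "density_map"
  map
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> grid %d x %d x %d, mean %.4g, sigma %.4g\n",
              x$grid[1], x$grid[2], x$grid[3], x$mean, x$sigma))
  invisible(x)
}

# Minimum Nyquist-adequate grid for a cell/dmin, inflated by `rate` samples
# per dmin/2 and rounded up to an even number (FFT-friendly).
default_grid <- function(cell, dmin, rate = 1.5) {
  n <- ceiling(rate * 2 * c(cell$a, cell$b, cell$c) / dmin)
  n + n %% 2
}

check_grid <- function(cell, dmin, grid_shape) {
  need <- ceiling(2 * c(cell$a, cell$b, cell$c) / dmin)
  if (any(grid_shape < need))
    stop(sprintf("grid %s too coarse for dmin %.2f A: minimum %s",
                 paste(grid_shape, collapse = "x"), dmin,
                 paste(need, collapse = "x")))
}

# Difference coefficients dF * exp(i phi) for dataset j vs dataset 1,
# after overall least-squares scaling (unless scale = FALSE).
difference_coefficients <- function(refl, dataset_index, scale = TRUE,
                                    quiet = TRUE) {
  stopifnot(dataset_index >= 2, dataset_index <= ncol(refl$amp))
  if (scale) refl <- scale_amplitudes(refl, dataset_index, quiet = quiet)
  dF <- refl$amp[, dataset_index] - refl$amp[, 1]
  list(hkl = refl$hkl, dF = dF, phase_rad = refl$phase * pi / 180)
}

#' Fobs(n) - Fobs(1) difference density map by FFT
#'
#' Synthesizes the difference Fourier map whose coefficients are the
#' amplitude differences between dataset \code{dataset_index} and the first
#' dataset, phased with the fixed first-dataset phases: rho(x) = (1/V)
#' sum_hkl dF cos(phi - 2 pi h.x), expanded over both Friedel hemispheres
#' and evaluated by FFT on the requested grid. F(000) is excluded, so the
#' map mean is zero (to rounding). Negative map values mark density loss.
#'
#' @param refl A \code{reflection_set} storing one Friedel hemisphere.
#' @param dataset_index Dataset to difference against the first (>= 2).
#' @param grid_shape Integer triple (nx, ny, nz); defaults to 1.5x the
#'   Nyquist minimum for \code{refl$dmin}. Must satisfy the Nyquist bound
#'   2 * cell_edge / dmin on each axis.
#' @param scale Apply the overall least-squares amplitude scale first.
#' @return A \code{density_map} with elements \code{values} (3D array, x
#'   fastest), \code{cell}, \code{mean} and \code{sigma} (population sd).
#' @seealso \code{\link{difference_map_direct}} for the direct-summation
#'   reference evaluation.
#' @export
difference_map <- function(refl, dataset_index, grid_shape = NULL,
                           scale = TRUE) {
  if (is.null(grid_shape)) grid_shape <- default_grid(refl$cell, refl$dmin)
  grid_shape <- as.integer(grid_shape)
  check_grid(refl$cell, refl$dmin, grid_shape)
  dc <- difference_coefficients(refl, dataset_index, scale = scale)
  coef <- complex(modulus = abs(dc$dF), argument = dc$phase_rad +
                    ifelse(dc$dF < 0, pi, 0))
  arr <- array(0 + 0i, dim = grid_shape)
  idx_p <- dc$hkl %% matrix(grid_shape, nrow(dc$hkl), 3, byrow = TRUE) + 1L
  idx_m <- (-dc$hkl) %% matrix(grid_shape, nrow(dc$hkl), 3, byrow = TRUE) + 1L
  arr[idx_p] <- coef
  arr[idx_m] <- Conj(coef)
  rho <- Re(stats::fft(arr)) / refl$cell$volume
  new_density_map(rho, refl$cell)
}

#' Difference map by direct Fourier summation (reference implementation)
#'
#' Evaluates the same sum as \code{\link{difference_map}} by explicit
#' cosine summation at every grid point, without FFT. Quadratic cost:
#' intended as the independent oracle for small problems, not production
#' use.
#'
#' @inheritParams difference_map
#' @return A \code{density_map}.
#' @export
difference_map_direct <- function(refl, dataset_index, grid_shape = NULL,
                                  scale = TRUE) {
  if (is.null(grid_shape)) grid_shape <- default_grid(refl$cell, refl$dmin)
  grid_shape <- as.integer(grid_shape)
  check_grid(refl$cell, refl$dmin, grid_shape)
  dc <- difference_coefficients(refl, dataset_index, scale = scale)
  x <- grid_frac(grid_shape)                       # npts x 3, x fastest
  p <- 2 * pi * (dc$hkl %*% t(x))                  # nrefl x npts
  rho <- as.vector(t(cos(p)) %*% (dc$dF * cos(dc$phase_rad)) +
                   t(sin(p)) %*% (dc$dF * sin(dc$phase_rad)))
  rho <- 2 * rho / refl$cell$volume
  new_density_map(array(rho, dim = grid_shape), refl$cell)
}

# Fractional coordinates of all grid points, first axis fastest (matches R
# array storage order).
grid_frac <- function(grid_shape) {
  g <- expand.grid(x = seq_len(grid_shape[1]) - 1,
                   y = seq_len(grid_shape[2]) - 1,
                   z = seq_len(grid_shape[3]) - 1)
  sweep(as.matrix(g), 2, grid_shape, "/")
}

#' Write a density map in CCP4/MRC format (mode 2)
#'
#' 32-bit real map with axis order X, Y, Z and the full unit cell as the
#' map extent. Values round-trip to single precision.
#'
#' @param map A \code{density_map}.
#' @param path Output path.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- map$grid
  writeBin(as.integer(c(n, 2L, 0L, 0L, 0L, n)), con, size = 4)
  writeBin(as.numeric(c(map$cell$a, map$cell$b, map$cell$c,
                        map$cell$alpha, map$cell$beta, map$cell$gamma)),
           con, size = 4)
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4)         # MAPC MAPR MAPS
  writeBin(as.numeric(c(min(map$values), max(map$values), map$mean)),
           con, size = 4)
  writeBin(as.integer(c(1L, 0L)), con, size = 4)              # ISPG, NSYMBT
  writeBin(integer(25), con, size = 4)                        # EXTRA
  writeBin(numeric(3), con, size = 4)                         # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.integer(0x00004144), con, size = 4)             # machine stamp (LE)
  writeBin(as.numeric(map$sigma), con, size = 4)
  writeBin(0L, con, size = 4)                                 # NLABL
  writeBin(integer(200), con, size = 4)                       # labels
  writeBin(as.numeric(map$values), con, size = 4)
  invisible(path)
}

#' Read a CCP4/MRC mode-2 density map
#'
#' @param path Path to a CCP4/MRC map file.
#' @return A \code{density_map}; axis order is permuted to X, Y, Z if the
#'   header stores another order.
#' @export
read_ccp4_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, integer(), 3, size = 4)
  mode <- readBin(con, integer(), 1, size = 4)
  if (length(mode) == 0 || !mode %in% 2L)
    stop("unsupported or missing CCP4 map mode: ",
         if (length(mode)) mode else "(truncated file)", " (only mode 2 supported)")
  readBin(con, integer(), 3, size = 4)                        # NxSTART
  readBin(con, integer(), 3, size = 4)                        # MX MY MZ
  cp <- readBin(con, numeric(), 6, size = 4)
  axes <- readBin(con, integer(), 3, size = 4)
  if (!all(sort(axes) == 1:3)) stop("invalid axis order in map header")
  readBin(con, numeric(), 3, size = 4)                        # min max mean
  readBin(con, integer(), 2, size = 4)                        # ISPG NSYMBT
  readBin(con, integer(), 25, size = 4)
  readBin(con, numeric(), 3, size = 4)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "MAP ")) stop("not a CCP4/MRC map file: ", path)
  readBin(con, integer(), 1, size = 4)
  readBin(con, numeric(), 1, size = 4)
  readBin(con, integer(), 1, size = 4)
  readBin(con, integer(), 200, size = 4)
  vals <- readBin(con, numeric(), prod(n), size = 4)
  if (length(vals) < prod(n)) stop("truncated map data in ", path)
  arr <- array(vals, dim = n)                    # stored (col, row, section)
  perm <- order(axes)                            # to crystallographic x,y,z
  arr <- aperm(arr, perm)
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6])
  new_density_map(arr, cell)
}
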