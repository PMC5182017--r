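#' Per-atom maximum density loss within a local vicinity
#'
#' For each heavy atom, D_loss is the maximum density-loss value in the
#' atom's local vicinity of the Fobs(n) - Fobs(1) difference map: the
#' maximum over all grid points within \code{radius} Angstrom of the atom
#' (minimum-image convention across periodic boundaries) of the negated
#' map value. A negative D_loss means the vicinity only gained density.
#' The nearest grid point is always included, so the voxel set is never
#' empty. Values are not clamped.
#'
#' @param map A \code{density_map}.
#' @param structure An \code{xtal_structure} sharing the map's cell.
#' @param radius Vicinity radius in Angstrom (default 1.5; must be positive
#'   and at least one grid spacing to be meaningful).
#' @param atoms Optional pre-filtered atom data.frame; defaults to the
#'   heavy, single-conformer polymer atoms of \code{structure}.
#' @return Numeric vector of D_loss values (map units), one per atom row,
#'   with \code{attr(,"radius")} recording the vicinity radius.
#' @export
compute_dloss <- function(map, structure, radius = 1.5, atoms = NULL) {
  stopifnot(radius > 0)
  if (!cells_equal(map$cell, structure$cell))
    stop("map and structure disagree on the unit cell")
  cell <- map$cell
  n <- map$grid
  # perpendicular width of the cell along each fractional axis
  perp <- 1 / sqrt(rowSums(cell$frac^2))
  if (radius > min(perp) / 2)
    stop(sprintf("vicinity radius %.2f A exceeds half the cell width (%.2f A)",
                 radius, min(perp) / 2))
  if (is.null(atoms)) atoms <- analysis_atoms(structure)
  # grid steps needed per axis to cover the sphere
  nstep <- pmax(1L, ceiling(radius * n / perp))
  offs <- as.matrix(expand.grid(-nstep[1]:nstep[1], -nstep[2]:nstep[2],
                                -nstep[3]:nstep[3]))
  frac <- orth_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
  out <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    centre <- round(frac[i, ] * n)          # nearest grid node
    nodes <- sweep(offs, 2, centre, "+")
    # minimum-image distance from atom to each candidate node
    d_frac <- sweep(sweep(nodes, 2, n, "/"), 2, frac[i, ])
    d_frac <- d_frac - round(d_frac)
    d <- sqrt(rowSums(frac_to_orth(cell, d_frac)^2))
    sel <- d <= radius
    if (!any(sel)) sel <- which.min(d)      # nearest node always included
    idx <- sweep(nodes[sel, , drop = FALSE], 2, n, "%%") + 1L
    out[i] <- max(-map$values[idx])
  }
  attr(out, "radius") <- radius
  out
}

#' Exhaustive-scan reference for \code{compute_dloss}
#'
#' Scans every grid point of the map, computing its minimum-image distance
#' to the atom, and takes the maximum negated value over points within the
#' radius (or the single nearest point when none fall inside). Cubic cost
#' in the grid; the independent oracle for the production sphere search.
#'
#' @inheritParams compute_dloss
#' @return Numeric vector of D_loss values, one per atom row.
#' @export
compute_dloss_exhaustive <- function(map, structure, radius = 1.5,
                                     atoms = NULL) {
  if (is.null(atoms)) atoms <- analysis_atoms(structure)
  cell <- map$cell
  pts <- frac_to_orth(cell, grid_frac(map$grid))
  vals <- as.numeric(map$values)
  out <- numeric(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    d <- min_image_dist(cell, as.numeric(atoms[i, c("x", "y", "z")]), pts)
    sel <- d <= radius
    if (!any(sel)) sel <- which.min(d)
    out[i] <- max(-vals[sel])
  }
  attr(out, "radius") <- radius
  out
}

#' A dose series: one model, a dose ladder, per-dose amplitude sets
#'
#' Bundles the initial-dataset coordinate model (used, unchanged, for every
#' dose), the reported dose ladder in MGy (first entry is the reference
#' dataset), and the reflection set holding one amplitude column per dose
#' plus the fixed first-dataset phases.
#'
#' @param structure An \code{xtal_structure} (the first-dataset model).
#' @param refl A \code{reflection_set} with one amplitude column per dose.
#' @param doses Strictly increasing numeric vector of doses (MGy), length
#'   equal to the number of amplitude columns.
#' @param labels Dataset labels; defaults to the reflection-set labels.
#' @return A \code{dose_series} object.
#' @export
dose_series <- function(structure, refl, doses, labels = refl$labels) {
  if (length(doses) != ncol(refl$amp))
    stop("one dose per amplitude column required")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (!cells_equal(structure$cell, refl$cell))
    stop("structure and reflections disagree on the unit cell")
  s <- list(structure = structure, refl = refl, doses = doses,
            labels = labels)
  class(s) <- "dose_series"
  s
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %d datasets, doses %s MGy\n",
              length(x$doses), paste(format(x$doses), collapse = ", ")))
  invisible(x)
}

#' Run the D_loss calculation over a dose series
#'
#' Builds the Fobs(n) - Fobs(1) difference map for every retained dataset
#' (n >= 2), computes per-atom D_loss, expresses it in map-sigma units,
#' and adds the C-alpha normalized column. Non-reference datasets with
#' doses below \code{dose_floor} MGy are excluded (the default 1 MGy floor
#' reflects the dose at which specific damage first becomes detectable;
#' set \code{dose_floor = 0} to disable, e.g. for low-dose controls).
#'
#' @param series A \code{dose_series}.
#' @param radius Vicinity radius in Angstrom.
#' @param dose_floor Minimum dose (MGy) for non-reference datasets.
#' @param grid_shape Map grid; defaults per \code{\link{difference_map}}.
#' @param quiet Suppress progress/log messages.
#' @return A \code{DlossTable}: data.frame with columns chain, resno,
#'   resname, atom, element, dataset, dose_MGy, dloss_raw, dloss_sigma,
#'   dloss_ca_norm; attributes \code{radius} and \code{map_sigmas}.
#' @export
run_series <- function(series, radius = 1.5, dose_floor = 1.0,
                       grid_shape = NULL, quiet = TRUE) {
  refl <- series$refl
  keep <- c(TRUE, series$doses[-1] >= dose_floor)
  if (sum(keep) < 2)
    stop("no dataset at or above the dose floor of ", dose_floor, " MGy")
  if (!quiet && any(!keep))
    message("dose floor ", dose_floor, " MGy excludes dataset(s): ",
            paste(series$labels[!keep], collapse = ", "))
  atoms <- analysis_atoms(series$structure)
  res <- list()
  sigmas <- numeric(0)
  for (j in which(keep)[-1]) {
    map <- difference_map(refl, j, grid_shape = grid_shape)
    dl <- compute_dloss(map, series$structure, radius = radius, atoms = atoms)
    sigmas[series$labels[j]] <- map$sigma
    res[[length(res) + 1L]] <- data.frame(
      chain = atoms$chain, resno = atoms$resno, resname = atoms$resname,
      atom = atoms$name, element = atoms$element,
      dataset = series$labels[j], dose_MGy = series$doses[j],
      dloss_raw = as.numeric(dl),
      dloss_sigma = if (map$sigma > 0) as.numeric(dl) / map$sigma else
        NA_real_,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, res)
  tab <- tryCatch(ca_normalize(tab), error = function(e) {
    # degenerate series (e.g. zero damage): normalization undefined
    message("C-alpha normalization unavailable: ", conditionMessage(e))
    tab$dloss_ca_norm <- NA_real_
    tab
  })
  attr(tab, "radius") <- radius
  attr(tab, "map_sigmas") <- sigmas
  class(tab) <- c("dloss_table", "data.frame")
  tab
}

#' C-alpha normalization of D_loss values
#'
#' Normalizes each atom's raw D_loss by the mean raw D_loss attained at
#' that dose by the set of C-alpha backbone atoms: normalized = (dloss -
#' mean_CA) / mean_CA. C-alpha atoms are radiation-insensitive, so this
#' expresses loss relative to a stable baseline; normalized values average
#' exactly 0 over the C-alpha set at every dose.
#'
#' @param tab A D_loss table with columns atom, dataset, dloss_raw.
#' @return The table with a \code{dloss_ca_norm} column (re)computed.
#' @export
ca_normalize <- function(tab) {
  ca <- tab$atom == "CA"
  if (!any(ca)) stop("no C-alpha (CA) atoms available for normalization")
  mean_ca <- tapply(tab$dloss_raw[ca], tab$dataset[ca], mean)
  if (any(mean_ca == 0))
    stop("mean C-alpha D_loss is zero at some dose; use raw values instead")
  m <- as.numeric(mean_ca[tab$dataset])
  tab$dloss_ca_norm <- (tab$dloss_raw - m) / m
  tab
}

#' Write a D_loss table as tab-separated values
#'
#' @param tab A D_loss table from \code{\link{run_series}}.
#' @param path Output path.
#' @export
write_dloss_table <- function(tab, path) {
  out <- as.data.frame(tab)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
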