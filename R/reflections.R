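new_reflection_set <- function(hkl, amp, phase, dmin, cell,
                               labels = colnames(amp)) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  amp <- as.matrix(amp)
  if (is.null(labels)) labels <- paste0("F", seq_len(ncol(amp)))
  colnames(amp) <- labels
  if (nrow(hkl) != nrow(amp) || nrow(hkl) != length(phase))
    stop("hkl, amplitude and phase dimensions disagree")
  if (any(amp < 0)) stop("negative amplitude")
  if (anyDuplicated(hkl))
    stop("duplicate Miller index (h,k,l) in reflection set")
  if (any(rowSums(abs(hkl)) == 0))
    stop("F(000) must be excluded from a reflection set")
  r <- list(hkl = hkl, amp = amp, phase = phase %% 360, dmin = dmin,
            cell = cell, labels = labels)
  class(r) <- "reflection_set"
  r
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections, %d dataset(s) [%s], dmin %.2f A\n",
              nrow(x$hkl), ncol(x$amp), paste(x$labels, collapse = ", "),
              x$dmin))
  invisible(x)
}

# 1/d for each (h,k,l) row under a cell: |t(frac) %*% h|.
inv_d <- function(cell, hkl) {
  rec <- t(cell$frac)              # columns a*, b*, c*
  sqrt(colSums((rec %*% t(hkl))^2))
}

#' Read reflection amplitudes and first-dataset phases from columnar text
#'
#' Whitespace-separated text with a header line naming columns: H K L, one
#' amplitude column per dataset, and one phase column (first dataset's
#' calculated phases, degrees). Lines starting with '#' are comments.
#' Reflections missing an amplitude in any dataset are dropped with a
#' message reporting the count.
#'
#' @param path Path to the reflection file.
#' @param cell An \code{xtal_cell} for the reflections (used for resolution
#'   bookkeeping).
#' @param dmin High-resolution limit in Angstrom; computed from the data
#'   when NULL.
#' @return A \code{reflection_set}.
#' @export
read_reflections <- function(path, cell, dmin = NULL) {
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  cn <- toupper(colnames(tab))
  need <- c("H", "K", "L")
  if (!all(need %in% cn)) stop("header must name H K L columns")
  phicol <- grep("^PHI", cn)
  if (length(phicol) != 1) stop("exactly one PHI* phase column required")
  ampcol <- setdiff(seq_along(cn), c(match(need, cn), phicol))
  if (length(ampcol) < 1) stop("no amplitude columns found")
  hkl <- as.matrix(tab[, match(need, cn)])
  amp <- as.matrix(tab[, ampcol, drop = FALSE])
  keep <- stats::complete.cases(amp) & !is.na(tab[[phicol]])
  if (any(!keep))
    message(sum(!keep), " reflection(s) dropped: missing amplitude or phase")
  if (any(amp[keep, ] < 0, na.rm = TRUE)) stop("negative amplitude in ", path)
  if (is.null(dmin)) dmin <- 1 / max(inv_d(cell, hkl[keep, , drop = FALSE]))
  new_reflection_set(hkl[keep, , drop = FALSE], amp[keep, , drop = FALSE],
                     tab[[phicol]][keep], dmin, cell,
                     labels = colnames(tab)[ampcol])
}

#' Write a reflection set as columnar text
#'
#' @param refl A \code{reflection_set}.
#' @param path Output path.
#' @export
write_reflections <- function(refl, path) {
  tab <- data.frame(H = refl$hkl[, 1], K = refl$hkl[, 2], L = refl$hkl[, 3])
  for (j in seq_len(ncol(refl$amp))) tab[[refl$labels[j]]] <- refl$amp[, j]
  tab$PHI1 <- refl$phase
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# reflection amplitudes, dmin %.4f A", refl$dmin), con)
  utils::write.table(format(tab, digits = 10, scientific = FALSE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Least-squares scale of a later dataset onto the first
#'
#' Multiplies dataset \code{dataset_index} amplitudes by the scalar k that
#' minimizes sum((k F_n - F_1)^2) over common reflections:
#' k = sum(F_1 F_n) / sum(F_n^2). A single overall scalar is used; no
#' resolution-binned or anisotropic scaling.
#'
#' @param refl A \code{reflection_set} with >= 2 datasets.
#' @param dataset_index Index (>= 2) of the dataset to scale.
#' @param quiet Suppress the log message reporting k.
#' @return The reflection set with the dataset rescaled; the applied scale
#'   is recorded in \code{attr(, "scales")}.
#' @export
scale_amplitudes <- function(refl, dataset_index, quiet = FALSE) {
  stopifnot(dataset_index >= 2, dataset_index <= ncol(refl$amp))
  f1 <- refl$amp[, 1]
  fn <- refl$amp[, dataset_index]
  if (all(fn == 0)) stop("cannot scale an all-zero amplitude set")
  k <- sum(f1 * fn) / sum(fn^2)
  refl$amp[, dataset_index] <- k * fn
  if (!quiet)
    message(sprintf("scale_amplitudes: dataset %d ('%s') scaled by k = %.6g",
                    dataset_index, refl$labels[dataset_index], k))
  sc <- attr(refl, "scales")
  if (is.null(sc)) sc <- numeric(0)
  sc[as.character(dataset_index)] <- k
  attr(refl, "scales") <- sc
  refl
}

#' Structure factors from a coordinate model (single-Gaussian atoms)
#'
#' Computes F(h) = sum_atoms occ * n_electrons * exp(-B s^2/4) *
#' exp(2 pi i h . x_frac) for every Miller index in one Friedel hemisphere
#' with resolution d >= dmin, excluding F(000). Each atom scatters as a
#' single Gaussian whose width is its B-factor envelope, weighted by its
#' electron count; this is a synthetic-fidelity model, not Cromer-Mann
#' scattering. Hydrogens are included if present in the structure.
#'
#' @param structure An \code{xtal_structure}.
#' @param dmin High-resolution cutoff in Angstrom (> 0).
#' @param label Dataset label for the amplitude column.
#' @return A \code{reflection_set} with one amplitude column and phases in
#'   degrees.
#' @export
structure_factors_from_model <- function(structure, dmin, label = "F1") {
  stopifnot(dmin > 0)
  if (nrow(structure$atoms) == 0) stop("empty structure")
  fc <- complex_structure_factors(structure, hemisphere_hkl(structure$cell, dmin))
  new_reflection_set(fc$hkl, matrix(Mod(fc$f), ncol = 1),
                     (Arg(fc$f) * 180 / pi) %% 360, dmin, structure$cell,
                     labels = label)
}

# All Miller indices in the standard hemisphere (l>0, or l=0 & k>0, or
# l=k=0 & h>0) with d >= dmin.
hemisphere_hkl <- function(cell, dmin) {
  hmax <- ceiling(cell$a / dmin)
  kmax <- ceiling(cell$b / dmin)
  lmax <- ceiling(cell$c / dmin)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax)
  hkl <- as.matrix(g)
  hemi <- hkl[, 3] > 0 |
    (hkl[, 3] == 0 & hkl[, 2] > 0) |
    (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0)
  hkl <- hkl[hemi, , drop = FALSE]
  hkl[inv_d(cell, hkl) <= 1 / dmin, , drop = FALSE]
}

# Complex structure factors for given hkl rows (vectorized over atoms).
complex_structure_factors <- function(structure, hkl) {
  a <- structure$atoms
  frac <- orth_to_frac(structure$cell, as.matrix(a[, c("x", "y", "z")]))
  s2 <- inv_d(structure$cell, hkl)^2
  w <- a$occ * a$n_electrons                     # per-atom weight
  phase <- 2 * pi * (hkl %*% t(frac))            # nrefl x natom
  # per-atom Debye-Waller envelope exp(-B s^2 / 4)
  dw <- exp(-outer(s2, a$b) / 4)
  re <- (cos(phase) * dw) %*% w
  im <- (sin(phase) * dw) %*% w
  list(hkl = hkl, f = complex(real = re, imaginary = im))
}
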