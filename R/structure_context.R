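# Van der Waals radii (Angstrom) used by the SASA calculation.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
                SE = 1.90)

#' Tyrosine hydroxyl hydrogen bonds to acidic carboxylates
#'
#' Finds all (Tyr OH, carboxylate oxygen) pairs at distances strictly under
#' the cutoff, where the acceptor is a Glu OE1/OE2 or Asp OD1/OD2 oxygen.
#' A plain distance criterion is used (no angular term; symmetry mates are
#' not considered). The Tyr residues of the structure are partitioned into
#' hydrogen-bonded and non-hydrogen-bonded subsets in the attributes.
#'
#' @param structure An \code{xtal_structure}.
#' @param cutoff Distance cutoff in Angstrom (pairs at exactly the cutoff
#'   are excluded).
#' @return Data frame of pairs (donor chain/resno, acceptor chain/resno/
#'   resname/atom, distance); attributes \code{hbonded} and
#'   \code{non_hbonded} list Tyr residue identifiers (chain:resno).
#' @export
find_tyr_hbonds <- function(structure, cutoff = 4.0) {
  a <- analysis_atoms(structure)
  don <- a[a$resname == "TYR" & a$name == "OH", , drop = FALSE]
  acc <- a[(a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
           (a$resname == "ASP" & a$name %in% c("OD1", "OD2")), , drop = FALSE]
  pairs <- list()
  if (nrow(don) > 0 && nrow(acc) > 0) {
    for (i in seq_len(nrow(don))) {
      d <- sqrt((acc$x - don$x[i])^2 + (acc$y - don$y[i])^2 +
                (acc$z - don$z[i])^2)
      hit <- which(d < cutoff)
      if (length(hit))
        pairs[[length(pairs) + 1L]] <- data.frame(
          donor_chain = don$chain[i], donor_resno = don$resno[i],
          acceptor_chain = acc$chain[hit], acceptor_resno = acc$resno[hit],
          acceptor_resname = acc$resname[hit], acceptor_atom = acc$name[hit],
          distance = d[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(donor_chain = character(), donor_resno = integer(),
               acceptor_chain = character(), acceptor_resno = integer(),
               acceptor_resname = character(), acceptor_atom = character(),
               distance = numeric(), stringsAsFactors = FALSE)
  tyr_ids <- unique(paste0(don$chain, ":", don$resno))
  hb_ids <- unique(paste0(out$donor_chain, ":", out$donor_resno))
  attr(out, "hbonded") <- hb_ids
  attr(out, "non_hbonded") <- setdiff(tyr_ids, hb_ids)
  out
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom solvent-accessible areas by sphere sampling: each heavy atom
#' carries \code{n_points} points on a sphere of radius (vdW + probe)
#' placed by a golden-spiral lattice; points buried inside any neighbour's
#' expanded sphere are discarded, and the accessible fraction scales the
#' full sphere area. For the tyrosine decarboxylation-context experiment,
#' \code{remove_carboxylates} deletes the Glu CD/OE1/OE2 and Asp CG/OD1/OD2
#' moieties (the CO2 group lost on decarboxylation) before the calculation.
#'
#' @param structure An \code{xtal_structure}.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom.
#' @param remove_carboxylates Delete acidic carboxylate moieties first.
#' @param radii Named vector of van der Waals radii by element.
#' @return Data frame with atom identity columns and \code{area} (A^2);
#'   rows align with the heavy single-conformer atoms used.
#' @export
solvent_accessibility <- function(structure, probe = 1.4, n_points = 960,
                                  remove_carboxylates = FALSE,
                                  radii = .vdw_radii) {
  a <- analysis_atoms(structure)
  if (remove_carboxylates) {
    drop <- (a$resname == "GLU" & a$name %in% c("CD", "OE1", "OE2")) |
            (a$resname == "ASP" & a$name %in% c("CG", "OD1", "OD2"))
    a <- a[!drop, , drop = FALSE]
  }
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  r <- unname(radii[a$element]) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sph <- golden_spiral(n_points)
  n <- nrow(a)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sph * r[i], 2, xyz[i, ], "+")
    # neighbours whose expanded sphere could bury a point of atom i
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      acc <- acc & rowSums(sweep(pts, 2, xyz[j, ])^2) >= r[j]^2
      if (!any(acc)) break
    }
    area[i] <- mean(acc) * 4 * pi * r[i]^2
  }
  out <- a[, c("serial", "name", "resname", "chain", "resno", "element")]
  out$area <- area
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}

# Deterministic golden-spiral point lattice on the unit sphere.
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible area of each tyrosine aromatic ring
#'
#' Sums per-atom areas over the ring atoms CG, CD1, CD2, CE1, CE2, CZ and
#' (by default) the OH hydroxyl of every Tyr residue.
#'
#' @param sasa Output of \code{\link{solvent_accessibility}}.
#' @param include_oh Include the OH oxygen in the ring sum.
#' @return Data frame with chain, resno and ring \code{area} per Tyr.
#' @export
tyr_ring_sasa <- function(sasa, include_oh = TRUE) {
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", if (include_oh) "OH")
  t <- sasa[sasa$resname == "TYR" & sasa$name %in% ring, , drop = FALSE]
  agg <- stats::aggregate(area ~ chain + resno, data = t, FUN = sum)
  agg[order(agg$chain, agg$resno), , drop = FALSE]
}

#' Distance from each Tyr hydroxyl to the nearest disulfide bond
#'
#' Disulfides are detected as Cys SG-SG pairs within 2.5 Angstrom; the
#' reported distance is from the Tyr OH oxygen to the disulfide bond
#' midpoint (set \code{to_midpoint = FALSE} for the nearest S atom).
#'
#' @param structure An \code{xtal_structure}.
#' @param ss_cutoff SG-SG bonding cutoff in Angstrom.
#' @param to_midpoint Measure to the bond midpoint (default) or nearest S.
#' @return Data frame with chain, resno and \code{distance} per Tyr OH;
#'   zero rows when the structure has no disulfide.
#' @export
disulfide_distance <- function(structure, ss_cutoff = 2.5,
                               to_midpoint = TRUE) {
  a <- analysis_atoms(structure)
  sg <- a[a$resname == "CYS" & a$name == "SG", , drop = FALSE]
  oh <- a[a$resname == "TYR" & a$name == "OH", , drop = FALSE]
  bonds <- NULL
  if (nrow(sg) >= 2) {
    cmb <- utils::combn(nrow(sg), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      d <- sqrt(sum((sg[i, c("x", "y", "z")] - sg[j, c("x", "y", "z")])^2))
      if (d <= ss_cutoff)
        bonds <- rbind(bonds, (as.numeric(sg[i, c("x", "y", "z")]) +
                               as.numeric(sg[j, c("x", "y", "z")])) / 2)
    }
    if (!to_midpoint && !is.null(bonds)) {
      # use S positions of bonded pairs instead of midpoints
      bonded <- NULL
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        d <- sqrt(sum((sg[i, c("x", "y", "z")] - sg[j, c("x", "y", "z")])^2))
        if (d <= ss_cutoff) bonded <- c(bonded, i, j)
      }
      bonds <- as.matrix(sg[unique(bonded), c("x", "y", "z")])
    }
  }
  if (is.null(bonds) || nrow(oh) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  dist <- vapply(seq_len(nrow(oh)), function(i) {
    min(sqrt(rowSums(sweep(bonds, 2,
                           as.numeric(oh[i, c("x", "y", "z")]))^2)))
  }, 0)
  data.frame(chain = oh$chain, resno = oh$resno, distance = dist,
             stringsAsFactors = FALSE)
}

#' Bdamage: packing-density-normalized B-factors
#'
#' For each heavy atom, the packing density is the count of other heavy
#' atoms within \code{r_pd} Angstrom (minimum image). Atoms are binned by
#' packing density into equal-width bins (bins with fewer than
#' \code{min_bin} atoms are merged with their neighbour), and Bdamage is
#' the atom's B-factor divided by the mean B-factor of its bin. Elevated
#' values flag disorder beyond what the atom's environment predicts.
#' Occupancies are assumed to be unity; real-data users should refit B
#' with unit occupancy first.
#'
#' @param structure An \code{xtal_structure}.
#' @param r_pd Packing-density radius in Angstrom.
#' @param n_bins Number of equal-width packing-density bins.
#' @param min_bin Minimum bin population before merging.
#' @return Data frame with atom identity, \code{packing_density},
#'   \code{bin}, and \code{bdamage}.
#' @export
compute_bdamage <- function(structure, r_pd = 7.0, n_bins = 10,
                            min_bin = 10) {
  a <- analysis_atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  pd <- integer(n)
  for (i in seq_len(n)) {
    d <- min_image_dist(structure$cell, xyz[i, ], xyz)
    pd[i] <- sum(d <= r_pd) - 1L          # exclude the atom itself
  }
  rng <- range(pd)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, n)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(pd, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    # merge under-populated bins into their lower neighbour (or upward at
    # the bottom) until every occupied bin holds at least min_bin atoms
    repeat {
      cnt <- table(bin)
      small <- names(cnt)[cnt < min_bin]
      if (length(small) == 0 || length(cnt) == 1) break
      b <- as.integer(small[1])
      lev <- sort(unique(bin))
      tgt <- if (b == min(lev)) min(lev[lev > b]) else max(lev[lev < b])
      bin[bin == b] <- tgt
    }
  }
  if (length(unique(bin)) == 1 && rng[1] != rng[2])
    warning("single packing-density bin: Bdamage degenerates to B/mean(B)")
  mean_b <- tapply(a$b, bin, mean)
  out <- a[, c("serial", "name", "resname", "chain", "resno")]
  out$packing_density <- pd
  out$bin <- as.integer(factor(bin))
  out$bdamage <- a$b / as.numeric(mean_b[as.character(bin)])
  attr(out, "r_pd") <- r_pd
  out
}

#' Relative Bdamage change between two structures
#'
#' For each atom a present in both records, the relative change is
#' [Bdamage(a, later) - Bdamage(a, first)] / Bdamage(a, first).
#'
#' @param first,later Outputs of \code{\link{compute_bdamage}} for the
#'   first and a later dataset (matched by chain, resno, atom name).
#' @return Data frame with atom identity and \code{relative_change}.
#' @export
bdamage_relative_change <- function(first, later) {
  key <- function(x) paste(x$chain, x$resno, x$name)
  m <- match(key(later), key(first))
  ok <- !is.na(m)
  data.frame(chain = later$chain[ok], resno = later$resno[ok],
             name = later$name[ok],
             relative_change = (later$bdamage[ok] - first$bdamage[m[ok]]) /
               first$bdamage[m[ok]],
             stringsAsFactors = FALSE)
}

#' Correlate Tyr hydroxyl D_loss with a structural covariate
#'
#' Per dataset, fits Tyr OH D_loss against a per-residue covariate (ring
#' solvent accessibility, disulfide distance, Bdamage change, ...) by
#' ordinary least squares and reports R-squared. Datasets with fewer than
#' \code{min_tyr} tyrosines are skipped with a message.
#'
#' @param tab A D_loss table.
#' @param covariate Data frame with chain, resno and a value column (last
#'   column used).
#' @param min_tyr Minimum number of Tyr residues required.
#' @return Data frame with dataset, n and r_squared for each dataset
#'   carrying enough tyrosines.
#' @export
correlate_context <- function(tab, covariate, min_tyr = 8) {
  oh <- tab[tab$resname == "TYR" & tab$atom == "OH", , drop = FALSE]
  val <- covariate[[ncol(covariate)]]
  key <- paste(covariate$chain, covariate$resno)
  res <- list()
  for (ds in unique(oh$dataset)) {
    sub <- oh[oh$dataset == ds, ]
    m <- match(paste(sub$chain, sub$resno), key)
    ok <- !is.na(m)
    if (sum(ok) < min_tyr) {
      message("dataset ", ds, " skipped: only ", sum(ok),
              " Tyr residues (need ", min_tyr, ")")
      next
    }
    r <- linear_r2(val[m[ok]], sub$dloss_raw[ok])
    res[[length(res) + 1L]] <- data.frame(dataset = ds, n = sum(ok),
                                          r_squared = r$statistic)
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(dataset = character(), n = integer(), r_squared = numeric())
}
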