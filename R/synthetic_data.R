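# Idealized side-chain templates (local Cartesian coordinates, Angstrom).
# Geometry uses standard bond lengths (C-C 1.52, ring 1.39, C-OH 1.37,
# carboxylate C-O 1.25, C-S 1.8, S-S 2.05); torsional realism is not
# needed, only correct atom taxonomy and plausible interatomic distances.
residue_template <- function(resname) {
  hex <- function() {
    ang <- c(270, 330, 30, 90, 150, 210) * pi / 180
    m <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
    rownames(m) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    m
  }
  mk <- function(...) {
    v <- list(...)
    m <- do.call(rbind, v)
    m
  }
  switch(resname,
    TYR = rbind(CA = c(1.24, -3.78, 0), CB = c(0, -2.90, 0), hex(),
                OH = c(0, 2.76, 0)),
    PHE = rbind(CA = c(1.24, -3.78, 0), CB = c(0, -2.90, 0), hex()),
    GLU = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG = c(2.03, 1.43, 0),
             CD = c(3.55, 1.43, 0), OE1 = c(4.17, 2.51, 0),
             OE2 = c(4.17, 0.35, 0)),
    GLN = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG = c(2.03, 1.43, 0),
             CD = c(3.55, 1.43, 0), OE1 = c(4.17, 2.51, 0),
             NE2 = c(4.17, 0.35, 0)),
    ASP = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG = c(2.03, 1.43, 0),
             OD1 = c(3.15, 1.98, 0), OD2 = c(1.32, 2.42, 0)),
    ASN = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG = c(2.03, 1.43, 0),
             OD1 = c(3.15, 1.98, 0), ND2 = c(1.32, 2.42, 0)),
    SER = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), OG = c(2.03, 1.33, 0)),
    THR = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), OG1 = c(2.03, 1.33, 0),
             CG2 = c(2.10, -1.25, 0.45)),
    LEU = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG = c(2.03, 1.43, 0),
             CD1 = c(3.55, 1.50, 0.20), CD2 = c(1.45, 2.50, 0.60)),
    ILE = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), CG1 = c(2.03, 1.43, 0),
             CG2 = c(1.10, -1.25, 0.60), CD1 = c(3.55, 1.50, 0.20)),
    CYS = mk(CA = c(0, 0, 0), CB = c(1.52, 0, 0), SG = c(2.30, 1.65, 0)),
    stop("no template for residue ", resname)
  )
}

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
}

# A placement unit: one or more residues placed together rigidly.
# Returns list(resnames, atom data per residue: names + xyz).
unit_tyr_glu_pair <- function() {
  tyr <- residue_template("TYR")
  glu <- residue_template("GLU") %*% t(rot_z(150))
  rownames(glu) <- rownames(residue_template("GLU"))
  # translate Glu so OE1 sits 2.9 A from the Tyr hydroxyl oxygen
  target <- tyr["OH", ] + c(2.51, 1.45, 0)
  glu <- sweep(glu, 2, target - glu["OE1", ], "+")
  list(resnames = c("TYR", "GLU"), coords = list(tyr, glu))
}

unit_disulfide_pair <- function() {
  c1 <- residue_template("CYS")
  c2 <- residue_template("CYS") %*% t(rot_z(180))
  rownames(c2) <- rownames(c1)
  target <- c1["SG", ] + c(1.45, 1.45, 0)    # S-S bond length 2.05 A
  c2 <- sweep(c2, 2, target - c2["SG", ], "+")
  list(resnames = c("CYS", "CYS"), coords = list(c1, c2))
}

unit_single <- function(resname) {
  list(resnames = resname, coords = list(residue_template(resname)))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a toy P1 structure with known damage-relevant features
#'
#' Builds a self-contained single-chain model holding idealized residues
#' of every type the damage analysis exercises: Tyr (two engineered with
#' the OH oxygen 2.9 Angstrom from a Glu carboxylate oxygen, at least two
#' isolated), Phe, Glu, Asp, Asn, Gln, Ser, Thr, Leu, Ile and disulfide-
#' bonded Cys pairs, each residue carrying its C-alpha. Units are placed
#' on a cubic lattice of 15 Angstrom slots inside a P1 cell sized to hold
#' them, shuffled and randomly rotated (seeded); occupancies are 1 and
#' B-factors are drawn uniformly from [10, 25] Angstrom^2.
#'
#' @param n_residues_per_type Residues per type (>= 1; the hydrogen-bond
#'   and isolated Tyr guarantees need >= 2).
#' @param seed Integer RNG seed; the same seed reproduces the structure
#'   exactly.
#' @param cell_edge Optional cubic cell edge (Angstrom); errors if too
#'   small for the requested residue count.
#' @return An \code{xtal_structure}.
#' @export
make_toy_structure <- function(n_residues_per_type = 2, seed = 1,
                               cell_edge = NULL) {
  stopifnot(n_residues_per_type >= 1)
  n <- n_residues_per_type
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  units <- c(
    replicate(2, unit_tyr_glu_pair(), simplify = FALSE),
    replicate(max(1, floor(n / 2)), unit_disulfide_pair(), simplify = FALSE),
    replicate(max(n, 2), unit_single("TYR"), simplify = FALSE),  # isolated Tyr
    if (n > 2) replicate(n - 2, unit_single("GLU"), simplify = FALSE),
    unlist(lapply(c("PHE", "ASP", "ASN", "GLN", "SER", "THR", "LEU", "ILE"),
                  function(r) replicate(n, unit_single(r), simplify = FALSE)),
           recursive = FALSE)
  )
  slot <- 15
  naxis <- ceiling(length(units)^(1 / 3))
  edge <- naxis * slot
  if (!is.null(cell_edge)) {
    if (cell_edge < edge)
      stop(sprintf("cell edge %.1f A too small for %d residues per type (need >= %.1f A)",
                   cell_edge, n, edge))
    edge <- cell_edge
    naxis <- floor(edge / slot)
    if (naxis^3 < length(units)) stop("cell too small for requested count")
  }
  cell <- unit_cell(edge, edge, edge, 90, 90, 90)

  centres <- as.matrix(expand.grid(seq_len(naxis), seq_len(naxis),
                                   seq_len(naxis))) * slot - slot / 2
  centres <- centres[sample(nrow(centres), length(units)), , drop = FALSE]

  rows <- list()
  serial <- 0L
  resno <- 0L
  for (u in seq_along(units)) {
    un <- units[[u]]
    allxyz <- do.call(rbind, un$coords)
    ctr <- colMeans(allxyz)
    rot <- random_rotation()
    for (k in seq_along(un$resnames)) {
      resno <- resno + 1L
      xyz <- sweep(un$coords[[k]], 2, ctr) %*% t(rot)
      xyz <- sweep(xyz, 2, centres[u, ], "+")
      nm <- rownames(un$coords[[k]])
      for (i in seq_along(nm)) {
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = nm[i], altloc = "",
          resname = un$resnames[k], chain = "A", resno = resno,
          element = element_from_name(nm[i]),
          x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
          occ = 1, b = stats::runif(1, 10, 25), het = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$n_electrons <- element_electrons(atoms$element)
  new_structure(atoms, cell, identifier = sprintf("toy_n%d_seed%d", n, seed))
}

#' Define a synthetic damage scenario
#'
#' Specifies which atom types lose occupancy at which per-dose rate (the
#' cleavage-like damage model), an optional rigid per-dose displacement of
#' Tyr/Phe aromatic rings (the disorder model), the amplitude noise level,
#' and the dose ladder. Losses and displacements accumulate linearly with
#' dataset index.
#'
#' @param target_spec Data frame with columns resname, atom,
#'   loss_per_dose (fractional occupancy lost per dose step); may have
#'   zero rows.
#' @param ring_displacement Rigid displacement (Angstrom per dose step)
#'   applied to Tyr and Phe ring atoms along a random per-residue
#'   direction.
#' @param noise_sigma Gaussian amplitude noise, as a fraction of the mean
#'   first-dataset amplitude.
#' @param doses Dose ladder in MGy (first = reference dataset).
#' @param seed Integer RNG seed.
#' @param dmin High-resolution limit (Angstrom) for the simulated data.
#' @return A \code{damage_scenario} list.
#' @export
damage_scenario <- function(target_spec = data.frame(resname = character(),
                                                     atom = character(),
                                                     loss_per_dose = numeric()),
                            ring_displacement = 0, noise_sigma = 0,
                            doses = c(0.5, 2, 4, 8), seed = 1, dmin = 2.8) {
  stopifnot(noise_sigma >= 0, ring_displacement >= 0,
            all(diff(doses) > 0), length(doses) >= 2)
  nstep <- length(doses) - 1
  if (nrow(target_spec) > 0) {
    if (any(target_spec$loss_per_dose < 0 | target_spec$loss_per_dose > 1))
      stop("loss_per_dose must lie in [0, 1]")
    if (any(target_spec$loss_per_dose * nstep > 1))
      stop("cumulative occupancy loss exceeds 1 over the dose ladder")
  }
  sc <- list(target_spec = target_spec, ring_displacement = ring_displacement,
             noise_sigma = noise_sigma, doses = doses, seed = seed,
             dmin = dmin)
  class(sc) <- "damage_scenario"
  sc
}

.ring_atoms <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")

#' Simulate a damage series with known ground truth
#'
#' Dataset 1 is the structure-factor set of the intact structure (its
#' calculated phases are retained as the fixed phase set). Each later
#' dataset n is the amplitude set of a modified model: targeted atoms have
#' occupancy reduced by (n-1) * loss_per_dose, and Tyr/Phe ring atoms are
#' rigidly displaced by (n-1) * ring_displacement Angstrom along a fixed
#' random per-residue direction. Gaussian noise of sd noise_sigma * mean
#' first-dataset amplitude is added to the later amplitudes and clipped at
#' zero. Every modification is recorded in the ground-truth table.
#'
#' @param structure An \code{xtal_structure} (e.g. from
#'   \code{\link{make_toy_structure}}).
#' @param scenario A \code{damage_scenario}.
#' @return List with \code{series} (a \code{dose_series}) and \code{truth}
#'   (data.frame: serial, chain, resno, resname, atom, dataset, dose_MGy,
#'   occ_loss, displacement).
#' @export
make_damage_series <- function(structure, scenario) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(scenario$seed)

  nset <- length(scenario$doses)
  ref <- structure_factors_from_model(structure, scenario$dmin, label = "ds1")
  amp <- matrix(0, nrow(ref$hkl), nset)
  amp[, 1] <- ref$amp[, 1]
  mean_amp <- mean(amp[, 1])

  a <- structure$atoms
  ts <- scenario$target_spec
  target_idx <- if (nrow(ts) > 0)
    which(paste(a$resname, a$name) %in% paste(ts$resname, ts$atom)) else
    integer(0)
  rate <- numeric(nrow(a))
  if (length(target_idx)) {
    m <- match(paste(a$resname, a$name)[target_idx],
               paste(ts$resname, ts$atom))
    rate[target_idx] <- ts$loss_per_dose[m]
  }
  ring_idx <- which(a$resname %in% c("TYR", "PHE") & a$name %in% .ring_atoms)
  ring_res <- unique(paste(a$chain, a$resno)[ring_idx])
  dirs <- matrix(stats::rnorm(3 * length(ring_res)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rownames(dirs) <- ring_res

  truth <- list()
  for (j in 2:nset) {
    step <- j - 1
    mod <- structure
    occ_loss <- pmin(rate * step, 1)
    mod$atoms$occ <- pmax(0, 1 - occ_loss)
    disp <- numeric(nrow(a))
    if (scenario$ring_displacement > 0 && length(ring_idx)) {
      d <- scenario$ring_displacement * step
      shift <- dirs[paste(a$chain, a$resno)[ring_idx], , drop = FALSE] * d
      mod$atoms[ring_idx, c("x", "y", "z")] <-
        mod$atoms[ring_idx, c("x", "y", "z")] + shift
      disp[ring_idx] <- d
    }
    fn <- structure_factors_from_model(mod, scenario$dmin)
    stopifnot(nrow(fn$hkl) == nrow(ref$hkl))
    f <- fn$amp[, 1]
    if (scenario$noise_sigma > 0)
      f <- pmax(0, f + stats::rnorm(length(f),
                                    sd = scenario$noise_sigma * mean_amp))
    amp[, j] <- f
    truth[[j - 1]] <- data.frame(
      serial = a$serial, chain = a$chain, resno = a$resno,
      resname = a$resname, atom = a$name, dataset = paste0("ds", j),
      dose_MGy = scenario$doses[j], occ_loss = occ_loss,
      displacement = disp, stringsAsFactors = FALSE)
  }
  labels <- paste0("ds", seq_len(nset))
  refl <- new_reflection_set(ref$hkl, amp, ref$phase, scenario$dmin,
                             structure$cell, labels = labels)
  truth <- do.call(rbind, truth)
  if (nrow(ts) > 0)
    attr(truth, "expected_order") <-
      paste(ts$resname, ts$atom)[order(-ts$loss_per_dose)]
  list(series = dose_series(structure, refl, scenario$doses, labels),
       truth = truth, scenario = scenario)
}

#' Write a synthetic damage series as a fixture directory
#'
#' Emits model.pdb, reflections.tsv, truth.tsv and manifest.yaml (seeds and
#' scenario parameters) into a directory; optionally the difference maps in
#' CCP4 format. Re-emission with the same inputs overwrites
#' deterministically.
#'
#' @param sim Output of \code{\link{make_damage_series}}.
#' @param dir Output directory (created if needed).
#' @param maps Also write per-dose difference maps as CCP4 files.
#' @return The directory path, invisibly.
#' @export
emit_fixture <- function(sim, dir, maps = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(sim$series$structure, file.path(dir, "model.pdb"))
  write_reflections(sim$series$refl, file.path(dir, "reflections.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- sim$scenario
  yaml::write_yaml(list(
    seed = sc$seed, doses_MGy = sc$doses, dmin = sc$dmin,
    noise_sigma = sc$noise_sigma, ring_displacement = sc$ring_displacement,
    targets = if (nrow(sc$target_spec)) sc$target_spec else "none",
    cell_edge = sim$series$structure$cell$a,
    n_atoms = nrow(sim$series$structure$atoms)
  ), file.path(dir, "manifest.yaml"))
  if (maps) {
    for (j in 2:length(sim$series$doses)) {
      m <- difference_map(sim$series$refl, j)
      write_ccp4_map(m, file.path(dir, sprintf("diff_ds%d.ccp4", j)))
    }
  }
  invisible(dir)
}
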