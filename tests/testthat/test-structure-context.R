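test_that("Tyr hydroxyl hydrogen bonds use a strict distance cutoff", {
  atoms <- rbind(
    atom_row("OH", "TYR", 1, 0, 0, 0),
    atom_row("OE1", "GLU", 2, 3.5, 0, 0),     # within 4 A
    atom_row("OH", "TYR", 3, 0, 10, 0),
    atom_row("OD1", "ASP", 4, 4.0, 10, 0))    # exactly 4 A: excluded
  s <- mk_struct(atoms, 30)
  hb <- find_tyr_hbonds(s)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_resno, 1)
  expect_equal(hb$acceptor_resname, "GLU")
  expect_equal(hb$distance, 3.5)
  # partition: bonded and non-bonded Tyr sets are disjoint and exhaustive
  expect_setequal(c(attr(hb, "hbonded"), attr(hb, "non_hbonded")),
                  c("A:1", "A:3"))
  expect_length(intersect(attr(hb, "hbonded"), attr(hb, "non_hbonded")), 0)
  # no acidic residues -> empty pair list is valid
  s2 <- mk_struct(atom_row("OH", "TYR", 1, 0, 0, 0), 30)
  expect_equal(nrow(find_tyr_hbonds(s2)), 0)
})

test_that("SASA of an isolated atom matches the analytic sphere", {
  s <- mk_struct(atom_row("CA", "GLY", 1, 10, 10, 10), 40)  # C, r = 1.70
  a <- solvent_accessibility(s)
  expect_lt(abs(a$area - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)
  # two atoms 100 A apart: no occlusion
  s2 <- xtal_structure(rbind(atom_row("CA", "GLY", 1, 10, 10, 10),
                             atom_row("CA", "GLY", 2, 110, 10, 10)),
                       unit_cell(200, 200, 200))
  a2 <- solvent_accessibility(s2)
  expect_equal(a2$area[1], a2$area[2])
  expect_lt(abs(a2$area[1] - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.01)
})

test_that("two-sphere overlap matches the spherical-cap closed form", {
  # equal expanded radii R: each sphere loses a cap of height R - d/2
  R <- 1.70 + 1.4
  for (d in c(2.0, 3.5, 5.0)) {
    s <- xtal_structure(rbind(atom_row("CA", "GLY", 1, 20, 20, 20),
                              atom_row("CA", "GLY", 2, 20 + d, 20, 20)),
                        unit_cell(60, 60, 60))
    a <- solvent_accessibility(s)
    analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    expect_lt(abs(a$area[1] - analytic) / analytic, 0.015)
  }
})

test_that("SASA decreases monotonically as a second atom approaches", {
  dists <- seq(6, 2, by = -0.5)
  areas <- vapply(dists, function(d) {
    s <- xtal_structure(rbind(atom_row("CA", "GLY", 1, 20, 20, 20),
                              atom_row("CA", "GLY", 2, 20 + d, 20, 20)),
                        unit_cell(60, 60, 60))
    solvent_accessibility(s)$area[1]
  }, 0)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("carboxylate removal deletes the CO2 moieties before SASA", {
  s <- make_toy_structure(1, seed = 13)
  a <- solvent_accessibility(s, remove_carboxylates = TRUE)
  expect_false(any(a$resname == "GLU" & a$name %in% c("CD", "OE1", "OE2")))
  expect_false(any(a$resname == "ASP" & a$name %in% c("CG", "OD1", "OD2")))
  full <- solvent_accessibility(s)
  # Tyr ring area never decreases when occluders are removed
  r1 <- tyr_ring_sasa(full)
  r2 <- tyr_ring_sasa(a)
  expect_true(all(r2$area >= r1$area - 1e-9))
  # ring sum covers the 7 ring + OH atoms
  n_tyr <- length(unique(s$atoms$resno[s$atoms$resname == "TYR"]))
  expect_equal(nrow(r1), n_tyr)
})

test_that("unknown elements are rejected by the SASA calculation", {
  atoms <- atom_row("XX", "UNK", 1, 5, 5, 5)
  atoms$element <- "C"
  s <- mk_struct(atoms, 20)
  s$atoms$element <- "XX"
  expect_error(solvent_accessibility(s), "XX")
})

test_that("disulfide distances use bonded SG pairs and midpoints", {
  atoms <- rbind(
    atom_row("SG", "CYS", 1, 0, 0, 0),
    atom_row("SG", "CYS", 2, 2.05, 0, 0),    # bonded: midpoint (1.025, 0, 0)
    atom_row("OH", "TYR", 3, 1.025, 6, 0))
  s <- mk_struct(atoms, 40)
  d <- disulfide_distance(s)
  expect_equal(d$distance, 6.0)
  # nearest-S alternative
  d2 <- disulfide_distance(s, to_midpoint = FALSE)
  expect_equal(d2$distance, sqrt(1.025^2 + 36))
  # SG pair at 3.5 A is not a disulfide
  s2 <- mk_struct(rbind(atom_row("SG", "CYS", 1, 0, 0, 0),
                        atom_row("SG", "CYS", 2, 3.5, 0, 0),
                        atom_row("OH", "TYR", 3, 0, 6, 0)), 40)
  expect_equal(nrow(disulfide_distance(s2)), 0)
})

test_that("with two disulfides the minimum midpoint distance is reported", {
  atoms <- rbind(
    atom_row("SG", "CYS", 1, 0, 0, 0), atom_row("SG", "CYS", 2, 2, 0, 0),
    atom_row("SG", "CYS", 3, 20, 0, 0), atom_row("SG", "CYS", 4, 22, 0, 0),
    atom_row("OH", "TYR", 5, 16, 0, 0))
  s <- mk_struct(atoms, 60)
  d <- disulfide_distance(s)
  # midpoints at x = 1 and x = 21; brute-force minimum is 5
  expect_equal(d$distance, 5)
})

test_that("Bdamage is 1 for uniform B and matches the change formula", {
  s <- make_toy_structure(1, seed = 21)
  s$atoms$b <- 18
  bd <- compute_bdamage(s)
  expect_equal(bd$bdamage, rep(1, nrow(bd)), tolerance = 1e-12)
  # relative change: 1.2 -> 1.8 gives 0.5
  first <- bd[1, ]; first$bdamage <- 1.2
  later <- bd[1, ]; later$bdamage <- 1.8
  expect_equal(bdamage_relative_change(first, later)$relative_change, 0.5)
})

test_that("packing densities match an O(n^2) pairwise oracle", {
  s <- make_toy_structure(1, seed = 22)
  bd <- compute_bdamage(s, r_pd = 7)
  a <- dlossr:::analysis_atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  oracle <- vapply(seq_len(nrow(a)), function(i) {
    d <- vapply(seq_len(nrow(a)), function(j) {
      df <- orth_to_frac(s$cell, matrix(xyz[j, ] - xyz[i, ], 1))
      df <- df - round(df)
      sqrt(sum(frac_to_orth(s$cell, df)^2))
    }, 0)
    sum(d <= 7) - 1L
  }, 0L)
  expect_equal(bd$packing_density, oracle)
})

test_that("Bdamage is invariant under rigid rotation and translation", {
  # a compact molecule in a roomy cell, so no pair distance is affected
  # by the periodic wrap (the invariance does not hold for cell-filling
  # contents, where rotation changes which images are adjacent)
  toy <- make_toy_structure(1, seed = 23)
  big <- unit_cell(150, 150, 150)
  s <- xtal_structure(toy$atoms, big)
  bd1 <- compute_bdamage(s)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s2 <- xtal_structure(s$atoms, big)
  s2$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(3, -2, 5), "+")
  bd2 <- compute_bdamage(s2)
  expect_equal(bd1$packing_density, bd2$packing_density)
  expect_equal(bd1$bdamage, bd2$bdamage, tolerance = 1e-12)
})

test_that("context correlation recovers affine relations and skips small sets", {
  # build a minimal D_loss table with 10 Tyr residues
  tab <- data.frame(chain = "A", resno = 1:10, resname = "TYR", atom = "OH",
                    dataset = "ds2", dloss_raw = seq(0.1, 1, 0.1))
  cov <- data.frame(chain = "A", resno = 1:10,
                    value = 3 * seq(0.1, 1, 0.1) + 2)
  r <- correlate_context(tab, cov)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # independent covariate: mean R2 over replicates is low at n = 30
  set.seed(6)
  r2s <- replicate(10, {
    tab2 <- data.frame(chain = "A", resno = 1:30, resname = "TYR",
                       atom = "OH", dataset = "ds2", dloss_raw = rnorm(30))
    cov2 <- data.frame(chain = "A", resno = 1:30, value = rnorm(30))
    correlate_context(tab2, cov2)$r_squared
  })
  expect_lt(mean(r2s), 0.1)
  # fewer than 8 Tyr -> dataset skipped
  expect_message(r3 <- correlate_context(tab[1:7, ], cov), "skipped")
  expect_equal(nrow(r3), 0)
})
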