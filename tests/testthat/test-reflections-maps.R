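test_that("reflection text files round-trip; bad input is rejected", {
  cell <- unit_cell(12, 13, 14)
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", "H K L F1 F2 PHI1",
               "1 0 0 3.0 2.5 10", "0 1 0 4.0 3.5 200", "1 1 0 5.0 4.5 355"), f)
  r <- read_reflections(f, cell)
  expect_equal(nrow(r$hkl), 3)
  expect_equal(ncol(r$amp), 2)
  expect_equal(r$amp[1, ], c(F1 = 3.0, F2 = 2.5))

  # a written set re-reads identically
  f2 <- tempfile()
  write_reflections(r, f2)
  r2 <- read_reflections(f2, cell)
  expect_equal(r2$hkl, r$hkl)
  expect_equal(unname(r2$amp), unname(r$amp), tolerance = 1e-8)

  writeLines(c("H K L F1 F2 PHI1", "1 0 0 3 2 10", "1 0 0 4 3 20"), f)
  expect_error(read_reflections(f, cell), "duplicate")
  writeLines(c("H K L F1 F2 PHI1", "1 0 0 -3 2 10"), f)
  expect_error(read_reflections(f, cell), "negative")
  # a reflection missing one dataset amplitude is dropped with a message
  writeLines(c("H K L F1 F2 PHI1", "1 0 0 3 2 10", "0 1 0 4 NA 20"), f)
  expect_message(r3 <- read_reflections(f, cell), "dropped")
  expect_equal(nrow(r3$hkl), 1)
})

test_that("amplitude scaling matches the closed form and a grid-search oracle", {
  r <- random_reflections(seed = 8)
  # F_n = 2 F_1 exactly -> k = 0.5
  r$amp[, 2] <- 2 * r$amp[, 1]
  rs <- scale_amplitudes(r, 2, quiet = TRUE)
  expect_equal(attr(rs, "scales")[["2"]], 0.5)
  expect_equal(rs$amp[, 2], r$amp[, 1], ignore_attr = TRUE)
  # F_n = F_1 -> k = 1
  r$amp[, 2] <- r$amp[, 1]
  expect_equal(attr(scale_amplitudes(r, 2, quiet = TRUE), "scales")[["2"]], 1)
  # seeded random data: k agrees with brute-force 1-D minimization
  r <- random_reflections(seed = 13)
  k <- attr(scale_amplitudes(r, 2, quiet = TRUE), "scales")[["2"]]
  obj <- function(kk) sum((kk * r$amp[, 2] - r$amp[, 1])^2)
  kgrid <- seq(k - 0.5, k + 0.5, length.out = 20001)
  expect_lt(abs(kgrid[which.min(vapply(kgrid, obj, 0))] - k), 1e-4)
  expect_lt(abs(optimize(obj, c(0.01, 100))$minimum - k), 1e-6)
  r$amp[, 2] <- 0
  expect_error(scale_amplitudes(r, 2), "all-zero")
})

test_that("difference map: zero coefficients give the zero map", {
  r <- random_reflections(seed = 2)
  r$amp[, 2] <- r$amp[, 1]
  m <- difference_map(r, 2, c(8, 10, 10))
  expect_equal(max(abs(m$values)), 0)
  expect_equal(m$sigma, 0)
})

test_that("difference map matches the analytic single-reflection form", {
  cell <- unit_cell(10, 10, 10)
  r <- dlossr:::new_reflection_set(matrix(c(1, 0, 0), 1), cbind(1, 0), 0,
                                   dmin = 3, cell)
  m <- difference_map(r, 2, c(8, 8, 8), scale = FALSE)  # dF = -1, phi = 0
  x <- (0:7) / 8
  expect_equal(m$values[, 1, 1], -(2 / cell$volume) * cos(2 * pi * x),
               tolerance = 1e-12)
  # every y,z column is identical for an (h,0,0) reflection
  expect_equal(m$values[, 3, 5], m$values[, 1, 1], tolerance = 1e-12)
})

test_that("FFT synthesis equals direct summation everywhere", {
  for (seed in 1:5) {
    r <- random_reflections(n = 20, seed = seed,
                            cell = unit_cell(11, 12, 13, 80, 95, 102))
    g <- c(10, 10, 12)
    mf <- difference_map(r, 2, g)
    md <- difference_map_direct(r, 2, g)
    expect_lt(max(abs(mf$values - md$values)) / max(abs(md$values)), 1e-6)
  }
})

test_that("map synthesis is linear and odd in the coefficients", {
  r <- random_reflections(n = 15, ndat = 3, seed = 21)
  g <- c(10, 12, 12)
  # linearity: dF_2 + dF_3 map equals sum of individual maps
  rab <- r
  rab$amp <- cbind(r$amp[, 1], r$amp[, 2] + r$amp[, 3] - r$amp[, 1])
  m_ab <- difference_map(rab, 2, g, scale = FALSE)
  m_a <- difference_map(r, 2, g, scale = FALSE)
  m_b <- difference_map(r, 3, g, scale = FALSE)
  expect_lt(max(abs(m_ab$values - m_a$values - m_b$values)) /
              max(abs(m_ab$values)), 1e-6)
  # negation: swapping datasets negates the map exactly
  rneg <- r
  rneg$amp <- cbind(r$amp[, 2], r$amp[, 1])
  m_neg <- difference_map(rneg, 2, g, scale = FALSE)
  expect_equal(m_neg$values, -m_a$values, tolerance = 1e-12)
})

test_that("grid coarser than Nyquist is rejected with the required minimum", {
  r <- random_reflections(seed = 3)  # dmin 3, cell 12x13x14
  expect_error(difference_map(r, 2, c(6, 10, 10)), "minimum")
})

test_that("model structure factors obey centering, shift and additivity", {
  cell <- unit_cell(10, 10, 10)
  at <- atom_row("CA", "GLY", 1, 0, 0, 0)
  s0 <- xtal_structure(transform(at, b = 0), cell)
  r0 <- structure_factors_from_model(s0, dmin = 3)
  # atom at origin, B = 0: all phases 0, amplitudes = n_electrons
  expect_lt(max(pmin(r0$phase, 360 - r0$phase)), 1e-6)
  expect_equal(unname(r0$amp[, 1]), rep(6, nrow(r0$hkl)), tolerance = 1e-10)

  # shift theorem: translating by fractional delta shifts phases by
  # 2 pi h . delta and leaves amplitudes unchanged
  delta <- c(0.15, 0.25, 0.05)
  s1 <- xtal_structure(transform(at, x = delta[1] * 10, y = delta[2] * 10,
                                 z = delta[3] * 10, b = 0), cell)
  r1 <- structure_factors_from_model(s1, dmin = 3)
  expect_equal(unname(r1$amp[, 1]), unname(r0$amp[, 1]), tolerance = 1e-10)
  expected <- (r0$phase + 360 * as.vector(r0$hkl %*% delta)) %% 360
  dphi <- abs(r1$phase - expected) %% 360
  expect_lt(max(pmin(dphi, 360 - dphi)), 1e-6)

  # additivity: two-atom F equals the sum of single-atom F's per reflection
  a2 <- rbind(atom_row("CA", "GLY", 1, 1.2, 3.4, 5.6, b = 12),
              atom_row("OG", "SER", 2, 7.8, 2.1, 4.3, b = 18))
  s12 <- xtal_structure(a2, cell)
  sA <- xtal_structure(a2[1, ], cell)
  sB <- xtal_structure(a2[2, ], cell)
  fAB <- dlossr:::complex_structure_factors(s12, dlossr:::hemisphere_hkl(cell, 3))
  fA <- dlossr:::complex_structure_factors(sA, dlossr:::hemisphere_hkl(cell, 3))
  fB <- dlossr:::complex_structure_factors(sB, dlossr:::hemisphere_hkl(cell, 3))
  expect_lt(max(Mod(fAB$f - fA$f - fB$f)), 1e-9)
})

test_that("reducing one atom's occupancy puts the difference-map minimum there", {
  s <- make_toy_structure(1, seed = 6)
  target <- which(s$atoms$resname == "GLU" & s$atoms$name == "OE1")[1]
  mod <- s
  mod$atoms$occ[target] <- 0.5
  r1 <- structure_factors_from_model(s, dmin = 2.5)
  r2 <- structure_factors_from_model(mod, dmin = 2.5)
  refl <- dlossr:::new_reflection_set(r1$hkl, cbind(r1$amp, r2$amp),
                                      r1$phase, 2.5, s$cell)
  m <- difference_map(refl, 2)
  idx <- which(m$values == min(m$values), arr.ind = TRUE)[1, ]
  peak <- frac_to_orth(s$cell, (idx - 1) / m$grid)
  spacing <- max(c(s$cell$a, s$cell$b, s$cell$c) / m$grid)
  d <- min_image_dist(s$cell, as.numeric(s$atoms[target, c("x", "y", "z")]),
                      peak)
  expect_lt(d, sqrt(3) * spacing + 1e-9)
})

test_that("CCP4 maps round-trip to single precision and reject non-maps", {
  set.seed(9)
  cell <- unit_cell(15, 16, 17, 88, 92, 95)
  m <- mk_map(array(rnorm(6 * 8 * 10), dim = c(6, 8, 10)), cell)
  f <- tempfile(fileext = ".ccp4")
  write_ccp4_map(m, f)
  m2 <- read_ccp4_map(f)
  expect_lt(max(abs(m2$values - m$values)), 1e-6)
  expect_equal(m2$cell$a, cell$a, tolerance = 1e-5)
  expect_equal(m2$cell$gamma, cell$gamma, tolerance = 1e-4)

  f2 <- tempfile()
  writeLines("this is not a map", f2)
  expect_error(read_ccp4_map(f2), "mode")
})
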