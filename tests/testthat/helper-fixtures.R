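# Shared fixture builders. Everything is generated in code at test time.

# A small hand-placed structure in a cubic P1 cell.
mk_struct <- function(atoms, edge = 20, ...) {
  xtal_structure(atoms, unit_cell(edge, edge, edge), ...)
}

atom_row <- function(name, resname, resno, x, y, z, chain = "A", b = 15,
                     occ = 1) {
  data.frame(name = name, resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, b = b, occ = occ,
             stringsAsFactors = FALSE)
}

# A seeded random hemisphere reflection set with ndat amplitude columns.
random_reflections <- function(n = 20, ndat = 2, cell = unit_cell(12, 13, 14),
                               dmin = 3, seed = 1) {
  set.seed(seed)
  hkl <- unique(matrix(sample(-3:3, n * 6, replace = TRUE), ncol = 3))
  hemi <- hkl[, 3] > 0 | (hkl[, 3] == 0 & hkl[, 2] > 0) |
    (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] > 0)
  hkl <- hkl[hemi, , drop = FALSE]
  hkl <- hkl[seq_len(min(n, nrow(hkl))), , drop = FALSE]
  amp <- matrix(abs(rnorm(nrow(hkl) * ndat, mean = 5)), ncol = ndat)
  dlossr:::new_reflection_set(hkl, amp, runif(nrow(hkl), 0, 360), dmin, cell)
}

# A density map built directly from a value array.
mk_map <- function(values, cell) dlossr:::new_density_map(values, cell)
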