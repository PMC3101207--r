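test_that("a PDB with N complete residues yields N-1 peptide units", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, helix_xyz(5))
  ch <- read_pdb_backbone(path)
  expect_s3_class(ch, "backbone_chain")
  expect_equal(ch$L, 5)
  expect_length(fatsurf:::unit_ids(ch), 4)
})

test_that("a residue missing a backbone atom is excluded with a warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, helix_xyz(5),
                drop_atoms = data.frame(resno = 3, elety = "O"))
  expect_warning(ch <- suppressMessages(read_pdb_backbone(path)),
                 "excluded")
  expect_equal(ch$L, 4)                      # residues 1,2,4,5 kept
  expect_length(fatsurf:::unit_ids(ch), 2)   # units (1,2) and (4,5)
  expect_equal(length(unique(ch$residues$segment)), 2)
})

test_that("an unparseable chain with no usable units is a hard error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(path, helix_xyz(2),
                drop_atoms = data.frame(resno = c(1, 2), elety = c("O", "N")))
  expect_error(suppressWarnings(read_pdb_backbone(path)))
})

test_that("altloc atoms resolve to the highest occupancy", {
  path <- withr::local_tempfile(fileext = ".pdb")
  xyz <- helix_xyz(3)
  shifted <- xyz$CA[2, ] + c(5, 0, 0)
  extra <- pdb_atom_line(99, "CA", "ALA", "A", 2, shifted, occ = 0.3,
                         alt = "B")
  write_toy_pdb(path, xyz, extra_lines = NULL)
  lines <- readLines(path)
  writeLines(append(lines, extra, after = 5), path)
  ch <- read_pdb_backbone(path)
  expect_equal(as.numeric(ch$residues$CA[2, ]), as.numeric(xyz$CA[2, ]),
               tolerance = 1e-3)
})

test_that("an ideal 20-residue helix parses with all planarity checks clean", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_ideal_helix_pdb(20, path)
  expect_no_warning(ch <- read_pdb_backbone(path))
  expect_length(fatsurf:::unit_ids(ch), 19)
  expect_equal(length(unique(ch$residues$segment)), 1)
  # consecutive units share a CA coordinate exactly
  for (k in 1:18)
    expect_identical(ch$units[[k]]$ca2, ch$units[[k + 1]]$ca1)
})

test_that("amide hydrogen placement follows the DSSP rule", {
  expect_equal(place_amide_hydrogen(c(1.33, 0, 0), c(0, 0, 0), c(0, 1.23, 0)),
               c(1.33, -1, 0))
  p <- c(1.2, 3.4, 5.6)
  expect_equal(place_amide_hydrogen(c(1.33, 0, 0), c(0, 0, 0), c(0, 1.23, 0),
                                    existing = p), p)
  expect_true(all(is.na(place_amide_hydrogen(c(0, 0, 0), c(1, 0, 0),
                                             c(2, 0, 0), proline = TRUE))))
})

test_that("Kabsch-Sander energy matches hand-computed values", {
  # symmetric geometry: N and H mirror images through the O-C axis
  expect_equal(kabsch_sander_energy(c(0, 0, 0), c(2, 0, 0),
                                    c(1, 2, 0), c(1, -2, 0)), 0)
  # linear favorable bond: r_ON=2.95, r_OH=1.95, r_CH=3.18, r_CN=4.18
  e <- kabsch_sander_energy(c(0, 0, 0), c(-1.23, 0, 0),
                            c(2.95, 0, 0), c(1.95, 0, 0))
  expect_equal(e, 0.084 * 332 * (1 / 2.95 + 1 / 3.18 - 1 / 1.95 - 1 / 4.18))
  expect_equal(e, -2.749938, tolerance = 1e-5)
  expect_lt(e, 0)
  # joint translation leaves the energy unchanged
  s <- c(1000, 1000, 1000)
  expect_equal(kabsch_sander_energy(c(0, 0, 0) + s, c(-1.23, 0, 0) + s,
                                    c(2.95, 0, 0) + s, c(1.95, 0, 0) + s), e)
  # clash sentinel, no division blow-up
  expect_identical(kabsch_sander_energy(c(0, 0, 0), c(1, 0, 0),
                                        c(0, 0, 0), c(1, 1, 0)), Inf)
})

test_that("bond inference on an ideal helix gives exclusively span-4 bonds", {
  ch <- dihedral_chain(20, -57, -47)
  bonds <- infer_hydrogen_bonds(ch)
  expect_equal(nrow(bonds), 15)
  expect_true(all(bonds$donor - bonds$acceptor == 4))
  expect_true(all(bonds$energy < -0.5))
  # single-unit chain: no bonds
  expect_equal(nrow(infer_hydrogen_bonds(dihedral_chain(2, -57, -47))), 0)
})

test_that("bond set is invariant under rigid motion", {
  ch <- dihedral_chain(15, -57, -47)
  b0 <- infer_hydrogen_bonds(ch)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  ch2 <- transform_chain(ch, R, shift = c(10, -20, 5))
  b1 <- infer_hydrogen_bonds(ch2)
  expect_equal(b0$donor, b1$donor)
  expect_equal(b0$acceptor, b1$acceptor)
  expect_equal(b0$energy, b1$energy, tolerance = 1e-9)
})

test_that("stub uniqueness holds after inference", {
  ch <- jitter_structure(dihedral_chain(25, -57, -47), 0.3, seed = 4)
  bonds <- infer_hydrogen_bonds(ch)
  expect_false(anyDuplicated(bonds$donor) > 0)
  expect_false(anyDuplicated(bonds$acceptor) > 0)
})

test_that("DSSP parsing honours cutoff, bifurcation rule and malformed lines", {
  ch <- dihedral_chain(8, -57, -47)
  lines <- c("==== synthetic ====",
             "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
             # residue 6 donates to 1 (-2.0) and to 2 (-1.0): keep best only
             paste0(formatC(sprintf("%5d%5d %s %s", 1, 1, "A", "A"),
                            width = -39),
                    sprintf("%6d,%4.1f", 0, 0), sprintf("%6d,%4.1f", 5, -2.0),
                    sprintf("%6d,%4.1f", 0, 0), sprintf("%6d,%4.1f", 0, 0)),
             paste0(formatC(sprintf("%5d%5d %s %s", 6, 6, "A", "A"),
                            width = -39),
                    sprintf("%6d,%4.1f", -5, -2.0), sprintf("%6d,%4.1f", 0, 0),
                    sprintf("%6d,%4.1f", -4, -1.0), sprintf("%6d,%4.1f", 0, 0)),
             # record below |cutoff|: excluded
             paste0(formatC(sprintf("%5d%5d %s %s", 3, 3, "A", "A"),
                            width = -39),
                    sprintf("%6d,%4.1f", 4, -0.2), sprintf("%6d,%4.1f", 0, 0),
                    sprintf("%6d,%4.1f", 0, 0), sprintf("%6d,%4.1f", 0, 0)),
             "garbage line that cannot be parsed")
  path <- withr::local_tempfile(fileext = ".dssp")
  writeLines(lines, path)
  expect_warning(bonds <- read_dssp_bonds(path, ch), "malformed")
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$donor, 6)
  expect_equal(bonds$acceptor, 1)
  expect_equal(bonds$energy, -2)
})

test_that("inferred and DSSP-rendered bonds round-trip identically", {
  ch <- dihedral_chain(20, -57, -47)
  bonds <- infer_hydrogen_bonds(ch)
  path <- withr::local_tempfile(fileext = ".dssp")
  render_dssp(ch, bonds, path)
  b2 <- read_dssp_bonds(path, ch)
  expect_equal(b2$donor, bonds$donor)
  expect_equal(b2$acceptor, bonds$acceptor)
  expect_equal(b2$energy, bonds$energy, tolerance = 0.05 + 1e-9)
})
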