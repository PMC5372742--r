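# Published per-subunit reference values for the Glu97Gln QueF
# disulfides (PDB 5UDG): torsions in, strain energies out. Frozen here
# as the geometry module's external anchors.
published_energies <- c(A = 15.023, B = 16.120, C = 14.772,
                        D = 18.584, E = 13.938)

test_that("torsion follows the right-handed convention", {
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # hand-computed cross-product oracle: n1 = (0,0,1), n2 = (0,-1,0),
  # (n1 x n2).b2hat = +1, n1.n2 = 0 => atan2(1, 0) = +90 degrees
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)), 90)
  # reversing the point order returns the same value
  expect_equal(dihedral_angle(c(1, 0, 1), c(1, 0, 0), c(0, 0, 0),
                              c(0, 1, 0)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "degenerate",
               class = "qf_validation_error")
  expect_error(dihedral_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                              c(-1, 0, 0)), "collinear",
               class = "qf_validation_error")
})

test_that("torsion agrees with an independent implementation on random points", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_lt(wrap_diff(mine, ref[1]), 1e-6)
  }
})

test_that("chi_angles recovers generator targets and swaps symmetrically", {
  target <- c(-59.85, -126.76, -105.12, 176.01, -66.90)
  co <- build_disulfide_coords(disulfide_spec(target[1], target[2],
                                              target[3], target[4],
                                              target[5]))
  chi <- chi_angles(co$res1, co$res2)
  expect_lt(max(abs(chi - target)), 1e-6)
  # argument swap exchanges primed/unprimed, keeps chi3
  rev <- chi_angles(co$res2, co$res1)
  expect_equal(unname(rev),
               unname(chi[c("chi1p", "chi2p", "chi3", "chi2", "chi1")]),
               tolerance = 1e-9)
  # missing atom is reported by residue and atom
  maimed <- co$res1
  maimed$xyz <- maimed$xyz[c("N", "CA", "CB"), ]
  expect_error(chi_angles(maimed, co$res2), "SG",
               class = "qf_validation_error")
})

test_that("sign classification reproduces the anchored -LHHook call", {
  cls <- classify_configuration(-59.85, -126.76, -105.12, 176.01, -66.90)
  expect_equal(cls$config_class, "-LHHook")
  expect_equal(cls$sign_pattern, c("-", "-", "-", "+", "-"))
  expect_false(cls$ambiguous)
})

test_that("rule-forced classes come out as derived", {
  # all-negative: chi2/chi2p share chi3's sign -> Spiral, LH, prefix -
  expect_equal(classify_configuration(-60, -80, -85, -80, -60)$config_class,
               "-LHSpiral")
  # chi2/chi2p share a positive chi3 -> RH Spiral with - prefix
  expect_equal(classify_configuration(-60, 100, 85, 100, -60)$config_class,
               "-RHSpiral")
  # both chi2 opposite to chi3 -> Staple
  expect_equal(classify_configuration(60, 80, -85, 80, 60)$config_class,
               "+LHStaple")
  # hooks keep mixed prefix order; spirals collapse it
  expect_equal(classify_configuration(-60, -80, -85, 80, 60)$config_class,
               "-/+LHHook")
  expect_equal(classify_configuration(60, -80, -85, 80, -60)$config_class,
               "+/-LHHook")
  expect_equal(classify_configuration(60, -80, -85, -80, -60)$config_class,
               "-/+LHSpiral")
  expect_equal(classify_configuration(-60, -80, -85, -80, 60)$config_class,
               "-/+LHSpiral")
})

test_that("the taxonomy has exactly 20 classes over all sign patterns", {
  grid <- expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1),
                      s4 = c(-1, 1), s5 = c(-1, 1))
  classes <- apply(grid, 1, function(s)
    classify_configuration(60 * s[1], 80 * s[2], 85 * s[3], 80 * s[4],
                           60 * s[5])$config_class)
  expect_equal(length(unique(classes)), 20)
})

test_that("near-zero angles flag the call as ambiguous", {
  cls <- classify_configuration(-0.2, -80, -85, -80, -60)
  expect_true(cls$ambiguous)
  expect_equal(cls$config_class, "-LHSpiral")
  expect_false(classify_configuration(-0.7, -80, -85, -80, -60)$ambiguous)
})

test_that("strain energy matches the published per-subunit values", {
  d <- glu97gln_dihedrals()
  e <- strain_energy(d$chi1, d$chi2, d$chi3, d$chi2p, d$chi1p)
  expect_equal(unname(e), unname(published_energies), tolerance = 0.005 / 15)
  expect_lt(max(abs(e - published_energies)), 0.005)
})

test_that("strain energy has the analytic value at torsion minima", {
  # threefold terms vanish at -60/-60/-60; 2*chi3 = -180 kills the
  # twofold term; 3*chi3 = -270 leaves exactly the 2.51 constant
  expect_equal(strain_energy(-60, -60, -90, -60, -60), 2.51)
  expect_equal(strain_energy(60, 180, -90, 180, 60), 2.51)
})

test_that("strain energy is bounded, symmetric and periodic", {
  set.seed(11)
  for (i in 1:200) {
    a <- runif(5, -180, 180)
    e <- strain_energy(a[1], a[2], a[3], a[4], a[5])
    expect_gte(e, 0)
    expect_lte(e, 84.5)
    # primed/unprimed swap symmetry
    expect_equal(strain_energy(a[5], a[4], a[3], a[2], a[1]), e)
    # 120-degree periodicity in the threefold angles
    expect_equal(strain_energy(a[1] + 120, a[2] - 120, a[3],
                               a[4] + 240, a[5] - 240), e,
                 tolerance = 1e-9)
    # chi3 mixed periodicity: full 360 period
    expect_equal(strain_energy(a[1], a[2], a[3] + 360, a[4], a[5]), e,
                 tolerance = 1e-9)
  }
})

test_that("bridge detection applies the cutoff, greediness and canonical order", {
  pdb <- tempfile(fileext = ".pdb")
  write_disulfide_pdb(glu97gln_specs(), pdb, seed = 3)
  m <- read_pdb(pdb)
  pairs <- detect_disulfides(m)
  expect_equal(nrow(pairs), 5)
  expect_true(all(pairs$res1 == 55 & pairs$res2 == 99))
  expect_true(all(pairs$chain1 == pairs$chain2))
  expect_equal(pairs$chain1, LETTERS[1:5])
  # tight cutoff removes everything (bonds are 2.03-2.07 A)
  expect_equal(nrow(detect_disulfides(m, geometry_config(2.0))), 0)
  # far-apart thiols are not bridged
  far <- read_pdb(write_fixture_pdb(two_cys_lines(ss = 3.5)))
  expect_equal(nrow(detect_disulfides(far)), 0)
  near <- read_pdb(write_fixture_pdb(two_cys_lines(ss = 2.05)))
  expect_equal(nrow(detect_disulfides(near)), 1)
})

test_that("planted bridges plus free cysteines are detected exactly", {
  # 5 planted bridges; then strip SG from a residue to make free/broken
  # cysteines that must not pair
  set.seed(9)
  specs <- lapply(1:5, function(i) {
    a <- runif(5, -180, 180)
    disulfide_spec(a[1], a[2], a[3], a[4], a[5])
  })
  pdb <- tempfile(fileext = ".pdb")
  write_disulfide_pdb(specs, pdb, seed = 4)
  lines <- readLines(pdb)
  # drop one SG of a sixth, unbridged cysteine pair placed far away
  free <- sub("^ATOM  ", "ATOM  ",
              vapply(1:3, function(k)
                pdb_atom_line(900 + k, c("N", "CA", "CB")[k], "CYS", "Z",
                              7, c(500 + k, 500, 500)), character(1)))
  writeLines(c(lines[-length(lines)], free, "END"), pdb)
  m <- read_pdb(pdb)
  expect_warning(pairs <- detect_disulfides(m), "no SG")
  expect_equal(nrow(pairs), 5)
})

test_that("analyze_structure assembles full per-bridge records", {
  pdb <- tempfile(fileext = ".pdb")
  write_disulfide_pdb(glu97gln_specs(), pdb, seed = 12)
  ana <- analyze_structure(read_pdb(pdb))
  expect_s3_class(ana, "disulfide_analysis")
  expect_equal(nrow(ana), 5)
  expect_true(all(ana$config_class == "-LHHook"))
  expect_true(all(ana$sign_pattern == "-,-,-,+,-"))
  # energies match the published column within what 3-decimal PDB
  # coordinates can carry (quantization moves angles by ~0.05 degrees)
  expect_lt(max(abs(ana$strain_energy_kJ_mol - published_energies)), 0.05)
  expect_equal(ana$ss_bond_length, glu97gln_dihedrals()$ss_bond_length,
               tolerance = 2e-3)
  # no cysteines -> empty result, not an error
  gly <- sub(" CYS ", " GLY ", two_cys_lines())
  empty <- analyze_structure(read_pdb(write_fixture_pdb(gly)))
  expect_equal(nrow(empty), 0)
})

test_that("analysis via specs is exact against the published energies", {
  # in-memory route (no file quantization): build -> measure -> energy
  d <- glu97gln_dihedrals()
  for (i in seq_len(nrow(d))) {
    co <- build_disulfide_coords(glu97gln_specs()[[i]])
    chi <- chi_angles(co$res1, co$res2)
    e <- strain_energy(chi[1], chi[2], chi[3], chi[4], chi[5])
    expect_lt(abs(e - published_energies[i]), 0.005)
  }
})

test_that("geometry reports carry fixed precision and provenance", {
  pdb <- tempfile(fileext = ".pdb")
  write_disulfide_pdb(glu97gln_specs()[1:2], pdb, seed = 5)
  out <- tempfile()
  paths <- write_geometry_report(analyze_structure(read_pdb(pdb)), out,
                                 seed = 5)
  expect_true(all(file.exists(paths)))
  lines <- readLines(paths[["tsv"]])
  expect_match(lines[1], "^# queftools .*seed=5")
  tab <- read.delim(paths[["tsv"]], comment.char = "#")
  expect_equal(nrow(tab), 2)
  # angles to 2 decimals, energies to 3
  expect_match(lines[3], "-\\d+\\.\\d\\d\t")
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(length(js$disulfides), 2)
})
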