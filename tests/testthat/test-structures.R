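toy_pair <- function(...) {
  make_toy_structure_pair(..., dir = file.path(tempdir(),
                                               paste0("toy", sample.int(1e6, 1))))
}

test_that("PDB reading resolves altlocs and takes the first model", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  N   GLY A   2       3.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      99.000  99.000  99.000  1.00  0.00           N",
    "ENDMDL",
    "END"), pdb)
  s <- read_structure(pdb)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.0)             # occupancy 0.6 copy kept
  expect_false(any(s$atoms$x == 99))  # model 1 only
  expect_equal(length(unique(s$atoms$resno)), 2)
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty))
})

test_that("site extraction honours the radius boundary and whole residues", {
  tp <- toy_pair(n_site_residues = 5, n_distant_residues = 4, seed = 2)
  s <- read_structure(tp$path_a)
  site <- extract_site(s, "LIG", 10)
  expect_equal(nrow(site$residues), 5)
  # monotone in radius
  site_small <- extract_site(s, "LIG", 4)
  site_large <- extract_site(s, "LIG", 40)
  key <- function(x) paste(x$residues$chain, x$residues$resno)
  expect_true(all(key(site_small) %in% key(site)))
  expect_true(all(key(site) %in% key(site_large)))
  expect_equal(nrow(site_large$residues), 9)
  expect_error(extract_site(s, "XYZ", 10), "available HET")
})

test_that("self-comparison gives identity 100 and rmsd 0", {
  tp <- toy_pair(n_site_residues = 8, n_distant_residues = 3, seed = 5)
  s <- read_structure(tp$path_a)
  site <- extract_site(s, "LIG", 10)
  cmp <- compare_sites(site, site, sasa = FALSE)
  expect_equal(cmp$identity, 100)
  expect_lt(cmp$rmsd, 1e-12)
})

test_that("renamed and rigidly moved copies report the planted identity and rmsd", {
  tp <- toy_pair(n_site_residues = 10, n_distant_residues = 5,
                 identity_fraction = 0.9, rotation_angle = 40,
                 translation = c(5, -3, 8), seed = 7)
  sa <- read_structure(tp$path_a)
  sb <- read_structure(tp$path_b)
  site_a <- extract_site(sa, "LIG", 10)
  site_b <- extract_site(sb, "LIG", 10)
  for (mode in c("heavy", "backbone", "ca")) {
    cmp <- compare_sites(site_a, site_b, atoms = mode, sasa = FALSE)
    expect_equal(cmp$identity, tp$truth$identity)
    # rigid motion is removed by superposition, up to PDB coordinate rounding
    expect_lt(cmp$rmsd, 0.01)
  }
  # a pure rotation alone is also removed
  tp2 <- toy_pair(n_site_residues = 6, n_distant_residues = 2,
                  rotation_angle = 25, seed = 8)
  cmp2 <- compare_sites(extract_site(read_structure(tp2$path_a), "LIG", 10),
                        extract_site(read_structure(tp2$path_b), "LIG", 10),
                        sasa = FALSE)
  expect_equal(cmp2$identity, 100)
  expect_lt(cmp2$rmsd, 0.01)
})

test_that("Kabsch RMSD is symmetric and rigid-motion invariant", {
  set.seed(10)
  x <- matrix(rnorm(30), 10)
  y <- x + matrix(rnorm(30, 0, 0.5), 10)
  f1 <- kabsch_superpose(x, y)
  f2 <- kabsch_superpose(y, x)
  expect_equal(f1$rmsd, f2$rmsd, tolerance = 1e-9)
  rot <- phorescreen:::random_rotation()
  y2 <- sweep(y %*% t(rot), 2, c(4, 4, 4), "+")
  expect_equal(kabsch_superpose(x, y2)$rmsd, f1$rmsd, tolerance = 1e-9)
})

test_that("Shrake-Rupley SASA matches analytic spheres", {
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  got <- shrake_rupley_sasa(one)$total
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # two atoms far apart: additive
  two <- data.frame(element = c("C", "C"), x = c(0, 100), y = 0, z = 0)
  expect_equal(shrake_rupley_sasa(two)$total, 2 * got, tolerance = 0.01)
  # fully overlapping atoms: one sphere in total
  dup <- data.frame(element = c("C", "C"), x = 0, y = 0, z = 0)
  expect_equal(shrake_rupley_sasa(dup)$total, got, tolerance = 0.01)
  # convergence: doubling the point count changes totals by < 0.5%
  set.seed(12)
  blob <- data.frame(element = sample(c("C", "N", "O"), 12, replace = TRUE),
                     x = rnorm(12, sd = 2), y = rnorm(12, sd = 2),
                     z = rnorm(12, sd = 2))
  s1 <- shrake_rupley_sasa(blob, n_points = 960)$total
  s2 <- shrake_rupley_sasa(blob, n_points = 1920)$total
  expect_lt(abs(s1 - s2) / s2, 0.005)
  expect_error(shrake_rupley_sasa(data.frame(element = "Xx", x = 0, y = 0,
                                             z = 0)),
               "van der Waals")
})

test_that("affinity pocket description finds a clearance maximum between walls", {
  tp <- toy_pair(n_site_residues = 10, n_distant_residues = 2, seed = 9)
  s <- read_structure(tp$path_a)
  site <- extract_site(s, "LIG", 10)
  # residues 1-3 act as the loop wall, residue 6 as the lysine stand-in
  pocket <- describe_affinity_pocket(site, 1:3, 6)
  expect_gt(pocket$radius, 1)
  d_loop <- min(sqrt(colSums((t(as.matrix(pocket$loop_atoms[, c("x", "y", "z")])) -
                                pocket$centroid)^2)))
  d_lys <- min(sqrt(colSums((t(as.matrix(pocket$lys_atoms[, c("x", "y", "z")])) -
                               pocket$centroid)^2)))
  expect_gt(d_loop, 1)
  expect_gt(d_lys, 1)
  expect_error(describe_affinity_pocket(site, 1:3, 999), "absent")
  # loop and lysine in direct contact: radius ~ 0, not an exception
  touching <- site
  touching$atoms <- site$atoms[site$atoms$resno %in% c(1, 2), , drop = FALSE]
  touching$atoms$x <- round(touching$atoms$x / 3)
  touching$atoms$y <- round(touching$atoms$y / 3)
  pk <- describe_affinity_pocket(touching, 1, 2, grid_step = 0.5)
  expect_gte(pk$radius, 0)
})
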