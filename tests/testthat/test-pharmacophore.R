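test_that("builtin screening models carry the published constants", {
  m1 <- builtin_model("ROCK1")
  expect_length(m1$points, 4)
  expect_equal(m1$points[[1]]$center, c(50.3, 98.8, 23.7))
  expect_equal(m1$points[[1]]$radius, 0.5)
  expect_equal(m1$points[[1]]$weight, 10)
  expect_equal(m1$points[[4]]$center, c(48.7, 104.7, 34.2))
  expect_equal(m1$hbond_constraint$resnum, 156L)
  expect_equal(m1$hbond_constraint$min_geometry_weight, 0.005)
  m2 <- builtin_model("ROCK2")
  expect_equal(m2$points[[1]]$center, c(-5.8, -5.0, -34.8))
  expect_equal(m2$points[[1]]$weight, 10)
  expect_equal(m2$points[[3]]$center, c(-5.4, -3.9, -34.2))
  expect_equal(m2$hbond_constraint$resnum, 172L)
  expect_equal(sum(vapply(m2$points, `[[`, 0, "weight")), 25)
  expect_error(builtin_model("ROCK3"))
})

test_that("model JSON round-trips exactly and validates its schema", {
  for (nm in c("ROCK1", "ROCK2")) {
    m <- builtin_model(nm)
    path <- tempfile(fileext = ".json")
    write_model_json(m, path)
    m2 <- read_model_json(path)
    expect_equal(lapply(m$points, `[[`, "center"),
                 lapply(m2$points, `[[`, "center"))
    expect_equal(lapply(m$points, `[[`, "radius"),
                 lapply(m2$points, `[[`, "radius"))
    expect_equal(m$hbond_constraint$weight, m2$hbond_constraint$weight)
  }
  bad <- tempfile(fileext = ".json")
  writeLines('{"name":"x"}', bad)
  expect_error(read_model_json(bad), "missing field")
  writeLines(paste0('{"name":"x","points":[{"kind":"Zap","center":[0,0,0],',
                    '"radius":1,"weight":1,"label":"a"}]}'), bad)
  expect_error(read_model_json(bad), "unknown feature kind")
})

test_that("feature perception types aromatic rings, acceptors and donors", {
  benzene <- perceive_features(parse_smiles("c1ccccc1", gen3d = TRUE))
  expect_equal(as.data.frame(benzene)$kind, "AromaticRing")
  ring_atoms <- as.integer(strsplit(benzene$atoms[1], ",")[[1]])
  expect_length(ring_atoms, 6)

  pyridine <- perceive_features(parse_smiles("c1ccncc1", gen3d = TRUE))
  expect_setequal(as.data.frame(pyridine)$kind, c("HBA", "AromaticRing"))
  expect_equal(sum(pyridine$kind == "HBA"), 1)

  phenol <- perceive_features(parse_smiles("Oc1ccccc1", gen3d = TRUE))
  expect_setequal(as.data.frame(phenol)$kind, c("HBA", "HBD", "AromaticRing"))
  # the hydroxyl oxygen is both donor and acceptor at the same position
  hba <- phenol[phenol$kind == "HBA", c("x", "y", "z")]
  hbd <- phenol[phenol$kind == "HBD", c("x", "y", "z")]
  expect_equal(unlist(hba), unlist(hbd), ignore_attr = TRUE)

  # 2D-only input is refused
  expect_error(perceive_features(parse_smiles("c1ccccc1")), "no conformer")
})

test_that("aromatic ring centroid sits at the unweighted atom centroid", {
  mol <- parse_smiles("c1ccccc1", gen3d = TRUE)
  g <- phorescreen:::heavy_graph(mol)
  feats <- perceive_features(mol)
  ctr <- colMeans(as.matrix(g$atoms[, c("x", "y", "z")]))
  expect_equal(unlist(feats[1, c("x", "y", "z")]), ctr,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("consensus map recovers planted points from jittered ligands", {
  model <- builtin_model("ROCK1")
  pxyz <- t(vapply(model$points, `[[`, numeric(3), "center"))
  pkind <- vapply(model$points, `[[`, "", "kind")
  set.seed(21)
  sets <- lapply(1:10, function(i) {
    ligand_features(pkind, pxyz + matrix(rnorm(12, 0, 0.2), ncol = 3))
  })
  cm <- consensus_map(sets, merge_radius = 1.0, min_support = 0.6)
  expect_length(cm$points, 4)
  got <- t(vapply(cm$points, `[[`, numeric(3), "center"))
  for (i in seq_len(4)) {
    d <- sqrt(rowSums(sweep(got, 2, pxyz[i, ])^2))
    expect_lt(min(d), 0.2)
  }
  # identical ligands: centres exact, radius at the floor
  sets0 <- lapply(1:5, function(i) ligand_features(pkind, pxyz))
  cm0 <- consensus_map(sets0, radius_floor = 0.5)
  expect_equal(vapply(cm0$points, `[[`, 0, "radius"), rep(0.5, 4))
})

test_that("consensus respects support, ligand order and rigid motions", {
  a <- ligand_features(c("AromaticRing", "HBA"), rbind(c(0, 0, 0), c(5, 0, 0)))
  b <- ligand_features(c("AromaticRing", "HBD"), rbind(c(0.2, 0, 0), c(0, 5, 0)))
  cm <- consensus_map(list(a, b), min_support = 1.0)
  expect_length(cm$points, 1)
  expect_equal(cm$points[[1]]$kind, "AromaticRing")
  # permutation invariance
  cm2 <- consensus_map(list(b, a), min_support = 1.0)
  expect_equal(cm$points[[1]]$center, cm2$points[[1]]$center)
  # equivariance under a common rigid motion
  set.seed(3)
  rot <- phorescreen:::random_rotation()
  shift <- c(3, -2, 7)
  move <- function(f) {
    xyz <- sweep(as.matrix(as.data.frame(f)[, c("x", "y", "z")]) %*% t(rot),
                 2, shift, "+")
    ligand_features(as.data.frame(f)$kind, xyz)
  }
  cm3 <- consensus_map(list(move(a), move(b)), min_support = 1.0)
  expect_equal(cm3$points[[1]]$center,
               as.numeric(rot %*% cm$points[[1]]$center + shift),
               tolerance = 1e-10)
  # no shared kinds: empty model with a warning, nothing fabricated
  c1 <- ligand_features("HBA", rbind(c(0, 0, 0)))
  c2 <- ligand_features("HBD", rbind(c(0, 0, 0)))
  expect_warning(cm4 <- consensus_map(list(c1, c2), min_support = 1.0),
                 "no consensus")
  expect_length(cm4$points, 0)
  expect_error(consensus_map(list(), min_support = 0.5), "no feature sets")
  expect_error(consensus_map(list(a), min_support = 1.5), "min_support")
})

test_that("feature perception is invariant to atom reordering", {
  # same molecule entered with different atom orders
  f1 <- perceive_features(parse_smiles("Oc1ccncc1", gen3d = TRUE))
  f2 <- perceive_features(parse_smiles("c1cc(O)ccn1", gen3d = TRUE))
  expect_equal(sort(table(as.data.frame(f1)$kind)),
               sort(table(as.data.frame(f2)$kind)))
})
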