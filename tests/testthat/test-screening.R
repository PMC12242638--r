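model_exact_features <- function(model) {
  ligand_features(vapply(model$points, `[[`, "", "kind"),
                  t(vapply(model$points, `[[`, numeric(3), "center")))
}

test_that("exact placement at the model centres scores the full weight sum", {
  m <- builtin_model("ROCK1")
  f <- model_exact_features(m)
  res <- match_model(f, m, require = "hinge HBA")
  expect_s3_class(res, "match_result")
  expect_equal(res$score, 25)  # 10 + 5 + 5 + 5
  expect_lt(res$rmsd, 1e-9)
  expect_true(all(res$satisfied))
  expect_equal(abs(det(res$rotation)), 1, tolerance = 1e-9)
})

test_that("matching is invariant under rigid motions of the ligand", {
  m <- builtin_model("ROCK2")
  f <- model_exact_features(m)
  set.seed(8)
  for (trial in 1:3) {
    rot <- phorescreen:::random_rotation()
    shift <- runif(3, -50, 50)
    xyz <- sweep(as.matrix(as.data.frame(f)[, c("x", "y", "z")]) %*% t(rot),
                 2, shift, "+")
    res <- match_model(ligand_features(as.data.frame(f)$kind, xyz), m,
                       require = "hinge HBA")
    expect_equal(res$score, 25)
    expect_lt(res$rmsd, 1e-8)
  }
})

test_that("matcher equals the exhaustive oracle on random instances", {
  set.seed(123)
  for (trial in 1:60) {
    inst <- random_match_instance()
    got <- match_model(inst$features, inst$model)
    want <- oracle_match(inst$features, inst$model)
    got_score <- if (is.null(got)) 0 else got$score
    want_score <- if (is.null(want)) 0 else want$score
    expect_equal(got_score, want_score, info = paste("trial", trial))
    if (!is.null(got) && !is.null(want) && want_score > 0) {
      expect_equal(got$correspondence, want$assign,
                   info = paste("assignment, trial", trial))
    }
  }
})

test_that("required points gate the match", {
  m <- builtin_model("ROCK1")
  # no HBA features at all: required hinge HBA is unsatisfiable
  f <- ligand_features(c("AromaticRing", "AromaticRing", "HBD"),
                       t(vapply(m$points[c(3, 4, 1)], `[[`, numeric(3),
                                "center")))
  expect_null(match_model(f, m, require = "hinge HBA"))
  # without the requirement the same features do match
  expect_false(is.null(match_model(f, m)))
  expect_error(match_model(f, m, require = "nope"), "not in model")
})

test_that("score is monotone under model-point deletion", {
  m <- builtin_model("ROCK1")
  set.seed(31)
  for (trial in 1:10) {
    inst <- random_match_instance(max_features = 6, max_points = 4)
    full <- match_model(inst$features, m)
    full_score <- if (is.null(full)) 0 else full$score
    for (drop in seq_along(m$points)) {
      sub <- pharmacophore_model("sub", lapply(m$points[-drop], function(p) {
        list(kind = p$kind, center = p$center, radius = p$radius,
             weight = p$weight, label = p$label)
      }))
      res <- match_model(inst$features, sub)
      expect_lte(if (is.null(res)) 0 else res$score, full_score)
    }
  }
})

test_that("superposition recovers exact transforms and never reflects", {
  set.seed(14)
  for (trial in 1:20) {
    x <- matrix(rnorm(9, sd = 4), 3)          # 3 non-collinear points
    rot <- phorescreen:::random_rotation()
    shift <- runif(3, -10, 10)
    y <- sweep(x %*% t(rot), 2, shift, "+")
    fit <- kabsch_superpose(x, y)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_lt(max(abs(fit$transform(x) - y)), 1e-9)
  }
  # mirrored configuration: proper rotation enforced, rmsd > 0
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  y <- x; y[, 3] <- -y[, 3]
  fit <- kabsch_superpose(x, y)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("hinge H-bond gate applies distance and angle cutoffs", {
  h <- c(0, 0, 0); donor <- c(0, 0, 1)
  expect_true(check_hinge_hbond(c(0, 0, -1.9), h, donor))   # 1.9 A, 180 deg
  expect_false(check_hinge_hbond(c(0, 0, -4.0), h, donor))  # too far
  expect_false(check_hinge_hbond(c(2.0, 0, 0), h, donor))   # 90 deg
  # boundary angle: exactly 120 degrees passes
  acc <- 2.0 * c(sin(120 * pi / 180), 0, cos(120 * pi / 180))
  expect_true(check_hinge_hbond(acc, h, donor))
})

test_that("library screening ranks by score, rmsd, then id, no-match last", {
  m <- builtin_model("ROCK1")
  exact <- model_exact_features(m)
  no_hba <- ligand_features("AromaticRing", rbind(c(0, 0, 0)))
  partial <- ligand_features(
    c("HBA", "AromaticRing"),
    rbind(m$points[[1]]$center, m$points[[3]]$center))
  ranked <- screen_library(list(good = exact, dead = no_hba, part = partial), m)
  expect_equal(ranked$compound_id, c("good", "part", "dead"))
  expect_equal(ranked$score, c(25, 15, 0))
  expect_equal(ranked$rank, 1:3)
  expect_error(screen_library(list(), m), "empty library")
})

test_that("screening scores are rigid-motion invariant across the library", {
  m <- builtin_model("ROCK1")
  lib <- make_planted_feature_library(m, n_actives = 5, n_decoys = 10,
                                      jitter_sigma = 0.3, seed = 4)
  r1 <- screen_library(lib$library, m)
  set.seed(99)
  rot <- phorescreen:::random_rotation()
  shift <- c(11, -7, 3)
  moved <- lapply(lib$library, function(f) {
    xyz <- sweep(as.matrix(as.data.frame(f)[, c("x", "y", "z")]) %*% t(rot),
                 2, shift, "+")
    ligand_features(as.data.frame(f)$kind, xyz)
  })
  r2 <- screen_library(moved, m)
  expect_equal(setNames(r2$score, r2$compound_id)[r1$compound_id],
               setNames(r1$score, r1$compound_id),
               tolerance = 1e-9)
})
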