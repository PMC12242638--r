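# Synthetic data with planted ground truth
# ----------------------------------------
# Generators for every input class the pipeline consumes: activity tables
# with known class composition, clustered point populations with a planted k,
# feature libraries with a planted pharmacophore, and toy two-chain structure
# pairs with known site identity/RMSD. Every generator is a pure function of
# its arguments and seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# small fragment grammar guaranteeing parseable, drug-like SMILES
fragment_grammar_smiles <- function() {
  pre <- c("", "C", "CC", "O", "N", "CO", "CN", "Cl", "FC(F)(F)")
  scaffold <- c("c1ccncc1", "c1ccccc1", "c1ccoc1", "c1ccsc1", "c1cncnc1",
                "c1ccc2ncccc2c1", "C1CCNCC1", "C1CCCCC1")
  post <- c("", "C", "O", "N", "CC", "C(=O)N", "C(=O)O", "CNC")
  g <- expand.grid(pre = pre, scaffold = scaffold, post = post,
                   stringsAsFactors = FALSE)
  unique(paste0(g$pre, g$scaffold, g$post))
}

#' Generate a bioactivity table with known composition
#'
#' Ki/Kd values are drawn log-uniform inside the correct band per class
#' (active <= 100 nM, inactive >= 5000 nM, intermediate strictly between);
#' IC50 rows are potent but excluded-by-type. SMILES come from a bundled
#' fragment grammar and are unique within the table.
#'
#' @param n_active,n_inactive,n_intermediate,n_ic50 class counts.
#' @param seed RNG seed.
#' @param active_nM,inactive_nM the class thresholds the table is built for.
#' @param dir optional output directory; when given, writes `activities.csv`
#'   and `truth.csv` and returns their paths in the result.
#' @return list with `table` (data.frame: compound_id, smiles, standard_type,
#'   standard_value, pchembl_value, target_id), `truth` (compound_id,
#'   true_class), and optionally `paths`.
#' @export
make_activity_table <- function(n_active, n_inactive, n_intermediate = 0,
                                n_ic50 = 0, seed = 1,
                                active_nM = 100, inactive_nM = 5000,
                                dir = NULL) {
  stopifnot(n_active >= 0, n_inactive >= 0, n_intermediate >= 0, n_ic50 >= 0)
  n <- n_active + n_inactive + n_intermediate + n_ic50
  if (n == 0) stop("all class counts are zero")
  pool <- fragment_grammar_smiles()
  if (n > length(pool)) stop("not enough distinct grammar SMILES for n = ", n)
  with_seed(seed, {
    smiles <- sample(pool, n)
    loguni <- function(k, lo, hi) 10^runif(k, log10(lo), log10(hi))
    value <- c(loguni(n_active, 0.1, active_nM),
               loguni(n_inactive, inactive_nM, 1e6),
               loguni(n_intermediate, active_nM * 1.01, inactive_nM * 0.99),
               loguni(n_ic50, 0.1, active_nM))
    type <- c(sample(c("Ki", "Kd"), n_active + n_inactive + n_intermediate,
                     replace = TRUE),
              rep("IC50", n_ic50))
    true_class <- c(rep("active", n_active), rep("inactive", n_inactive),
                    rep("intermediate", n_intermediate),
                    rep("excluded_type", n_ic50))
    ord <- sample(n)
    tab <- data.frame(
      compound_id = sprintf("SYN%04d", seq_len(n)),
      smiles = smiles[ord],
      standard_type = type[ord],
      standard_value = round(value[ord], 4),
      pchembl_value = round(9 - log10(value[ord]), 2),
      target_id = "SYNTARGET",
      stringsAsFactors = FALSE
    )
    truth <- data.frame(compound_id = tab$compound_id,
                        true_class = true_class[ord],
                        stringsAsFactors = FALSE)
    out <- list(table = tab, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      p1 <- file.path(dir, "activities.csv")
      p2 <- file.path(dir, "truth.csv")
      write.csv(tab, p1, row.names = FALSE)
      write.csv(truth, p2, row.names = FALSE)
      out$paths <- c(activities = p1, truth = p2)
    }
    out
  })
}

random_rigid_motion <- function(scale = 20) {
  list(rotation = random_rotation(),
       translation = runif(3, -scale, scale))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$rotation), 2, motion$translation, "+")
}

#' Generate a feature library with a planted pharmacophore
#'
#' Actives place one feature of the right kind at each model point centre
#' plus isotropic Gaussian jitter, add `n_distractors` random extra features,
#' and apply a random rigid motion per compound (screening must be frame
#' free). Decoys follow `decoy_mode`: `scramble_positions` keeps the kind
#' multiset but randomizes the geometry, `drop_required_feature` builds an
#' active-like compound without any hydrogen-bond acceptor, `random_features`
#' draws kinds and positions at random.
#'
#' @param model a `pharmacophore_model` (default the built-in ROCK1 model).
#' @param n_actives,n_decoys library composition (default 20/180).
#' @param jitter_sigma per-axis Gaussian jitter of active features, Angstrom.
#' @param decoy_mode one of "scramble_positions", "drop_required_feature",
#'   "random_features".
#' @param n_distractors extra random features added to every compound.
#' @param seed RNG seed.
#' @return list with `library` (named list of `ligand_features`) and `labels`
#'   (named 0/1 vector, 1 = active).
#' @export
make_planted_feature_library <- function(model = builtin_model("ROCK1"),
                                         n_actives = 20, n_decoys = 180,
                                         jitter_sigma = 0.3,
                                         decoy_mode = c("scramble_positions",
                                                        "drop_required_feature",
                                                        "random_features"),
                                         n_distractors = 3, seed = 1) {
  decoy_mode <- match.arg(decoy_mode)
  stopifnot(n_actives >= 1, n_decoys >= 1, jitter_sigma >= 0)
  pxyz <- t(vapply(model$points, `[[`, numeric(3), "center"))
  pkind <- vapply(model$points, `[[`, "", "kind")
  full_score <- sum(vapply(model$points, `[[`, 0, "weight"))
  # distractor/decoy positions are drawn in the bounding box of a jittered
  # realization, so the spatial scale of both classes tracks the jitter and
  # score distributions converge as the jitter grows
  jitter_box <- function(ref) {
    list(lo = apply(ref, 2, min) - 3, hi = apply(ref, 2, max) + 3)
  }
  rand_pos_in <- function(k, box) cbind(runif(k, box$lo[1], box$hi[1]),
                                        runif(k, box$lo[2], box$hi[2]),
                                        runif(k, box$lo[3], box$hi[3]))
  with_seed(seed, {
    mk_active <- function() {
      xyz <- pxyz + matrix(rnorm(length(pxyz), 0, jitter_sigma), ncol = 3)
      kinds <- pkind
      if (n_distractors > 0) {
        kinds <- c(kinds, sample(FEATURE_KINDS, n_distractors, replace = TRUE))
        xyz <- rbind(xyz, rand_pos_in(n_distractors, jitter_box(xyz)))
      }
      ligand_features(kinds, apply_rigid(xyz, random_rigid_motion()))
    }
    mk_decoy <- switch(decoy_mode,
      scramble_positions = function() {
        # a decoy is an active-like realization whose position-to-kind
        # association is permuted: identical position statistics, scrambled
        # chemistry. Rejection sampling guarantees no decoy fully satisfies
        # the planted model, keeping the labels true by construction.
        kinds <- c(pkind, if (n_distractors > 0)
          sample(FEATURE_KINDS, n_distractors, replace = TRUE))
        for (try in 1:50) {
          ref <- pxyz + matrix(rnorm(length(pxyz), 0, jitter_sigma), ncol = 3)
          pos <- rbind(ref, rand_pos_in(length(kinds) - nrow(ref),
                                        jitter_box(ref)))
          pos <- pos[sample(nrow(pos)), , drop = FALSE]
          cand <- ligand_features(kinds, apply_rigid(pos, random_rigid_motion()))
          m <- match_model(cand, model)
          if (is.null(m) || m$score < full_score) return(cand)
        }
        cand
      },
      drop_required_feature = function() {
        keep <- pkind != "HBA"
        kinds <- pkind[keep]
        xyz <- pxyz[keep, , drop = FALSE] +
          matrix(rnorm(3 * sum(keep), 0, jitter_sigma), ncol = 3)
        if (n_distractors > 0) {
          kinds <- c(kinds, sample(setdiff(FEATURE_KINDS, "HBA"),
                                   n_distractors, replace = TRUE))
          xyz <- rbind(xyz, rand_pos_in(n_distractors, jitter_box(xyz)))
        }
        ligand_features(kinds, apply_rigid(xyz, random_rigid_motion()))
      },
      random_features = function() {
        k <- length(pkind) + n_distractors
        box <- jitter_box(pxyz + matrix(rnorm(length(pxyz), 0, jitter_sigma),
                                        ncol = 3))
        ligand_features(sample(FEATURE_KINDS, k, replace = TRUE),
                        apply_rigid(rand_pos_in(k, box), random_rigid_motion()))
      })
    library <- c(replicate(n_actives, mk_active(), simplify = FALSE),
                 replicate(n_decoys, mk_decoy(), simplify = FALSE))
    names(library) <- c(sprintf("ACT%04d", seq_len(n_actives)),
                        sprintf("DEC%04d", seq_len(n_decoys)))
    labels <- setNames(c(rep(1L, n_actives), rep(0L, n_decoys)), names(library))
    list(library = library, labels = labels)
  })
}

#' Generate Gaussian blob populations with a planted cluster count
#'
#' Blob centres are drawn by rejection sampling until all pairwise distances
#' are at least `separation`; points are isotropic Gaussians (sd `sigma`).
#'
#' @param k_true number of planted clusters (>= 2).
#' @param points_per_cluster points per blob.
#' @param separation minimum centre-to-centre distance (same units as
#'   `sigma`).
#' @param sigma within-blob standard deviation (default 1).
#' @param dimension embedding dimension (default 2).
#' @param seed RNG seed.
#' @return list with `coords` (matrix) and `labels` (integer truth).
#' @export
make_planted_clusters <- function(k_true, points_per_cluster = 30,
                                  separation = 10, sigma = 1, dimension = 2,
                                  seed = 1) {
  stopifnot(k_true >= 2, separation > 0, points_per_cluster >= 1)
  with_seed(seed, {
    box <- separation * k_true
    centers <- matrix(runif(dimension, 0, box), 1)
    tries <- 0
    while (nrow(centers) < k_true) {
      cand <- runif(dimension, 0, box)
      if (min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= separation) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1
      if (tries > 1e5) stop("could not place ", k_true,
                            " centres at separation ", separation)
    }
    coords <- do.call(rbind, lapply(seq_len(k_true), function(k) {
      sweep(matrix(rnorm(points_per_cluster * dimension, 0, sigma),
                   points_per_cluster), 2, centers[k, ], "+")
    }))
    labels <- rep(seq_len(k_true), each = points_per_cluster)
    list(coords = coords, labels = labels, centers = centers)
  })
}

# minimal fixed-width PDB writer for the toy structures
format_pdb_atom <- function(serial, name, resname, chain, resno, xyz, het,
                            element) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Generate a toy structure pair with known site identity and RMSD
#'
#' Structure A holds a three-atom HETATM ligand (resname LIG) at the origin,
#' `n_site_residues` five-atom residues (N, CA, C, O, CB) arranged on a ring
#' 5-8 Angstrom from the ligand, and `n_distant_residues` placed about 30
#' Angstrom away. Structure B is a rigid copy of A in which a fraction
#' `1 - identity_fraction` of site residues is renamed, so a 10-Angstrom site
#' comparison must report `identity = 100 * identity_fraction` and RMSD 0.
#'
#' @param n_site_residues residues within the site (default 10).
#' @param n_distant_residues residues outside it (default 5).
#' @param identity_fraction fraction of site residues keeping their name.
#' @param rotation_angle rigid rotation applied to copy B, degrees about a
#'   seeded random axis.
#' @param translation rigid translation applied to copy B (length 3).
#' @param seed RNG seed.
#' @param dir output directory (created); PDB files are written there.
#' @return list with `path_a`, `path_b` and `truth` (identity percent, rmsd,
#'   n_site_residues, renamed residue numbers).
#' @export
make_toy_structure_pair <- function(n_site_residues = 10,
                                    n_distant_residues = 5,
                                    identity_fraction = 1,
                                    rotation_angle = 0,
                                    translation = c(0, 0, 0),
                                    seed = 1, dir = tempdir()) {
  stopifnot(identity_fraction >= 0, identity_fraction <= 1,
            n_site_residues >= 1)
  resnames <- c("ALA", "LEU", "SER", "VAL", "THR", "PHE", "GLU", "LYS",
                "ASP", "ARG", "ILE", "MET")
  with_seed(seed, {
    site_names <- sample(resnames, n_site_residues, replace = TRUE)
    far_names <- sample(resnames, max(n_distant_residues, 1),
                        replace = TRUE)[seq_len(n_distant_residues)]
    build_residue <- function(center) {
      # alanine-like heavy-atom arrangement around the residue centre
      offs <- rbind(N = c(-1.2, 0.6, 0), CA = c(0, 0, 0), C = c(1.3, 0.5, 0),
                    O = c(1.5, 1.7, 0.3), CB = c(-0.2, -1.0, 1.1))
      sweep(offs, 2, center, "+")
    }
    centers <- lapply(seq_len(n_site_residues), function(i) {
      ang <- 2 * pi * (i - 1) / n_site_residues
      r <- 5 + 3 * (i %% 3) / 2
      c(r * cos(ang), r * sin(ang), (i %% 4) - 1.5)
    })
    far_centers <- lapply(seq_len(n_distant_residues), function(i) {
      ang <- 2 * pi * (i - 1) / max(1, n_distant_residues)
      c(30 * cos(ang), 30 * sin(ang), 5)
    })
    lig_xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0))
    atoms <- list()
    add_res <- function(resname, resno, xyz_mat, het = FALSE,
                        names_ = rownames(xyz_mat),
                        elements = substr(names_, 1, 1)) {
      for (j in seq_len(nrow(xyz_mat))) {
        atoms[[length(atoms) + 1]] <<- list(
          name = names_[j], resname = resname, resno = resno,
          xyz = xyz_mat[j, ], het = het, element = elements[j])
      }
    }
    for (i in seq_len(n_site_residues)) {
      add_res(site_names[i], i, build_residue(centers[[i]]))
    }
    for (i in seq_len(n_distant_residues)) {
      add_res(far_names[i], n_site_residues + i,
              build_residue(far_centers[[i]]))
    }
    add_res("LIG", n_site_residues + n_distant_residues + 1, lig_xyz,
            het = TRUE, names_ = c("C1", "C2", "C3"),
            elements = c("C", "C", "C"))
    write_pdb <- function(path, atoms, motion = NULL, rename = integer()) {
      lines <- character()
      for (s in seq_along(atoms)) {
        at <- atoms[[s]]
        xyz <- at$xyz
        if (!is.null(motion)) xyz <- as.numeric(apply_rigid(rbind(xyz), motion))
        resname <- at$resname
        if (at$resno %in% rename && !at$het) {
          resname <- if (resname == "GLY") "ALA" else "GLY"
        }
        lines <- c(lines, format_pdb_atom(s, at$name, resname, "A", at$resno,
                                          xyz, at$het, at$element))
      }
      writeLines(c(lines, "END"), path)
    }
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    path_a <- file.path(dir, "toy_a.pdb")
    path_b <- file.path(dir, "toy_b.pdb")
    write_pdb(path_a, atoms)
    n_rename <- round((1 - identity_fraction) * n_site_residues)
    renamed <- if (n_rename > 0) sample(seq_len(n_site_residues), n_rename)
               else integer()
    motion <- NULL
    if (rotation_angle != 0 || any(translation != 0)) {
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      th <- rotation_angle * pi / 180
      k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                    -axis[2], axis[1], 0), 3, byrow = TRUE)
      rot <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
      motion <- list(rotation = rot, translation = as.numeric(translation))
    }
    write_pdb(path_b, atoms, motion = motion, rename = renamed)
    list(path_a = path_a, path_b = path_b,
         truth = list(identity = 100 * (n_site_residues - length(renamed)) /
                        n_site_residues,
                      rmsd = 0,
                      n_site_residues = n_site_residues,
                      renamed_resno = sort(renamed)))
  })
}
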