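# Pharmacophore models and ligand features
# ----------------------------------------
# A pharmacophore model is a named set of typed 3D points (hydrogen-bond
# acceptor, donor, aromatic-ring centre) with a tolerance radius and a weight,
# optionally carrying a protein H-bond constraint. Ligand features are
# perceived from 3D conformers with explicit substructure typing rules, and
# consensus maps are elucidated from sets of pre-aligned ligands.

FEATURE_KINDS <- c("HBA", "HBD", "AromaticRing")

new_pharmacophore_point <- function(kind, center, radius, weight, label) {
  stopifnot(kind %in% FEATURE_KINDS, radius > 0, weight > 0,
            length(center) == 3)
  list(kind = kind, center = as.numeric(center), radius = radius,
       weight = weight, label = label)
}

#' Construct a pharmacophore model
#'
#' @param name model name.
#' @param points list of points, each a list with `kind` (one of "HBA",
#'   "HBD", "AromaticRing"), `center` (xyz, Angstrom), `radius` (> 0),
#'   `weight` (> 0) and a unique `label`.
#' @param frame_pdb_id PDB entry defining the coordinate frame (informative).
#' @param hbond_constraint optional list with `chain`, `resnum`, `atom`,
#'   `weight`, `min_geometry_weight`, and optionally resolved 3D positions
#'   `h_pos` and `donor_pos` for geometric checking.
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(name, points, frame_pdb_id = NA_character_,
                                hbond_constraint = NULL) {
  stopifnot(length(points) >= 1)
  pts <- lapply(points, function(p) {
    new_pharmacophore_point(p$kind, p$center, p$radius, p$weight, p$label)
  })
  labels <- vapply(pts, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("point labels must be unique")
  structure(list(name = name, frame_pdb_id = frame_pdb_id, points = pts,
                 hbond_constraint = hbond_constraint),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("Pharmacophore model '", x$name, "' (frame ", x$frame_pdb_id, "), ",
      length(x$points), " points\n", sep = "")
  for (p in x$points) {
    cat(sprintf("  %-12s %-20s center (%.1f, %.1f, %.1f) r %.1f w %g\n",
                p$kind, p$label, p$center[1], p$center[2], p$center[3],
                p$radius, p$weight))
  }
  if (!is.null(x$hbond_constraint)) {
    hb <- x$hbond_constraint
    cat(sprintf("  protein H-bond constraint %s%s:%s, weight %g\n",
                hb$chain %||% "", hb$resnum, hb$atom, hb$weight))
  }
  invisible(x)
}

#' Published four-point ROCK1/ROCK2 screening models
#'
#' Returns the four-point pharmacophore model used for pharmacophore-
#' constrained screening of each ROCK isoform: a hinge hydrogen-bond acceptor
#' (weight 10), an acceptor toward the catalytic lysine (weight 5), an
#' aromatic ring centre at the hinge binder (weight 5), and an aromatic ring
#' centre in the affinity pocket between the glycine-rich loop and the
#' catalytic lysine (weight 5), plus a required protein H-bond to the hinge
#' methionine backbone NH (Met156 in ROCK1, Met172 in ROCK2). Coordinates are
#' in the frame of the named PDB entry (6E9W for ROCK1, 7JNT for ROCK2).
#'
#' @param name "ROCK1" or "ROCK2".
#' @return a `pharmacophore_model`.
#' @export
builtin_model <- function(name = c("ROCK1", "ROCK2")) {
  name <- match.arg(name)
  if (name == "ROCK1") {
    pharmacophore_model(
      name = "ROCK1",
      frame_pdb_id = "6E9W",
      points = list(
        list(kind = "HBA", center = c(50.3, 98.8, 23.7), radius = 0.5,
             weight = 10, label = "hinge HBA"),
        list(kind = "HBA", center = c(50.6, 105.4, 30.1), radius = 0.7,
             weight = 5, label = "Lys HBA"),
        list(kind = "AromaticRing", center = c(50.5, 99.6, 24.9), radius = 2,
             weight = 5, label = "hinge ring"),
        list(kind = "AromaticRing", center = c(48.7, 104.7, 34.2), radius = 2,
             weight = 5, label = "affinity-pocket ring")
      ),
      hbond_constraint = list(chain = "A", resnum = 156L, resname = "MET",
                              atom = "H", weight = 10,
                              min_geometry_weight = 0.005)
    )
  } else {
    pharmacophore_model(
      name = "ROCK2",
      frame_pdb_id = "7JNT",
      points = list(
        list(kind = "HBA", center = c(-5.8, -5.0, -34.8), radius = 0.5,
             weight = 10, label = "hinge HBA"),
        list(kind = "HBA", center = c(-2.3, 2.3, -30.5), radius = 0.7,
             weight = 5, label = "Lys HBA"),
        list(kind = "AromaticRing", center = c(-5.4, -3.9, -34.2), radius = 2,
             weight = 5, label = "hinge ring"),
        list(kind = "AromaticRing", center = c(-1.6, 5.8, -33.1), radius = 2,
             weight = 5, label = "affinity-pocket ring")
      ),
      hbond_constraint = list(chain = "A", resnum = 172L, resname = "MET",
                              atom = "H", weight = 10,
                              min_geometry_weight = 0.005)
    )
  }
}

#' Write / read a pharmacophore model as JSON
#'
#' Schema: `{name, frame_pdb_id, points: [{kind, center, radius, weight,
#' label}], hbond_constraint: {chain, resnum, atom, weight,
#' min_geometry_weight}}`.
#'
#' @param model a `pharmacophore_model`.
#' @param path output / input file path.
#' @return `read_model_json` returns a `pharmacophore_model`;
#'   `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  obj <- list(name = model$name, frame_pdb_id = model$frame_pdb_id,
              points = lapply(model$points, function(p) {
                list(kind = p$kind, center = p$center, radius = p$radius,
                     weight = p$weight, label = p$label)
              }),
              hbond_constraint = model$hbond_constraint)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("name", "points")) {
    if (is.null(obj[[f]])) stop("model JSON missing field: ", f)
  }
  pts <- lapply(obj$points, function(p) {
    for (f in c("kind", "center", "radius", "weight", "label")) {
      if (is.null(p[[f]])) stop("model point missing field: ", f)
    }
    if (!(p$kind %in% FEATURE_KINDS)) stop("unknown feature kind: ", p$kind)
    list(kind = p$kind, center = as.numeric(unlist(p$center)),
         radius = p$radius, weight = p$weight, label = p$label)
  })
  hb <- obj$hbond_constraint
  if (!is.null(hb)) {
    hb <- lapply(hb, function(v) if (is.list(v)) as.numeric(unlist(v)) else v)
  }
  pharmacophore_model(obj$name, pts,
                      frame_pdb_id = obj$frame_pdb_id %||% NA_character_,
                      hbond_constraint = hb)
}

# Feature typing rules (editable): SMARTS-style semantics implemented on the
# heavy-atom graph. Acceptors are neutral N/O excluding amide N and aromatic
# N-H; donors are heavy atoms bearing a polar hydrogen.
is_amide_n <- function(g, i) {
  if (g$atoms$element[i] != "N") return(FALSE)
  for (j in g$adj[[i]]) {
    if (g$atoms$element[j] != "C") next
    b <- g$bonds
    for (k in g$adj[[j]]) {
      if (g$atoms$element[k] != "O") next
      hit <- which((b$a1 == j & b$a2 == k) | (b$a1 == k & b$a2 == j))
      if (length(hit) && !b$aromatic[hit[1]] && b$order[hit[1]] == 2) return(TRUE)
    }
  }
  FALSE
}

#' Perceive pharmacophoric features of a 3D conformer
#'
#' HBA: nitrogen or oxygen, not positively charged, not an amide nitrogen,
#' and (for N) not carrying a hydrogen while aromatic (pyrrole-type N is no
#' acceptor); positioned at the atom. HBD: N or O bearing at least one
#' hydrogen, positioned at the heavy atom. AromaticRing: one feature per
#' smallest aromatic ring, at the unweighted centroid of the ring atoms.
#' Features are ordered by (kind, first source atom index).
#'
#' @param mol a `psmol` with 3D coordinates (e.g. from
#'   [read_sdf_molecules()] or `parse_smiles(..., gen3d = TRUE)`).
#' @return data.frame of class `ligand_features`: columns `kind`, `x`, `y`,
#'   `z`, `atoms` (comma-separated source atom indices, heavy-atom
#'   numbering).
#' @export
perceive_features <- function(mol) {
  stopifnot(inherits(mol, "psmol"))
  g <- heavy_graph(mol)
  xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
  if (nrow(xyz) && max(abs(xyz)) < 1e-9 && nrow(xyz) > 1) {
    stop("no conformer: molecule has no 3D coordinates")
  }
  feats <- list()
  add <- function(kind, pos, atoms) {
    feats[[length(feats) + 1]] <<- data.frame(
      kind = kind, x = pos[1], y = pos[2], z = pos[3],
      atoms = paste(atoms, collapse = ","), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(g$atoms))) {
    el <- g$atoms$element[i]
    if (!(el %in% c("N", "O"))) next
    if (g$n_h[i] > 0) add("HBD", xyz[i, ], i)
    acceptor <- g$atoms$charge[i] <= 0 && !is_amide_n(g, i)
    if (el == "N" && g$atoms$aromatic[i] && g$n_h[i] > 0) acceptor <- FALSE
    if (acceptor) add("HBA", xyz[i, ], i)
  }
  for (ring in aromatic_rings(g)) {
    add("AromaticRing", colMeans(xyz[ring, , drop = FALSE]), ring)
  }
  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(), x = numeric(), y = numeric(), z = numeric(),
               atoms = character())
  first_atom <- vapply(strsplit(out$atoms, ","), function(a) min(as.integer(a)),
                       integer(1))
  out <- out[order(match(out$kind, FEATURE_KINDS), first_atom), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ligand_features", "data.frame")
  out
}

#' Construct a feature set directly from kinds and coordinates
#'
#' @param kind character vector of feature kinds.
#' @param coords n x 3 matrix of positions (Angstrom).
#' @return `ligand_features` data.frame.
#' @export
ligand_features <- function(kind, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(kind) == nrow(coords), all(kind %in% FEATURE_KINDS))
  out <- data.frame(kind = kind, x = coords[, 1], y = coords[, 2],
                    z = coords[, 3], atoms = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ligand_features", "data.frame")
  out
}

#' Consensus pharmacophore map from pre-aligned ligands
#'
#' Groups same-kind features across ligands by single-linkage clustering at
#' `merge_radius`; groups supported by at least `min_support` of the ligands
#' become model points with the group centroid as centre and
#' `max(radius_floor, RMS spread)` as radius. All weights default to 1.
#' Ligands must already share a coordinate frame (e.g. crystal poses of
#' superposed structures).
#'
#' @param feature_sets list of `ligand_features`, one per ligand.
#' @param merge_radius single-linkage merge distance in Angstrom (default 1).
#' @param min_support minimum fraction of ligands contributing to a point
#'   (default 0.6).
#' @param radius_floor minimum point radius in Angstrom (default 0.5).
#' @param name model name.
#' @return a `pharmacophore_model`; a model with zero points (plus a warning)
#'   when no feature group reaches `min_support`.
#' @export
consensus_map <- function(feature_sets, merge_radius = 1.0, min_support = 0.6,
                          radius_floor = 0.5, name = "consensus") {
  if (!length(feature_sets)) stop("no feature sets supplied")
  if (min_support > 1 || min_support <= 0) stop("min_support must be in (0, 1]")
  n_lig <- length(feature_sets)
  all_feats <- do.call(rbind, lapply(seq_along(feature_sets), function(i) {
    f <- as.data.frame(feature_sets[[i]])
    if (!nrow(f)) return(NULL)
    f$ligand <- i
    f
  }))
  pts <- list()
  for (kind in FEATURE_KINDS) {
    sub <- all_feats[all_feats$kind == kind, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0) next
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    groups <- if (nrow(sub) == 1) 1L else {
      hc <- hclust(dist(xyz), method = "single")
      cutree(hc, h = merge_radius)
    }
    for (gid in unique(groups)) {
      members <- which(groups == gid)
      support <- length(unique(sub$ligand[members])) / n_lig
      if (support < min_support) next
      ctr <- colMeans(xyz[members, , drop = FALSE])
      spread <- sqrt(mean(rowSums(sweep(xyz[members, , drop = FALSE], 2, ctr)^2)))
      pts[[length(pts) + 1]] <- list(
        kind = kind, center = ctr, radius = max(radius_floor, spread),
        weight = 1,
        label = sprintf("%s %d", kind, length(pts) + 1))
    }
  }
  if (!length(pts)) {
    warning("no consensus points reached min_support; returning empty model")
    out <- structure(list(name = name, frame_pdb_id = NA_character_,
                          points = list(), hbond_constraint = NULL),
                     class = "pharmacophore_model")
    return(out)
  }
  pharmacophore_model(name, pts)
}
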