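# Protein-structure utilities
# ---------------------------
# PDB reading (first model, altloc resolved by occupancy), ligand-radius
# binding-site extraction, site comparison (residue identity, Kabsch RMSD
# over selectable atom sets, Shrake-Rupley SASA), and a grid-based
# description of the affinity pocket between the glycine-rich loop and the
# catalytic lysine.

# Bondi van der Waals radii (Angstrom), overridable
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
                 S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90,
                 Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39,
                 Fe = 2.00, Mn = 2.00)

#' Read a protein structure from a PDB file
#'
#' The first model of multi-model files is used; alternate locations are
#' resolved to the highest-occupancy copy (ties go to altloc 'A'). HETATM
#' ligands are retained and indexed by residue name.
#'
#' @param path PDB file.
#' @return object of class `ps_structure`: list with `atoms` (data.frame:
#'   chain, resno, resid, elety, element, x, y, z, occupancy, het) and
#'   `ligand_resnames`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (!nrow(a) || !any(a$type == "ATOM")) stop("no ATOM records in ", path)
  # altloc resolution
  a$alt[is.na(a$alt) | a$alt == ""] <- ""
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    occ <- a$o[idx]; occ[is.na(occ)] <- 1
    best <- idx[order(-occ, a$alt[idx] != "A", a$alt[idx])][1]
    keep[idx] <- FALSE; keep[best] <- TRUE
  }
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  guess <- toupper(substr(gsub("[0-9']", "", a$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  atoms <- data.frame(
    chain = a$chain, resno = a$resno, resid = a$resid, elety = a$elety,
    element = paste0(toupper(substr(elem, 1, 1)),
                     tolower(substr(elem, 2, nchar(elem)))),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms,
                 ligand_resnames = unique(atoms$resid[atoms$het &
                   !(atoms$resid %in% c("HOH", "WAT"))])),
            class = "ps_structure")
}

#' @export
print.ps_structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno)[!x$atoms$het])),
      "residues; HET:", paste(x$ligand_resnames, collapse = " "), "\n")
  invisible(x)
}

#' Extract a binding site by distance from a bound ligand
#'
#' Selects whole residues having at least one heavy atom within `radius` of
#' any heavy atom of the named ligand. Waters are excluded by default.
#'
#' @param struct a `ps_structure`.
#' @param ligand_resname HETATM residue name of the ligand.
#' @param radius selection radius in Angstrom (default 10).
#' @param include_waters keep waters in the site.
#' @return object of class `binding_site`: list with `residues` (data.frame:
#'   chain, resno, resid), `atoms` (subset of structure atoms),
#'   `ligand_resname`, `radius`.
#' @export
extract_site <- function(struct, ligand_resname, radius = 10,
                         include_waters = FALSE) {
  stopifnot(inherits(struct, "ps_structure"), radius > 0)
  a <- struct$atoms
  lig <- a[a$het & a$resid == ligand_resname & a$element != "H", , drop = FALSE]
  if (!nrow(lig)) {
    stop("ligand '", ligand_resname, "' not found; available HET residues: ",
         paste(struct$ligand_resnames, collapse = ", "))
  }
  prot <- a[!a$het & a$element != "H", , drop = FALSE]
  if (!include_waters) prot <- prot[!(prot$resid %in% c("HOH", "WAT")), , drop = FALSE]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  mind <- apply(pxyz, 1, function(p) {
    sqrt(min(colSums((t(lxyz) - p)^2)))
  })
  near <- unique(paste(prot$chain, prot$resno)[mind <= radius])
  in_site <- paste(a$chain, a$resno) %in% near & !a$het
  site_atoms <- a[in_site, , drop = FALSE]
  residues <- unique(site_atoms[, c("chain", "resno", "resid")])
  residues <- residues[order(residues$chain, residues$resno), , drop = FALSE]
  structure(list(residues = residues, atoms = site_atoms,
                 ligand_resname = ligand_resname, radius = radius,
                 parent = struct),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat("Binding site:", nrow(x$residues), "residues within", x$radius,
      "A of", x$ligand_resname, "\n")
  invisible(x)
}

# simple global alignment (Needleman-Wunsch, match 1 / mismatch 0 / gap -1)
# of two residue-name vectors; returns index pairs
align_residue_strings <- function(a, b) {
  n <- length(a); m <- length(b)
  sc <- matrix(0, n + 1, m + 1)
  sc[1, ] <- -(0:m); sc[, 1] <- -(0:n)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sc[i + 1, j + 1] <- max(sc[i, j] + (a[i] == b[j]),
                            sc[i, j + 1] - 1, sc[i + 1, j] - 1)
  }
  pairs <- matrix(integer(), 0, 2)
  i <- n; j <- m
  while (i > 0 && j > 0) {
    if (sc[i + 1, j + 1] == sc[i, j] + (a[i] == b[j])) {
      pairs <- rbind(c(i, j), pairs); i <- i - 1; j <- j - 1
    } else if (sc[i + 1, j + 1] == sc[i, j + 1] - 1) i <- i - 1 else j <- j - 1
  }
  pairs
}

#' Compare two binding sites: identity, RMSD, SASA
#'
#' Residues are paired by sorted residue order when the sites have equal
#' length, otherwise by global alignment of the residue-name strings.
#' Identity is the percentage of aligned pairs with identical residue names.
#' RMSD is the Kabsch superposition over shared named atoms of aligned
#' identical residues (`atoms = "heavy"`, default), or over Calpha /
#' backbone atoms. SASA is computed for each site in its parent structure
#' context.
#'
#' @param site_a,site_b `binding_site` objects.
#' @param atoms atom selection for RMSD: "heavy", "backbone" or "ca".
#' @param sasa compute per-site solvent-accessible surface areas (slower).
#' @return object of class `site_comparison`: list with `identity` (percent),
#'   `rmsd` (Angstrom), `n_aligned`, `aligned_pairs`, and `sasa_a`/`sasa_b`
#'   when requested.
#' @export
compare_sites <- function(site_a, site_b, atoms = c("heavy", "backbone", "ca"),
                          sasa = TRUE) {
  atoms <- match.arg(atoms)
  stopifnot(inherits(site_a, "binding_site"), inherits(site_b, "binding_site"))
  ra <- site_a$residues; rb <- site_b$residues
  if (!nrow(ra) || !nrow(rb)) stop("empty binding site")
  if (nrow(ra) == nrow(rb)) {
    pairs <- cbind(seq_len(nrow(ra)), seq_len(nrow(rb)))
  } else {
    pairs <- align_residue_strings(ra$resid, rb$resid)
  }
  if (!nrow(pairs)) stop("no alignable residue pairs")
  same <- ra$resid[pairs[, 1]] == rb$resid[pairs[, 2]]
  identity <- 100 * sum(same) / nrow(pairs)
  sel <- switch(atoms,
                ca = c("CA"),
                backbone = c("N", "CA", "C", "O"),
                heavy = NULL)
  xa <- NULL; xb <- NULL
  for (k in which(same)) {
    aa <- site_a$atoms[site_a$atoms$chain == ra$chain[pairs[k, 1]] &
                         site_a$atoms$resno == ra$resno[pairs[k, 1]], , drop = FALSE]
    bb <- site_b$atoms[site_b$atoms$chain == rb$chain[pairs[k, 2]] &
                         site_b$atoms$resno == rb$resno[pairs[k, 2]], , drop = FALSE]
    aa <- aa[aa$element != "H", , drop = FALSE]
    bb <- bb[bb$element != "H", , drop = FALSE]
    if (!is.null(sel)) {
      aa <- aa[aa$elety %in% sel, , drop = FALSE]
      bb <- bb[bb$elety %in% sel, , drop = FALSE]
    }
    shared <- intersect(aa$elety, bb$elety)
    aa <- aa[match(shared, aa$elety), , drop = FALSE]
    bb <- bb[match(shared, bb$elety), , drop = FALSE]
    if (nrow(aa)) {
      xa <- rbind(xa, as.matrix(aa[, c("x", "y", "z")]))
      xb <- rbind(xb, as.matrix(bb[, c("x", "y", "z")]))
    }
  }
  if (is.null(xa) || nrow(xa) < 3) stop("no alignable atom pairs")
  fit <- kabsch_superpose(xa, xb)
  out <- list(identity = identity, rmsd = fit$rmsd, n_aligned = nrow(pairs),
              n_atoms = nrow(xa), atoms = atoms,
              aligned_pairs = data.frame(
                resid_a = ra$resid[pairs[, 1]], resno_a = ra$resno[pairs[, 1]],
                resid_b = rb$resid[pairs[, 2]], resno_b = rb$resno[pairs[, 2]],
                identical = same))
  if (sasa) {
    out$sasa_a <- site_sasa(site_a)
    out$sasa_b <- site_sasa(site_b)
  }
  class(out) <- "site_comparison"
  out
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("Site comparison: identity %.1f%%, RMSD %.3f A over %d atoms (%s)\n",
              x$identity, x$rmsd, x$n_atoms, x$atoms))
  if (!is.null(x$sasa_a)) {
    cat(sprintf("  SASA: %.0f vs %.0f A^2\n", x$sasa_a, x$sasa_b))
  }
  invisible(x)
}

# deterministic quasi-uniform sphere points (golden-spiral generator)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point sampling with a deterministic golden-spiral point set.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` (hydrogens,
#'   if present, are used as occluders too).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 960).
#' @param radii named vdW radius table (defaults to Bondi values).
#' @param subset optional row indices: report SASA only for these atoms
#'   (neighbours still occlude).
#' @return list with `total` (Angstrom^2) and `per_atom`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               radii = BONDI_RADII, subset = NULL) {
  el <- atoms$element
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  r <- unname(radii[el]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  # exactly coincident duplicates of the same element count once: this is the
  # continuous limit of two spheres approaching (each exposes a hemisphere)
  dup <- duplicated(data.frame(el, round(xyz, 9)))
  pts <- sphere_points(n_points)
  idx <- if (is.null(subset)) seq_len(n) else subset
  per <- numeric(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    if (dup[i]) next
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 > 0 & d2 < (r + r[i])^2)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- colSums((t(surf) - xyz[j, ])^2)
      free <- free & dd > r[j]^2
      if (!any(free)) break
    }
    per[q] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  list(total = sum(per), per_atom = per)
}

# SASA of a site's atoms in the context of its parent structure
site_sasa <- function(site, probe = 1.4, n_points = 960) {
  parent <- site$parent$atoms
  parent <- parent[parent$element != "H", , drop = FALSE]
  parent <- parent[!(parent$resid %in% c("HOH", "WAT")) & !parent$het, , drop = FALSE]
  key_parent <- paste(parent$chain, parent$resno, parent$elety)
  key_site <- paste(site$atoms$chain, site$atoms$resno, site$atoms$elety)
  subset <- which(key_parent %in% key_site)
  shrake_rupley_sasa(parent, probe = probe, n_points = n_points,
                     subset = subset)$total
}

#' Describe the affinity pocket between the Gly-rich loop and the catalytic lysine
#'
#' Collects the atoms of the glycine-rich loop residue range and the catalytic
#' lysine side chain, then estimates the pocket centre as the point of a
#' 0.5-Angstrom grid (spanning the gap between the two groups) that maximizes
#' the clearance to any atom's van der Waals surface.
#'
#' @param site a `binding_site`.
#' @param glycine_loop_resrange integer range of loop residue numbers (e.g.
#'   `83:88` for ROCK1).
#' @param catalytic_lys_resnum residue number of the catalytic lysine.
#' @param grid_step grid spacing in Angstrom (default 0.5).
#' @return list with `loop_atoms`, `lys_atoms` (data.frames), `centroid`,
#'   `radius` (maximal inscribed sphere, >= 0).
#' @export
describe_affinity_pocket <- function(site, glycine_loop_resrange,
                                     catalytic_lys_resnum, grid_step = 0.5) {
  a <- site$atoms
  loop <- a[a$resno %in% glycine_loop_resrange, , drop = FALSE]
  lys <- a[a$resno == catalytic_lys_resnum &
             a$elety %in% c("CB", "CG", "CD", "CE", "NZ"), , drop = FALSE]
  if (!nrow(loop)) stop("glycine-loop residues ",
                        paste(range(glycine_loop_resrange), collapse = "-"),
                        " absent from site")
  if (!nrow(lys)) stop("catalytic lysine ", catalytic_lys_resnum,
                       " absent from site")
  walls <- rbind(loop, lys)
  wall_xyz <- as.matrix(walls[, c("x", "y", "z")])
  wr <- BONDI_RADII[walls$element]
  wr[is.na(wr)] <- 1.7
  lo <- pmin(colMeans(as.matrix(loop[, c("x", "y", "z")])),
             colMeans(as.matrix(lys[, c("x", "y", "z")])))
  hi <- pmax(colMeans(as.matrix(loop[, c("x", "y", "z")])),
             colMeans(as.matrix(lys[, c("x", "y", "z")])))
  lo <- lo - 2; hi <- hi + 2
  gx <- seq(lo[1], hi[1], by = grid_step)
  gy <- seq(lo[2], hi[2], by = grid_step)
  gz <- seq(lo[3], hi[3], by = grid_step)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  clearance <- apply(grid, 1, function(p) {
    min(sqrt(colSums((t(wall_xyz) - p)^2)) - wr)
  })
  best <- which.max(clearance)
  list(loop_atoms = loop, lys_atoms = lys,
       centroid = as.numeric(grid[best, ]),
       radius = max(0, clearance[best]))
}
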