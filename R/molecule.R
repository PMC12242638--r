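#' @importFrom stats prcomp dist hclust cutree kmeans runif rnorm setNames
#' @importFrom utils read.csv write.csv head
NULL

# Internal molecule representation
# ---------------------------------
# A `psmol` is a light molecular graph built from Tripos MOL2 text (OpenBabel
# handles format conversion and aromaticity perception).  Atoms keep element,
# coordinates, Tripos type, aromatic flag and formal charge; hydrogens are
# folded into a per-heavy-atom H count so graph algorithms (fingerprints, ring
# perception, feature typing) run on the heavy-atom skeleton.

ob_options <- function(...) {
  nm <- c(...)
  if (length(nm) == 0) return(data.frame(names = character(), args = character()))
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

#' Convert between chemical file formats
#'
#' Thin wrapper around OpenBabel's format conversion (via ChemmineOB) used by
#' all structure input in this package.
#'
#' @param from,to format codes understood by OpenBabel (e.g. "SMI", "SDF",
#'   "MOL2", "CAN").
#' @param source input text in the `from` format.
#' @param opts character vector of OpenBabel generation options, e.g. "h"
#'   (add explicit hydrogens) or "gen3D".
#' @return output text in the `to` format.
#' @keywords internal
convert_chem_format <- function(from, to, source, opts = character()) {
  ChemmineOB::convertFormat(from, to, source, options = ob_options(opts))
}

#' Canonical SMILES of a (possibly multi-fragment) SMILES string
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES, or `NA_character_` if the input does not parse.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  out <- tryCatch(
    suppressWarnings(convert_chem_format("SMI", "CAN", paste0(smiles, " m"))),
    error = function(e) ""
  )
  line <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(line) == 0 || !nzchar(line[1])) return(NA_character_)
  strsplit(line[1], "[ \t]")[[1]][1]
}

# Number of heavy atoms in a single-fragment SMILES, NA if unparseable.
heavy_atom_count <- function(smiles) {
  m <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  if (is.null(m)) return(NA_integer_)
  sum(m$atoms$element != "H")
}

#' Strip salt counterions, keeping the largest organic fragment
#'
#' Splits a SMILES on the fragment separator and keeps the fragment with the
#' most heavy atoms, preferring carbon-containing (organic) fragments. Ties go
#' to the first fragment in input order.
#'
#' @param smiles a SMILES string, possibly multi-fragment ("." separated).
#' @return SMILES of the retained fragment (not canonicalized), or
#'   `NA_character_` on parse failure.
#' @export
desalt_smiles <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0) return(NA_character_)
  if (length(frags) == 1) {
    return(if (is.na(heavy_atom_count(frags))) NA_character_ else frags)
  }
  n_heavy <- vapply(frags, heavy_atom_count, integer(1))
  if (all(is.na(n_heavy))) return(NA_character_)
  organic <- grepl("C|c", frags) & !is.na(n_heavy)
  pool <- if (any(organic)) which(organic) else which(!is.na(n_heavy))
  frags[pool[which.max(n_heavy[pool])]]
}

# Parse Tripos MOL2 text into a psmol object.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sec <- cumsum(grepl("^@<TRIPOS>", lines))
  tags <- sub("^@<TRIPOS>", "", lines[grepl("^@<TRIPOS>", lines)])
  get_section <- function(tag) {
    idx <- which(tags == tag)
    if (length(idx) == 0) return(character())
    body <- lines[sec == idx[1]][-1]
    body[nzchar(trimws(body))]
  }
  at <- get_section("ATOM")
  if (length(at) == 0) stop("MOL2 text contains no atoms")
  f <- strsplit(trimws(at), "[ \t]+")
  atoms <- data.frame(
    idx = as.integer(vapply(f, `[`, "", 1)),
    name = vapply(f, `[`, "", 2),
    x = as.numeric(vapply(f, `[`, "", 3)),
    y = as.numeric(vapply(f, `[`, "", 4)),
    z = as.numeric(vapply(f, `[`, "", 5)),
    type = vapply(f, `[`, "", 6),
    stringsAsFactors = FALSE
  )
  atoms$element <- vapply(strsplit(atoms$type, ".", fixed = TRUE), `[`, "", 1)
  # Tripos uses e.g. "NA" for sodium; normalise capitalisation
  atoms$element <- paste0(
    toupper(substr(atoms$element, 1, 1)),
    tolower(substr(atoms$element, 2, nchar(atoms$element)))
  )
  atoms$aromatic <- grepl("\\.ar$", atoms$type)
  atoms$charge <- 0L
  attr_body <- get_section("UNITY_ATOM_ATTR")
  if (length(attr_body) > 1) {
    i <- 1
    while (i <= length(attr_body)) {
      hdr <- strsplit(trimws(attr_body[i]), "[ \t]+")[[1]]
      aidx <- suppressWarnings(as.integer(hdr[1]))
      nattr <- suppressWarnings(as.integer(hdr[2]))
      if (is.na(aidx) || is.na(nattr)) break
      for (j in seq_len(nattr)) {
        kv <- strsplit(trimws(attr_body[i + j]), "[ \t]+")[[1]]
        if (kv[1] == "charge") atoms$charge[atoms$idx == aidx] <- as.integer(kv[2])
      }
      i <- i + nattr + 1
    }
  }
  bd <- get_section("BOND")
  bonds <- if (length(bd)) {
    g <- strsplit(trimws(bd), "[ \t]+")
    data.frame(
      a1 = as.integer(vapply(g, `[`, "", 2)),
      a2 = as.integer(vapply(g, `[`, "", 3)),
      type = vapply(g, `[`, "", 4),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), type = character())
  }
  bonds$aromatic <- bonds$type == "ar"
  bonds$order <- ifelse(bonds$type %in% c("1", "2", "3"),
                        suppressWarnings(as.integer(bonds$type)), 1L)
  bonds$order[bonds$type == "ar"] <- 1L
  bonds$order[bonds$type == "am"] <- 1L
  mol <- list(atoms = atoms, bonds = bonds)
  class(mol) <- "psmol"
  mol
}

#' Parse a SMILES string into an internal molecule object
#'
#' OpenBabel perceives aromaticity and adds explicit hydrogens; the result is
#' a heavy-atom graph with hydrogen counts, suitable for fingerprinting and
#' feature perception (no 3D coordinates unless `gen3d = TRUE`).
#'
#' @param smiles single SMILES string.
#' @param gen3d generate a single 3D conformer (slower).
#' @return a `psmol` object.
#' @export
parse_smiles <- function(smiles, gen3d = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  opts <- if (gen3d) c("gen3D", "h") else "h"
  txt <- tryCatch(
    suppressWarnings(convert_chem_format("SMI", "MOL2", paste0(smiles, " m"), opts)),
    error = function(e) ""
  )
  if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt)) {
    stop("SMILES does not parse: ", smiles)
  }
  m <- parse_mol2(txt)
  m$smiles <- smiles
  m
}

#' Read molecules from SDF text or file
#'
#' Accepts a multi-record SDF; each record is converted to MOL2 (preserving
#' 3D coordinates and perceiving aromaticity) and parsed.
#'
#' @param path path to an SDF file, or raw SDF text via `text`.
#' @param text SDF text (used when `path` is missing).
#' @return list of `psmol` objects, named by the SDF title line when present.
#' @export
read_sdf_molecules <- function(path, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  recs <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[grepl("V2000|V3000", recs)]
  mols <- lapply(recs, function(r) {
    title <- strsplit(r, "\n")[[1]][1]
    txt <- suppressWarnings(convert_chem_format("SDF", "MOL2",
                                                paste0(r, "\n$$$$\n"), "h"))
    m <- parse_mol2(txt)
    m$title <- trimws(title)
    m
  })
  names(mols) <- vapply(mols, function(m) if (nzchar(m$title %||% "")) m$title else "", "")
  mols
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Heavy-atom view: adjacency list, per-atom H count, bond table restricted to
# heavy atoms (indices renumbered 1..n_heavy).
heavy_graph <- function(mol) {
  is_h <- mol$atoms$element == "H"
  heavy_idx <- mol$atoms$idx[!is_h]
  map <- integer(max(mol$atoms$idx))
  map[heavy_idx] <- seq_along(heavy_idx)
  b <- mol$bonds
  h1 <- is_h[match(b$a1, mol$atoms$idx)]
  h2 <- is_h[match(b$a2, mol$atoms$idx)]
  nh <- integer(length(heavy_idx))
  hb <- b[xor(h1, h2), , drop = FALSE]
  if (nrow(hb)) {
    heavies <- ifelse(is_h[match(hb$a1, mol$atoms$idx)], hb$a2, hb$a1)
    t <- table(factor(map[heavies], levels = seq_along(heavy_idx)))
    nh <- as.integer(t)
  }
  bb <- b[!h1 & !h2, , drop = FALSE]
  adj <- vector("list", length(heavy_idx))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (nrow(bb)) {
    u <- map[bb$a1]; v <- map[bb$a2]
    for (k in seq_len(nrow(bb))) {
      adj[[u[k]]] <- c(adj[[u[k]]], v[k])
      adj[[v[k]]] <- c(adj[[v[k]]], u[k])
    }
    bb$a1 <- u; bb$a2 <- v
  }
  list(
    atoms = mol$atoms[!is_h, , drop = FALSE],
    bonds = bb,
    adj = adj,
    n_h = nh,
    orig_idx = heavy_idx
  )
}

# Bond-in-ring flags: bond (u,v) is in a ring iff u and v stay connected after
# removing the bond (BFS).  Returns logical per bond row.
ring_bonds <- function(g) {
  n <- length(g$adj)
  out <- logical(nrow(g$bonds))
  if (!nrow(g$bonds)) return(out)
  for (k in seq_len(nrow(g$bonds))) {
    u <- g$bonds$a1[k]; v <- g$bonds$a2[k]
    seen <- logical(n); seen[u] <- TRUE
    queue <- u
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      for (w in g$adj[[cur]]) {
        if (cur == u && w == v) next
        if (cur == v && w == u) next
        if (!seen[w]) {
          if (w == v) { found <- TRUE; break }
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    out[k] <- found
  }
  out
}

# Smallest ring through a given bond, restricted to an optional atom subset.
# Returns integer vector of atom indices (in heavy numbering) or NULL.
smallest_ring_through <- function(g, u, v, subset = NULL) {
  n <- length(g$adj)
  ok <- if (is.null(subset)) rep(TRUE, n) else seq_len(n) %in% subset
  if (!ok[u] || !ok[v]) return(NULL)
  # shortest path u..v avoiding the direct bond
  prev <- rep(NA_integer_, n)
  seen <- logical(n); seen[u] <- TRUE
  queue <- u
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (w in g$adj[[cur]]) {
      if ((cur == u && w == v) || (cur == v && w == u)) next
      if (!ok[w] || seen[w]) next
      seen[w] <- TRUE; prev[w] <- cur
      if (w == v) {
        path <- v
        while (path[1] != u) path <- c(prev[path[1]], path)
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}

# All smallest aromatic rings (deduplicated atom sets) of the heavy graph.
aromatic_rings <- function(g) {
  arb <- which(g$bonds$aromatic & ring_bonds(g))
  if (!length(arb)) return(list())
  arom_atoms <- which(g$atoms$aromatic)
  rings <- list()
  seen <- character()
  for (k in arb) {
    r <- smallest_ring_through(g, g$bonds$a1[k], g$bonds$a2[k], subset = arom_atoms)
    if (is.null(r)) next
    key <- paste(sort(r), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1]] <- sort(r) }
  }
  rings
}

# Fused aromatic ring systems: connected components over shared atoms.
aromatic_ring_systems <- function(rings) {
  if (!length(rings)) return(list())
  n <- length(rings)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] && length(intersect(rings[[i]], rings[[j]])) >= 2) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    members <- rings[comp == cc]
    list(rings = members, atoms = sort(unique(unlist(members))))
  })
}

#' Molecular properties via OpenBabel
#'
#' @param smiles SMILES string.
#' @return data.frame with canonical SMILES, formula, MW (average atomic
#'   masses), H-bond donor/acceptor counts, logP, TPSA.
#' @export
molecular_properties <- function(smiles) {
  res <- ChemmineOB::forEachMol("SMILES", paste0(smiles, " m"),
                                function(m) ChemmineOB::prop_OB(m))
  res[[1]]
}

#' Count potential stereocentres lacking a specified configuration
#'
#' Potential tetrahedral stereocentres are sp3 carbons whose four substituent
#' branches (implicit hydrogen counted as a branch) are pairwise structurally
#' distinct under iterative neighbourhood (Weisfeiler-Lehman style) refinement.
#' Specified centres are counted from the stereo marks OpenBabel retains in
#' the canonical SMILES; the unspecified count is their difference.
#'
#' @param smiles SMILES string (single fragment).
#' @return integer count of unspecified potential stereocentres.
#' @export
count_unspecified_stereocenters <- function(smiles) {
  mol <- parse_smiles(smiles)
  g <- heavy_graph(mol)
  n <- length(g$adj)
  if (n == 0) return(0L)
  # iterative colour refinement on the heavy graph (+H counts)
  col <- as.integer(factor(paste(g$atoms$element, g$n_h, g$atoms$charge,
                                 lengths(g$adj), g$atoms$aromatic)))
  for (it in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      paste(col[i], paste(sort(col[g$adj[[i]]]), collapse = ","), sep = "|")
    }, "")
    newcol <- as.integer(factor(sig))
    if (length(unique(newcol)) == length(unique(col))) break
    col <- newcol
  }
  bond_order <- function(i, j) {
    b <- g$bonds
    hit <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
    if (!length(hit)) return(1L)
    if (b$aromatic[hit[1]]) return(0L) else b$order[hit[1]]
  }
  n_potential <- 0L
  for (i in seq_len(n)) {
    if (g$atoms$element[i] != "C" || g$atoms$aromatic[i]) next
    nb <- g$adj[[i]]
    deg <- length(nb) + g$n_h[i]
    if (deg != 4L || g$n_h[i] > 1L) next
    if (length(nb) && any(vapply(nb, function(j) bond_order(i, j), 0L) != 1L)) next
    branch_cols <- col[nb]
    if (g$n_h[i] == 1L) branch_cols <- c(branch_cols, -1L)
    if (length(unique(branch_cols)) == 4L) n_potential <- n_potential + 1L
  }
  can <- canonical_smiles(smiles)
  n_specified <- 0L
  if (!is.na(can)) {
    hits <- gregexpr("@@|@", can)[[1]]
    n_specified <- sum(hits > 0)
  }
  max(0L, n_potential - n_specified)
}
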