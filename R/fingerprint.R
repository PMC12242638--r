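# Circular (ECFP-style) fingerprints
# -----------------------------------
# Extended-connectivity fingerprinting on the heavy-atom graph: per-atom
# initial invariants are iteratively hashed together with sorted
# (bond order, neighbour identifier) pairs up to the configured radius,
# identifiers arising from duplicate atom environments are removed, and the
# surviving identifiers are folded into a fixed-width bit vector.

# stable 31-bit polynomial hash of an integer vector
hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + (x %% 2147483647)) %% 2147483647
  as.integer(h)
}

# bond code entering the hash: 1/2/3 single/double/triple, 4 aromatic
bond_codes <- function(g) {
  code <- g$bonds$order
  code[g$bonds$aromatic] <- 4L
  code
}

ecfp_identifiers <- function(mol, radius = 3L) {
  g <- heavy_graph(mol)
  n <- length(g$adj)
  if (n == 0) return(integer())
  ring <- logical(n)
  rb <- ring_bonds(g)
  if (any(rb)) ring[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  elno <- match(g$atoms$element, c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Fe", "Cu", "Zn", "Se", "Br", "I"
  ))
  elno[is.na(elno)] <- 99L
  id <- vapply(seq_len(n), function(i) {
    hash_ints(c(elno[i], length(g$adj[[i]]), g$n_h[i],
                g$atoms$charge[i], as.integer(ring[i])))
  }, 0L)
  bcode <- bond_codes(g)
  bond_lookup <- new.env(hash = TRUE)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      assign(paste(g$bonds$a1[k], g$bonds$a2[k]), k, envir = bond_lookup)
      assign(paste(g$bonds$a2[k], g$bonds$a1[k]), k, envir = bond_lookup)
    }
  }
  env_bonds <- rep(list(integer()), n)   # bond set covered per atom identifier
  emitted_ids <- id                      # radius-0 identifiers, all atoms
  emitted_envs <- character()            # bond-environment keys already used
  for (r in seq_len(radius)) {
    new_id <- id
    new_env <- env_bonds
    for (i in seq_len(n)) {
      nb <- g$adj[[i]]
      if (!length(nb)) { new_id[i] <- hash_ints(c(r, id[i])); next }
      bk <- vapply(nb, function(j) get(paste(i, j), envir = bond_lookup), 0L)
      ord <- order(bcode[bk], id[nb])
      parts <- c(r, id[i])
      for (k in ord) parts <- c(parts, bcode[bk[k]], id[nb[k]])
      new_id[i] <- hash_ints(parts)
      new_env[[i]] <- sort(unique(c(env_bonds[[i]], unlist(env_bonds[nb]), bk)))
    }
    keys <- vapply(new_env, function(b) paste(b, collapse = ","), "")
    # duplicate environments: keep one representative (smallest identifier),
    # and none if the environment was already emitted at a smaller radius
    ord <- order(keys, new_id)
    keep <- logical(n)
    last_key <- NA_character_
    for (i in ord) {
      if (keys[i] %in% emitted_envs) next
      if (identical(keys[i], last_key)) next
      keep[i] <- TRUE
      last_key <- keys[i]
    }
    emitted_ids <- c(emitted_ids, new_id[keep])
    emitted_envs <- c(emitted_envs, keys[keep])
    id <- new_id
    env_bonds <- new_env
  }
  emitted_ids
}

#' Circular fingerprint of a molecule
#'
#' ECFP-style fingerprint with bond diameter `2 * radius` (default diameter 6)
#' hashed onto `n_bits` bits. Deterministic for a given structure and
#' invariant to the SMILES spelling.
#'
#' @param x a SMILES string or a `psmol` object.
#' @param radius neighbourhood radius in bonds (default 3, i.e. ECFP_6).
#' @param n_bits folded fingerprint length (default 2048); `NULL` returns the
#'   raw set of distinct environment identifiers instead of a bit vector.
#' @return integer vector of 0/1 of length `n_bits`, or a sorted integer
#'   vector of identifiers when `n_bits = NULL`.
#' @export
circular_fingerprint <- function(x, radius = 3L, n_bits = 2048L) {
  mol <- if (inherits(x, "psmol")) x else parse_smiles(x)
  ids <- ecfp_identifiers(mol, radius = radius)
  if (is.null(n_bits)) return(sort(unique(ids)))
  bits <- integer(n_bits)
  bits[(ids %% n_bits) + 1L] <- 1L
  bits
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @param ids compound identifiers (default the SMILES themselves).
#' @param radius,n_bits see [circular_fingerprint()].
#' @return binary matrix, one row per compound, rownames = ids.
#' @export
fingerprint_matrix <- function(smiles, ids = smiles, radius = 3L, n_bits = 2048L) {
  stopifnot(length(smiles) == length(ids))
  m <- t(vapply(smiles, circular_fingerprint, integer(n_bits),
                radius = radius, n_bits = n_bits))
  rownames(m) <- ids
  m
}

#' Tanimoto distance matrix of binary fingerprints
#'
#' `d(i, j) = 1 - |A and B| / |A or B|`; two all-zero rows are identical by
#' convention (distance 0).
#'
#' @param fps binary matrix (rows = compounds).
#' @return symmetric distance matrix with zero diagonal, entries in `[0, 1]`.
#' @export
tanimoto_distance_matrix <- function(fps) {
  fps <- as.matrix(fps)
  stopifnot(nrow(fps) >= 2, all(fps %in% c(0, 1)))
  inter <- fps %*% t(fps)
  on <- rowSums(fps)
  uni <- outer(on, on, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  d <- 1 - sim
  diag(d) <- 0
  dimnames(d) <- list(rownames(fps), rownames(fps))
  d
}
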