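# Bioactivity curation
# --------------------
# Turns ChEMBL-style activity exports into the active / inactive / candidate
# sets screened downstream: activity-class partition on Ki/Kd values,
# salt stripping, duplicate / stereochemistry / molecular-weight filters, and
# Tanimoto diversity selection.

#' Parse a bioactivity table from CSV
#'
#' One record per row. Rows whose SMILES does not parse or whose value is
#' non-numeric are returned in a rejects table with a reason, never silently
#' dropped.
#'
#' @param path CSV file path.
#' @param columns named list mapping the fields `smiles`, `type`, `value` (and
#'   optionally `id`, `pchembl`, `target`) to header names in the file.
#' @return list with `records` (data.frame: compound_id, smiles,
#'   standard_type, standard_value, pchembl_value, target_id) and `rejects`
#'   (data.frame: row, smiles, reason).
#' @export
parse_activity_table <- function(path,
                                 columns = list(smiles = "smiles",
                                                type = "standard_type",
                                                value = "standard_value",
                                                id = "compound_id",
                                                pchembl = "pchembl_value",
                                                target = "target_id")) {
  if (!file.exists(path)) stop("activity table not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (req in c("smiles", "type", "value")) {
    if (is.null(columns[[req]]) || !(columns[[req]] %in% names(raw))) {
      stop("configuration error: mandatory column '", req,
           "' (header '", columns[[req]], "') missing from ", path)
    }
  }
  pick <- function(field, default) {
    cn <- columns[[field]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else default
  }
  n <- nrow(raw)
  rec <- data.frame(
    compound_id = as.character(pick("id", if (n) paste0("cmpd_", seq_len(n)) else character())),
    smiles = as.character(raw[[columns$smiles]]),
    standard_type = as.character(raw[[columns$type]]),
    standard_value = suppressWarnings(as.numeric(as.character(raw[[columns$value]]))),
    pchembl_value = suppressWarnings(as.numeric(as.character(pick("pchembl", rep(NA, n))))),
    target_id = as.character(pick("target", rep(NA_character_, n))),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    return(list(records = rec,
                rejects = data.frame(row = integer(), smiles = character(),
                                     reason = character())))
  }
  bad_value <- is.na(rec$standard_value)
  can <- vapply(rec$smiles, function(s) canonical_smiles(s), "")
  bad_smiles <- is.na(can)
  reason <- ifelse(bad_smiles & bad_value, "unparseable SMILES; non-numeric value",
            ifelse(bad_smiles, "unparseable SMILES",
            ifelse(bad_value, "non-numeric value", NA)))
  rejects <- data.frame(row = which(!is.na(reason)),
                        smiles = rec$smiles[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(records = rec[is.na(reason), , drop = FALSE], rejects = rejects)
}

#' Partition activity records into actives, inactives and exclusions
#'
#' Only Ki and Kd measurements take part in class assignment: a compound is
#' active when its value is at or below `active_nM` and inactive when at or
#' above `inactive_nM` (with `inactive_strict = TRUE` the inactive rule
#' becomes a strict `>`). Values strictly between the thresholds are excluded
#' as "intermediate activity"; IC50 and other types are excluded as
#' "unsupported type". When one compound carries several Ki/Kd values the most
#' potent (lowest nM) record decides its class.
#'
#' @param records data.frame as produced by [parse_activity_table()].
#' @param active_nM activity ceiling for the active class (default 100 nM,
#'   equivalent to pChEMBL >= 7).
#' @param inactive_nM activity floor for the inactive class (default 5000 nM).
#' @param inactive_strict logical; require value strictly above `inactive_nM`
#'   for the inactive class instead of `>=`.
#' @return object of class `labeled_set`: list with data.frames `actives`,
#'   `inactives`, `excluded` (with a `reason` column).
#' @export
classify_activity <- function(records, active_nM = 100, inactive_nM = 5000,
                              inactive_strict = FALSE) {
  stopifnot(nrow(records) > 0)
  if (any(records$standard_value < 0, na.rm = TRUE)) {
    stop("validation error: negative standard_value in row(s) ",
         paste(which(records$standard_value < 0), collapse = ", "))
  }
  is_kikd <- records$standard_type %in% c("Ki", "Kd")
  excluded <- records[!is_kikd, , drop = FALSE]
  excluded$reason <- if (nrow(excluded)) "unsupported type" else character()
  kk <- records[is_kikd, , drop = FALSE]
  if (nrow(kk)) {
    # duplicate resolution: keep the most potent record per compound
    ord <- order(kk$compound_id, kk$standard_value)
    kk <- kk[ord, , drop = FALSE]
    dup <- duplicated(kk$compound_id)
    dups <- kk[dup, , drop = FALSE]
    if (nrow(dups)) {
      dups$reason <- "duplicate measurement (less potent)"
      excluded <- rbind(excluded, dups)
    }
    kk <- kk[!dup, , drop = FALSE]
    kk <- kk[order(match(kk$compound_id, records$compound_id)), , drop = FALSE]
  }
  inactive_ok <- if (inactive_strict) kk$standard_value > inactive_nM
                 else kk$standard_value >= inactive_nM
  active_ok <- kk$standard_value <= active_nM
  mid <- !active_ok & !inactive_ok
  mids <- kk[mid, , drop = FALSE]
  if (nrow(mids)) {
    mids$reason <- "intermediate activity"
    excluded <- rbind(excluded, mids)
  }
  out <- list(actives = kk[active_ok, , drop = FALSE],
              inactives = kk[inactive_ok, , drop = FALSE],
              excluded = excluded)
  class(out) <- "labeled_set"
  out
}

#' @export
print.labeled_set <- function(x, ...) {
  cat("Labeled activity set:",
      nrow(x$actives), "active,", nrow(x$inactives), "inactive,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Structural filters: desalting, duplicates, stereochemistry, MW
#'
#' Each compound is desalted (largest organic fragment kept) and
#' canonicalized; exact duplicates by canonical SMILES, compounds with any
#' unspecified potential stereocentre, and compounds with molecular weight at
#' or above `max_mw` (inclusive) are removed. Molecular weight uses average
#' atomic masses on the desalted parent.
#'
#' @param compounds data.frame with columns `compound_id` and `smiles`.
#' @param max_mw inclusive molecular-weight cutoff in Da (default 550).
#' @return list with `kept` (input order preserved; adds `canonical_smiles`
#'   and `mol_weight`) and `removed` (with `reason`).
#' @export
apply_structural_filters <- function(compounds, max_mw = 550) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  n <- nrow(compounds)
  res <- compounds
  res$canonical_smiles <- NA_character_
  res$mol_weight <- NA_real_
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    parent <- desalt_smiles(res$smiles[i])
    if (is.na(parent)) { reason[i] <- "unparseable SMILES"; next }
    can <- canonical_smiles(parent)
    if (is.na(can)) { reason[i] <- "unparseable SMILES"; next }
    res$canonical_smiles[i] <- can
    props <- molecular_properties(can)
    res$mol_weight[i] <- props$MW
    if (res$mol_weight[i] >= max_mw) { reason[i] <- sprintf("MW >= %g", max_mw); next }
    if (count_unspecified_stereocenters(can) > 0) {
      reason[i] <- "unspecified stereocenter"
      next
    }
    if (i > 1 && can %in% res$canonical_smiles[seq_len(i - 1)][is.na(reason[seq_len(i - 1)])]) {
      reason[i] <- "duplicate structure"
    }
  }
  list(kept = res[is.na(reason), , drop = FALSE],
       removed = cbind(res[!is.na(reason), , drop = FALSE],
                       reason = reason[!is.na(reason)]))
}

#' Hinge-binder heteroaromatic prefilter
#'
#' ATP-competitive kinase inhibitors anchor to the hinge through an aromatic
#' nitrogen heterocycle. A compound passes when it contains at least one
#' aromatic ring system of 5 or 6 atoms, or a fused bicyclic aromatic system
#' of 10 perimeter atoms (naphthalene-like), with at least one ring nitrogen.
#'
#' @param smiles SMILES string or `psmol` object.
#' @return logical.
#' @export
hinge_motif_filter <- function(smiles) {
  mol <- if (inherits(smiles, "psmol")) smiles else parse_smiles(smiles)
  g <- heavy_graph(mol)
  rings <- aromatic_rings(g)
  if (!length(rings)) return(FALSE)
  has_n <- function(atoms) any(g$atoms$element[atoms] == "N")
  for (r in rings) if (length(r) %in% c(5L, 6L) && has_n(r)) return(TRUE)
  for (sys in aromatic_ring_systems(rings)) {
    if (length(sys$rings) == 2L && length(sys$atoms) == 10L && has_n(sys$atoms)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Diversity selection by hierarchical Tanimoto clustering
#'
#' Clusters compounds by hierarchical clustering of the circular-fingerprint
#' Tanimoto distance matrix, cuts the tree at `distance_threshold`, and
#' returns one representative per cluster (the cluster medoid under Tanimoto
#' distance; ties go to the lowest input index).
#'
#' @param compounds data.frame with `compound_id` and `smiles` (ideally the
#'   canonical SMILES from [apply_structural_filters()]).
#' @param distance_threshold tree cut height (default 0.5).
#' @param linkage hierarchical linkage criterion (default "average").
#' @param fps optional precomputed fingerprint matrix (rows follow
#'   `compounds`).
#' @return list with `representatives` (subset of `compounds`),
#'   `cluster_labels` (integer per compound) and `n_clusters`.
#' @export
diversity_select <- function(compounds, distance_threshold = 0.5,
                             linkage = "average", fps = NULL) {
  if (nrow(compounds) == 0) stop("validation error: no compounds")
  if (nrow(compounds) == 1) {
    return(list(representatives = compounds, cluster_labels = 1L, n_clusters = 1L))
  }
  if (is.null(fps)) {
    fps <- fingerprint_matrix(compounds$smiles, ids = compounds$compound_id)
  }
  d <- tanimoto_distance_matrix(fps)
  hc <- hclust(stats::as.dist(d), method = linkage)
  labels <- cutree(hc, h = distance_threshold)
  med <- medoid_representatives(d, labels)
  list(representatives = compounds[med, , drop = FALSE],
       cluster_labels = as.integer(labels),
       n_clusters = length(unique(labels)))
}
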