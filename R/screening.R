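# Pharmacophore-constrained screening
# -----------------------------------
# Conformers are matched against a model by enumerating kind-compatible
# injective point-to-feature assignments (pruned by pairwise distance
# compatibility), superposing matched features onto point centres with the
# Kabsch algorithm, and scoring as the summed weight of points whose feature
# lands inside the point radius. Libraries are ranked by best score over up
# to `max_conformers` conformers per compound.

feature_coords <- function(features) {
  as.matrix(as.data.frame(features)[, c("x", "y", "z"), drop = FALSE])
}

# enumerate injective assignments point-subset -> features with backtracking;
# `required` gives indices of points that must be assigned.
enumerate_assignments <- function(model, features, required_idx, prune = TRUE) {
  m <- length(model$points)
  fkind <- as.data.frame(features)$kind
  fxyz <- feature_coords(features)
  pxyz <- t(vapply(model$points, `[[`, numeric(3), "center"))
  prad <- vapply(model$points, `[[`, 0, "radius")
  pkind <- vapply(model$points, `[[`, "", "kind")
  fdist <- as.matrix(dist(fxyz))
  pdist <- as.matrix(dist(pxyz))
  compat <- lapply(seq_len(m), function(i) which(fkind == pkind[i]))
  results <- list()
  assign_vec <- rep(NA_integer_, m)
  recurse <- function(i) {
    if (i > m) {
      if (sum(!is.na(assign_vec)) >= max(1L, length(required_idx))) {
        results[[length(results) + 1L]] <<- assign_vec
      }
      return(invisible())
    }
    # option: leave point i unmatched (unless required)
    if (!(i %in% required_idx)) {
      assign_vec[i] <<- NA_integer_
      recurse(i + 1L)
    }
    for (f in compat[[i]]) {
      if (f %in% assign_vec) next
      ok <- TRUE
      if (prune) {
        for (j in seq_len(i - 1L)) {
          fj <- assign_vec[j]
          if (is.na(fj)) next
          if (abs(fdist[f, fj] - pdist[i, j]) > prad[i] + prad[j]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign_vec[i] <<- f
      recurse(i + 1L)
      assign_vec[i] <<- NA_integer_
    }
    invisible()
  }
  recurse(1L)
  results
}

score_assignment <- function(model, features, assignment) {
  matched <- which(!is.na(assignment))
  if (!length(matched)) return(NULL)
  fxyz <- feature_coords(features)
  pxyz <- t(vapply(model$points, `[[`, numeric(3), "center"))
  fit <- kabsch_superpose(fxyz[assignment[matched], , drop = FALSE],
                          pxyz[matched, , drop = FALSE])
  moved <- fit$transform(fxyz)
  satisfied <- rep(FALSE, length(model$points))
  for (i in matched) {
    dd <- sqrt(sum((moved[assignment[i], ] - pxyz[i, ])^2))
    satisfied[i] <- dd <= model$points[[i]]$radius
  }
  weights <- vapply(model$points, `[[`, 0, "weight")
  list(correspondence = assignment, transform = fit, rmsd = fit$rmsd,
       satisfied = satisfied, score = sum(weights[satisfied]))
}

#' Match a conformer's features against a pharmacophore model
#'
#' Enumerates kind-compatible injective assignments of model points to ligand
#' features that cover at least the `require`d points, pruned by pairwise
#' distance compatibility (`|d_features - d_points| <= r_a + r_b`). Each
#' assignment is scored after proper-rotation least-squares superposition of
#' the matched features onto the point centres: a point is satisfied when its
#' feature lands within the point radius, and the score is the summed weight
#' of satisfied points. The best assignment wins (ties: lower RMSD, then
#' lexicographically smaller assignment). Required points must end up
#' satisfied; if no assignment achieves that the result is no-match (`NULL`).
#'
#' @param features a `ligand_features` data.frame.
#' @param model a `pharmacophore_model`.
#' @param require character vector of point labels that must be matched and
#'   satisfied (default none).
#' @param prune use the distance-compatibility pruning (the unpruned path is
#'   exhaustive and only sensible for testing).
#' @return object of class `match_result` (list with `correspondence`,
#'   `rotation`, `translation`, `rmsd`, `satisfied`, `score`,
#'   `matched_labels`), or `NULL` for no-match.
#' @export
match_model <- function(features, model, require = character(), prune = TRUE) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (!length(model$points)) stop("validation error: model has zero points")
  features <- as.data.frame(features)
  if (!nrow(features)) return(NULL)
  labels <- vapply(model$points, `[[`, "", "label")
  if (!all(require %in% labels)) {
    stop("required labels not in model: ",
         paste(setdiff(require, labels), collapse = ", "))
  }
  required_idx <- which(labels %in% require)
  assignments <- enumerate_assignments(model, features, required_idx, prune)
  best <- NULL
  for (a in assignments) {
    sc <- score_assignment(model, features, a)
    if (is.null(sc)) next
    if (length(required_idx) && !all(sc$satisfied[required_idx])) next
    if (is.null(best)) { best <- sc; next }
    better <- sc$score > best$score ||
      (sc$score == best$score && sc$rmsd < best$rmsd - 1e-12) ||
      (sc$score == best$score && abs(sc$rmsd - best$rmsd) <= 1e-12 &&
         lex_less(sc$correspondence, best$correspondence))
    if (better) best <- sc
  }
  if (is.null(best)) return(NULL)
  structure(list(
    correspondence = best$correspondence,
    rotation = best$transform$rotation,
    translation = best$transform$translation,
    rmsd = best$rmsd,
    satisfied = best$satisfied,
    score = best$score,
    matched_labels = labels[!is.na(best$correspondence)],
    hbond_ok = NA
  ), class = "match_result")
}

# lexicographic comparison of assignment vectors with NA treated as +Inf
lex_less <- function(a, b) {
  a[is.na(a)] <- .Machine$integer.max
  b[is.na(b)] <- .Machine$integer.max
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Pharmacophore match: score %g, rmsd %.3f A, %d/%d points satisfied\n",
              x$score, x$rmsd, sum(x$satisfied), length(x$satisfied)))
  invisible(x)
}

#' Geometric protein hydrogen-bond check
#'
#' True when the (transformed) acceptor lies within `max_dist` of the donor
#' hydrogen and the donor-H-acceptor angle is at least `min_angle` degrees.
#'
#' @param acceptor_pos acceptor position (length-3).
#' @param h_pos donor hydrogen position.
#' @param donor_pos donor heavy-atom position.
#' @param max_dist H...acceptor distance cutoff in Angstrom (default 2.5).
#' @param min_angle donor-H-acceptor angle cutoff in degrees (default 120).
#' @return logical.
#' @export
check_hinge_hbond <- function(acceptor_pos, h_pos, donor_pos,
                              max_dist = 2.5, min_angle = 120) {
  acceptor_pos <- as.numeric(acceptor_pos)
  h_pos <- as.numeric(h_pos); donor_pos <- as.numeric(donor_pos)
  d <- sqrt(sum((acceptor_pos - h_pos)^2))
  if (d > max_dist) return(FALSE)
  v1 <- donor_pos - h_pos; v2 <- acceptor_pos - h_pos
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang >= min_angle - 1e-9
}

# apply the protein H-bond gate of a model to a match result, if the model
# carries resolved donor coordinates
apply_hbond_gate <- function(match, features, model, ...) {
  hb <- model$hbond_constraint
  if (is.null(match) || is.null(hb) || is.null(hb$h_pos) || is.null(hb$donor_pos)) {
    return(match)
  }
  labels <- vapply(model$points, `[[`, "", "label")
  hba_idx <- which(labels == "hinge HBA")
  if (!length(hba_idx) || is.na(match$correspondence[hba_idx])) {
    match$hbond_ok <- FALSE
    return(match)
  }
  fxyz <- feature_coords(features)
  moved <- sweep(fxyz %*% t(match$rotation), 2, match$translation, "+")
  acc <- moved[match$correspondence[hba_idx], ]
  match$hbond_ok <- check_hinge_hbond(acc, hb$h_pos, hb$donor_pos, ...)
  match
}

#' Screen a conformer library against a pharmacophore model
#'
#' For each compound the best match over at most `max_conformers` conformers
#' is kept. Compounds with no admissible match receive score 0 and rank after
#' all matched compounds; ranking is by score (descending), RMSD (ascending),
#' then compound id.
#'
#' @param library named list; each element is a compound given as a list of
#'   conformers, each conformer a `ligand_features` data.frame (a bare
#'   `ligand_features` is treated as a single conformer).
#' @param model a `pharmacophore_model`.
#' @param max_conformers cap on conformers examined per compound (default
#'   200).
#' @param require point labels that must be matched and satisfied (default
#'   "hinge HBA" when the model has such a point).
#' @return data.frame of class `screen_ranking`: compound_id, score, rmsd,
#'   best_conformer, n_conformers_tried, matched_labels, hbond_ok, rank.
#' @export
screen_library <- function(library, model, max_conformers = 200,
                           require = NULL) {
  if (!length(library)) stop("empty library")
  labels <- vapply(model$points, `[[`, "", "label")
  if (is.null(require)) {
    require <- intersect("hinge HBA", labels)
  }
  ids <- names(library)
  if (is.null(ids)) ids <- sprintf("cmpd_%03d", seq_along(library))
  rows <- lapply(seq_along(library), function(ci) {
    confs <- library[[ci]]
    if (inherits(confs, "ligand_features") || is.data.frame(confs)) {
      confs <- list(confs)
    }
    stopifnot(length(confs) >= 1)
    confs <- confs[seq_len(min(length(confs), max_conformers))]
    best <- NULL; best_conf <- NA_integer_
    for (k in seq_along(confs)) {
      m <- match_model(confs[[k]], model, require = require)
      m <- apply_hbond_gate(m, confs[[k]], model)
      if (!is.null(m) && isFALSE(m$hbond_ok)) m <- NULL
      if (is.null(m)) next
      if (is.null(best) || m$score > best$score ||
          (m$score == best$score && m$rmsd < best$rmsd)) {
        best <- m; best_conf <- k
      }
    }
    data.frame(
      compound_id = ids[ci],
      score = if (is.null(best)) 0 else best$score,
      rmsd = if (is.null(best)) NA_real_ else best$rmsd,
      best_conformer = best_conf,
      n_conformers_tried = length(confs),
      matched_labels = if (is.null(best)) "" else
        paste(best$matched_labels, collapse = ";"),
      hbond_ok = if (is.null(best)) NA else best$hbond_ok,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$score, ifelse(is.na(out$rmsd), Inf, out$rmsd), out$compound_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("screen_ranking", "data.frame")
  out
}

#' Generate conformer feature sets for SMILES input
#'
#' Convenience path from SMILES to a screenable library: one 3D conformer per
#' compound is embedded with OpenBabel and its features perceived.
#'
#' @param smiles character vector.
#' @param ids compound ids.
#' @return named list of `ligand_features`, suitable for [screen_library()].
#' @export
featurize_smiles <- function(smiles, ids = smiles) {
  out <- lapply(smiles, function(s) perceive_features(parse_smiles(s, gen3d = TRUE)))
  names(out) <- ids
  out
}
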