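# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive each quantity with a different code path.

# Exhaustive pharmacophore matcher: enumerate every injective kind-compatible
# assignment (no pruning), score by Kabsch fit, apply the documented
# tie-break (score desc, rmsd asc, lexicographic assignment).
oracle_match <- function(features, model, require = character()) {
  f <- as.data.frame(features)
  labels <- vapply(model$points, `[[`, "", "label")
  req <- which(labels %in% require)
  m <- length(model$points)
  pk <- vapply(model$points, `[[`, "", "kind")
  pc <- t(vapply(model$points, `[[`, numeric(3), "center"))
  pr <- vapply(model$points, `[[`, 0, "radius")
  pw <- vapply(model$points, `[[`, 0, "weight")
  fx <- as.matrix(f[, c("x", "y", "z")])
  lex_lt <- function(a, b) {
    a[is.na(a)] <- .Machine$integer.max
    b[is.na(b)] <- .Machine$integer.max
    i <- which(a != b)
    length(i) > 0 && a[i[1]] < b[i[1]]
  }
  best <- NULL
  assign <- rep(NA_integer_, m)
  rec <- function(i) {
    if (i > m) {
      mt <- which(!is.na(assign))
      if (!length(mt)) return(invisible())
      fit <- kabsch_superpose(fx[assign[mt], , drop = FALSE],
                              pc[mt, , drop = FALSE])
      moved <- fit$transform(fx)
      sat <- rep(FALSE, m)
      for (q in mt) {
        sat[q] <- sqrt(sum((moved[assign[q], ] - pc[q, ])^2)) <= pr[q]
      }
      if (length(req) && !all(sat[req])) return(invisible())
      sc <- sum(pw[sat])
      if (is.null(best) || sc > best$score ||
          (sc == best$score && fit$rmsd < best$rmsd - 1e-12) ||
          (sc == best$score && abs(fit$rmsd - best$rmsd) <= 1e-12 &&
             lex_lt(assign, best$assign))) {
        best <<- list(score = sc, rmsd = fit$rmsd, assign = assign)
      }
      return(invisible())
    }
    if (!(i %in% req)) { assign[i] <<- NA_integer_; rec(i + 1) }
    for (ff in which(f$kind == pk[i])) {
      if (ff %in% assign) next
      assign[i] <<- ff; rec(i + 1); assign[i] <<- NA_integer_
    }
    invisible()
  }
  rec(1)
  best
}

random_match_instance <- function(max_features = 8, max_points = 5) {
  nf <- sample(3:max_features, 1)
  np <- sample(2:max_points, 1)
  kinds <- c("HBA", "HBD", "AromaticRing")
  model <- pharmacophore_model("rand", lapply(seq_len(np), function(i) {
    list(kind = sample(kinds, 1), center = runif(3, -5, 5),
         radius = runif(1, 0.5, 2), weight = sample(c(5, 10), 1),
         label = paste0("p", i))
  }))
  feats <- ligand_features(sample(kinds, nf, replace = TRUE),
                           matrix(runif(nf * 3, -5, 5), ncol = 3))
  list(model = model, features = feats)
}

# Per-point silhouette from first principles
oracle_mean_silhouette <- function(labels, d) {
  d <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Circular-environment enumeration by string labels: an independent
# re-derivation of the fingerprint abstraction. Returns the set of distinct
# environment strings after the same covered-bond-set deduplication.
oracle_environment_set <- function(smiles, radius = 3L) {
  g <- phorescreen:::heavy_graph(parse_smiles(smiles))
  n <- length(g$adj)
  rb <- phorescreen:::ring_bonds(g)
  ring <- logical(n)
  if (any(rb)) ring[unique(c(g$bonds$a1[rb], g$bonds$a2[rb]))] <- TRUE
  lab <- vapply(seq_len(n), function(i) {
    paste(g$atoms$element[i], length(g$adj[[i]]), g$n_h[i],
          g$atoms$charge[i], as.integer(ring[i]), sep = "_")
  }, "")
  bond_key <- function(i, j) {
    b <- g$bonds
    k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))[1]
    list(idx = k, code = if (b$aromatic[k]) 4L else b$order[k])
  }
  env_bonds <- rep(list(integer()), n)
  out <- lab                      # radius-0 strings, all atoms
  seen_envs <- character()
  for (r in seq_len(radius)) {
    newlab <- lab
    newenv <- env_bonds
    for (i in seq_len(n)) {
      nb <- g$adj[[i]]
      if (!length(nb)) { newlab[i] <- paste0(r, "{", lab[i], "}"); next }
      info <- lapply(nb, function(j) bond_key(i, j))
      parts <- vapply(seq_along(nb), function(q) {
        paste0(info[[q]]$code, ":", lab[nb[q]])
      }, "")
      newlab[i] <- paste0(r, "{", lab[i], ";", paste(sort(parts), collapse = ","), "}")
      newenv[[i]] <- sort(unique(c(env_bonds[[i]], unlist(env_bonds[nb]),
                                   vapply(info, `[[`, 0L, "idx"))))
    }
    keys <- vapply(newenv, function(b) paste(b, collapse = ","), "")
    ord <- order(keys, newlab)
    kept_keys <- character()
    for (i in ord) {
      if (keys[i] %in% seen_envs || keys[i] %in% kept_keys) next
      out <- c(out, newlab[i])
      kept_keys <- c(kept_keys, keys[i])
    }
    seen_envs <- c(seen_envs, kept_keys)
    lab <- newlab
    env_bonds <- newenv
  }
  unique(out)
}

set_tanimoto <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# small adjusted Rand index (cross-checked against mclust in tests)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}
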