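# Chemical-space embedding and clustering
# ---------------------------------------
# Fingerprint populations are embedded to two dimensions (Z-score + PCA, or
# metric MDS of the Tanimoto distance matrix) and clustered; the clustering
# algorithm and k are selected jointly by the mean silhouette coefficient
# over a k grid, and k-medoids names one representative compound per cluster.

#' Z-score + PCA embedding of a fingerprint matrix
#'
#' Bits are standardized per column (constant bits map to zero rather than
#' NaN, preserving column indexing), the top two principal components are
#' taken, and each dimension is min-max rescaled to `[0, 1]`. A constant
#' dimension rescales to 0.
#'
#' @param fps binary fingerprint matrix (rows = compounds, >= 3 rows).
#' @return object of class `chem_embedding`: list with `coords` (n x 2 matrix
#'   in `[0,1]`), `method = "PCA"`, `diagnostic` (fraction of variance
#'   explained by the two components).
#' @export
zscore_pca_embed <- function(fps) {
  fps <- as.matrix(fps)
  if (nrow(fps) < 3) stop("validation error: need at least 3 compounds for PCA")
  mu <- colMeans(fps)
  sdv <- apply(fps, 2, stats::sd)
  z <- sweep(fps, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = 2)
  coords <- pc$x[, 1:2, drop = FALSE]
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  explained <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  rescale01 <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-9 * max(1, abs(r[1]))) return(rep(0, length(v)))
    (v - r[1]) / diff(r)
  }
  coords <- apply(coords, 2, rescale01)
  dimnames(coords) <- list(rownames(fps), c("dim1", "dim2"))
  structure(list(coords = coords, method = "PCA", diagnostic = explained),
            class = "chem_embedding")
}

#' Metric multidimensional scaling of a distance matrix
#'
#' Least-squares metric MDS (SMACOF majorization) initialized from classical
#' scaling, which makes the result fully deterministic. Stress is the
#' normalized Kruskal stress-1 of the final configuration.
#'
#' @param distances symmetric distance matrix with zero diagonal.
#' @param ndim embedding dimension (default 2).
#' @param max_iter,tol majorization iteration controls.
#' @return `chem_embedding` with `coords`, `method = "MDS"`, `diagnostic`
#'   (stress-1).
#' @export
mds_embed <- function(distances, ndim = 2, max_iter = 300, tol = 1e-10) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("validation error: distance matrix must be symmetric")
  }
  if (any(diag(d) != 0)) stop("validation error: nonzero diagonal")
  n <- nrow(d)
  x <- suppressWarnings(stats::cmdscale(d, k = ndim))
  if (ncol(x) < ndim) x <- cbind(x, matrix(0, n, ndim - ncol(x)))
  stress1 <- function(x) {
    dh <- as.matrix(dist(x))
    sqrt(sum((d - dh)^2) / max(sum(d^2), .Machine$double.eps))
  }
  s_old <- stress1(x)
  w <- matrix(1, n, n)               # unit weights; V+ = (1/n) centering
  diag(w) <- 0
  for (it in seq_len(max_iter)) {
    dh <- as.matrix(dist(x))
    b <- ifelse(dh > 0, -w * d / pmax(dh, .Machine$double.eps), 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x_new <- (b %*% x) / n
    s_new <- stress1(x_new)
    if (!is.finite(s_new) || s_new > s_old) break   # majorization is monotone
    x <- x_new
    if (s_old - s_new < tol) { s_old <- s_new; break }
    s_old <- s_new
  }
  dimnames(x) <- list(rownames(d), paste0("dim", seq_len(ndim)))
  structure(list(coords = x, method = "MDS", diagnostic = s_old),
            class = "chem_embedding")
}

#' Mean silhouette coefficient of a labeling
#'
#' @param labels integer cluster labels.
#' @param d distance matrix (or `dist`).
#' @return mean over points of `(b - a) / max(a, b)`.
#' @export
mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(as.integer(labels), stats::as.dist(as.matrix(d)))
  mean(sil[, "sil_width"])
}

# deterministic farthest-point initial centers for k-means
farthest_point_init <- function(x, k) {
  n <- nrow(x)
  ctr <- colMeans(x)
  first <- which.min(rowSums(sweep(x, 2, ctr, "-")^2))
  sel <- first
  while (length(sel) < k) {
    dmin <- apply(as.matrix(dist(x))[, sel, drop = FALSE], 1, min)
    dmin[sel] <- -1
    sel <- c(sel, which.max(dmin))
  }
  x[sel, , drop = FALSE]
}

fit_clustering <- function(x, d, method, k, seed) {
  if (method == "hierarchical") {
    hc <- hclust(stats::as.dist(d), method = "average")
    return(cutree(hc, k = k))
  }
  if (method == "kmeans") {
    if (is.null(x)) stop("kmeans requires coordinates, not a distance matrix")
    best <- kmeans(x, centers = farthest_point_init(x, k), iter.max = 100)
    if (!is.null(seed)) {
      old <- .Random.seed_get()
      set.seed(seed)
      for (r in 1:9) {
        cand <- tryCatch(kmeans(x, centers = k, iter.max = 100),
                         error = function(e) NULL)
        if (!is.null(cand) && cand$tot.withinss < best$tot.withinss) best <- cand
      }
      .Random.seed_set(old)
    }
    return(as.integer(best$cluster))
  }
  if (method == "kmedoids") {
    return(as.integer(cluster::pam(stats::as.dist(d), k = k,
                                   cluster.only = TRUE)))
  }
  stop("unknown clustering method: ", method)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Silhouette-driven selection of clustering algorithm and k
#'
#' Fits every requested method at every k in `k_range`, scores each labeling
#' by the mean silhouette coefficient, and returns the winner. Ties are broken
#' by smaller k, then by method order hierarchical < kmeans < kmedoids.
#'
#' @param x a `chem_embedding`, a coordinate matrix, or a symmetric distance
#'   matrix (with `is_distance = TRUE`).
#' @param methods subset of c("hierarchical", "kmeans", "kmedoids").
#' @param k_range integer candidates for k (default 3:30; truncated to n - 1
#'   with a warning when the data are smaller).
#' @param is_distance interpret `x` as a distance matrix.
#' @param seed seed for the k-means restarts.
#' @return object of class `clustering_result`: list with `labels`, `method`,
#'   `k`, `mean_silhouette`, `medoid_ids` (row indices), `candidates`
#'   (data.frame of all method x k scores).
#' @export
select_clustering <- function(x, methods = c("hierarchical", "kmeans", "kmedoids"),
                              k_range = 3:30, is_distance = FALSE, seed = 1L) {
  methods <- match.arg(methods, c("hierarchical", "kmeans", "kmedoids"),
                       several.ok = TRUE)
  if (inherits(x, "chem_embedding")) x <- x$coords
  x <- as.matrix(x)
  if (is_distance) {
    d <- x
    coords <- NULL
    methods <- setdiff(methods, "kmeans")
    if (!length(methods)) stop("kmeans cannot run on a distance matrix")
  } else {
    coords <- x
    d <- as.matrix(dist(x))
  }
  n <- nrow(d)
  if (max(d) < .Machine$double.eps) stop("degenerate data: all points identical")
  if (n <= max(k_range)) {
    k_range <- k_range[k_range <= n - 1]
    warning("k range truncated to n - 1 = ", n - 1)
  }
  if (!length(k_range)) stop("no feasible k for n = ", n)
  method_order <- c("hierarchical", "kmeans", "kmedoids")
  cand <- expand.grid(method = intersect(method_order, methods), k = sort(k_range),
                      stringsAsFactors = FALSE)
  cand$mean_silhouette <- NA_real_
  fits <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    lab <- tryCatch(fit_clustering(coords, d, cand$method[i], cand$k[i], seed),
                    error = function(e) NULL)
    if (is.null(lab) || length(unique(lab)) < 2) next
    fits[[i]] <- lab
    cand$mean_silhouette[i] <- mean_silhouette(lab, d)
  }
  ok <- which(!is.na(cand$mean_silhouette))
  if (!length(ok)) stop("degenerate data: no valid clustering")
  ord <- ok[order(-cand$mean_silhouette[ok], cand$k[ok],
                  match(cand$method[ok], method_order))]
  best <- ord[1]
  labels <- fits[[best]]
  med <- medoid_representatives(d, labels)
  structure(list(labels = as.integer(labels),
                 method = cand$method[best],
                 k = as.integer(cand$k[best]),
                 mean_silhouette = cand$mean_silhouette[best],
                 medoid_ids = med,
                 candidates = cand),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("Clustering:", x$method, "k =", x$k,
      sprintf("(mean silhouette %.3f)\n", x$mean_silhouette))
  invisible(x)
}

#' Medoid representative of each cluster
#'
#' The medoid is the member minimizing the summed distance to its co-members;
#' ties are broken by the lowest row index.
#'
#' @param d distance matrix.
#' @param labels cluster labels covering all rows of `d`.
#' @return integer vector of row indices, one per distinct label (in label
#'   order).
#' @export
medoid_representatives <- function(d, labels) {
  d <- as.matrix(d)
  stopifnot(length(labels) == nrow(d))
  vapply(sort(unique(labels)), function(l) {
    members <- which(labels == l)
    if (length(members) == 1) return(members)
    sums <- rowSums(d[members, members, drop = FALSE])
    members[which.min(sums)]
  }, integer(1))
}
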