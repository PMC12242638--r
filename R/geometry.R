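# Rigid-body geometry
# -------------------
# Kabsch least-squares superposition restricted to proper rotations, shared
# by the pharmacophore matcher and the binding-site comparison.

#' Kabsch superposition of paired point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `x %*% t(R) + t` onto `y` (rows are paired points). Reflections are never
#' returned: when the optimal orthogonal transform is improper the sign of the
#' smallest singular direction is flipped.
#'
#' @param x,y n x 3 matrices of paired coordinates (n >= 1).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd`, and `transform(points)` applying the fit to new coordinates.
#' @export
kabsch_superpose <- function(x, y) {
  x <- matrix(as.numeric(x), ncol = 3)
  y <- matrix(as.numeric(y), ncol = 3)
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 1)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  h <- t(x0) %*% y0
  s <- svd(h)
  dsign <- sign(det(s$v %*% t(s$u)))
  if (dsign == 0) dsign <- 1
  r <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  trans <- cy - as.numeric(r %*% cx)
  fitted <- sweep(x %*% t(r), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(
    rotation = r,
    translation = trans,
    rmsd = rmsd,
    transform = function(points) {
      points <- matrix(as.numeric(points), ncol = 3)
      sweep(points %*% t(r), 2, trans, "+")
    }
  )
}

#' Root-mean-square deviation of paired coordinates
#' @param x,y n x 3 matrices.
#' @return RMSD in the input units.
#' @export
coord_rmsd <- function(x, y) {
  x <- matrix(as.numeric(x), ncol = 3); y <- matrix(as.numeric(y), ncol = 3)
  stopifnot(nrow(x) == nrow(y))
  sqrt(mean(rowSums((x - y)^2)))
}

# random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
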