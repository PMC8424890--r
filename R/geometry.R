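# small 3D geometry kernel used by all detectors; coordinates in Angstrom

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Minimum pairwise distance between two coordinate sets
#'
#' @param a,b numeric matrices with 3 columns (x, y, z), one row per atom.
#' @return The minimum Euclidean distance in Angstrom.
#' @examples
#' min_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))
#' @export
min_distance <- function(a, b) {
  a <- coord_matrix(a)
  b <- coord_matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("min_distance() requires non-empty coordinate sets", call. = FALSE)
  }
  # pairwise squared distances via the expansion |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  x
}

# interior angle at b of the path a-b-c, in degrees, in [0, 180]
angle_deg <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# angle between two (unoriented) directions folded to [0, 90] degrees
folded_angle_deg <- function(u, v) {
  u <- unit(u)
  v <- unit(v)
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}

# least-squares plane through >= 3 points: centroid + unit normal
# (normal = eigenvector of the smallest eigenvalue of the covariance)
best_fit_plane <- function(coords) {
  coords <- coord_matrix(coords)
  if (nrow(coords) < 3L) stop("plane fit needs at least 3 atoms", call. = FALSE)
  ctr <- colMeans(coords)
  centered <- sweep(coords, 2, ctr)
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  if (ev$values[2] < 1e-9) {
    stop("collinear atoms: ring plane is undefined", call. = FALSE)
  }
  list(centroid = ctr, normal = unit(ev$vectors[, 3L]))
}

# rotation matrix for angle (degrees) about unit axis, Rodrigues form
rotation_matrix <- function(axis, angle_deg) {
  k <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
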