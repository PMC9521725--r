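#' Generate a closed triangulated ellipsoidal chamber surface
#'
#' Builds a latitude/longitude triangulation of the ellipsoid
#' `(x/a)^2 + (y/b)^2 + (z/c)^2 = 1` centred at `center`, as a stand-in for
#' the mapped cardiac chamber. With `n_theta` latitude bands and `n_phi`
#' meridians the surface is closed (two pole fans plus quad strips split
#' into triangles). Optionally maps each electrode to its nearest vertex.
#'
#' @param radii Semi-axes a, b, c in mm (length 1 or 3; a single value gives
#'   a sphere).
#' @param center Ellipsoid centre, mm (length 3).
#' @param n_theta Number of latitude bands (>= 3).
#' @param n_phi Number of meridians (>= 3).
#' @param electrodes Optional electrode position matrix (n x 3, named rows);
#'   when given, a nearest-vertex map is attached.
#' @return A list of class `deep_mesh` with `vertices` (V x 3 matrix, mm),
#'   `faces` (F x 3 integer matrix, 1-based, counter-clockwise outward),
#'   and, when `electrodes` was supplied, `nearest_vertex` (named integer
#'   vector) and `nearest_distance` (named numeric, mm).
#' @export
#' @examples
#' m <- generate_mesh(30, electrodes = rbind(E1 = c(0, 0, 29)))
#' m$vertices[m$nearest_vertex["E1"], ]
generate_mesh <- function(radii = 30, center = c(0, 0, 0),
                          n_theta = 24, n_phi = 48, electrodes = NULL) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0)) {
    stop_typed("bad_mesh", "radii must be 1 or 3 positive finite values")
  }
  if (n_theta < 3L || n_phi < 3L) {
    stop_typed("bad_mesh", "need at least 3 latitude bands and 3 meridians")
  }

  # interior ring vertices + 2 poles
  theta <- seq(0, pi, length.out = n_theta + 1L)[-c(1L, n_theta + 1L)]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  grid <- expand.grid(phi = phi, theta = theta)
  ring <- cbind(
    x = radii[1] * sin(grid$theta) * cos(grid$phi),
    y = radii[2] * sin(grid$theta) * sin(grid$phi),
    z = radii[3] * cos(grid$theta)
  )
  north <- c(0, 0, radii[3])
  south <- c(0, 0, -radii[3])
  vertices <- rbind(north, ring, south)
  vertices <- sweep(vertices, 2L, center, `+`)
  rownames(vertices) <- NULL
  colnames(vertices) <- c("x", "y", "z")

  n_rings <- n_theta - 1L
  vid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  south_id <- nrow(vertices)

  faces <- vector("list", 2L * n_phi + 2L * n_phi * (n_rings - 1L))
  k <- 0L
  for (j in seq_len(n_phi)) {                 # north fan
    k <- k + 1L
    faces[[k]] <- c(1L, vid(1L, j), vid(1L, j + 1L))
  }
  if (n_rings > 1L) {
    for (i in seq_len(n_rings - 1L)) {        # quad strips
      for (j in seq_len(n_phi)) {
        a <- vid(i, j); b <- vid(i, j + 1L)
        cc <- vid(i + 1L, j); d <- vid(i + 1L, j + 1L)
        k <- k + 1L; faces[[k]] <- c(a, cc, b)
        k <- k + 1L; faces[[k]] <- c(b, cc, d)
      }
    }
  }
  for (j in seq_len(n_phi)) {                 # south fan
    k <- k + 1L
    faces[[k]] <- c(south_id, vid(n_rings, j + 1L), vid(n_rings, j))
  }
  faces <- do.call(rbind, faces)
  storage.mode(faces) <- "integer"

  mesh <- structure(list(vertices = vertices, faces = faces,
                         radii = radii, center = center),
                    class = "deep_mesh")
  if (!is.null(electrodes)) {
    nv <- nearest_vertices(mesh, electrodes)
    mesh$nearest_vertex <- nv$index
    mesh$nearest_distance <- nv$distance
  }
  mesh
}

#' Nearest mesh vertex for each query point (Euclidean, brute force)
#'
#' @param mesh A `deep_mesh`.
#' @param points n x 3 matrix of positions, mm; row names are kept.
#' @return List with `index` (1-based vertex ids) and `distance` (mm), both
#'   named after the query rows.
#' @export
nearest_vertices <- function(mesh, points) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_typed("bad_mesh", "points must be n x 3")
  idx <- integer(nrow(points))
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums(sweep(mesh$vertices, 2L, points[i, ], `-`)^2)
    idx[i] <- which.min(d2)
    dist[i] <- sqrt(d2[idx[i]])
  }
  names(idx) <- rownames(points)
  names(dist) <- rownames(points)
  list(index = idx, distance = dist)
}

#' Typical edge length of a mesh (median over all face edges)
#' @param mesh A `deep_mesh`.
#' @return Median edge length in mm.
#' @export
mesh_edge_length <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  stats::median(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                                v[e[, 2], , drop = FALSE])^2)))
}

#' @export
print.deep_mesh <- function(x, ...) {
  cat(sprintf("Chamber surface mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  semi-axes (mm): %s; median edge %.2f mm\n",
              paste(format(x$radii), collapse = ", "), mesh_edge_length(x)))
  if (!is.null(x$nearest_vertex)) {
    cat(sprintf("  %d electrodes mapped to nearest vertices\n",
                length(x$nearest_vertex)))
  }
  invisible(x)
}
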