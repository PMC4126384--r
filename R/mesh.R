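## Structured hexahedral meshing of the RVE box and point location for
## embedded fiber nodes.

#' Structured hexahedral mesh of a box domain
#'
#' Per-axis element counts are `max(1, round(size / target_element_size))`.
#' Nodes are ordered lexicographically with x fastest:
#' `id = 1 + ix + iy (nx+1) + iz (nx+1)(ny+1)`.  Connectivity follows the
#' VTK hexahedron ordering, giving positive Jacobians everywhere.
#'
#' @param domain a [box_domain()].
#' @param target_element_size requested element edge length in um.
#' @return Object of class `fe_mesh` with `nodes` (N x 3), `conn`
#'   (nel x 8, integer), per-axis counts `nelem`, spacings `h`, and face
#'   node sets `z0`, `z1`.
#' @export
mesh_box <- function(domain, target_element_size = 0.2) {
  stopifnot(inherits(domain, "box_domain"), target_element_size > 0)
  sz <- box_sizes(domain)
  ne <- pmax(1L, as.integer(round(sz / target_element_size)))
  nn <- ne + 1L
  xs <- seq(0, sz[1], length.out = nn[1])
  ys <- seq(0, sz[2], length.out = nn[2])
  zs <- seq(0, sz[3], length.out = nn[3])
  nodes <- cbind(rep(xs, times = nn[2] * nn[3]),
                 rep(rep(ys, each = nn[1]), times = nn[3]),
                 rep(zs, each = nn[1] * nn[2]))
  nid <- function(ix, iy, iz) 1L + ix + iy * nn[1] + iz * nn[1] * nn[2]
  ix <- rep(0:(ne[1] - 1L), times = ne[2] * ne[3])
  iy <- rep(rep(0:(ne[2] - 1L), each = ne[1]), times = ne[3])
  iz <- rep(0:(ne[3] - 1L), each = ne[1] * ne[2])
  conn <- cbind(nid(ix, iy, iz), nid(ix + 1L, iy, iz),
                nid(ix + 1L, iy + 1L, iz), nid(ix, iy + 1L, iz),
                nid(ix, iy, iz + 1L), nid(ix + 1L, iy, iz + 1L),
                nid(ix + 1L, iy + 1L, iz + 1L), nid(ix, iy + 1L, iz + 1L))
  storage.mode(conn) <- "integer"
  structure(list(nodes = nodes, conn = conn, nelem = ne, nnode = nn,
                 h = sz / ne, domain = domain,
                 z0 = which(nodes[, 3] <= 0),
                 z1 = which(nodes[, 3] >= sz[3] - 1e-12)),
            class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("structured hex mesh: %d x %d x %d = %d elements, %d nodes\n",
              x$nelem[1], x$nelem[2], x$nelem[3], prod(x$nelem),
              nrow(x$nodes)))
  invisible(x)
}

#' Host element and trilinear weights of an embedded point
#'
#' Finds the structured-grid element containing `point` by index
#' arithmetic and returns the trilinear shape-function weights at the
#' point's local coordinates (partition of unity holds to round-off).
#'
#' @param point length-3 coordinate inside the domain.
#' @param mesh an [mesh_box()] mesh.
#' @return List with `element` (1-based element index), `nodes` (the 8
#'   host node ids in connectivity order) and `weights`.
#' @export
locate_host_and_weights <- function(point, mesh) {
  stopifnot(inherits(mesh, "fe_mesh"), length(point) == 3L)
  sz <- box_sizes(mesh$domain)
  if (any(point < -1e-9) || any(point > sz + 1e-9))
    stop("geometry error: point lies outside the mesh domain")
  idx <- pmin(pmax(floor(point / mesh$h), 0), mesh$nelem - 1L)
  el <- as.integer(1L + idx[1] + idx[2] * mesh$nelem[1] +
                     idx[3] * mesh$nelem[1] * mesh$nelem[2])
  lc <- 2 * (point - idx * mesh$h) / mesh$h - 1  # local coords in [-1, 1]
  lc <- pmin(pmax(lc, -1), 1)
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  w <- 0.125 * (1 + lc[1] * sgn[, 1]) * (1 + lc[2] * sgn[, 2]) *
    (1 + lc[3] * sgn[, 3])
  list(element = el, nodes = mesh$conn[el, ], weights = as.numeric(w))
}
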