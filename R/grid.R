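#' Voxel grid
#'
#' A regular axis-aligned voxel lattice. Voxel indices are 0-based and refer
#' to voxel centres; world coordinates are millimetres. The voxel-to-world
#' map is \code{world = origin + index * voxel}, i.e. a diagonal affine, which
#' is the single coordinate convention used throughout the package (the NIfTI
#' affine written on export is built from it).
#'
#' @param shape integer length-3, number of voxels per axis.
#' @param voxel numeric length-3 (or scalar), voxel size in mm.
#' @param origin world coordinate of voxel (0,0,0); default centres the grid
#'   on the world origin.
#' @return an object of class \code{vox_grid}.
#' @export
vox_grid <- function(shape, voxel, origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  stopifnot(length(voxel) == 3L, all(voxel > 0))
  if (is.null(origin)) origin <- -(shape - 1L) * voxel / 2
  stopifnot(length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, voxel = as.numeric(voxel),
                 origin = as.numeric(origin)),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

#' Grid affine as a 4x4 voxel-to-world matrix
#' @param grid a \code{vox_grid}.
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  rbind(cbind(diag(grid$voxel), grid$origin), c(0, 0, 0, 1))
}

grid_from_affine <- function(affine, shape) {
  m <- affine[1:3, 1:3]
  if (max(abs(m - diag(diag(m)))) > 1e-6)
    stop("only axis-aligned (diagonal) affines are supported", call. = FALSE)
  vox_grid(shape, diag(m), affine[1:3, 4])
}

## points: n x 3 world mm -> n x 3 continuous 0-based voxel coordinates
world_to_voxel <- function(grid, pts) {
  pts <- rbind(pts)
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$voxel, "/")
}

voxel_to_world <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk, 2, grid$voxel, "*"), 2, grid$origin, "+")
}

## nearest-voxel 0-based integer indices (no bounds clipping)
nearest_voxel <- function(grid, pts) {
  round(world_to_voxel(grid, pts))
}

## 1-based linear index into an array of dim grid$shape; NA if out of bounds
voxel_linear <- function(grid, ijk) {
  ijk <- rbind(ijk)
  ok <- ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
        ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
        ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
  idx <- 1 + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
  idx[!ok] <- NA_integer_
  idx
}

in_grid <- function(grid, pts) {
  v <- world_to_voxel(grid, pts)
  v[, 1] > -0.5 & v[, 1] < grid$shape[1] - 0.5 &
  v[, 2] > -0.5 & v[, 2] < grid$shape[2] - 0.5 &
  v[, 3] > -0.5 & v[, 3] < grid$shape[3] - 0.5
}

## world coordinates of every voxel centre, n_voxels x 3, in array order
grid_coords <- function(grid) {
  s <- grid$shape
  i <- rep.int(0:(s[1] - 1L), s[2] * s[3])
  j <- rep.int(rep(0:(s[2] - 1L), each = s[1]), s[3])
  k <- rep(0:(s[3] - 1L), each = s[1] * s[2])
  voxel_to_world(grid, cbind(i, j, k))
}

half_diagonal <- function(grid) sqrt(sum(grid$voxel^2)) / 2

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel - b$voxel)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

## world coordinates (n x 3) of TRUE voxels of a mask array on grid
mask_coords <- function(grid, mask) {
  idx <- which(mask) - 1L
  s <- grid$shape
  i <- idx %% s[1]
  j <- (idx %/% s[1]) %% s[2]
  k <- idx %/% (s[1] * s[2])
  voxel_to_world(grid, cbind(i, j, k))
}

## binary dilation of a logical 3-D array by one voxel (26-connectivity)
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] | mask[xs - dx, ys - dy, zs - dz]
  }
  out
}

## sphere / box masks used by the phantom fixture; coords may be passed to
## avoid recomputing the voxel-centre table
sphere_mask <- function(grid, centre, radius, coords = NULL) {
  co <- if (is.null(coords)) grid_coords(grid) else coords
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 + (co[, 3] - centre[3])^2
  array(d2 <= radius^2, dim = grid$shape)
}

box_mask <- function(grid, centre, half_width, coords = NULL) {
  co <- if (is.null(coords)) grid_coords(grid) else coords
  ok <- abs(co[, 1] - centre[1]) <= half_width[1] &
        abs(co[, 2] - centre[2]) <= half_width[2] &
        abs(co[, 3] - centre[3]) <= half_width[3]
  array(ok, dim = grid$shape)
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}
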