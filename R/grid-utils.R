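# 3D grid index arithmetic shared by the generator and the cluster correction.

#' Convert between linear voxel indices and 3D coordinates
#'
#' Linear indices are 1-based with the x coordinate varying fastest
#' (R array order), giving a bijection with integer coordinates.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param idx integer vector of linear voxel indices.
#' @param coords integer matrix with three columns (x, y, z).
#' @return `voxelCoords()` returns an `n x 3` integer matrix;
#'   `voxelIndex()` returns an integer vector.
#' @export
voxelCoords <- function(grid, idx) {
  stopifnot(is(grid, "VoxelGrid"))
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > nVoxels(grid)))
    stop("voxel index outside the grid")
  arrayInd(idx, grid@dims)
}

#' @rdname voxelCoords
#' @export
voxelIndex <- function(grid, coords) {
  stopifnot(is(grid, "VoxelGrid"))
  coords <- matrix(as.integer(coords), ncol = 3)
  d <- grid@dims
  if (length(coords) && (any(coords < 1L) || any(coords[, 1] > d[1]) ||
                         any(coords[, 2] > d[2]) || any(coords[, 3] > d[3])))
    stop("coordinates outside the grid")
  coords[, 1] + d[1] * (coords[, 2] - 1L) + d[1] * d[2] * (coords[, 3] - 1L)
}

# offset table for a connectivity level; rows are (dx, dy, dz), origin excluded
.neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(connectivity,
    "faces" = ord == 1,
    "faces+edges" = ord >= 1 & ord <= 2,
    "faces+edges+corners" = ord >= 1,
    stop("unknown connectivity: ", connectivity))
  g[keep, , drop = FALSE]
}

# linear indices of in-grid neighbours of `idx` for each offset row;
# returns a list: one integer vector per input index? No — vectorized:
# for a vector of indices, returns a two-column matrix (from, to) of
# neighbour pairs with `to` inside the grid.
.neighbour_pairs <- function(grid, idx, connectivity) {
  d <- grid@dims
  off <- .neighbour_offsets(connectivity)
  # use only "positive" offsets so each undirected pair appears once
  pos <- off[off[, 1] + 10 * off[, 2] + 100 * off[, 3] > 0, , drop = FALSE]
  co <- voxelCoords(grid, idx)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(pos))) {
    nx <- co[, 1] + pos[r, 1]; ny <- co[, 2] + pos[r, 2]; nz <- co[, 3] + pos[r, 3]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
    if (any(ok)) {
      from <- c(from, idx[ok])
      to <- c(to, nx[ok] + d[1] * (ny[ok] - 1L) + d[1] * d[2] * (nz[ok] - 1L))
    }
  }
  cbind(from = from, to = to)
}
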