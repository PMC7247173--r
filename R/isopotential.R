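## Isopotential surface extraction from scalar potential grids.

#' Extract an isopotential mesh from a scalar grid
#'
#' Marches the grid cells with the same consistency-guaranteed 256-case
#' table used by the solid mesher.  For a positive threshold `k` the mesh
#' bounds the region with potential `>= k`; for negative `k` the region with
#' potential `<= k`.  The grid is padded with one layer of exterior values so
#' regions cut by the grid box are capped and the mesh is closed.  Vertices
#' are placed on grid edges by linear interpolation of the potential.
#'
#' @param grid a `potential_grid` (see [point_charge_grid()] or
#'   [read_opendx()]).
#' @param k isopotential threshold, nonzero, in the grid's units.
#' @return a closed [triangle_mesh()]; empty (with a warning) if the
#'   threshold is outside the grid's value range.
#' @examples
#' g <- point_charge_grid(data.frame(x = 0, y = 0, z = 0, q = 1),
#'                        origin = c(-4, -4, -4), delta = 0.5,
#'                        counts = c(17, 17, 17))
#' m <- extract_isopotential_mesh(g, 0.5)   # phi = q/r = 0.5 at r = 2
#' @export
extract_isopotential_mesh <- function(grid, k) {
  stopifnot(inherits(grid, "potential_grid"), is.finite(k), k != 0)
  vals <- grid$values
  inside_fun <- if (k > 0) function(v) v >= k else function(v) v <= k
  if (!any(inside_fun(vals))) {
    warning("threshold outside the grid's value range: empty isosurface")
    return(triangle_mesh())
  }
  dims <- dim(vals)
  pad_val <- if (k > 0) min(vals) - abs(k) - 1 else max(vals) + abs(k) + 1
  pv <- array(pad_val, dims + 2L)
  pv[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- vals
  A <- inside_fun(pv)
  pd <- dims + 2L
  ncell <- pd - 1L
  ## 8-bit mask per cell from shifted corner slabs
  mask <- array(0L, ncell)
  for (c in 1:8) {
    off <- CORNER_OFFSETS[c, ]
    mask <- mask + bitwShiftL(1L, c - 1L) *
      A[(1 + off[1]):(ncell[1] + off[1]),
        (1 + off[2]):(ncell[2] + off[2]),
        (1 + off[3]):(ncell[3] + off[3])]
  }
  surf <- which(mask >= 1L & mask <= 254L, arr.ind = TRUE)
  if (nrow(surf) == 0) return(triangle_mesh())
  cells <- unname(as.matrix(surf)) - 1L      # 0-based padded cell index
  edges <- mc_edge_defs()
  eaxis <- apply(edges, 1, function(e)
    which(CORNER_OFFSETS[e[1] + 1, ] != CORNER_OFFSETS[e[2] + 1, ]))
  nxc <- pd[1]; nyc <- pd[2]
  cid <- function(idx) idx[, 1] + nxc * (idx[, 2] + nyc * idx[, 3])
  ## collect crossed edges of surface cells
  keys12 <- matrix(0, nrow(cells), 12)
  crossed12 <- matrix(FALSE, nrow(cells), 12)
  val_at <- function(idx) pv[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)]
  in_at <- function(idx) A[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)]
  for (e in 1:12) {
    lo <- sweep(cells, 2, CORNER_OFFSETS[edges[e, 1] + 1, ], "+")
    hi <- sweep(cells, 2, CORNER_OFFSETS[edges[e, 2] + 1, ], "+")
    keys12[, e] <- cid(lo) * 3 + (eaxis[e] - 1)
    crossed12[, e] <- xor(in_at(lo), in_at(hi))
  }
  mkeys <- sort(unique(as.vector(keys12[crossed12])))
  ## vertex per crossed edge by linear interpolation to the level k
  ax <- mkeys %% 3 + 1
  lo_id <- mkeys %/% 3
  lo_idx <- cbind(lo_id %% nxc, (lo_id %/% nxc) %% nyc, lo_id %/% (nxc * nyc))
  hi_idx <- lo_idx
  hi_idx[cbind(seq_along(ax), ax)] <- hi_idx[cbind(seq_along(ax), ax)] + 1
  v0 <- val_at(lo_idx); v1 <- val_at(hi_idx)
  tt <- pmin(pmax((k - v0) / (v1 - v0), 0), 1)
  coord <- function(idx) sweep((idx - 1) * grid$delta, 2, grid$origin, "+")
  pts <- coord(lo_idx) * (1 - tt) + coord(hi_idx) * tt
  ## triangulate with the shared lookup table
  tab <- mc_table()
  vidx12 <- matrix(match(keys12, mkeys), nrow(cells), 12)
  tris <- vector("list", nrow(cells))
  mvec <- mask[surf]
  for (i in seq_len(nrow(cells))) {
    tr <- tab[[mvec[i] + 1]]
    if (length(tr) == 0) next
    tris[[i]] <- matrix(vidx12[i, tr + 1], ncol = 3, byrow = TRUE)
  }
  tri <- do.call(rbind, tris)
  mesh_weld(triangle_mesh(pts, tri))
}
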