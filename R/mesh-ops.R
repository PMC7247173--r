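## Volumetric and shape metrics on triangle meshes.

#' Enclosed volume by the Surveyor's formula
#'
#' Divides any (possibly nonconvex) closed oriented mesh into signed
#' tetrahedra against the origin and sums their volumes.  For a single
#' outward-oriented shell the result is the enclosed volume; for a mesh with
#' internal voids the voids contribute negatively.  Translation invariant.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param signed if `TRUE` return the raw signed sum (voids negative);
#'   otherwise the absolute value is returned for single shells.
#' @return volume in cubic Angstrom.
#' @export
surveyor_volume <- function(mesh, signed = FALSE) {
  if (nrow(mesh$triangles) == 0) return(0)
  if (!mesh_is_closed(mesh)) stop("surveyor_volume needs a closed mesh")
  v <- signed_volume_sum(mesh$vertices, mesh$triangles)
  if (signed) v else abs(v)
}

## raw signed volume sum (no closedness check)
signed_volume_sum <- function(V, Tr) {
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c <- V[Tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

## undirected edge keys of all triangle edges (3 per triangle)
mesh_edge_keys <- function(mesh) {
  Tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  pmin(e[, 1], e[, 2]) * (n + 1) + pmax(e[, 1], e[, 2])
}

#' Mesh validation
#'
#' `mesh_is_closed()` checks that every edge is shared by exactly two
#' triangles; `mesh_is_watertight()` additionally requires consistent
#' orientation (each directed edge appears exactly once).
#' `mesh_euler_characteristic()` returns `V - E + F`.
#'
#' @param mesh a [triangle_mesh()].
#' @return logical (or integer for the Euler characteristic).
#' @export
mesh_is_closed <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(TRUE)
  tab <- table(mesh_edge_keys(mesh))
  all(tab == 2L)
}

#' @rdname mesh_is_closed
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(TRUE)
  if (!mesh_is_closed(mesh)) return(FALSE)
  Tr <- mesh$triangles
  n <- nrow(mesh$vertices)
  dir_e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  keys <- dir_e[, 1] * (n + 1) + dir_e[, 2]
  !anyDuplicated(keys)
}

#' @rdname mesh_is_closed
#' @export
mesh_euler_characteristic <- function(mesh) {
  nV <- nrow(mesh$vertices)
  nF <- nrow(mesh$triangles)
  nE <- length(unique(mesh_edge_keys(mesh)))
  as.integer(nV - nE + nF)
}

## drop vertices not referenced by any triangle, reindexing triangles
mesh_compact <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(triangle_mesh())
  used <- sort(unique(as.vector(mesh$triangles)))
  map <- integer(nrow(mesh$vertices)); map[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(map[mesh$triangles], ncol = 3))
}

#' Split a mesh into connected shells
#'
#' Connected components of the triangle adjacency graph (triangles sharing an
#' edge).  Each component is returned as its own compact mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @return list of meshes, one per shell.
#' @export
mesh_shells <- function(mesh) {
  nT <- nrow(mesh$triangles)
  if (nT == 0) return(list())
  keys <- mesh_edge_keys(mesh)          # 3*nT, triangle t at rows t, t+nT, t+2nT
  ord <- order(keys)
  comp <- integer(nT)
  ## union-find over triangles
  parent <- seq_len(nT)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  i <- 1
  ks <- keys[ord]
  tri_of <- ((ord - 1L) %% nT) + 1L
  while (i < length(ks)) {
    j <- i
    while (j < length(ks) && ks[j + 1] == ks[i]) j <- j + 1
    if (j > i) {
      r1 <- find(tri_of[i])
      for (k in (i + 1):j) {
        r2 <- find(tri_of[k])
        if (r1 != r2) parent[r2] <- r1
      }
    }
    i <- j + 1
  }
  roots <- vapply(seq_len(nT), find, integer(1))
  labs <- match(roots, unique(roots))
  lapply(seq_len(max(labs)), function(l) {
    mesh_compact(triangle_mesh(mesh$vertices,
                               mesh$triangles[labs == l, , drop = FALSE]))
  })
}

#' Extract volumetric fragments from a multi-shell mesh
#'
#' Splits the mesh into connected shells, computes each shell's signed
#' volume (the mesher orients outer shells outward, so void shells come out
#' negative), and assigns each void to the enclosing positive shell by a
#' ray-parity point-in-shell test.  Fragment volume is the outer volume minus
#' its voids; fragments are sorted by descending volume.
#'
#' @param mesh a closed [triangle_mesh()], possibly with several shells.
#' @return data frame with columns `id`, `volume` (cubic Angstrom),
#'   `cx`, `cy`, `cz` (area-weighted surface centroid), `n_triangles`, and a
#'   list column `mesh` holding each fragment's shells as a mesh.
#' @export
extract_fragments <- function(mesh) {
  shells <- mesh_shells(mesh)
  if (length(shells) == 0)
    return(data.frame(id = integer(0), volume = numeric(0), cx = numeric(0),
                      cy = numeric(0), cz = numeric(0),
                      n_triangles = integer(0)))
  sv <- vapply(shells, function(s) signed_volume_sum(s$vertices, s$triangles),
               numeric(1))
  pos <- which(sv >= 0); neg <- which(sv < 0)
  owner <- integer(length(shells)); owner[pos] <- pos
  for (v in neg) {
    ## a void belongs to the positive shell that contains it
    probe <- shells[[v]]$vertices[1, ]
    host <- NA_integer_
    for (p in pos) {
      if (point_in_shell(shells[[p]], probe)) { host <- p; break }
    }
    owner[v] <- if (is.na(host)) v else host
  }
  frs <- lapply(pos, function(p) {
    members <- which(owner == p)
    vol <- sum(sv[members])
    sub <- shells[members]
    V <- do.call(rbind, lapply(sub, `[[`, "vertices"))
    offs <- cumsum(c(0, vapply(sub, function(s) nrow(s$vertices), numeric(1))))
    Tr <- do.call(rbind, lapply(seq_along(sub), function(i)
      sub[[i]]$triangles + offs[i]))
    m <- triangle_mesh(V, Tr)
    cen <- tri_area_centroid(m)
    list(volume = vol, mesh = m, centroid = cen,
         n_triangles = nrow(Tr))
  })
  ord <- order(-vapply(frs, `[[`, numeric(1), "volume"))
  frs <- frs[ord]
  out <- data.frame(id = seq_along(frs),
                    volume = vapply(frs, `[[`, numeric(1), "volume"),
                    cx = vapply(frs, function(f) f$centroid[1], numeric(1)),
                    cy = vapply(frs, function(f) f$centroid[2], numeric(1)),
                    cz = vapply(frs, function(f) f$centroid[3], numeric(1)),
                    n_triangles = vapply(frs, `[[`, integer(1), "n_triangles"))
  out$mesh <- lapply(frs, `[[`, "mesh")
  out
}

## area-weighted centroid of a mesh surface
tri_area_centroid <- function(mesh) {
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 1], , drop = FALSE]; b <- V[Tr[, 2], , drop = FALSE]
  c <- V[Tr[, 3], , drop = FALSE]
  u <- b - a; w <- c - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sqrt(rowSums(nrm^2)) / 2
  cen <- (a + b + c) / 3
  colSums(cen * area) / sum(area)
}

## parity point-in-shell test with deterministic jittered re-casts
point_in_shell <- function(shell, p) {
  bb <- rbind(apply(shell$vertices, 2, min), apply(shell$vertices, 2, max))
  far <- bb[2, ] + c(1.23, 2.34, 3.45) * (bb[2, ] - bb[1, ] + 1)
  for (att in 1:5) {
    tgt <- far + (att - 1) * c(0.137, 0.291, -0.173)
    hits <- segment_triangle_hits(p, tgt, shell$vertices, shell$triangles)
    if (!is.na(hits)) return(hits %% 2 == 1)
  }
  FALSE
}

## count proper segment-triangle intersections; NA if a hit is degenerate
## (too close to an edge/vertex of a triangle or to the segment ends)
segment_triangle_hits <- function(p0, p1, V, Tr, eps = 1e-9) {
  d <- p1 - p0
  a <- V[Tr[, 1], , drop = FALSE]
  e1 <- V[Tr[, 2], , drop = FALSE] - a
  e2 <- V[Tr[, 3], , drop = FALSE] - a
  ## Moller-Trumbore, vectorized over triangles
  h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
             d[3] * e2[, 1] - d[1] * e2[, 3],
             d[1] * e2[, 2] - d[2] * e2[, 1])
  det <- rowSums(e1 * h)
  s <- matrix(p0, nrow(a), 3, byrow = TRUE) - a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  keep <- abs(det) > 1e-14
  u <- ifelse(keep, rowSums(s * h) / det, Inf)
  v <- ifelse(keep, (q[, 1] * d[1] + q[, 2] * d[2] + q[, 3] * d[3]) / det, Inf)
  t <- ifelse(keep, rowSums(e2 * q) / det, Inf)
  inside <- u >= eps & v >= eps & (u + v) <= 1 - eps & t >= eps & t <= 1 - eps
  near <- is.finite(u) &
    ((u > -eps & u < eps) | (v > -eps & v < eps) |
     (u + v > 1 - eps & u + v < 1 + eps)) &
    t > -eps & t < 1 + eps
  if (any(near & !inside)) return(NA_integer_)
  sum(inside)
}

#' Displacement distance between two meshes
#'
#' For every vertex of `mesh_a`, the exact distance to the nearest point on
#' the surface of `mesh_b` -- whether that point falls in a triangle's
#' interior, on an edge, or at a corner.  Summarized as minimum, mean and
#' maximum over vertices.  Note the measure is asymmetric:
#' `displacement_distance(a, b)` differs from `displacement_distance(b, a)`
#' in general.  Nearest-triangle search is accelerated by a uniform spatial
#' hash over triangle bounding boxes.
#'
#' @param mesh_a,mesh_b nonempty [triangle_mesh()] objects.
#' @return named numeric vector `c(min, mean, max)` in Angstrom.
#' @export
displacement_distance <- function(mesh_a, mesh_b) {
  stopifnot(nrow(mesh_a$vertices) > 0, nrow(mesh_b$triangles) > 0)
  V <- mesh_b$vertices; Tr <- mesh_b$triangles
  ta <- V[Tr[, 1], , drop = FALSE]
  tb <- V[Tr[, 2], , drop = FALSE]
  tc <- V[Tr[, 3], , drop = FALSE]
  lob <- pmin(ta, pmin(tb, tc)); hib <- pmax(ta, pmax(tb, tc))
  bb_lo <- apply(lob, 2, min); bb_hi <- apply(hib, 2, max)
  ## hash cell size: median triangle extent, floored to avoid tiny cells
  h <- max(stats::median(apply(hib - lob, 1, max)), 1e-6)
  dims <- pmax(ceiling((bb_hi - bb_lo) / h), 1)
  cell_of <- function(P) {
    ix <- pmin(pmax(floor((P[, 1] - bb_lo[1]) / h), 0), dims[1] - 1)
    iy <- pmin(pmax(floor((P[, 2] - bb_lo[2]) / h), 0), dims[2] - 1)
    iz <- pmin(pmax(floor((P[, 3] - bb_lo[3]) / h), 0), dims[3] - 1)
    cbind(ix, iy, iz)
  }
  ## register triangles in every cell their bbox overlaps
  reg <- new.env(hash = TRUE, size = 1024L)
  clo <- cell_of(lob); chi <- cell_of(hib)
  for (t in seq_len(nrow(Tr))) {
    for (ix in clo[t, 1]:chi[t, 1]) for (iy in clo[t, 2]:chi[t, 2])
      for (iz in clo[t, 3]:chi[t, 3]) {
        key <- as.character(ix + dims[1] * (iy + dims[2] * iz))
        reg[[key]] <- c(reg[[key]], t)
      }
  }
  q <- mesh_a$vertices
  dmin <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    p <- q[i, ]
    cc <- cell_of(matrix(p, 1, 3))[1, ]
    best <- Inf; ring <- 0
    repeat {
      cand <- integer(0)
      lo <- pmax(cc - ring, 0); hi <- pmin(cc + ring, dims - 1)
      for (ix in lo[1]:hi[1]) for (iy in lo[2]:hi[2]) for (iz in lo[3]:hi[3]) {
        if (ring > 0 && ix > lo[1] && ix < hi[1] && iy > lo[2] && iy < hi[2] &&
            iz > lo[3] && iz < hi[3]) next   # interior already searched
        key <- as.character(ix + dims[1] * (iy + dims[2] * iz))
        cand <- c(cand, reg[[key]])
      }
      if (length(cand) > 0) {
        d <- point_triangle_distance(p, ta[cand, , drop = FALSE],
                                     tb[cand, , drop = FALSE],
                                     tc[cand, , drop = FALSE])
        best <- min(best, min(d))
      }
      ## safe stop: everything beyond the searched rings is farther than best
      if (is.finite(best) && best <= ring * h) break
      if (all(cc - ring <= 0) && all(cc + ring >= dims - 1)) break
      ring <- ring + 1
    }
    dmin[i] <- best
  }
  c(min = min(dmin), mean = mean(dmin), max = max(dmin))
}

## exact point-to-triangle distance, vectorized over triangles (Ericson's
## region decomposition via barycentric clamping)
point_triangle_distance <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(a), 3, byrow = TRUE) - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(a), 3, byrow = TRUE) - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- ifelse(abs(denom) > 0, vb / denom, 0)
  w <- ifelse(abs(denom) > 0, vc / denom, 0)
  ## interior candidate
  close <- a + v * ab + w * ac
  ## clamp to the three edges and corners
  t_ab <- pmin(pmax(ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0), 0), 1)
  t_ac <- pmin(pmax(ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0), 0), 1)
  bc <- c - b
  t_bc <- pmin(pmax(rowSums(bc * bp) / pmax(rowSums(bc * bc), 1e-300), 0), 1)
  cand1 <- a + t_ab * ab
  cand2 <- a + t_ac * ac
  cand3 <- b + t_bc * bc
  d_int <- ifelse(v >= 0 & w >= 0 & v + w <= 1,
                  rowSums((matrix(p, nrow(a), 3, byrow = TRUE) - close)^2), Inf)
  dd <- function(q) rowSums((matrix(p, nrow(a), 3, byrow = TRUE) - q)^2)
  sqrt(pmin(d_int, pmin(dd(cand1), pmin(dd(cand2), dd(cand3)))))
}
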