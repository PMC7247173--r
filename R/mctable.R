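## Marching-cubes lookup table, generated at load time.
##
## Rather than transcribing a published 256-entry table, the table is built
## programmatically from a face-local pairing rule.  On each cube face the
## crossed edges are paired by segments that separate inside corners from
## outside corners; on the ambiguous face configuration (two diagonal inside
## corners) the pairing always cuts off each inside corner.  Because the rule
## depends only on the face configuration -- which two face-adjacent cubes
## share -- adjacent cubes always agree on the shared face and the resulting
## meshes are watertight by construction.  Directed segments (inside corners
## kept to the left, viewed from outside the cube) chain into oriented
## boundary cycles, which are fan-triangulated with outward normals.

## canonical cube edges: ids 0..11; axis-x edges first, then y, then z
mc_edge_defs <- function() {
  defs <- NULL
  for (bit in c(1L, 2L, 4L)) {
    for (c in 0:7) {
      if (bitwAnd(c, bit) == 0L) defs <- rbind(defs, c(c, c + bit))
    }
  }
  defs   # 12 x 2, 0-based corner numbers
}

mc_build_table <- function() {
  edges <- mc_edge_defs()
  corner_xyz <- CORNER_OFFSETS     # 8 x 3, 0/1
  ## midpoints of edges (geometric proxies for orientation decisions)
  emid <- (corner_xyz[edges[, 1] + 1, ] + corner_xyz[edges[, 2] + 1, ]) / 2

  ## 6 faces: (axis a, side s); in-plane axes (p, q) with e_p x e_q = outward
  faces <- list()
  cyc <- list(`1` = c(2L, 3L), `2` = c(3L, 1L), `3` = c(1L, 2L))
  for (a in 1:3) for (s in 0:1) {
    pq <- cyc[[as.character(a)]]
    if (s == 0L) pq <- rev(pq)       # outward normal is -e_a
    corners <- which(corner_xyz[, a] == s) - 1L
    fedges <- which(corner_xyz[edges[, 1] + 1, a] == s &
                    corner_xyz[edges[, 2] + 1, a] == s)
    faces[[length(faces) + 1]] <- list(p = pq[1], q = pq[2],
                                       corners = corners, edges = fedges)
  }

  cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

  table <- vector("list", 256)
  for (mask in 0:255) {
    inside <- bitwAnd(mask, bitwShiftL(1L, 0:7)) > 0L
    crossed <- xor(inside[edges[, 1] + 1], inside[edges[, 2] + 1])
    if (!any(crossed)) { table[[mask + 1]] <- integer(0); next }
    segs <- NULL   # rows: (from_edge, to_edge), 1-based edge indices
    for (f in faces) {
      fe <- f$edges[crossed[f$edges]]
      if (length(fe) == 0) next
      prj <- function(pt3) c(pt3[f$p], pt3[f$q])
      ins_c <- f$corners[inside[f$corners + 1]]
      if (length(fe) == 2) {
        m1 <- prj(emid[fe[1], ]); m2 <- prj(emid[fe[2], ])
        x <- prj(corner_xyz[ins_c[1] + 1, ])
        pair <- if (cross2(m2 - m1, x - m1) > 0) c(fe[1], fe[2]) else c(fe[2], fe[1])
        segs <- rbind(segs, pair)
      } else if (length(fe) == 4) {
        ## ambiguous face: two diagonal inside corners; cut off each one
        stopifnot(length(ins_c) == 2)
        for (ic in ins_c) {
          touch <- fe[edges[fe, 1] == ic | edges[fe, 2] == ic]
          stopifnot(length(touch) == 2)
          m1 <- prj(emid[touch[1], ]); m2 <- prj(emid[touch[2], ])
          x <- prj(corner_xyz[ic + 1, ])
          pair <- if (cross2(m2 - m1, x - m1) > 0) c(touch[1], touch[2])
                  else c(touch[2], touch[1])
          segs <- rbind(segs, pair)
        }
      } else stop("impossible face crossing count")
    }
    ## chain directed segments into cycles
    from <- segs[, 1]; to <- segs[, 2]
    stopifnot(!anyDuplicated(from), !anyDuplicated(to))
    nxt <- integer(12); nxt[from] <- to
    used <- logical(12)
    tris <- integer(0)
    for (startE in from) {
      if (used[startE]) next
      cyc_e <- startE
      e <- nxt[startE]
      while (e != startE) { cyc_e <- c(cyc_e, e); e <- nxt[e] }
      used[cyc_e] <- TRUE
      if (length(cyc_e) >= 3) {
        for (i in 2:(length(cyc_e) - 1)) {
          tris <- c(tris, cyc_e[1], cyc_e[i], cyc_e[i + 1])
        }
      }
    }
    table[[mask + 1]] <- tris - 1L   # 0-based edge ids
  }

  ## fix global orientation using the single-inside-corner case: the patch
  ## normal must point from the inside corner toward the outside
  tr <- table[[2]]   # mask = 1, corner 0 inside
  v <- emid[tr + 1, , drop = FALSE]
  n <- c((v[2, 2] - v[1, 2]) * (v[3, 3] - v[1, 3]) -
         (v[2, 3] - v[1, 3]) * (v[3, 2] - v[1, 2]),
         (v[2, 3] - v[1, 3]) * (v[3, 1] - v[1, 1]) -
         (v[2, 1] - v[1, 1]) * (v[3, 3] - v[1, 3]),
         (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
         (v[2, 2] - v[1, 2]) * (v[3, 1] - v[1, 1]))
  outward <- sum(n * (colMeans(v) - corner_xyz[1, ]))
  if (outward < 0) {
    table <- lapply(table, function(tr) {
      if (length(tr) == 0) return(tr)
      m <- matrix(tr, ncol = 3, byrow = TRUE)[, c(1, 3, 2), drop = FALSE]
      as.integer(t(m))
    })
  }
  table
}

.mc_env <- new.env(parent = emptyenv())

## memoized accessor
mc_table <- function() {
  if (is.null(.mc_env$table)) .mc_env$table <- mc_build_table()
  .mc_env$table
}
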