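## CSG expression trees.
##
## A CSG node implements the three basic functions by logic over its operand
## results: boolean logic for containment, interval-set algebra for segment
## intersection, and a setwise union for starting cubes (so that disconnected
## regions of the final solid are never lost before the root-level filter).

csg_node <- function(op, left, right) {
  stopifnot(op %in% c("union", "intersection", "difference"),
            inherits(left, "csg_solid"), inherits(right, "csg_solid"))
  structure(list(op = op, left = left, right = right),
            class = c("csg_node", "csg_solid"))
}

#' CSG operations
#'
#' Compose solids with union, intersection and (ordered) difference.  The
#' tree shape is caller-defined; no rebalancing is performed.
#' `csg_union_all()` folds a list of solids into a balanced union tree.
#'
#' Boundary semantics follow the global "surface is inside" rule; for a
#' difference `A - B` a point on the boundary of `B` is inside `B` and hence
#' excluded from the result.
#'
#' @param a,b operand solids (`b` is subtracted for the difference).
#' @param solids list of solids for `csg_union_all()`.
#' @return a solid of class `"csg_node"`.
#' @examples
#' s1 <- sphere(c(0, 0, 0), 1); s2 <- sphere(c(1, 0, 0), 1)
#' contains_point(csg_difference(s1, s2), c(0.6, 0, 0))  # FALSE: inside both
#' @export
csg_union <- function(a, b) csg_node("union", a, b)

#' @rdname csg_union
#' @export
csg_intersection <- function(a, b) csg_node("intersection", a, b)

#' @rdname csg_union
#' @export
csg_difference <- function(a, b) csg_node("difference", a, b)

#' @rdname csg_union
#' @export
csg_union_all <- function(solids) {
  stopifnot(length(solids) >= 1)
  while (length(solids) > 1) {
    nxt <- list()
    for (i in seq(1, length(solids), by = 2)) {
      nxt[[length(nxt) + 1]] <-
        if (i + 1 <= length(solids)) csg_union(solids[[i]], solids[[i + 1]])
        else solids[[i]]
    }
    solids <- nxt
  }
  solids[[1]]
}

#' @export
contains_point.csg_node <- function(s, p) {
  p <- as_points(p)
  a <- contains_point(s$left, p)
  b <- contains_point(s$right, p)
  switch(s$op,
         union        = a | b,
         intersection = a & b,
         difference   = a & !b)
}

#' @export
intersect_segment.csg_node <- function(s, seg) {
  a <- intersect_segment(s$left, seg)
  b <- intersect_segment(s$right, seg)
  switch(s$op,
         union        = iv_union(a, b),
         intersection = iv_intersect(a, b),
         difference   = iv_diff(a, b))
}

#' @export
find_starting_cubes.csg_node <- function(s, lat) {
  unique_cubes(rbind(find_starting_cubes(s$left, lat),
                     find_starting_cubes(s$right, lat)))
}

#' @export
solid_bbox.csg_node <- function(s) {
  bl <- solid_bbox(s$left)
  if (s$op == "difference") return(bl)
  br <- solid_bbox(s$right)
  if (s$op == "union")
    return(rbind(pmin(bl[1, ], br[1, ]), pmax(bl[2, ], br[2, ])))
  ## intersection: intersect the boxes, falling back to the left box when the
  ## boxes are disjoint (result is empty anyway)
  lo <- pmax(bl[1, ], br[1, ]); hi <- pmin(bl[2, ], br[2, ])
  if (any(lo > hi)) bl else rbind(lo, hi)
}

## collect leaf solids of a tree (a leaf is anything that is not a csg_node)
csg_leaves <- function(s) {
  if (!inherits(s, "csg_node")) return(list(s))
  c(csg_leaves(s$left), csg_leaves(s$right))
}
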