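## Interval sets on the segment parameter t.
##
## An interval set is a numeric matrix with two columns (lo, hi), each row a
## closed interval, kept sorted and pairwise disjoint by iv_normalize().  The
## empty set is the 0-row matrix.  All CSG segment logic reduces to union /
## intersection / difference on these sets.

#' Create an interval set
#'
#' Interval sets represent the "inside" stretches of a parameterized segment
#' as sorted, disjoint, closed intervals `[lo, hi]`.  They are the common
#' currency of all `intersect_segment()` methods.
#'
#' @param lo,hi numeric vectors of equal length; `lo[i] <= hi[i]` is enforced
#'   by swapping where violated.
#' @return a normalized interval set (two-column matrix).
#' @examples
#' interval_set(c(0, 1), c(2, 3))   # merges to [0, 3]
#' interval_set()                   # the empty set
#' @export
interval_set <- function(lo = numeric(0), hi = numeric(0)) {
  stopifnot(length(lo) == length(hi))
  m <- cbind(lo = pmin(lo, hi), hi = pmax(lo, hi))
  iv_normalize(m)
}

iv_empty <- function() {
  m <- matrix(numeric(0), ncol = 2)
  colnames(m) <- c("lo", "hi")
  m
}

#' Normalize an interval set
#'
#' Sorts intervals and merges any that overlap or whose gap is smaller than
#' `gap`.  Merging intervals that touch (or nearly touch) prevents spurious
#' zero-width exterior slivers from tangency handling.
#'
#' @param m two-column matrix of intervals (any order, may overlap).
#' @param gap gap below which adjacent intervals are fused (default the
#'   tangency separation, 1e-9).
#' @return sorted disjoint interval matrix.
#' @export
iv_normalize <- function(m, gap = EPS_TANGENT) {
  if (is.null(m) || nrow(m) == 0) return(iv_empty())
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  lo <- m[, 1]; hi <- m[, 2]
  out_lo <- lo[1]; out_hi <- hi[1]
  k <- 1L
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      if (lo[i] <= out_hi[k] + gap) {
        if (hi[i] > out_hi[k]) out_hi[k] <- hi[i]
      } else {
        k <- k + 1L
        out_lo[k] <- lo[i]; out_hi[k] <- hi[i]
      }
    }
  }
  m <- cbind(lo = out_lo, hi = out_hi)
  m
}

#' Union, intersection and difference of interval sets
#'
#' Set algebra on normalized interval sets.  `iv_diff()` is ordered
#' (`a` minus `b`) and removes `b`'s closed intervals including endpoints;
#' normalization then re-closes at machine epsilon, mirroring the CSG
#' difference boundary rule.
#'
#' @param a,b normalized interval sets.
#' @return a normalized interval set.
#' @export
iv_union <- function(a, b) iv_normalize(rbind(a, b))

#' @rdname iv_union
#' @export
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(iv_empty())
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1])
    hi <- pmin(a[i, 2], b[, 2])
    keep <- lo <= hi
    out[[i]] <- cbind(lo[keep], hi[keep])
  }
  iv_normalize(do.call(rbind, out))
}

#' @rdname iv_union
#' @export
iv_diff <- function(a, b) {
  if (nrow(a) == 0) return(iv_empty())
  if (nrow(b) == 0) return(iv_normalize(a))
  res <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1]; hi <- a[i, 2]
    pieces <- NULL
    cur <- lo
    for (j in seq_len(nrow(b))) {
      blo <- b[j, 1]; bhi <- b[j, 2]
      if (bhi < cur || blo > hi) next
      if (blo > cur) pieces <- rbind(pieces, c(cur, blo))
      cur <- max(cur, bhi)
      if (cur >= hi) break
    }
    if (cur < hi) pieces <- rbind(pieces, c(cur, hi))
    res[[i]] <- pieces
  }
  m <- do.call(rbind, res)
  if (is.null(m)) return(iv_empty())
  ## drop slivers thinner than machine-scale produced by closed-interval
  ## subtraction, then re-close
  m <- m[m[, 2] - m[, 1] > .Machine$double.eps, , drop = FALSE]
  iv_normalize(m)
}

## clip an interval set to [lo, hi]
iv_clip <- function(m, lo, hi) {
  if (nrow(m) == 0) return(m)
  l <- pmax(m[, 1], lo); h <- pmin(m[, 2], hi)
  keep <- l <= h
  cbind(lo = l[keep], hi = h[keep])
}

## total measure of an interval set
iv_length <- function(m) if (nrow(m) == 0) 0 else sum(m[, 2] - m[, 1])

## is parameter t inside the set (closed, with tolerance)?
iv_covers <- function(m, t, tol = 0) {
  if (nrow(m) == 0) return(rep(FALSE, length(t)))
  vapply(t, function(ti) any(m[, 1] - tol <= ti & ti <= m[, 2] + tol), logical(1))
}
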