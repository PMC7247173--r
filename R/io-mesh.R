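## Triangle-mesh readers and writers: OFF, OBJ, STL (ASCII and binary).
## ASCII dialects carry full double precision; OFF/OBJ outputs start with a
## comment header recording the provenance (resolution, probe radii, config
## hash) passed by the caller.

provenance_lines <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), " = ", unlist(provenance))
}

#' Mesh file input/output
#'
#' `write_off()`/`read_off()` handle ASCII OFF (lossless at full double
#' precision); `write_obj()`/`read_obj()` the Wavefront OBJ subset with
#' 1-based `f` records; `write_stl()`/`read_stl()` ASCII or binary STL
#' (binary coordinates are float32).  STL files carry no shared-vertex
#' topology, so `read_stl()` re-welds identical vertices.
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @param provenance optional named list written as `# key = value` comment
#'   headers (OFF/OBJ only).
#' @param binary write binary STL (default TRUE).
#' @return readers return a [triangle_mesh()]; writers return `path`
#'   invisibly.
#' @export
write_off <- function(mesh, path, provenance = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("OFF", con)
  writeLines(provenance_lines(provenance), con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (nv == 0) return(triangle_mesh())
  vm <- matrix(as.numeric(unlist(strsplit(ln[3:(2 + nv)], "\\s+"))),
               nv, 3, byrow = TRUE)
  fl <- strsplit(ln[(3 + nv):(2 + nv + nf)], "\\s+")
  fm <- t(vapply(fl, function(x) as.integer(x[2:4]), integer(3))) + 1L
  triangle_mesh(vm, fm)
}

#' @rdname write_off
#' @export
write_obj <- function(mesh, path, provenance = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenance_lines(provenance), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  if (length(vs) == 0) return(triangle_mesh())
  vm <- matrix(as.numeric(unlist(lapply(strsplit(vs, "\\s+"), `[`, 2:4))),
               length(vs), 3, byrow = TRUE)
  ## face entries may carry /vt/vn suffixes; indices are 1-based
  fidx <- lapply(strsplit(fs, "\\s+"), function(x)
    as.integer(sub("/.*", "", x[2:4])))
  fm <- do.call(rbind, fidx)
  triangle_mesh(vm, fm)
}

#' @rdname write_off
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; Tr <- mesh$triangles
  a <- V[Tr[, 1], , drop = FALSE]; b <- V[Tr[, 2], , drop = FALSE]
  c <- V[Tr[, 3], , drop = FALSE]
  u <- b - a; w <- c - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nn <- sqrt(rowSums(n^2)); nn[nn == 0] <- 1
  n <- n / nn
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(Tr)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(Tr))) {
      writeBin(as.numeric(c(n[t, ], a[t, ], b[t, ], c[t, ])), con,
               size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (t in seq_len(nrow(Tr))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g",
                           n[t, 1], n[t, 2], n[t, 3]),
                   "  outer loop",
                   sprintf("    vertex %.17g %.17g %.17g",
                           c(a[t, 1], b[t, 1], c[t, 1]),
                           c(a[t, 2], b[t, 2], c[t, 2]),
                           c(a[t, 3], b[t, 3], c[t, 3])),
                   "  endloop", "endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' @rdname write_off
#' @export
read_stl <- function(path) {
  head5 <- readBin(path, "raw", 5)
  is_ascii <- identical(rawToChar(head5), "solid") && {
    ## binary files may also start with "solid"; check the size equation
    sz <- file.size(path)
    con <- file(path, "rb"); on.exit(close(con), add = TRUE)
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con); on.exit()
    !(length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * ntri)
  }
  if (is_ascii) {
    ln <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", ln, value = TRUE)
    vm <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                          `[`, 2:4))),
                 length(vl), 3, byrow = TRUE)
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80))
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    vm <- matrix(0, 3 * ntri, 3)
    for (t in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      vm[(3 * t - 2):(3 * t), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      invisible(readBin(con, "raw", 2))
    }
  }
  ## weld identical vertices back into shared topology
  key <- paste(vm[, 1], vm[, 2], vm[, 3])
  uq <- !duplicated(key)
  idx <- match(key, key[uq])
  triangle_mesh(vm[uq, , drop = FALSE],
                matrix(idx, ncol = 3, byrow = TRUE))
}
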