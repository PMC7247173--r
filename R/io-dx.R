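## OpenDX scalar-grid reader/writer (the dialect emitted by common
## Poisson-Boltzmann solvers: gridpositions / gridconnections / rank-0 data
## with z varying fastest).

#' OpenDX scalar grid input/output
#'
#' @param grid a `potential_grid` (see [point_charge_grid()]).
#' @param path file path.
#' @param comments optional character vector written as `#` header lines.
#' @return `read_opendx()` returns a `potential_grid`; `write_opendx()`
#'   returns `path` invisibly.
#' @export
write_opendx <- function(grid, path, comments = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comments)) writeLines(paste("#", comments), con)
  n <- grid$counts
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     n[1], n[2], n[3]), con)
  writeLines(sprintf("origin %.9g %.9g %.9g",
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.9g 0 0", grid$delta), con)
  writeLines(sprintf("delta 0 %.9g 0", grid$delta), con)
  writeLines(sprintf("delta 0 0 %.9g", grid$delta), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     n[1], n[2], n[3]), con)
  writeLines(sprintf(
    "object 3 class array type double rank 0 items %d data follows",
    prod(n)), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))   # z fastest
  full <- length(vals) - length(vals) %% 3
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (full < length(vals))
    writeLines(paste(sprintf("%.9g", vals[(full + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' @rdname write_opendx
#' @export
read_opendx <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!startsWith(trimws(ln), "#")]
  gp <- grep("gridpositions", ln, value = TRUE)[1]
  counts <- as.integer(utils::tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org <- grep("^\\s*origin", ln, value = TRUE)[1]
  origin <- as.numeric(utils::tail(strsplit(trimws(org), "\\s+")[[1]], 3))
  dl <- grep("^\\s*delta", ln, value = TRUE)
  dm <- t(vapply(strsplit(trimws(dl), "\\s+"),
                 function(x) as.numeric(x[2:4]), numeric(3)))
  delta <- max(abs(dm))
  start <- grep("data follows", ln)[1] + 1
  stopn <- grep("^\\s*(attribute|object \")", ln)
  stopn <- stopn[stopn > start]
  end <- if (length(stopn) > 0) min(stopn) - 1 else length(ln)
  vals <- as.numeric(unlist(strsplit(trimws(ln[start:end]), "\\s+")))
  stopifnot(length(vals) == prod(counts))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  structure(list(origin = origin, delta = delta, counts = counts,
                 values = arr),
            class = "potential_grid")
}
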