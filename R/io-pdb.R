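## PDB input and van der Waals radius assignment.

#' Element-keyed van der Waals radius table
#'
#' Default radii in Angstrom: H 1.20, C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80; unknown elements fall back to 1.70.  Override entries by passing
#' a named vector to [read_pdb_atoms()].
#'
#' @return named numeric vector of radii.
#' @export
vdw_radius_table <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records via `bio3d::read.pdb()` and assigns van der
#' Waals radii from the element table.  Alternate locations keep the highest
#' occupancy (ties resolved toward altloc 'A').  Hydrogens are included when
#' present.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier(s) to keep.
#' @param het include HETATM records (default TRUE).
#' @param resid optional residue-name filter (e.g. a ligand code).
#' @param radii named radius overrides merged over [vdw_radius_table()].
#' @param default_radius radius for unknown elements (with a warning).
#' @return data frame with `x`, `y`, `z`, `radius`, `element`, `serial`,
#'   `resid`, `chain`.
#' @export
read_pdb_atoms <- function(path, chain = NULL, het = TRUE, resid = NULL,
                           radii = NULL, default_radius = 1.70) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if (!is.null(resid)) at <- at[at$resid %in% resid, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after selection")
  ## altloc policy: highest occupancy wins, ties toward 'A'
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety)), ,
             drop = FALSE]
  }
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  ## fall back to the first letter of the atom name
  elem[miss] <- toupper(substr(gsub("[0-9]", "", trimws(at$elety[miss])), 1, 1))
  tabl <- vdw_radius_table()
  if (!is.null(radii)) tabl[names(radii)] <- radii
  r <- unname(tabl[elem])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning(sprintf("%d atoms with unknown element (%s): default radius %.2f",
                    sum(unknown),
                    paste(unique(elem[unknown]), collapse = ","),
                    default_radius))
    r[unknown] <- default_radius
  }
  data.frame(x = at$x, y = at$y, z = at$z, radius = r, element = elem,
             serial = at$eleno, resid = at$resid, chain = at$chain)
}

#' Write atoms to a PDB file
#'
#' Minimal fixed-column ATOM records; used by the fixtures subcommand to
#' emit toy molecules.
#'
#' @param atoms atom data frame (`x`, `y`, `z`, `element`; other columns
#'   optional).
#' @param path output file.
#' @export
write_pdb_atoms <- function(atoms, path) {
  el <- if ("element" %in% names(atoms)) atoms$element else "C"
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), substr(paste0(el, seq_len(nrow(atoms))), 1, 4),
    "UNK", "A", seq_len(nrow(atoms)),
    atoms$x, atoms$y, atoms$z, 1.0, 0.0, el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
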