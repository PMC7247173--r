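## Solid representations of ligand-binding cavities.

#' Cavity construction parameters
#'
#' @param ligand_sphere_radius radius of the spheres centered on ligand
#'   atoms whose union describes the ligand neighborhood (default 5.0).
#' @param probe_small solvent probe radius for the molecular solid
#'   (default 1.4, water).
#' @param probe_large probe radius of the envelope solid bounding the outer
#'   extent of the cavity: the region inaccessible to molecular fragments
#'   larger than twice this radius (default 5.0).
#' @return a `cavity_spec` list.
#' @export
cavity_spec <- function(ligand_sphere_radius = 5.0, probe_small = 1.4,
                        probe_large = 5.0) {
  stopifnot(ligand_sphere_radius > 0, probe_small > 0,
            probe_large > probe_small)
  structure(list(ligand_sphere_radius = ligand_sphere_radius,
                 probe_small = probe_small, probe_large = probe_large),
            class = "cavity_spec")
}

#' Build the solid representation of a binding cavity
#'
#' The cavity is the CSG difference of the ligand-neighborhood sphere union
#' minus the receptor's molecular solid (small probe), intersected with the
#' receptor's large-probe envelope solid:
#' `(U ligand spheres - molecular_solid(receptor, probe_small)) ^
#' molecular_solid(receptor, probe_large)`.
#'
#' @param receptor,ligand atom data frames (`x`, `y`, `z`, `radius`).
#' @param spec a [cavity_spec()].
#' @param resolution meshing resolution, Angstrom.
#' @param workers forked workers for the mesher.
#' @return a closed [triangle_mesh()] of the cavity; empty (with a warning)
#'   when the ligand neighborhood misses the envelope entirely.
#' @export
build_binding_cavity <- function(receptor, ligand, spec = cavity_spec(),
                                 resolution = 0.5, workers = 1L) {
  stopifnot(nrow(receptor) > 0, nrow(ligand) > 0)
  lig_spheres <- csg_union_all(lapply(seq_len(nrow(ligand)), function(i)
    sphere(c(ligand$x[i], ligand$y[i], ligand$z[i]),
           spec$ligand_sphere_radius)))
  mol <- build_molecular_solid(receptor, spec$probe_small)
  env <- build_molecular_solid(receptor, spec$probe_large)
  cavity <- csg_intersection(csg_difference(lig_spheres, mol), env)
  ## the lattice needs to cover only the ligand neighborhood, where the
  ## cavity lives -- not the whole receptor
  lat <- build_lattice(list(lig_spheres), resolution)
  out <- mesh_solid_boundary(cavity, resolution, workers = workers,
                             lattice = lat)
  if (nrow(out$triangles) == 0)
    warning("empty cavity: ligand neighborhood does not reach the envelope")
  out
}
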