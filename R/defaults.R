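# Reference materials and the fitted Isochrysis galbana double-shell model.

#' Seawater-like suspending medium
#'
#' f/2 culture medium: conductivity 2.9 S/m as measured by conductivity
#' meter; relative permittivity 78 (seawater-like).
#'
#' @param conductivity Medium conductivity in S/m.
#' @param relative_permittivity Medium relative permittivity.
#' @return A [material()].
#' @export
seawater_medium <- function(conductivity = 2.9, relative_permittivity = 78) {
  material(relative_permittivity, conductivity)
}

#' Polystyrene bead material
#'
#' Lossless solid with relative permittivity 2.55, used for 2/3/5 um
#' calibration beads and microplastic surrogates.
#'
#' @return A [material()].
#' @export
polystyrene <- function() material(2.55, 0)

#' Oil-like lipid inclusion material
#'
#' Default dielectric properties for the lipid storage vesicles mixed into
#' the cytoplasmic core: relative permittivity 2.2, conductivity 1e-6 S/m.
#'
#' @return A [material()].
#' @export
lipid_oil <- function() material(2.2, 1e-6)

#' Fitted double-shell model of an Isochrysis galbana cell
#'
#' The cell is a cytoplasmic core with 20% lipid vesicle volume fraction
#' (core host: relative permittivity 63, conductivity 1.12 S/m), wrapped in a
#' 5 nm plasma membrane (permittivity 6, conductivity 5e-4 S/m) and a 100 nm
#' organic scale layer (permittivity 13, conductivity 9.9e-3 S/m).
#'
#' @param radius Outer cell radius in metres (default 2.5 um; the cell radius
#'   is not tightly constrained by population-averaged spectra).
#' @param eps_i,sigma_i Core host (cytoplasm) relative permittivity and
#'   conductivity (S/m).
#' @param lipid_fraction Lipid volume fraction of the core.
#' @param eps_m,sigma_m Membrane relative permittivity and conductivity.
#' @param eps_s,sigma_s Scale-layer relative permittivity and conductivity.
#' @param membrane_nm,scale_nm Shell thicknesses in nanometres.
#' @param lipid Lipid inclusion [material()].
#' @param core_premixed Treat (`eps_i`, `sigma_i`) as the already-mixed core
#'   values instead of the host values (see [shelled_particle()]).
#' @return A [shelled_particle()].
#' @examples
#' spec <- cm_spectrum(galbana_cell(), seawater_medium())
#' relaxation_frequency(spec) / 1e6  # MHz
#' @export
galbana_cell <- function(radius = 2.5e-6,
                         eps_i = 63, sigma_i = 1.12,
                         lipid_fraction = 0.20,
                         eps_m = 6, sigma_m = 5.0e-4,
                         eps_s = 13, sigma_s = 9.9e-3,
                         membrane_nm = 5, scale_nm = 100,
                         lipid = lipid_oil(),
                         core_premixed = FALSE) {
  shelled_particle(
    outer_radius = radius,
    core_host = material(eps_i, sigma_i),
    lipid = lipid,
    lipid_fraction = lipid_fraction,
    shells = list(
      shell_layer(material(eps_m, sigma_m), membrane_nm * 1e-9),
      shell_layer(material(eps_s, sigma_s), scale_nm * 1e-9)
    ),
    core_premixed = core_premixed
  )
}
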