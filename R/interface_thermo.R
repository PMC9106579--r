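# Thermodynamics of non-specific particle adsorption to droplet interfaces:
# sharp (Pickering) and finite-width interface variants, derived quantities,
# and condensation/adhesion bookkeeping. Energies are carried in k_BT.

# energy conversion: area (nm^2) x interfacial energy (uJ m^-2) -> k_BT
area_energy_kBT <- function(area_nm2, gamma_uJ_m2, temperature) {
  area_nm2 * gamma_uJ_m2 * 1e-24 / kBT_joule(temperature)
}

#' Adsorption model of a particle at a droplet interface
#'
#' Holds the particle geometry (surface area `A0`, interface-covered area
#' `Ax`, volume `V0`, radius `R`, all in nm), the interface half-width `w`
#' (nm) and the interfacial energies (`gamma_tg`, `gamma_tc` particle-granule
#' and particle-cytosol; `gamma_cg` granule-cytosol; uJ m^-2). For spheres
#' (`sphere = TRUE`) `A0` and `V0` are derived from `R`.
#'
#' @param R particle radius, nm (sphere case).
#' @param A0,Ax,V0 particle surface area, interface-covered area (nm^2) and
#'   volume (nm^3); derived from `R` when `sphere = TRUE`.
#' @param w interface half-width, nm.
#' @param gamma_tg,gamma_tc,gamma_cg interfacial energies, uJ m^-2.
#' @param temperature temperature, K.
#' @param sphere flag: enforce sphere consistency `A0 = 4 pi R^2`,
#'   `V0 = 4/3 pi R^3`.
#' @return an `adsorption_model` object.
#' @export
adsorption_model <- function(R = 2, A0 = NULL, Ax = NULL, V0 = NULL, w = 100,
                             gamma_tg = 15, gamma_tc = 15, gamma_cg = 15,
                             temperature = 310, sphere = is.null(A0)) {
  if (sphere) {
    stopifnot(R > 0)
    A0 <- 4 * pi * R^2
    V0 <- 4 / 3 * pi * R^3
    if (is.null(Ax)) Ax <- pi * R^2
  }
  stopifnot(A0 > 0, V0 > 0, w > 0, gamma_cg > 0, temperature > 0)
  structure(list(R = R, A0 = A0, Ax = Ax, V0 = V0, w = w,
                 gamma_tg = gamma_tg, gamma_tc = gamma_tc,
                 gamma_cg = gamma_cg, delta_gamma = gamma_tg - gamma_tc,
                 temperature = temperature, sphere = sphere),
            class = "adsorption_model")
}

#' Sharp-interface (Pickering) affinities
#'
#' Bulk affinity `-dG_g = -A0 * delta_gamma`; at neutral wetting
#' (`delta_gamma = 0`) the particle binds the interface with affinity
#' `Ax * gamma_cg`. The general sharp-interface branch is the classical
#' spherical-particle detachment energy, quadratic in
#' `delta_gamma / gamma_cg`; beyond `|delta_gamma| = gamma_cg` the particle
#' is fully wetted by one phase and the surface affinity vanishes.
#'
#' @param model an [adsorption_model()].
#' @return tibble: `dG_g_neg` (bulk affinity), `dG_s_neutral`
#'   (neutral-wetting surface affinity), `dG_s_sphere` (spherical detachment
#'   energy), all in k_BT.
#' @export
sharp_interface_affinities <- function(model) {
  Tm <- model$temperature
  dGg <- -area_energy_kBT(model$A0, model$delta_gamma, Tm)
  dGs_neutral <- area_energy_kBT(model$Ax, model$gamma_cg, Tm)
  costh <- model$delta_gamma / model$gamma_cg
  dGs_sphere <- if (abs(costh) >= 1) 0 else {
    if (!model$sphere) NA_real_
    else area_energy_kBT(pi * model$R^2, model$gamma_cg, Tm) *
      (1 - abs(costh))^2
  }
  tibble::tibble(dG_g_neg = dGg, dG_s_neutral = dGs_neutral,
                 dG_s_sphere = dGs_sphere)
}

#' Free energy of a small particle across a finite-width interface
#'
#' Quadratic expansion of the energy landscape about the interface centre
#' (`x = 0`), valid for `|x| < w`:
#' `dG(x) = A0 (dgamma/2)(1 - x/w) - V0 (3/2)(gamma_cg/w)(1/2 - x^2/w^2)`.
#' Outside the interface the bulk values apply (0 on the cytosol side,
#' `A0 * dgamma` on the granule side); evaluations beyond `|x| > w` are
#' clamped there with a warning.
#'
#' @param model an [adsorption_model()].
#' @param x position(s) across the interface, nm (negative = granule side).
#' @return `dG(x)` in k_BT.
#' @export
finite_interface_energy <- function(model, x) {
  Tm <- model$temperature
  w <- model$w
  inner <- abs(x) < w
  if (any(abs(x) > w)) warning("position outside |x| <= w; clamped to bulk")
  quad <- area_energy_kBT(model$A0, model$delta_gamma, Tm) / 2 * (1 - x / w) -
    area_energy_kBT(model$V0 / w, model$gamma_cg, Tm) * 1.5 *
      (0.5 - x^2 / w^2)
  bulk <- ifelse(x >= w, 0, area_energy_kBT(model$A0, model$delta_gamma, Tm))
  ifelse(inner, quad, bulk)
}

#' Surface-affinity relation of the finite-interface model
#'
#' `-dG_s = a0 + (1/2)(-dG_g) + (-dG_g)^2 / (32 a0)`.
#'
#' @param a0 neutral-point surface affinity, k_BT.
#' @param dGg_neg bulk affinity `-dG_g`, k_BT.
#' @return surface affinity `-dG_s`, k_BT.
#' @export
surface_affinity_relation <- function(a0, dGg_neg) {
  a0 + dGg_neg / 2 + dGg_neg^2 / (32 * a0)
}

#' Equilibrium position and surface affinity at a finite-width interface
#'
#' `x_eq = A0 w^2 dgamma / (6 V0 gamma_cg)`; `a0 = pi R^2 gamma_cg (R / w)`
#' for spheres (generally `a0 = (3/4) V0 gamma_cg / w`); the surface affinity
#' follows [surface_affinity_relation()] with `-dG_g = -A0 dgamma`.
#'
#' @param model an [adsorption_model()].
#' @return tibble: `x_eq_nm`, `a0`, `dG_g_neg`, `dG_s_neg`,
#'   `expansion_valid` (`FALSE` when `|x_eq| > w`).
#' @export
equilibrium_and_affinity <- function(model) {
  Tm <- model$temperature
  x_eq <- model$A0 * model$w^2 * model$delta_gamma /
    (6 * model$V0 * model$gamma_cg)
  a0 <- area_energy_kBT(0.75 * model$V0 / model$w, model$gamma_cg, Tm)
  dGg <- -area_energy_kBT(model$A0, model$delta_gamma, Tm)
  tibble::tibble(
    x_eq_nm = x_eq, a0 = a0, dG_g_neg = dGg,
    dG_s_neg = surface_affinity_relation(a0, dGg),
    expansion_valid = abs(x_eq) <= model$w
  )
}

#' Droplet interfacial energy implied by a neutral-wetting surface affinity
#'
#' `gamma_cg = affinity * k_BT / Ax`. Because a single sub-unit is the
#' smallest plausible adsorbing aggregate, the estimate is an upper bound for
#' the interfacial energy.
#'
#' @param affinity_kBT surface affinity at neutral wetting, k_BT.
#' @param Ax_nm2 interface-covered area, nm^2.
#' @param temperature temperature, K.
#' @return interfacial energy, uJ m^-2.
#' @export
estimate_gamma <- function(affinity_kBT, Ax_nm2, temperature = 310) {
  stopifnot(Ax_nm2 > 0)
  affinity_kBT * kBT_joule(temperature) * 1e24 / Ax_nm2
}

#' Condensation pressure and elastic cavitation criterion
#'
#' `p_cond = n_L k_B T ln(n / n_sat)`; in an ideal elastic medium cavities
#' grow without bound when `p_cond > 5 E / 6`.
#'
#' @param n_L droplet number density, m^-3.
#' @param n,n_sat continuous-phase and saturation number densities, m^-3.
#' @param E Young's modulus of the surrounding medium, Pa.
#' @param temperature temperature, K.
#' @return tibble: `p_cond_Pa`, `unbounded_growth`.
#' @export
condensation_and_cavitation <- function(n_L, n, n_sat, E,
                                        temperature = 310) {
  stopifnot(n_L > 0, n > 0, n_sat > 0)
  p <- n_L * kBT_joule(temperature) * log(n / n_sat)
  tibble::tibble(p_cond_Pa = p, unbounded_growth = p > 5 * E / 6)
}

#' Adhesion energy and filament-scale binding
#'
#' Work of adhesion `W = gamma_cg + gamma_tc - gamma_tg` (positive W can do
#' work); a filament with `nu` contacting sub-units per unit length binds the
#' interface with energy `per_subunit * nu * L`, linear in its length.
#'
#' @param gamma_cg,gamma_tc,gamma_tg interfacial energies, uJ m^-2.
#' @param per_subunit_kBT per-sub-unit surface affinity, k_BT.
#' @param nu_per_um contacting sub-units per micrometre of filament.
#' @param L_um filament length, um.
#' @return tibble: `W_uJ_m2`, `filament_energy_kBT`.
#' @export
adhesion_and_filament <- function(gamma_cg, gamma_tc, gamma_tg,
                                  per_subunit_kBT = 0.1, nu_per_um = 500,
                                  L_um = 1) {
  stopifnot(nu_per_um >= 0, L_um >= 0)
  tibble::tibble(
    W_uJ_m2 = gamma_cg + gamma_tc - gamma_tg,
    filament_energy_kBT = per_subunit_kBT * nu_per_um * L_um
  )
}
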