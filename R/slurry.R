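#' Species catalog: molecular weights and hydration ratios
#'
#' Monomer molecular weights (kg/kmol) for the tracked species. Glucan and
#' xylan are carried as anhydro-monomer equivalents, so hydrolysis to the free
#' sugar adds one water per monomer: the hydration ratios
#' `r_g = MW_G / MW_g` and `r_x = MW_X / MW_x` convert sugar mass back to
#' polysaccharide-equivalent mass. Lignin is chemically heterogeneous; a
#' representative monomer weight of 200 kg/kmol is used for both insoluble and
#' soluble lignin (literature range roughly 188-211).
#'
#' The enzyme molecular weight converts a mass loading to a molar enzyme
#' concentration. The cocktail is lumped, so `MW_E` is a nominal value: it is
#' algebraically confounded with the rate coefficients (only the product
#' `k_i * c_ET` enters the rates), and any fixed choice gives a self-consistent
#' model. The default is 65,000 kg/kmol.
#'
#' @param MW_G,MW_X Anhydroglucose / anhydroxylose monomer weights (kg/kmol).
#' @param MW_L,MW_sL Insoluble / soluble lignin monomer weights (kg/kmol).
#' @param MW_g,MW_x Glucose / xylose molecular weights (kg/kmol).
#' @param MW_E Lumped enzyme molecular weight (kg/kmol).
#' @return A `species_catalog` list with the weights plus derived `r_g`, `r_x`.
#' @examples
#' cat <- species_catalog()
#' cat$r_g # 162.14 / 180.16
#' @export
species_catalog <- function(MW_G = 162.14, MW_X = 132.12, MW_L = 200,
                            MW_sL = 200, MW_g = 180.16, MW_x = 150.13,
                            MW_E = 65000) {
  mw <- c(MW_G = MW_G, MW_X = MW_X, MW_L = MW_L, MW_sL = MW_sL,
          MW_g = MW_g, MW_x = MW_x, MW_E = MW_E)
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop("all molecular weights must be strictly positive", call. = FALSE)
  }
  if (MW_G >= MW_g || MW_X >= MW_x) {
    stop("monomer must be lighter than its hydrated sugar (r_g, r_x < 1)",
         call. = FALSE)
  }
  if (MW_L < 188 || MW_L > 211 || MW_sL < 188 || MW_sL > 211) {
    warning("lignin molecular weight outside the typical 188-211 kg/kmol range",
            call. = FALSE)
  }
  structure(
    list(MW_G = MW_G, MW_X = MW_X, MW_L = MW_L, MW_sL = MW_sL,
         MW_g = MW_g, MW_x = MW_x, MW_E = MW_E,
         r_g = MW_G / MW_g, r_x = MW_X / MW_x),
    class = "species_catalog"
  )
}

#' Density specification for the slurry mixture rule
#'
#' The total slurry density follows a harmonic mixing rule between the liquid
#' density and the skeletal density of the insoluble solids. For dilute
#' slurries (insoluble solids below ~15 weight percent and skeletal density
#' below ~1400 kg/m3) approximating the slurry density by the liquid density
#' incurs under 5 percent error; `use_constant_density = TRUE` (the default)
#' applies that approximation.
#'
#' @param rho_l Liquid density (kg/m3).
#' @param rho_is Skeletal density of insoluble solids (kg/m3).
#' @param use_constant_density If `TRUE`, `slurry_density()` returns `rho_l`.
#' @return A `density_spec` list.
#' @export
density_spec <- function(rho_l = 1000, rho_is = 1400,
                         use_constant_density = TRUE) {
  if (!is.finite(rho_l) || !is.finite(rho_is) || rho_l <= 0 || rho_is <= 0) {
    stop("densities must be strictly positive", call. = FALSE)
  }
  if (rho_is < rho_l) {
    warning("skeletal solids density below liquid density is unusual",
            call. = FALSE)
  }
  structure(
    list(rho_l = rho_l, rho_is = rho_is,
         use_constant_density = isTRUE(use_constant_density)),
    class = "density_spec"
  )
}

# canonical state ordering shared by the R and compiled ODE right-hand sides
state_names <- c("f_GR", "f_GF", "f_X", "f_L", "f_O",
                 "f_g", "f_x", "f_sL", "f_ET")

#' Construct a slurry state vector
#'
#' A slurry state is a named numeric vector of mass fractions on the
#' total-slurry basis: recalcitrant and facile glucan (`f_GR`, `f_GF`), xylan
#' (`f_X`), insoluble lignin (`f_L`), inert insolubles (`f_O`, ash and
#' uncharacterized structural carbohydrates), glucose (`f_g`), xylose (`f_x`),
#' soluble lignin (`f_sL`) and total enzyme (`f_ET`). The insoluble-solids
#' fraction is `f_is = f_GR + f_GF + f_X + f_L + f_O` and the liquid mass
#' fraction is `f_l = 1 - f_is`.
#'
#' @param f_GR,f_GF,f_X,f_L,f_O,f_g,f_x,f_sL,f_ET Mass fractions in `[0, 1]`.
#' @return Named numeric vector of class `slurry_state`.
#' @export
slurry_state <- function(f_GR = 0, f_GF = 0, f_X = 0, f_L = 0, f_O = 0,
                         f_g = 0, f_x = 0, f_sL = 0, f_ET = 0) {
  s <- c(f_GR = f_GR, f_GF = f_GF, f_X = f_X, f_L = f_L, f_O = f_O,
         f_g = f_g, f_x = f_x, f_sL = f_sL, f_ET = f_ET)
  validate_state(s)
  structure(s, class = "slurry_state")
}

validate_state <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("all mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(s) > 1 + 1e-12) {
    stop("solute + solid mass fractions exceed 1", call. = FALSE)
  }
  if (insoluble_fraction(s) >= 1) {
    stop("insoluble-solids fraction must be below 1", call. = FALSE)
  }
  invisible(s)
}

#' Insoluble-solids mass fraction of a state
#'
#' @param state A `slurry_state` (or any named vector with the state fields).
#' @return `f_is = f_GR + f_GF + f_X + f_L + f_O`.
#' @export
insoluble_fraction <- function(state) {
  unname(state[["f_GR"]] + state[["f_GF"]] + state[["f_X"]] +
           state[["f_L"]] + state[["f_O"]])
}

#' Total slurry density
#'
#' Harmonic mixing rule
#' `rho_T = (f_is / rho_is + f_l / rho_l)^-1`; under the constant-density
#' approximation the liquid density is returned unchanged.
#'
#' @param state A `slurry_state`.
#' @param dens A [density_spec()].
#' @return Slurry density (kg/m3).
#' @examples
#' s <- slurry_state(f_GR = 0.15)
#' slurry_density(s, density_spec(use_constant_density = FALSE))
#' @export
slurry_density <- function(state, dens = density_spec()) {
  f_is <- insoluble_fraction(state)
  if (f_is < 0 || f_is >= 1) stop("f_is must lie in [0, 1)", call. = FALSE)
  if (dens$use_constant_density) return(dens$rho_l)
  1 / (f_is / dens$rho_is + (1 - f_is) / dens$rho_l)
}

#' Liquid volume fraction of the slurry
#'
#' `eps_l = (rho_T / rho_l) * f_l` converts between the total-slurry and
#' liquid-volume concentration bases. In constant-density mode this reduces to
#' the liquid mass fraction `f_l`.
#'
#' @inheritParams slurry_density
#' @return Liquid volume fraction in `(0, 1]` (m3 liquid / m3 slurry).
#' @export
liquid_volume_fraction <- function(state, dens = density_spec()) {
  rho_T <- slurry_density(state, dens)
  (rho_T / dens$rho_l) * (1 - insoluble_fraction(state))
}

#' Convert between mass fraction and slurry-basis molar concentration
#'
#' `f_i = MW_i * c_i_slurry / rho_T`, so `c_i_slurry = f_i * rho_T / MW_i`
#' (kmol per m3 of whole slurry). Vectorized over its arguments.
#'
#' @param f Mass fraction(s) on the total-slurry basis.
#' @param MW Molecular weight(s), kg/kmol.
#' @param rho_T Slurry density, kg/m3.
#' @return Molar concentration, kmol/m3 slurry.
#' @export
mass_fraction_to_slurry_molar <- function(f, MW, rho_T) {
  if (any(MW <= 0)) stop("molecular weight must be positive", call. = FALSE)
  f * rho_T / MW
}

#' @rdname mass_fraction_to_slurry_molar
#' @param c_slurry Molar concentration, kmol/m3 slurry.
#' @export
slurry_molar_to_mass_fraction <- function(c_slurry, MW, rho_T) {
  if (any(MW <= 0)) stop("molecular weight must be positive", call. = FALSE)
  c_slurry * MW / rho_T
}

#' Convert between slurry-basis and liquid-basis molar concentrations
#'
#' `c_slurry = eps_l * c_liquid`: soluble species live in the liquid phase,
#' whose volume fraction of the slurry is `eps_l`.
#'
#' @param c_slurry Concentration, kmol/m3 slurry.
#' @param eps_l Liquid volume fraction in `(0, 1]`.
#' @return Concentration, kmol/m3 liquid.
#' @export
slurry_to_liquid_molar <- function(c_slurry, eps_l) {
  if (any(eps_l <= 0) || any(eps_l > 1)) {
    stop("degenerate slurry: eps_l must lie in (0, 1]", call. = FALSE)
  }
  c_slurry / eps_l
}

#' @rdname slurry_to_liquid_molar
#' @param c_liquid Concentration, kmol/m3 liquid.
#' @export
liquid_to_slurry_molar <- function(c_liquid, eps_l) {
  if (any(eps_l <= 0) || any(eps_l > 1)) {
    stop("degenerate slurry: eps_l must lie in (0, 1]", call. = FALSE)
  }
  c_liquid * eps_l
}
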