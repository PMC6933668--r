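#' Competitive adsorption / inhibition parameters
#'
#' Enzyme adsorption is modeled as instantaneous equilibria with dissociation
#' coefficients for each sink: recalcitrant glucan (`K_dR`), facile glucan,
#' xylan, soluble lignin and soluble sugars. Only `K_dR` is kept in absolute
#' units (kmol/m3 liquid); the other sinks enter through dimensionless ratios
#' `kappa_Rj = K_dR / K_dj`, so larger `kappa` means relatively stronger
#' binding to that sink than to recalcitrant glucan. `kappa_RF` doubles as the
#' reciprocal of the accessibility of recalcitrant glucan (see
#' [accessibility()]).
#'
#' @param K_dR Dissociation coefficient for recalcitrant glucan
#'   (kmol/m3 liquid).
#' @param kappa_RF,kappa_RX,kappa_RL,kappa_Rs Dimensionless ratios of `K_dR`
#'   to the dissociation coefficients for facile glucan, xylan, soluble
#'   lignin, and soluble sugars.
#' @return An `adsorption_params` list.
#' @export
adsorption_params <- function(K_dR = 0.05, kappa_RF = 9.34, kappa_RX = 11.3,
                              kappa_RL = 50, kappa_Rs = 50) {
  v <- c(K_dR = K_dR, kappa_RF = kappa_RF, kappa_RX = kappa_RX,
         kappa_RL = kappa_RL, kappa_Rs = kappa_Rs)
  if (any(!is.finite(v)) || K_dR <= 0 || any(v[-1] < 0)) {
    stop("K_dR must be positive and all kappa ratios non-negative",
         call. = FALSE)
  }
  structure(as.list(v), class = "adsorption_params")
}

#' Accessibility of recalcitrant glucan
#'
#' Under the linear accessibility interpretation, only a fraction `alpha` of
#' recalcitrant glucan is reachable by enzyme, and facile glucan adsorbs like
#' fully accessible recalcitrant glucan; then `kappa_RF = 1 / alpha`. Values
#' of `kappa_RF` below 1 have no accessibility interpretation and trigger a
#' warning (the reciprocal is still returned).
#'
#' @param params An [adsorption_params()].
#' @return `alpha = 1 / kappa_RF`.
#' @export
accessibility <- function(params) {
  if (params$kappa_RF < 1) {
    warning("kappa_RF < 1: accessibility interpretation invalid",
            call. = FALSE)
  }
  1 / params$kappa_RF
}

# Regularized partition denominator D' = c_GR * D. Finite as c_GR -> 0, which
# is reachable at substrate exhaustion. All concentration args >= 0;
# c_sL, c_ss on the liquid basis, the rest on the slurry basis.
partition_denominator_reg <- function(c_GR, c_GF, c_X, c_sL, c_ss, eps_l,
                                      params) {
  c_GR + params$kappa_RF * c_GF + params$kappa_RX * c_X +
    eps_l * (params$K_dR + params$kappa_RL * c_sL + params$kappa_Rs * c_ss)
}

#' Equilibrium partition denominator
#'
#' The common denominator of the closed-form enzyme partition:
#' `D = 1 + kappa_RF * c_GF/c_GR + kappa_RX * c_X/c_GR +
#' (eps_l / c_GR) * (K_dR + kappa_RL * c_sL + kappa_Rs * c_ss)`.
#' Internally everything is computed from the regularized product
#' `D' = c_GR * D`, which stays finite as recalcitrant glucan is depleted;
#' this function reports `D` itself (`Inf` at `c_GR = 0`).
#'
#' @param c_GR,c_GF,c_X Substrate concentrations, kmol/m3 slurry.
#' @param c_sL,c_ss Soluble lignin and total soluble sugar concentrations,
#'   kmol/m3 liquid.
#' @param eps_l Liquid volume fraction.
#' @param params An [adsorption_params()].
#' @return Dimensionless denominator, `>= 1` whenever `c_GR > 0`.
#' @export
partition_denominator <- function(c_GR, c_GF, c_X, c_sL, c_ss, eps_l,
                                  params = adsorption_params()) {
  conc <- c(c_GR, c_GF, c_X, c_sL, c_ss)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (eps_l <= 0 || eps_l > 1) stop("eps_l must lie in (0, 1]", call. = FALSE)
  Dp <- partition_denominator_reg(c_GR, c_GF, c_X, c_sL, c_ss, eps_l, params)
  if (Dp <= 0) {
    stop(paste("degenerate partition: no substrate, no inhibitor and no",
               "free-pool scale (K_dR) present"), call. = FALSE)
  }
  Dp / c_GR
}

# Core closed-form partition on raw concentrations; returns the six pools on
# the slurry basis. Used by both the user-facing wrapper and the ODE RHS.
partition_pools <- function(c_ET, c_GR, c_GF, c_X, c_sL, c_ss, eps_l, params) {
  Dp <- partition_denominator_reg(c_GR, c_GF, c_X, c_sL, c_ss, eps_l, params)
  if (Dp <= 0) {
    stop(paste("degenerate partition: no substrate, no inhibitor and no",
               "free-pool scale (K_dR) present"), call. = FALSE)
  }
  s <- c_ET / Dp
  c(c_Ef  = eps_l * params$K_dR * s,
    c_EGR = c_GR * s,
    c_EGF = params$kappa_RF * c_GF * s,
    c_EX  = params$kappa_RX * c_X * s,
    c_EsL = eps_l * params$kappa_RL * c_sL * s,
    c_Ess = eps_l * params$kappa_Rs * c_ss * s)
}

#' Partition total enzyme among substrates, inhibitors and solution
#'
#' Solves the closed-form equilibrium split of the lumped enzyme pool into six
#' components: free in solution, adsorbed to recalcitrant glucan, to facile
#' glucan, and to xylan, and unproductively bound to soluble lignin and to
#' soluble sugars (glucose + xylose). All six are returned as slurry-basis
#' molar concentrations, which makes the closure
#' `sum(pools) == c_ET` exact; liquid-basis free/inhibited pools are the
#' returned values divided by `eps_l`.
#'
#' @param state A [slurry_state()].
#' @param params An [adsorption_params()].
#' @param catalog A [species_catalog()].
#' @param dens A [density_spec()].
#' @return A one-row tibble with columns `c_Ef`, `c_EGR`, `c_EGF`, `c_EX`,
#'   `c_EsL`, `c_Ess` (kmol/m3 slurry) plus `eps_l` and `D_reg`.
#' @examples
#' s <- slurry_state(f_GR = 0.04, f_GF = 0.03, f_X = 0.006, f_ET = 1e-3)
#' partition_enzyme(s)
#' @export
partition_enzyme <- function(state, params = adsorption_params(),
                             catalog = species_catalog(),
                             dens = density_spec()) {
  validate_state(state)
  rho_T <- slurry_density(state, dens)
  eps_l <- liquid_volume_fraction(state, dens)
  c_ET <- state[["f_ET"]] * rho_T / catalog$MW_E
  c_GR <- state[["f_GR"]] * rho_T / catalog$MW_G
  c_GF <- state[["f_GF"]] * rho_T / catalog$MW_G
  c_X <- state[["f_X"]] * rho_T / catalog$MW_X
  c_sL <- state[["f_sL"]] * rho_T / catalog$MW_sL / eps_l
  c_ss <- (state[["f_g"]] * rho_T / catalog$MW_g +
             state[["f_x"]] * rho_T / catalog$MW_x) / eps_l
  pools <- partition_pools(c_ET, c_GR, c_GF, c_X, c_sL, c_ss, eps_l, params)
  tibble::as_tibble(c(
    as.list(pools),
    list(eps_l = eps_l,
         D_reg = partition_denominator_reg(c_GR, c_GF, c_X, c_sL, c_ss,
                                           eps_l, params))
  ))
}
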