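#' Hydrolysis and lignin-solubilization rate coefficients
#'
#' Adsorbed enzyme converts its substrate by first-order kinetics in the
#' adsorbed-enzyme concentration: `-r_GR = k_R * c_EGR`, `-r_GF = k_F * c_EGF`,
#' `-r_X = k_X * c_EX` (1/h). Lignin is solubilized in proportion to the
#' structural-carbohydrate conversion rate,
#' `r_L = k_L * c_L * (r_GR + r_X)`, with `k_L` in m3 liquid/kmol. By default
#' the facile and recalcitrant rate coefficients are tied (`k_F = k_R`): the
#' biphasic rate is attributed to accessibility, not to intrinsic kinetics.
#'
#' @param k_R,k_F,k_X First-order rate coefficients (1/h).
#' @param k_L Lignin-solubilization coupling (m3 liquid/kmol).
#' @param tie_kR_kF If `TRUE` (default), `k_F` is forced equal to `k_R`.
#' @param lignin_couples_facile If `TRUE`, facile-glucan conversion also
#'   drives lignin solubilization; the default (`FALSE`) couples lignin to the
#'   recalcitrant-glucan and xylan rates only.
#' @return A `rate_params` list.
#' @export
rate_params <- function(k_R = 14713, k_F = k_R, k_X = 10000, k_L = 729.5,
                        tie_kR_kF = TRUE, lignin_couples_facile = FALSE) {
  if (isTRUE(tie_kR_kF)) k_F <- k_R
  v <- c(k_R = k_R, k_F = k_F, k_X = k_X, k_L = k_L)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("rate coefficients must be non-negative", call. = FALSE)
  }
  structure(list(k_R = k_R, k_F = k_F, k_X = k_X, k_L = k_L,
                 tie_kR_kF = isTRUE(tie_kR_kF),
                 lignin_couples_facile = isTRUE(lignin_couples_facile)),
            class = "rate_params")
}

#' Molar reaction rates on the slurry basis
#'
#' Substrate rates are first order in adsorbed enzyme; products mirror their
#' substrates exactly on the molar basis: `r_g = -(r_GR + r_GF)`,
#' `r_x = -r_X`, `r_sL = -r_L`.
#'
#' @param partition One row of [partition_enzyme()] output (or a named list
#'   with `c_EGR`, `c_EGF`, `c_EX`).
#' @param c_L Insoluble-lignin concentration, kmol/m3 slurry.
#' @param rates A [rate_params()].
#' @return A one-row tibble of molar rates `r_GR, r_GF, r_X, r_L, r_g, r_x,
#'   r_sL` (kmol/(m3 slurry h)); substrate rates are `<= 0`.
#' @export
molar_rates <- function(partition, c_L, rates = rate_params()) {
  if (c_L < 0 || any(c(partition$c_EGR, partition$c_EGF, partition$c_EX) < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  r_GR <- -rates$k_R * partition$c_EGR
  r_GF <- -rates$k_F * partition$c_EGF
  r_X <- -rates$k_X * partition$c_EX
  carb <- if (rates$lignin_couples_facile) r_GR + r_GF + r_X else r_GR + r_X
  r_L <- rates$k_L * c_L * carb
  tibble::tibble(r_GR = r_GR, r_GF = r_GF, r_X = r_X, r_L = r_L,
                 r_g = -(r_GR + r_GF), r_x = -r_X, r_sL = -r_L)
}

#' Mass-basis reaction rates
#'
#' Converts molar slurry-basis rates to normalized mass rates
#' `R_i = MW_i * r_i / rho_T` (kg species per kg slurry per h), using each
#' species' own monomer molecular weight; the soluble-lignin rate uses
#' `MW_sL`. Because the sugar is heavier than its anhydro monomer, total
#' tracked mass grows during hydrolysis by the hydration water taken up.
#'
#' @param molar A one-row tibble from [molar_rates()].
#' @param catalog A [species_catalog()].
#' @param rho_T Slurry density (kg/m3).
#' @return A one-row tibble of mass rates `R_GR, R_GF, R_X, R_L, R_g, R_x,
#'   R_sL` (kg/(kg h)).
#' @export
mass_rates <- function(molar, catalog = species_catalog(), rho_T = 1000) {
  tibble::tibble(
    R_GR = catalog$MW_G * molar$r_GR / rho_T,
    R_GF = catalog$MW_G * molar$r_GF / rho_T,
    R_X = catalog$MW_X * molar$r_X / rho_T,
    R_L = catalog$MW_L * molar$r_L / rho_T,
    R_g = catalog$MW_g * molar$r_g / rho_T,
    R_x = catalog$MW_x * molar$r_x / rho_T,
    R_sL = catalog$MW_sL * molar$r_sL / rho_T
  )
}
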