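#' Full model parameter set
#'
#' Bundles the kinetic rate coefficients, the adsorption/inhibition
#' parameters, and the initial facile fraction of glucan `y_F0` (the fraction
#' of total glucan that starts in the easily digested population). The
#' defaults are the package's reference best-fit set for deacetylated,
#' dilute-acid-pretreated corn stover hydrolyzed by a lumped commercial
#' cellulase cocktail at 50 C and pH 5:
#' `k_R = k_F = 14713 1/h`, `k_X = 10000 1/h`, `k_L = 729.5 m3/kmol`,
#' `K_dR = 0.05 kmol/m3`, `kappa_RF = 9.34`, `kappa_RX = 11.3`,
#' `kappa_RL = 50`, `kappa_Rs = 50`, `y_F0 = 0.60`.
#'
#' @param rates A [rate_params()].
#' @param adsorption An [adsorption_params()].
#' @param y_F0 Initial facile fraction of glucan, in `[0, 1]`.
#' @return An `eh_params` list with elements `rates`, `adsorption`, `y_F0`.
#' @examples
#' p <- eh_params()
#' update_params(p, k_R = 2e4, y_F0 = 0.5)
#' @export
eh_params <- function(rates = rate_params(), adsorption = adsorption_params(),
                      y_F0 = 0.60) {
  if (!is.finite(y_F0) || y_F0 < 0 || y_F0 > 1) {
    stop("y_F0 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(rates = rates, adsorption = adsorption, y_F0 = y_F0),
            class = "eh_params")
}

#' @rdname eh_params
#' @export
reference_params <- function() eh_params()

# flat named-vector view used by calibration and sensitivity
param_names <- c("k_R", "k_F", "k_X", "k_L", "K_dR",
                 "kappa_RF", "kappa_RX", "kappa_RL", "kappa_Rs", "y_F0")

#' Flatten / update a parameter set
#'
#' `params_vector()` returns the named numeric vector of all ten parameters;
#' `update_params()` returns a copy of `params` with any subset replaced by
#' name (respecting the `k_R = k_F` tie when active).
#'
#' @param params An [eh_params()].
#' @return `params_vector()`: named numeric vector; `update_params()`: an
#'   `eh_params`.
#' @export
params_vector <- function(params) {
  c(k_R = params$rates$k_R, k_F = params$rates$k_F, k_X = params$rates$k_X,
    k_L = params$rates$k_L, K_dR = params$adsorption$K_dR,
    kappa_RF = params$adsorption$kappa_RF,
    kappa_RX = params$adsorption$kappa_RX,
    kappa_RL = params$adsorption$kappa_RL,
    kappa_Rs = params$adsorption$kappa_Rs,
    y_F0 = params$y_F0)
}

#' @rdname params_vector
#' @param ... Named scalar replacements drawn from
#'   `k_R, k_F, k_X, k_L, K_dR, kappa_RF, kappa_RX, kappa_RL, kappa_Rs, y_F0`.
#' @export
update_params <- function(params, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), param_names)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- as.list(params_vector(params))
  v[names(upd)] <- upd
  if (params$rates$tie_kR_kF && !("k_F" %in% names(upd))) v$k_F <- v$k_R
  eh_params(
    rates = rate_params(k_R = v$k_R, k_F = v$k_F, k_X = v$k_X, k_L = v$k_L,
                        tie_kR_kF = params$rates$tie_kR_kF,
                        lignin_couples_facile =
                          params$rates$lignin_couples_facile),
    adsorption = adsorption_params(K_dR = v$K_dR, kappa_RF = v$kappa_RF,
                                   kappa_RX = v$kappa_RX,
                                   kappa_RL = v$kappa_RL,
                                   kappa_Rs = v$kappa_Rs),
    y_F0 = v$y_F0
  )
}
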