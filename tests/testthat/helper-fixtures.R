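# shared fixtures: small states and parameter sets used across test files

toy_state <- function() {
  slurry_state(f_GR = 0.03, f_GF = 0.02, f_X = 0.006, f_L = 0.02,
               f_O = 0.01, f_g = 0.01, f_x = 0.015, f_sL = 0.001,
               f_ET = 1e-3)
}

# random valid slurry state; solids and solutes kept well inside bounds
random_state <- function() {
  slurry_state(
    f_GR = runif(1, 0, 0.06), f_GF = runif(1, 0, 0.05),
    f_X = runif(1, 0, 0.01), f_L = runif(1, 0, 0.03),
    f_O = runif(1, 0, 0.02), f_g = runif(1, 0, 0.06),
    f_x = runif(1, 0, 0.02), f_sL = runif(1, 0, 0.005),
    f_ET = runif(1, 0, 2e-3)
  )
}

random_adsorption <- function() {
  adsorption_params(K_dR = 10^runif(1, -3, 0),
                    kappa_RF = runif(1, 1, 20), kappa_RX = runif(1, 0, 20),
                    kappa_RL = runif(1, 0, 50), kappa_Rs = runif(1, 0, 50))
}

# Independent oracle for the enzyme partition: recover the individual
# dissociation coefficients from K_dR and the kappa ratios, then find free
# enzyme numerically as the root of the total-enzyme closure with each pool
# expressed through its raw equilibrium relation. Never touches the
# closed-form denominator.
oracle_partition <- function(state, ads, catalog = species_catalog(),
                             dens = density_spec()) {
  rho_T <- slurry_density(state, dens)
  eps_l <- liquid_volume_fraction(state, dens)
  c_ET <- state[["f_ET"]] * rho_T / catalog$MW_E
  c_GR <- state[["f_GR"]] * rho_T / catalog$MW_G
  c_GF <- state[["f_GF"]] * rho_T / catalog$MW_G
  c_X <- state[["f_X"]] * rho_T / catalog$MW_X
  c_sL <- state[["f_sL"]] * rho_T / catalog$MW_sL / eps_l
  c_ss <- (state[["f_g"]] * rho_T / catalog$MW_g +
             state[["f_x"]] * rho_T / catalog$MW_x) / eps_l
  K_dF <- ads$K_dR / ads$kappa_RF
  K_dX <- ads$K_dR / ads$kappa_RX
  K_IL <- ads$K_dR / ads$kappa_RL
  K_Is <- ads$K_dR / ads$kappa_Rs
  pools <- function(c_Ef) {
    c(c_Ef = eps_l * c_Ef,
      c_EGR = c_Ef * c_GR / ads$K_dR,
      c_EGF = c_Ef * c_GF / K_dF,
      c_EX = c_Ef * c_X / K_dX,
      c_EsL = eps_l * c_Ef * c_sL / K_IL,
      c_Ess = eps_l * c_Ef * c_ss / K_Is)
  }
  if (c_ET == 0) return(pools(0))
  g <- function(c_Ef) sum(pools(c_Ef)) - c_ET
  hi <- c_ET / eps_l
  root <- uniroot(g, lower = 0, upper = hi, tol = 1e-15 * hi)$root
  pools(root)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) /
                  pmax(abs(expected), .Machine$double.eps)), tol)
}
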