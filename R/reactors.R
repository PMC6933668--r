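#' Batch reactor condition
#'
#' Describes one batch hydrolysis experiment: the initial insoluble-solids
#' fraction, the composition of those solids, the enzyme loading, and the
#' background soluble concentrations of the pretreated liquor.
#'
#' @param f_is0 Initial insoluble-solids mass fraction, in `[0, 1)`.
#' @param w Named weight fractions of the insoluble solids
#'   (`G` glucan, `X` xylan, `L` lignin, `O` inert); must sum to 1.
#' @param lambda_E Enzyme loading, kg enzyme per kg initial glucan
#'   (e.g. 20 mg/g = 0.020).
#' @param rho_g,rho_x,rho_sL Background glucose, xylose and soluble-lignin
#'   concentrations in the initial liquor (kg/m3 liquid = g/L).
#' @param y_F0 Optional initial facile fraction of glucan; when `NULL`
#'   (default) the model parameter set's `y_F0` is used.
#' @param duration Simulation horizon (h).
#' @return A `batch_condition` list.
#' @examples
#' ref <- batch_condition(f_is0 = 0.10, lambda_E = 0.020)
#' @export
batch_condition <- function(f_is0, w = c(G = 0.62, X = 0.06, L = 0.22,
                                         O = 0.10),
                            lambda_E = 0, rho_g = 0, rho_x = 0, rho_sL = 0,
                            y_F0 = NULL, duration = 168) {
  if (!is.finite(f_is0) || f_is0 < 0 || f_is0 >= 1) {
    stop("f_is0 must lie in [0, 1)", call. = FALSE)
  }
  need <- c("G", "X", "L", "O")
  if (!all(need %in% names(w))) {
    stop("w must name weight fractions G, X, L, O", call. = FALSE)
  }
  w <- w[need]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("solids weight fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (lambda_E < 0) stop("lambda_E must be non-negative", call. = FALSE)
  if (any(c(rho_g, rho_x, rho_sL) < 0)) {
    stop("background concentrations must be non-negative", call. = FALSE)
  }
  if (!is.null(y_F0) && (y_F0 < 0 || y_F0 > 1)) {
    stop("y_F0 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(f_is0 = f_is0, w = w, lambda_E = lambda_E, rho_g = rho_g,
                 rho_x = rho_x, rho_sL = rho_sL, y_F0 = y_F0,
                 duration = duration),
            class = "batch_condition")
}

#' Membrane-CSTR stream specification
#'
#' Four streams connect to the reactor: a pretreated-slurry feed, an enzyme
#' solution feed, a solids-free ultrafiltration permeate, and a whole-slurry
#' purge. The reactor holds constant mass `m_T`, so by default the purge rate
#' is computed from the closure
#' `mdot_p = mdot_s + mdot_e - mdot_m` (see [purge_from_closure()]). The
#' membrane rejects the fraction `eta_E` of soluble enzyme (free plus sugar-
#' and lignin-inhibited pools); adsorbed enzyme travels with the solids and is
#' fully retained.
#'
#' @param mdot_s_in Slurry feed rate (kg/h).
#' @param mdot_e_in Enzyme solution feed rate (kg/h).
#' @param mdot_m_out Permeate rate (kg/h).
#' @param mdot_p_out Purge rate (kg/h); computed from closure when `NULL`.
#' @param m_T Reactor holdup mass (kg); default a 5 L vessel of water-density
#'   slurry.
#' @param feed A [batch_condition()] describing the slurry feed composition
#'   (its `lambda_E` should be 0: enzyme enters through its own stream).
#' @param enzyme_feed_gL Enzyme concentration in the enzyme stream (g/L).
#' @param eta_E Membrane rejection coefficient for soluble enzyme, `[0, 1]`.
#' @param startup_h Duration of the batch-mode startup phase (h).
#' @return A `stream_spec` list.
#' @export
stream_spec <- function(mdot_s_in, mdot_e_in, mdot_m_out, mdot_p_out = NULL,
                        m_T = 5, feed = batch_condition(0.05),
                        enzyme_feed_gL = 0, eta_E = 0.5, startup_h = 6) {
  flows <- c(mdot_s_in, mdot_e_in, mdot_m_out)
  if (any(!is.finite(flows)) || any(flows < 0)) {
    stop("stream mass-flow rates must be non-negative", call. = FALSE)
  }
  if (is.null(mdot_p_out)) {
    mdot_p_out <- purge_from_closure(mdot_s_in, mdot_e_in, mdot_m_out)
  } else {
    gap <- abs(mdot_s_in + mdot_e_in - mdot_m_out - mdot_p_out)
    scale <- max(mdot_s_in + mdot_e_in, .Machine$double.eps)
    if (gap / scale > 1e-6) {
      stop("stream closure violated: inflows must equal outflows",
           call. = FALSE)
    }
  }
  if (m_T <= 0) stop("reactor holdup m_T must be positive", call. = FALSE)
  if (eta_E < 0 || eta_E > 1) stop("eta_E must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(feed, "batch_condition"))
  structure(list(mdot_s_in = mdot_s_in, mdot_e_in = mdot_e_in,
                 mdot_m_out = mdot_m_out, mdot_p_out = mdot_p_out,
                 m_T = m_T, feed = feed, enzyme_feed_gL = enzyme_feed_gL,
                 eta_E = eta_E, startup_h = startup_h),
            class = "stream_spec")
}

#' Purge rate enforcing constant reactor mass
#'
#' `mdot_p = mdot_s_in + mdot_e_in - mdot_m_out`.
#'
#' @param mdot_s_in,mdot_e_in,mdot_m_out Stream rates (kg/h).
#' @return Purge rate (kg/h).
#' @examples
#' purge_from_closure(0.42, 0.138, 0.276) # 0.282
#' @export
purge_from_closure <- function(mdot_s_in, mdot_e_in, mdot_m_out) {
  p <- mdot_s_in + mdot_e_in - mdot_m_out
  if (any(p < 0)) {
    stop("infeasible streams: permeate exceeds total feed", call. = FALSE)
  }
  p
}

#' Nominal residence time of the CSTR
#'
#' Reactor holdup mass divided by the purge rate, `m_T / mdot_p_out` (h).
#' Returns `Inf` when the purge is zero.
#'
#' @param streams A [stream_spec()].
#' @return Residence time (h).
#' @export
residence_time <- function(streams) {
  if (streams$mdot_p_out == 0) return(Inf)
  streams$m_T / streams$mdot_p_out
}

#' Initial slurry state for a batch condition
#'
#' Splits the solids into species by their weight fractions, divides glucan
#' into facile and recalcitrant parts by `y_F0`, sets the enzyme fraction from
#' the loading `f_ET0 = lambda_E * w_G * f_is0`, and converts the liquor
#' background concentrations (g/L) to slurry mass fractions through the
#' initial liquid volume fraction.
#'
#' @param cond A [batch_condition()].
#' @param params An [eh_params()] (supplies `y_F0` unless the condition
#'   overrides it).
#' @param catalog A [species_catalog()].
#' @param dens A [density_spec()].
#' @return A [slurry_state()].
#' @export
initial_state <- function(cond, params = eh_params(),
                          catalog = species_catalog(),
                          dens = density_spec()) {
  y_F0 <- if (is.null(cond$y_F0)) params$y_F0 else cond$y_F0
  f_G0 <- cond$w[["G"]] * cond$f_is0
  f_is0 <- cond$f_is0
  rho_T <- if (dens$use_constant_density) dens$rho_l else
    1 / (f_is0 / dens$rho_is + (1 - f_is0) / dens$rho_l)
  eps_l <- rho_T / dens$rho_l * (1 - f_is0)
  slurry_state(
    f_GR = (1 - y_F0) * f_G0,
    f_GF = y_F0 * f_G0,
    f_X = cond$w[["X"]] * f_is0,
    f_L = cond$w[["L"]] * f_is0,
    f_O = cond$w[["O"]] * f_is0,
    f_g = cond$rho_g * eps_l / rho_T,
    f_x = cond$rho_x * eps_l / rho_T,
    f_sL = cond$rho_sL * eps_l / rho_T,
    f_ET = cond$lambda_E * f_G0
  )
}

# Flat parameter vector consumed by the compiled RHS (order documented in
# src/eh_deriv.c). flows/feed all zero gives the batch reactor.
pack_parms <- function(params, catalog, dens,
                       flows = c(0, 0, 0, 0), m_T = 1, eta_E = 0,
                       feed_state = rep(0, 8), f_E_feed = 0) {
  pv <- params_vector(params)
  c(pv[["k_R"]], pv[["k_F"]], pv[["k_X"]], pv[["k_L"]], pv[["K_dR"]],
    pv[["kappa_RF"]], pv[["kappa_RX"]], pv[["kappa_RL"]], pv[["kappa_Rs"]],
    catalog$MW_G, catalog$MW_X, catalog$MW_L, catalog$MW_g, catalog$MW_x,
    catalog$MW_sL, catalog$MW_E,
    dens$rho_l, dens$rho_is, as.numeric(dens$use_constant_density),
    flows, m_T, eta_E, feed_state, f_E_feed,
    as.numeric(params$rates$lignin_couples_facile))
}

# Pure-R right-hand side, arithmetic mirror of src/eh_deriv.c. Exposed through
# batch_rhs()/cstr_rhs() and used to cross-check the compiled path.
eh_rhs_r <- function(state, params, catalog, dens,
                     flows = c(0, 0, 0, 0), m_T = 1, eta_E = 0,
                     feed_state = rep(0, 8), f_E_feed = 0) {
  f <- pmax(as.numeric(state[state_names]), 0)
  names(f) <- state_names
  a_s <- flows[1] / m_T; a_e <- flows[2] / m_T
  a_m <- flows[3] / m_T; a_p <- flows[4] / m_T

  f_is <- f[["f_GR"]] + f[["f_GF"]] + f[["f_X"]] + f[["f_L"]] + f[["f_O"]]
  f_l <- 1 - f_is
  rho_T <- if (dens$use_constant_density) dens$rho_l else
    1 / (f_is / dens$rho_is + f_l / dens$rho_l)
  eps_l <- rho_T / dens$rho_l * f_l

  c_ET <- f[["f_ET"]] * rho_T / catalog$MW_E
  c_GR <- f[["f_GR"]] * rho_T / catalog$MW_G
  c_GF <- f[["f_GF"]] * rho_T / catalog$MW_G
  c_X <- f[["f_X"]] * rho_T / catalog$MW_X
  c_L <- f[["f_L"]] * rho_T / catalog$MW_L
  c_sL <- f[["f_sL"]] * rho_T / catalog$MW_sL / eps_l
  c_ss <- (f[["f_g"]] * rho_T / catalog$MW_g +
             f[["f_x"]] * rho_T / catalog$MW_x) / eps_l

  ads <- params$adsorption
  pool <- partition_pools(c_ET, c_GR, c_GF, c_X, c_sL, c_ss, eps_l, ads)

  cut <- function(x) x / (x + 1e-12)
  kin <- params$rates
  r_GR <- -kin$k_R * pool[["c_EGR"]] * cut(f[["f_GR"]])
  r_GF <- -kin$k_F * pool[["c_EGF"]] * cut(f[["f_GF"]])
  r_X <- -kin$k_X * pool[["c_EX"]] * cut(f[["f_X"]])
  carb <- if (kin$lignin_couples_facile) r_GR + r_GF + r_X else r_GR + r_X
  r_L <- kin$k_L * c_L * carb * cut(f[["f_L"]])

  R_GR <- catalog$MW_G * r_GR / rho_T
  R_GF <- catalog$MW_G * r_GF / rho_T
  R_X <- catalog$MW_X * r_X / rho_T
  R_L <- catalog$MW_L * r_L / rho_T
  R_g <- catalog$MW_g * (-(r_GR + r_GF)) / rho_T
  R_x <- catalog$MW_x * (-r_X) / rho_T
  R_sL <- catalog$MW_sL * (-r_L) / rho_T

  fd <- feed_state
  c(f_GR = a_s * fd[1] - a_p * f[["f_GR"]] + R_GR,
    f_GF = a_s * fd[2] - a_p * f[["f_GF"]] + R_GF,
    f_X = a_s * fd[3] - a_p * f[["f_X"]] + R_X,
    f_L = a_s * fd[4] - a_p * f[["f_L"]] + R_L,
    f_O = a_s * fd[5] - a_p * f[["f_O"]],
    f_g = a_s * fd[6] - a_p * f[["f_g"]] - a_m * f[["f_g"]] / eps_l + R_g,
    f_x = a_s * fd[7] - a_p * f[["f_x"]] - a_m * f[["f_x"]] / eps_l + R_x,
    f_sL = a_s * fd[8] - a_p * f[["f_sL"]] - a_m * f[["f_sL"]] / eps_l + R_sL,
    f_ET = a_e * f_E_feed - a_p * f[["f_ET"]] -
      a_m * eta_E * catalog$MW_E *
        (pool[["c_Ess"]] + pool[["c_EsL"]] + pool[["c_Ef"]]) /
        (rho_T * eps_l))
}

#' Batch-reactor time derivative of the slurry state
#'
#' Composes the equilibrium enzyme partition, the molar rates, and the
#' mass-rate conversion into the full derivative vector. Enzyme and inert
#' fractions are conserved in batch.
#'
#' @param state A [slurry_state()] (or named vector in the same order).
#' @param params An [eh_params()].
#' @param catalog A [species_catalog()].
#' @param dens A [density_spec()].
#' @return Named numeric derivative vector (1/h) in state order.
#' @export
batch_rhs <- function(state, params = eh_params(),
                      catalog = species_catalog(), dens = density_spec()) {
  eh_rhs_r(state, params, catalog, dens)
}

#' Membrane-CSTR time derivative of the slurry state
#'
#' Adds the stream terms to [batch_rhs()]: insoluble species enter with the
#' slurry feed and leave only through the purge; soluble species leave through
#' purge and permeate (permeate carries them at liquid-phase concentration,
#' the `1/eps_l` enrichment); the enzyme balance loses soluble enzyme pools
#' through the membrane attenuated by `eta_E`. With all flows zero this is
#' identical to [batch_rhs()].
#'
#' @inheritParams batch_rhs
#' @param streams A [stream_spec()].
#' @return Named numeric derivative vector (1/h).
#' @export
cstr_rhs <- function(state, streams, params = eh_params(),
                     catalog = species_catalog(), dens = density_spec()) {
  fs <- initial_state(no_enzyme(streams$feed), params, catalog, dens)
  eh_rhs_r(state, params, catalog, dens,
           flows = c(streams$mdot_s_in, streams$mdot_e_in,
                     streams$mdot_m_out, streams$mdot_p_out),
           m_T = streams$m_T, eta_E = streams$eta_E,
           feed_state = as.numeric(fs[1:8]),
           f_E_feed = streams$enzyme_feed_gL / dens$rho_l)
}

no_enzyme <- function(cond) { cond$lambda_E <- 0; cond }

# deSolve wrapper around the R-level RHS (used when use_compiled = FALSE)
rhs_desolve_r <- function(t, y, parms) {
  list(eh_rhs_r(stats::setNames(y, state_names), parms$params, parms$catalog,
                parms$dens, parms$flows, parms$m_T, parms$eta_E,
                parms$feed_state, parms$f_E_feed))
}

integrate_phase <- function(y0, times, params, catalog, dens,
                            flows = c(0, 0, 0, 0), m_T = 1, eta_E = 0,
                            feed_state = rep(0, 8), f_E_feed = 0,
                            rtol = 1e-8, atol = 1e-12, use_compiled = TRUE) {
  out <- if (use_compiled) {
    deSolve::ode(y = y0, times = times, func = "eh_deriv",
                 parms = pack_parms(params, catalog, dens, flows, m_T, eta_E,
                                    feed_state, f_E_feed),
                 dllname = "ehsim", initfunc = "eh_init",
                 method = "lsoda", rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times, func = rhs_desolve_r,
                 parms = list(params = params, catalog = catalog, dens = dens,
                              flows = flows, m_T = m_T, eta_E = eta_E,
                              feed_state = feed_state, f_E_feed = f_E_feed),
                 method = "lsoda", rtol = rtol, atol = atol)
  }
  d <- diagnostics_ok(out, utils::tail(times, 1))
  if (!d$ok) stop("ODE integration failed: ", d$msg, call. = FALSE)
  out
}

diagnostics_ok <- function(out, t_end) {
  if (nrow(out) == 0 || abs(out[nrow(out), "time"] - t_end) > 1e-8) {
    return(list(ok = FALSE, msg = sprintf(
      "integrator stopped at t = %.4g h before the requested %.4g h",
      out[nrow(out), "time"], t_end)))
  }
  list(ok = TRUE, msg = "")
}

# Assemble the tidy trajectory from a deSolve matrix.
trajectory_tibble <- function(out, cond, params, catalog, dens,
                              phase = "batch") {
  tb <- tibble::as_tibble(as.data.frame(out))
  names(tb)[1] <- "time_h"
  neg <- vapply(tb[state_names], function(x) any(x < -1e-10), logical(1))
  if (any(neg)) {
    warning("negative state values clipped to zero: ",
            paste(state_names[neg], collapse = ", "), call. = FALSE)
  }
  tb[state_names] <- lapply(tb[state_names], pmax, 0)
  f_is <- tb$f_GR + tb$f_GF + tb$f_X + tb$f_L + tb$f_O
  rho_T <- if (dens$use_constant_density) rep(dens$rho_l, nrow(tb)) else
    1 / (f_is / dens$rho_is + (1 - f_is) / dens$rho_l)
  eps_l <- rho_T / dens$rho_l * (1 - f_is)
  tb$f_is <- f_is
  tb$c_g_g_per_L <- tb$f_g * rho_T / eps_l
  tb$c_x_g_per_L <- tb$f_x * rho_T / eps_l
  s0 <- initial_state(cond, params, catalog, dens)
  tb$X_t <- conversion_from_fractions(tb$f_g, tb$f_x, s0[["f_g"]],
                                      s0[["f_x"]], cond, catalog)
  tb$phase <- phase
  tb <- tb[, c("time_h", state_names, "f_is", "c_g_g_per_L", "c_x_g_per_L",
               "X_t", "phase")]
  structure(tb, class = c("eh_trajectory", class(tb)),
            condition = cond, params = params, catalog = catalog, dens = dens)
}

conversion_from_fractions <- function(f_g, f_x, f_g0, f_x0, cond, catalog) {
  denom <- cond$f_is0 * (cond$w[["G"]] + cond$w[["X"]])
  if (denom <= 0) {
    stop("conversion undefined: condition has no carbohydrate", call. = FALSE)
  }
  (catalog$r_g * (f_g - f_g0) + catalog$r_x * (f_x - f_x0)) / denom
}

#' Simulate a batch hydrolysis experiment
#'
#' Integrates the batch ODE system with a stiff-capable solver (lsoda) from
#' the condition's initial state. The fast facile phase and the slow
#' recalcitrant tail span widely separated rate scales, so tight tolerances
#' are the default (`rtol = 1e-8`, `atol = 1e-12`).
#'
#' @param cond A [batch_condition()].
#' @param params An [eh_params()].
#' @param times Output time grid (h); defaults to half-hour resolution over
#'   the condition's duration.
#' @param catalog A [species_catalog()].
#' @param dens A [density_spec()].
#' @param rtol,atol Solver tolerances.
#' @param use_compiled Use the compiled right-hand side (default) or the
#'   pure-R one.
#' @return An `eh_trajectory` tibble with one row per time point: the nine
#'   state fractions, `f_is`, liquid-phase sugar concentrations in g/L, and
#'   the carbohydrate conversion `X_t`.
#' @examples
#' \donttest{
#' ref <- batch_condition(0.10, lambda_E = 0.020, rho_x = 15, rho_g = 5,
#'                        rho_sL = 1)
#' traj <- simulate_batch(ref)
#' }
#' @export
simulate_batch <- function(cond, params = eh_params(), times = NULL,
                           catalog = species_catalog(), dens = density_spec(),
                           rtol = 1e-8, atol = 1e-12, use_compiled = TRUE) {
  if (is.null(times)) times <- seq(0, cond$duration, by = 0.5)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("output times must be strictly increasing", call. = FALSE)
  }
  y0 <- initial_state(cond, params, catalog, dens)
  out <- integrate_phase(as.numeric(y0), times, params, catalog, dens,
                         rtol = rtol, atol = atol,
                         use_compiled = use_compiled)
  colnames(out) <- c("time", state_names)
  trajectory_tibble(out, cond, params, catalog, dens, phase = "batch")
}

#' Carbohydrate conversion along a trajectory
#'
#' Total conversion of glucan plus xylan into soluble sugars, corrected for
#' the hydration-water mass gained on hydrolysis:
#' `X_t = (r_g (f_g - f_g0) + r_x (f_x - f_x0)) / (f_is0 (w_G + w_X))`,
#' where `r_g`, `r_x` are the anhydro-monomer to sugar molecular-weight
#' ratios.
#'
#' @param traj An `eh_trajectory`.
#' @param cond The generating [batch_condition()]; defaults to the one stored
#'   on the trajectory.
#' @return A tibble with `time_h` and `X_t`.
#' @export
conversion <- function(traj, cond = attr(traj, "condition")) {
  catalog <- attr(traj, "catalog") %||% species_catalog()
  f_g0 <- traj$f_g[1]
  f_x0 <- traj$f_x[1]
  tibble::tibble(
    time_h = traj$time_h,
    X_t = conversion_from_fractions(traj$f_g, traj$f_x, f_g0, f_x0, cond,
                                    catalog)
  )
}

#' Simulate continuous enzymatic hydrolysis with membrane liquor removal
#'
#' Runs a batch-mode startup phase (no streams) from the startup condition,
#' then switches on the four streams and continues as a constant-mass CSTR
#' whose permeate is solids-free and partially enzyme-rejecting. The returned
#' trajectory carries a `phase` column (`"batch"` / `"continuous"`) and the
#' switch time as attribute `switch_h`.
#'
#' @param streams A [stream_spec()].
#' @param params An [eh_params()].
#' @param startup A [batch_condition()] for the initial reactor charge;
#'   defaults to the feed composition with enzyme loading implied by the
#'   enzyme stream (see Details in the methods vignette).
#' @param duration Continuous-phase duration after startup (h).
#' @param times Optional full output grid (h).
#' @inheritParams simulate_batch
#' @return An `eh_trajectory` tibble.
#' @export
simulate_ceh <- function(streams, params = eh_params(), startup = NULL,
                         duration = 72, times = NULL,
                         catalog = species_catalog(), dens = density_spec(),
                         rtol = 1e-8, atol = 1e-12, use_compiled = TRUE) {
  if (is.null(startup)) startup <- default_startup(streams)
  t_sw <- streams$startup_h
  if (is.null(times)) {
    times <- seq(0, t_sw + duration, by = 0.25)
    if (!(t_sw %in% times)) times <- c(times, t_sw)
  }
  times <- sort(unique(times))
  t1 <- times[times <= t_sw]
  if (!(t_sw %in% t1)) t1 <- c(t1, t_sw)
  t2 <- times[times >= t_sw]
  if (!(t_sw %in% t2)) t2 <- c(t_sw, t2)

  y0 <- initial_state(startup, params, catalog, dens)
  out1 <- integrate_phase(as.numeric(y0), t1, params, catalog, dens,
                          rtol = rtol, atol = atol,
                          use_compiled = use_compiled)
  y1 <- out1[nrow(out1), -1]
  fs <- initial_state(no_enzyme(streams$feed), params, catalog, dens)
  out2 <- integrate_phase(as.numeric(y1), t2, params, catalog, dens,
                          flows = c(streams$mdot_s_in, streams$mdot_e_in,
                                    streams$mdot_m_out, streams$mdot_p_out),
                          m_T = streams$m_T, eta_E = streams$eta_E,
                          feed_state = as.numeric(fs[1:8]),
                          f_E_feed = streams$enzyme_feed_gL / dens$rho_l,
                          rtol = rtol, atol = atol,
                          use_compiled = use_compiled)
  out <- rbind(out1, out2[-1, , drop = FALSE])
  colnames(out) <- c("time", state_names)
  phase <- ifelse(out[, "time"] <= t_sw, "batch", "continuous")
  tr <- trajectory_tibble(out, startup, params, catalog, dens, phase = phase)
  attr(tr, "streams") <- streams
  attr(tr, "switch_h") <- t_sw
  tr
}

# Startup charge for CEH: feed solids composition at the feed f_is, enzyme
# dosed at the loading implied by the enzyme-to-glucan feed ratio.
default_startup <- function(streams) {
  feed <- streams$feed
  glucan_feed <- streams$mdot_s_in * feed$f_is0 * feed$w[["G"]]
  lambda <- if (glucan_feed > 0) {
    streams$mdot_e_in * streams$enzyme_feed_gL / 1000 / glucan_feed
  } else 0
  cond <- feed
  cond$lambda_E <- lambda
  cond
}

`%||%` <- function(a, b) if (is.null(a)) b else a
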