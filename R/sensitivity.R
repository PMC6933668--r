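#' One-at-a-time local sensitivity sweep
#'
#' Perturbs a single model parameter by the given relative deltas (default
#' -30%, 0, +30%) around a base parameter set and re-simulates either the
#' reference batch scenario or a continuous (CEH) run, returning the response
#' trajectories keyed by delta. Batch responses are the total carbohydrate
#' conversion `X_t` plus the sugar concentrations; CEH responses are glucose
#' and `f_is`. A simulation failure at one delta is recorded (`ok = FALSE`)
#' and the sweep continues.
#'
#' @param base An [eh_params()] around which to sweep.
#' @param param Name of the parameter to vary (one of
#'   `k_R, k_F, k_X, k_L, K_dR, kappa_RF, kappa_RX, kappa_RL, kappa_Rs,
#'   y_F0`).
#' @param deltas Relative changes; each must exceed -1.
#' @param scenario `"batch"` or `"ceh"`.
#' @param cond Batch scenario condition (defaults to the reference batch
#'   condition: 10% solids, 20 mg/g loading, background sugars).
#' @param streams CEH scenario streams (defaults to the 5%-solids reference
#'   run).
#' @param times Output grid (h).
#' @param catalog,dens See [simulate_batch()].
#' @return An `eh_sweep` tibble: `parameter`, `delta`, `value`, `ok`,
#'   `time_h`, `X_t`, `c_g_g_per_L`, `c_x_g_per_L`, `f_is`.
#' @examples
#' \donttest{
#' sw <- run_sweep(eh_params(), "k_R")
#' }
#' @export
run_sweep <- function(base = eh_params(), param = "k_R",
                      deltas = c(-0.3, 0, 0.3),
                      scenario = c("batch", "ceh"),
                      cond = reference_condition(), streams = ceh_streams(1),
                      times = NULL, catalog = species_catalog(),
                      dens = density_spec()) {
  scenario <- match.arg(scenario)
  if (!param %in% param_names) {
    stop("unknown parameter: ", param, call. = FALSE)
  }
  if (any(deltas <= -1)) stop("deltas must exceed -1", call. = FALSE)
  base_value <- params_vector(base)[[param]]
  rows <- lapply(deltas, function(d) {
    value <- base_value * (1 + d)
    p <- do.call(update_params, c(list(base),
                                  stats::setNames(list(value), param)))
    traj <- tryCatch(
      if (scenario == "batch") {
        simulate_batch(cond, p, times = times, catalog = catalog,
                       dens = dens)
      } else {
        simulate_ceh(streams, p, times = times, catalog = catalog,
                     dens = dens)
      },
      error = function(e) NULL
    )
    if (is.null(traj)) {
      return(tibble::tibble(parameter = param, delta = d, value = value,
                            ok = FALSE, time_h = NA_real_, X_t = NA_real_,
                            c_g_g_per_L = NA_real_, c_x_g_per_L = NA_real_,
                            f_is = NA_real_))
    }
    tibble::tibble(parameter = param, delta = d, value = value, ok = TRUE,
                   time_h = traj$time_h, X_t = traj$X_t,
                   c_g_g_per_L = traj$c_g_g_per_L,
                   c_x_g_per_L = traj$c_x_g_per_L, f_is = traj$f_is)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("eh_sweep", class(out)), scenario = scenario)
}

#' Mean initial production rate of a trajectory
#'
#' Operationalizes the "initial rate" of carbohydrate digestion as the mean
#' rate of change of a response over the first hour of simulation.
#'
#' @param traj An `eh_trajectory`.
#' @param response Column to difference (default `X_t`).
#' @param window Averaging window (h).
#' @return Mean rate over the window (response units per hour).
#' @export
initial_rate <- function(traj, response = "X_t", window = 1) {
  i <- which(traj$time_h <= window)
  i1 <- i[length(i)]
  (traj[[response]][i1] - traj[[response]][1]) /
    (traj$time_h[i1] - traj$time_h[1])
}

#' Reference batch condition
#'
#' The duplicate-run anchor of the batch design: 10% insoluble solids at
#' 20 mg enzyme per g glucan, with the default background liquor (5 g/L
#' glucose, 15 g/L xylose, 1 g/L soluble lignin).
#'
#' @param ... Overrides passed to [batch_condition()].
#' @return A [batch_condition()].
#' @export
reference_condition <- function(...) {
  args <- utils::modifyList(
    list(f_is0 = 0.10, lambda_E = 0.020, rho_g = 5, rho_x = 15, rho_sL = 1),
    list(...)
  )
  do.call(batch_condition, args)
}
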