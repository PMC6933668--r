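#' Batch experimental design
#'
#' The seven-condition batch design supported by the model: a reference
#' condition (10% insoluble solids, 20 mg enzyme per g glucan, no added
#' glucose) run in duplicate, two reduced-solids conditions, two
#' reduced-loading conditions, and two added-glucose conditions. Sugars are
#' sampled at 4, 8, 24, 28, 72, 120 and 168 h; insoluble solids at 24 and
#' 168 h.
#'
#' @return A tibble with columns `condition_id`, `f_is0`, `loading_mg_g`,
#'   `added_glucose_gL`.
#' @export
batch_design <- function() {
  tibble::tribble(
    ~condition_id, ~f_is0, ~loading_mg_g, ~added_glucose_gL,
    "ref_a",       0.10,   20,            0,
    "ref_b",       0.10,   20,            0,
    "fis_7.5",     0.075,  20,            0,
    "fis_5",       0.05,   20,            0,
    "load_15",     0.10,   15,            0,
    "load_10",     0.10,   10,            0,
    "glc_20",      0.10,   20,            20,
    "glc_50",      0.10,   20,            50
  )
}

#' Sampling grids of the batch design
#'
#' @return Named list with the sugar and insoluble-solids sampling times (h).
#' @export
batch_sampling <- function() {
  list(sugars = c(4, 8, 24, 28, 72, 120, 168), f_is = c(24, 168))
}

#' Continuous (CEH) experimental design
#'
#' Three membrane-CSTR runs at increasing target solids, all at 10 mg/g
#' enzyme loading in a 5 kg holdup vessel with a soluble-enzyme membrane
#' rejection of 0.5. The purge rate is computed from the constant-mass
#' closure and the nominal residence time is holdup over purge.
#'
#' @return A tibble with one row per run.
#' @export
ceh_design <- function() {
  d <- tibble::tribble(
    ~run, ~target_f_is, ~loading_mg_g, ~mdot_e_in, ~enzyme_feed_gL,
      ~mdot_s_in, ~feed_f_is, ~mdot_m_out,
    1, 0.050, 10, 0.138, 0.89, 0.420, 0.050, 0.276,
    2, 0.075, 10, 0.072, 2.70, 0.426, 0.075, 0.222,
    3, 0.085, 10, 0.054, 3.60, 0.348, 0.100, 0.152
  )
  d$mdot_p_out <- purge_from_closure(d$mdot_s_in, d$mdot_e_in, d$mdot_m_out)
  d$residence_h <- 5 / d$mdot_p_out
  d
}

#' Stream specification for one CEH design run
#'
#' @param run Run number (1, 2 or 3) in [ceh_design()].
#' @param background Named background liquor concentrations (g/L) carried by
#'   the slurry feed: `glucose`, `xylose`, `soluble_lignin`.
#' @param startup_h Batch startup duration (h).
#' @param m_T Reactor holdup (kg).
#' @param eta_E Membrane enzyme rejection.
#' @return A [stream_spec()].
#' @export
ceh_streams <- function(run = 1,
                        background = c(glucose = 5, xylose = 15,
                                       soluble_lignin = 1),
                        startup_h = 6, m_T = 5, eta_E = 0.5) {
  d <- ceh_design()
  d <- d[d$run == run, ]
  if (nrow(d) != 1) stop("run must be 1, 2 or 3", call. = FALSE)
  feed <- batch_condition(d$feed_f_is, lambda_E = 0,
                          rho_g = background[["glucose"]],
                          rho_x = background[["xylose"]],
                          rho_sL = background[["soluble_lignin"]])
  stream_spec(mdot_s_in = d$mdot_s_in, mdot_e_in = d$mdot_e_in,
              mdot_m_out = d$mdot_m_out, m_T = m_T, feed = feed,
              enzyme_feed_gL = d$enzyme_feed_gL, eta_E = eta_E,
              startup_h = startup_h)
}

#' Measurement noise model for synthetic datasets
#'
#' Multiplicative Gaussian noise, truncated at zero: a measured value is
#' `value * max(0, 1 + sd * z)` with standard normal `z`. Sugar assays scale
#' with concentration, motivating the multiplicative law. Set both standard
#' deviations to zero for exact model output.
#'
#' @param sd_sugars Relative s.d. for glucose and xylose (default 0.03).
#' @param sd_f_is Relative s.d. for insoluble solids (default 0.05).
#' @param seed Optional RNG seed; fixed seeds regenerate identical datasets.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sd_sugars = 0.03, sd_f_is = 0.05, seed = NULL) {
  if (sd_sugars < 0 || sd_f_is < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  structure(list(sd_sugars = sd_sugars, sd_f_is = sd_f_is, seed = seed),
            class = "noise_model")
}

apply_noise <- function(value, observable, noise) {
  sd <- ifelse(observable == "f_is", noise$sd_f_is, noise$sd_sugars)
  value * pmax(0, 1 + sd * stats::rnorm(length(value)))
}

#' Generate synthetic batch datasets
#'
#' Simulates every condition of the batch design under `params`, samples the
#' printed grids (sugars at 7 time points, insoluble solids at 2), and
#' applies the noise model. With zero noise the observations equal the model
#' output exactly, so a refit started at the generating parameters has
#' objective ~0. The pretreated liquor's background sugar levels are not part
#' of the design table and default to 5 g/L glucose, 15 g/L xylose and 1 g/L
#' soluble lignin (a fixture convention, configurable).
#'
#' @param params Generating [eh_params()].
#' @param design Design tibble, see [batch_design()].
#' @param noise A [noise_model()].
#' @param background Named background liquor concentrations (g/L).
#' @param catalog,dens See [simulate_batch()].
#' @return A tibble of observations (`condition_id`, `time_h`, `observable`,
#'   `value`) carrying the named list of generating [batch_condition()]s as
#'   attribute `"conditions"`, ready for [fit_batch()].
#' @export
generate_batch_set <- function(params = eh_params(), design = batch_design(),
                               noise = noise_model(),
                               background = c(glucose = 5, xylose = 15,
                                              soluble_lignin = 1),
                               catalog = species_catalog(),
                               dens = density_spec()) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  grids <- batch_sampling()
  conditions <- list()
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    cond <- batch_condition(
      f_is0 = d$f_is0, lambda_E = d$loading_mg_g / 1000,
      rho_g = background[["glucose"]] + d$added_glucose_gL,
      rho_x = background[["xylose"]],
      rho_sL = background[["soluble_lignin"]]
    )
    conditions[[d$condition_id]] <<- cond
    times <- sort(unique(c(0, grids$sugars, grids$f_is)))
    traj <- simulate_batch(cond, params, times = times, catalog = catalog,
                           dens = dens)
    mod_s <- model_observables(traj, grids$sugars)
    mod_f <- model_observables(traj, grids$f_is)
    obs <- dplyr::bind_rows(
      tibble::tibble(time_h = grids$sugars, observable = "glucose",
                     value = mod_s$glucose),
      tibble::tibble(time_h = grids$sugars, observable = "xylose",
                     value = mod_s$xylose),
      tibble::tibble(time_h = grids$f_is, observable = "f_is",
                     value = mod_f$f_is)
    )
    obs$value <- apply_noise(obs$value, obs$observable, noise)
    obs$condition_id <- d$condition_id
    obs[, c("condition_id", "time_h", "observable", "value")]
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "conditions") <- conditions
  attr(out, "noise") <- noise
  out
}

#' Generate synthetic continuous (CEH) datasets
#'
#' Simulates the three membrane-CSTR runs (batch startup followed by
#' continuous operation) and samples glucose, xylose and insoluble solids
#' every `sample_every` hours of continuous operation.
#'
#' @inheritParams generate_batch_set
#' @param sample_every Sampling interval after startup (h).
#' @param duration Continuous-phase duration (h).
#' @param startup_h Batch startup duration (h).
#' @return A tibble of observations keyed by `condition_id` (`"ceh_1"` ...),
#'   with the generating [stream_spec()]s as attribute `"streams"`.
#' @export
generate_ceh_set <- function(params = eh_params(), noise = noise_model(),
                             background = c(glucose = 5, xylose = 15,
                                            soluble_lignin = 1),
                             sample_every = 7, duration = 72, startup_h = 6,
                             catalog = species_catalog(),
                             dens = density_spec()) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  streams_list <- list()
  rows <- lapply(1:3, function(run) {
    streams <- ceh_streams(run, background = background,
                           startup_h = startup_h)
    streams_list[[paste0("ceh_", run)]] <<- streams
    sample_t <- startup_h + seq(sample_every, duration, by = sample_every)
    times <- sort(unique(c(0, startup_h, sample_t)))
    traj <- simulate_ceh(streams, params, duration = duration, times = times,
                         catalog = catalog, dens = dens)
    mod <- model_observables(traj, sample_t)
    obs <- dplyr::bind_rows(
      tibble::tibble(time_h = sample_t, observable = "glucose",
                     value = mod$glucose),
      tibble::tibble(time_h = sample_t, observable = "xylose",
                     value = mod$xylose),
      tibble::tibble(time_h = sample_t, observable = "f_is",
                     value = mod$f_is)
    )
    obs$value <- apply_noise(obs$value, obs$observable, noise)
    obs$condition_id <- paste0("ceh_", run)
    obs[, c("condition_id", "time_h", "observable", "value")]
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "streams") <- streams_list
  attr(out, "noise") <- noise
  out
}
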