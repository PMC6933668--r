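#' Default box bounds for calibration
#'
#' Per-parameter lower/upper bounds and the scale on which each parameter is
#' searched: `"log"` for positive multiplicative quantities, `"linear"` for
#' `k_L` (lower bound 0) and `y_F0`. Several best-fit values in this system
#' sit on round bounds (`k_X` at 1e4, `kappa_RL` and `kappa_Rs` at 50); the
#' defaults reproduce that geometry and are fully configurable.
#'
#' @return A tibble with columns `term`, `lower`, `upper`, `scale`.
#' @export
default_bounds <- function() {
  tibble::tribble(
    ~term,       ~lower, ~upper, ~scale,
    "k_R",       1,      1e6,    "log",
    "k_X",       1,      1e4,    "log",
    "k_L",       0,      1e4,    "linear",
    "K_dR",      1e-4,   10,     "log",
    "kappa_RF",  0.1,    50,     "log",
    "kappa_RX",  0.1,    50,     "log",
    "kappa_RL",  0.1,    50,     "log",
    "kappa_Rs",  0.1,    50,     "log",
    "y_F0",      0,      1,      "linear"
  )
}

# Smooth bijections between the box and the real line: a scaled logit, taken
# in log-space for "log"-scale parameters. Nelder-Mead then searches an
# unconstrained space and can only ever propose in-bounds values.
to_unconstrained <- function(theta, bounds) {
  z <- numeric(length(theta))
  for (i in seq_along(theta)) {
    b <- bounds[bounds$term == names(theta)[i], ]
    u <- if (b$scale == "log") {
      (log(theta[i]) - log(b$lower)) / (log(b$upper) - log(b$lower))
    } else {
      (theta[i] - b$lower) / (b$upper - b$lower)
    }
    u <- min(max(u, 1e-10), 1 - 1e-10)
    z[i] <- log(u / (1 - u))
  }
  stats::setNames(z, names(theta))
}

from_unconstrained <- function(z, bounds) {
  theta <- numeric(length(z))
  for (i in seq_along(z)) {
    b <- bounds[bounds$term == names(z)[i], ]
    u <- 1 / (1 + exp(-z[i]))
    th <- if (b$scale == "log") {
      exp(log(b$lower) + u * (log(b$upper) - log(b$lower)))
    } else {
      b$lower + u * (b$upper - b$lower)
    }
    theta[i] <- min(max(th, b$lower), b$upper)
  }
  stats::setNames(theta, names(z))
}

free_param_names <- function(params) {
  if (params$rates$tie_kR_kF) {
    c("k_R", "k_X", "k_L", "K_dR", "kappa_RF", "kappa_RX", "kappa_RL",
      "kappa_Rs", "y_F0")
  } else {
    c("k_R", "k_F", "k_X", "k_L", "K_dR", "kappa_RF", "kappa_RX", "kappa_RL",
      "kappa_Rs", "y_F0")
  }
}

# conditions: named list of batch_condition keyed by condition_id
conditions_of <- function(data, conditions = NULL) {
  conditions <- conditions %||% attr(data, "conditions")
  if (is.null(conditions)) {
    stop("no conditions: supply `conditions` or use data carrying them",
         call. = FALSE)
  }
  ids <- unique(data$condition_id)
  missing <- setdiff(ids, names(conditions))
  if (length(missing)) {
    stop("conditions missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conditions[ids]
}

observables <- c("glucose", "xylose", "f_is")

model_observables <- function(traj, times) {
  i <- match(round(times, 9), round(traj$time_h, 9))
  tibble::tibble(
    time_h = times,
    glucose = traj$c_g_g_per_L[i],
    xylose = traj$c_x_g_per_L[i],
    f_is = traj$f_is[i]
  )
}

#' Weighted least-squares objective for batch calibration
#'
#' Simulates every condition present in `data` and accumulates scaled squared
#' residuals over all observations. Sugar residuals (g/L) are divided by the
#' per-condition, per-observable data maximum; insoluble-solids residuals are
#' divided by 0.01, making the objective unit-free. A failed simulation
#' contributes a large finite penalty rather than an error, so a simplex
#' search can recover.
#'
#' @param params An [eh_params()].
#' @param data Observations: a tibble with columns `condition_id`, `time_h`,
#'   `observable` (one of `"glucose"`, `"xylose"`, `"f_is"`), `value`, and
#'   optionally `weight`.
#' @param conditions Named list of [batch_condition()]s keyed by
#'   `condition_id`; taken from `attr(data, "conditions")` when omitted.
#' @param catalog,dens See [simulate_batch()].
#' @param rtol,atol Solver tolerances used inside the objective.
#' @param detail If `TRUE`, return the residual tibble instead of the scalar.
#' @return Scalar objective (or residual tibble when `detail = TRUE`).
#' @export
eh_objective <- function(params, data, conditions = NULL,
                         catalog = species_catalog(), dens = density_spec(),
                         rtol = 1e-7, atol = 1e-11, detail = FALSE) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  bad <- setdiff(unique(data$observable), observables)
  if (length(bad)) {
    stop("unknown observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  conditions <- conditions_of(data, conditions)
  if (!("weight" %in% names(data))) data$weight <- 1
  res <- lapply(names(conditions), function(id) {
    obs <- data[data$condition_id == id, ]
    cond <- conditions[[id]]
    times <- sort(unique(c(0, obs$time_h)))
    traj <- tryCatch(
      simulate_batch(cond, params, times = times, catalog = catalog,
                     dens = dens, rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(traj)) return(NULL)
    mod <- model_observables(traj, obs$time_h)
    pred <- vapply(seq_len(nrow(obs)),
                   function(k) mod[[obs$observable[k]]][k], numeric(1))
    scale <- vapply(obs$observable, function(o) {
      if (o == "f_is") 0.01 else max(obs$value[obs$observable == o])
    }, numeric(1))
    tibble::tibble(condition_id = id, time_h = obs$time_h,
                   observable = obs$observable, value = obs$value,
                   fitted = pred, weight = obs$weight,
                   residual = (pred - obs$value) / scale)
  })
  failed <- vapply(res, is.null, logical(1))
  if (any(failed)) {
    if (detail) stop("simulation failed during residual evaluation",
                     call. = FALSE)
    return(1e6 * sum(failed))
  }
  res <- dplyr::bind_rows(res)
  if (detail) return(res)
  sum(res$weight * res$residual^2)
}

#' Calibrate the model to batch datasets
#'
#' Constrained nonlinear least squares by derivative-free simplex search
#' (Nelder-Mead), with box bounds enforced through smooth logit/log
#' transforms of the parameters. The search is local, so it is repeated from
#' `n_starts` initializations, each obtained by perturbing `init` with seeded
#' log-uniform factors in `[1 - perturb, 1 + perturb]` (with `perturb = 0`
#' every start is `init` itself); the best converged start is polished by one
#' simplex restart and returned.
#'
#' @inheritParams eh_objective
#' @param init Starting [eh_params()]; its `tie_kR_kF` setting decides
#'   whether `k_F` is a free parameter.
#' @param bounds Bounds tibble as from [default_bounds()].
#' @param n_starts Number of perturbed starts (1 = start exactly at `init`).
#' @param perturb Relative half-width of the start perturbation.
#' @param seed RNG seed for the start perturbations (recorded in the result).
#' @param maxit Simplex iteration cap per start.
#' @param reltol Simplex convergence tolerance.
#' @return An `eh_fit` object: best-fit `params`, `objective`, per-start
#'   diagnostics, residuals, and bound-activity flags. Use [generics::tidy()]
#'   / [generics::glance()] or `autoplot()` on it.
#' @export
fit_batch <- function(data, init = eh_params(), conditions = NULL,
                      bounds = default_bounds(), n_starts = 8, perturb = 0.5,
                      seed = NULL, maxit = 2000, reltol = 1e-10,
                      catalog = species_catalog(), dens = density_spec(),
                      rtol = 1e-7, atol = 1e-11) {
  conditions <- conditions_of(data, conditions)
  free <- free_param_names(init)
  if (!all(free %in% bounds$term)) {
    if (!init$rates$tie_kR_kF && !("k_F" %in% bounds$term)) {
      kf <- bounds[bounds$term == "k_R", ]
      kf$term <- "k_F"
      bounds <- dplyr::bind_rows(bounds, kf)
    }
    if (!all(free %in% bounds$term)) {
      stop("bounds missing for: ",
           paste(setdiff(free, bounds$term), collapse = ", "), call. = FALSE)
    }
  }
  theta0 <- params_vector(init)[free]
  # keep starts strictly interior so the logit transform is finite
  clip <- function(th) {
    for (i in seq_along(th)) {
      b <- bounds[bounds$term == names(th)[i], ]
      lo <- b$lower + 1e-9 * (b$upper - b$lower)
      th[i] <- min(max(th[i], lo), b$upper - 1e-9 * (b$upper - b$lower))
    }
    th
  }

  obj_z <- function(z) {
    th <- from_unconstrained(stats::setNames(z, free), bounds)
    p <- do.call(update_params, c(list(init), as.list(th)))
    eh_objective(p, data, conditions, catalog, dens, rtol, atol)
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    if (perturb == 0) return(clip(theta0))
    fac <- exp(stats::runif(length(theta0), log(1 - perturb),
                            log(1 + perturb)))
    clip(theta0 * fac)
  })

  runs <- lapply(seq_along(starts), function(i) {
    z0 <- to_unconstrained(starts[[i]], bounds)
    fit <- tryCatch(
      stats::optim(z0, obj_z, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(ok = FALSE, start = i))
    list(ok = TRUE, start = i, value = fit$value, par = fit$par,
         counts = fit$counts[["function"]], convergence = fit$convergence)
  })
  ok <- vapply(runs, `[[`, logical(1), "ok")
  if (!any(ok)) stop("all optimization starts failed", call. = FALSE)
  values <- vapply(runs[ok], `[[`, numeric(1), "value")
  best <- runs[ok][[which.min(values)]]

  # polish: restart the simplex at the incumbent to escape a collapsed simplex
  polish <- stats::optim(best$par, obj_z, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
  if (polish$value < best$value) {
    best$par <- polish$par
    best$value <- polish$value
    best$counts <- best$counts + polish$counts[["function"]]
    best$convergence <- polish$convergence
  }

  theta_hat <- from_unconstrained(stats::setNames(best$par, free), bounds)
  params_hat <- do.call(update_params, c(list(init), as.list(theta_hat)))
  at_bound <- vapply(free, function(nm) {
    b <- bounds[bounds$term == nm, ]
    span <- b$upper - b$lower
    (theta_hat[[nm]] - b$lower) <= 1e-6 * max(abs(b$lower), span * 1e-3) ||
      (b$upper - theta_hat[[nm]]) <= 1e-6 * max(abs(b$upper), span * 1e-3)
  }, logical(1))

  residuals <- eh_objective(params_hat, data, conditions, catalog, dens,
                            rtol, atol, detail = TRUE)
  start_tbl <- dplyr::bind_rows(lapply(runs, function(r) {
    tibble::tibble(start = r$start, ok = r$ok,
                   objective = if (r$ok) r$value else NA_real_,
                   evaluations = if (r$ok) r$counts else NA_integer_,
                   convergence = if (r$ok) r$convergence else NA_integer_)
  }))
  structure(
    list(params = params_hat, objective = best$value, residuals = residuals,
         starts = start_tbl, best_start = best$start,
         convergence = best$convergence, at_bound = at_bound,
         bounds = bounds, free = free, seed = seed, n_obs = nrow(data),
         conditions = conditions, catalog = catalog, dens = dens),
    class = "eh_fit"
  )
}

#' @export
print.eh_fit <- function(x, ...) {
  cat("Batch calibration fit (Nelder-Mead, ", nrow(x$starts), " start(s))\n",
      sep = "")
  cat(sprintf("  objective: %.6g over %d observations\n", x$objective,
              x$n_obs))
  est <- params_vector(x$params)[x$free]
  for (nm in x$free) {
    cat(sprintf("  %-9s %12.5g%s\n", nm, est[[nm]],
                if (x$at_bound[[nm]]) "  (at bound)" else ""))
  }
  invisible(x)
}

#' Tidy a batch calibration fit
#'
#' @param x An `eh_fit` from [fit_batch()].
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`, and
#'   `at_bound`.
#' @export
tidy.eh_fit <- function(x, ...) {
  est <- params_vector(x$params)[x$free]
  tibble::tibble(term = x$free, estimate = unname(est),
                 at_bound = unname(x$at_bound[x$free]))
}

#' One-row fit summary
#'
#' @param x An `eh_fit` from [fit_batch()].
#' @param ... Unused.
#' @return A tibble with the objective value, observation and start counts,
#'   and convergence code of the best start.
#' @export
glance.eh_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n_obs = x$n_obs,
                 n_starts = nrow(x$starts), best_start = x$best_start,
                 convergence = x$convergence)
}
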