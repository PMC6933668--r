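config_blocks <- c("schema_version", "species", "density", "kinetics",
                   "adsorption", "batch", "ceh", "fit", "noise")

config_keys <- list(
  species = c("MW_G", "MW_X", "MW_L", "MW_sL", "MW_g", "MW_x", "MW_E"),
  density = c("rho_l", "rho_is", "use_constant_density"),
  kinetics = c("k_R", "k_F", "k_X", "k_L", "tie_kR_kF",
               "lignin_couples_facile"),
  adsorption = c("K_dR", "kappa_RF", "kappa_RX", "kappa_RL", "kappa_Rs"),
  batch = c("f_is0", "w_G", "w_X", "w_L", "w_O", "lambda_E", "rho_g",
            "rho_x", "rho_sL", "y_F0", "duration"),
  ceh = c("mdot_s_in", "mdot_e_in", "mdot_m_out", "mdot_p_out", "m_T",
          "feed_f_is", "enzyme_feed_gL", "eta_E", "startup_h", "duration"),
  fit = c("n_starts", "perturb", "seed", "maxit", "reltol"),
  noise = c("sd_sugars", "sd_f_is", "seed")
)

#' Load and validate a model configuration file
#'
#' Configurations are YAML with at most the blocks `species`, `density`,
#' `kinetics`, `adsorption`, `batch`, `ceh`, `fit` and `noise`; unknown
#' blocks or keys are rejected with an error naming the offender. Keys not
#' present fall back to the package defaults (the reference best-fit
#' parameter set and water-density constant-density mode). Units follow the
#' constructors: rate coefficients 1/h, `k_L` m3/kmol, `K_dR` kmol/m3 liquid,
#' densities kg/m3, flows kg/h, background concentrations g/L.
#'
#' @param path Path to a YAML file.
#' @return A validated `eh_config` list with components `catalog`, `dens`,
#'   `params`, and (when the blocks are present) `batch`, `ceh`, `fit`,
#'   `noise`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config parse error: ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

build_config <- function(raw) {
  bad <- setdiff(names(raw), config_blocks)
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (blk in intersect(names(raw), names(config_keys))) {
    bad <- setdiff(names(raw[[blk]]), config_keys[[blk]])
    if (length(bad)) {
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  get_blk <- function(b) raw[[b]] %||% list()
  catalog <- do.call(species_catalog, get_blk("species"))
  dens <- do.call(density_spec, get_blk("density"))
  kin <- get_blk("kinetics")
  ads <- get_blk("adsorption")
  check_positive <- function(blk, keys) {
    for (k in keys) {
      v <- raw[[blk]][[k]]
      if (!is.null(v) && (!is.numeric(v) || v < 0)) {
        stop("config key ", blk, ".", k,
             " must be a non-negative number", call. = FALSE)
      }
    }
  }
  check_positive("adsorption", config_keys$adsorption)
  check_positive("kinetics", c("k_R", "k_F", "k_X", "k_L"))
  y_F0 <- (get_blk("batch"))$y_F0 %||% 0.60
  params <- eh_params(rates = do.call(rate_params, kin),
                      adsorption = do.call(adsorption_params, ads),
                      y_F0 = y_F0)

  out <- list(catalog = catalog, dens = dens, params = params, raw = raw)
  if (!is.null(raw$batch)) {
    b <- raw$batch
    w <- c(G = b$w_G %||% 0.62, X = b$w_X %||% 0.06, L = b$w_L %||% 0.22,
           O = b$w_O %||% 0.10)
    out$batch <- batch_condition(
      f_is0 = b$f_is0 %||% 0.10, w = w, lambda_E = b$lambda_E %||% 0.020,
      rho_g = b$rho_g %||% 0, rho_x = b$rho_x %||% 0,
      rho_sL = b$rho_sL %||% 0, y_F0 = b$y_F0,
      duration = b$duration %||% 168
    )
  }
  if (!is.null(raw$ceh)) {
    cc <- raw$ceh
    feed <- batch_condition(cc$feed_f_is %||% 0.05, lambda_E = 0,
                            rho_g = cc$rho_g %||% 0,
                            rho_x = cc$rho_x %||% 0)
    out$ceh <- stream_spec(
      mdot_s_in = cc$mdot_s_in, mdot_e_in = cc$mdot_e_in,
      mdot_m_out = cc$mdot_m_out, mdot_p_out = cc$mdot_p_out,
      m_T = cc$m_T %||% 5, feed = feed,
      enzyme_feed_gL = cc$enzyme_feed_gL %||% 0,
      eta_E = cc$eta_E %||% 0.5, startup_h = cc$startup_h %||% 6
    )
    out$ceh_duration <- cc$duration %||% 72
  }
  if (!is.null(raw$fit)) out$fit <- raw$fit
  if (!is.null(raw$noise)) out$noise <- do.call(noise_model, raw$noise)
  structure(out, class = "eh_config")
}

#' Save a configuration back to YAML
#'
#' Writes the raw block structure of a loaded configuration, so
#' save-then-load is the identity.
#'
#' @param config An `eh_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config$raw, path)
  invisible(path)
}
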