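trajectory_columns <- c("time_h", "f_GR", "f_GF", "f_X", "f_L", "f_O", "f_g",
                        "f_x", "f_sL", "f_ET", "f_is", "c_g_g_per_L",
                        "c_x_g_per_L", "X_t")

#' Write / read a trajectory CSV
#'
#' The on-disk dialect is UTF-8 CSV with '.' decimal separators and the fixed
#' header `time_h, f_GR, f_GF, f_X, f_L, f_O, f_g, f_x, f_sL, f_ET, f_is,
#' c_g_g_per_L, c_x_g_per_L, X_t`; values are written with 12 significant
#' digits so a write-read round trip is lossless at that precision.
#'
#' @param traj An `eh_trajectory`.
#' @param path Output path.
#' @return `path` invisibly (write) / a tibble (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  tb <- as.data.frame(traj)[, trajectory_columns]
  tb[] <- lapply(tb, function(x) signif(x, 12))
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trajectory_columns, names(tb))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  non_num <- names(tb)[!vapply(tb, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric cell(s) in column(s): ",
         paste(non_num, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(tb$time_h, strictly = TRUE)) {
    stop("time_h must be strictly increasing", call. = FALSE)
  }
  tb
}

#' Write / read an observation dataset CSV
#'
#' Long-format observations with header `condition_id, time_h, observable,
#' value`. The generating conditions, when present as the `"conditions"`
#' attribute, are stored in a YAML sidecar next to the CSV
#' (`<path>.meta.yml`) and restored on read.
#'
#' @param data Observation tibble (see [generate_batch_set()]).
#' @param path Output path.
#' @return `path` invisibly (write) / the observation tibble with restored
#'   conditions attribute (read).
#' @export
write_dataset_csv <- function(data, path) {
  tb <- as.data.frame(data)[, c("condition_id", "time_h", "observable",
                                "value")]
  tb$time_h <- signif(tb$time_h, 12)
  tb$value <- signif(tb$value, 12)
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  conds <- attr(data, "conditions")
  if (!is.null(conds)) {
    meta <- lapply(conds, function(cc) {
      list(f_is0 = cc$f_is0, w_G = cc$w[["G"]], w_X = cc$w[["X"]],
           w_L = cc$w[["L"]], w_O = cc$w[["O"]], lambda_E = cc$lambda_E,
           rho_g = cc$rho_g, rho_x = cc$rho_x, rho_sL = cc$rho_sL,
           duration = cc$duration)
    })
    yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0) stop("empty observation file", call. = FALSE)
  need <- c("condition_id", "time_h", "observable", "value")
  missing <- setdiff(need, names(tb))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tb$time_h) || !is.numeric(tb$value)) {
    stop("non-numeric cell(s) in time_h or value", call. = FALSE)
  }
  meta_path <- paste0(path, ".meta.yml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    conds <- lapply(meta, function(m) {
      batch_condition(f_is0 = m$f_is0,
                      w = c(G = m$w_G, X = m$w_X, L = m$w_L, O = m$w_O),
                      lambda_E = m$lambda_E, rho_g = m$rho_g,
                      rho_x = m$rho_x, rho_sL = m$rho_sL,
                      duration = m$duration)
    })
    attr(tb, "conditions") <- conds
  }
  tb
}
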