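#' @title File I/O for pipeline stages
#' @description CSV/JSON readers and writers for time-activity tables and
#'   fitted kinetics, round-trip stable on canonical files.
#' @name io
NULL

#' Read a time-activity CSV
#'
#' Two layouts are accepted. The value layout has columns
#' `patient_id, organ, t_h, value` (optionally `sd`), with `value` the
#' fraction of injected activity. The raw-count layout has columns
#' `patient_id, organ, t_h, ant_main, post_main, ant_low, post_low,
#' ant_up, post_up`; counts are triple-energy-window scatter corrected and
#' converted to fractions by the conjugate-view method against the
#' whole-body row (organ `"whole_body"`) at the earliest time point of
#' each patient.
#'
#' @param path CSV path.
#' @param w_main,w_lower,w_upper Energy-window widths (keV) for the
#'   raw-count layout.
#' @return Data frame `patient_id, organ, t_h, value` (plus `sd` if
#'   present).
#' @export
read_tac_csv <- function(path, w_main = 41.6, w_lower = 17.5, w_upper = 23.8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_cols <- c("patient_id", "organ", "t_h")
  missing <- setdiff(base_cols, names(df))
  if (length(missing)) {
    stop("malformed TAC file, missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if ("value" %in% names(df)) return(df)
  count_cols <- c("ant_main", "post_main", "ant_low", "post_low",
                  "ant_up", "post_up")
  missing <- setdiff(count_cols, names(df))
  if (length(missing)) {
    stop("malformed TAC file, missing column(s): ",
         paste(c("value (or raw-count columns:", missing, ")"),
               collapse = " "))
  }
  corr_ant <- tew_scatter_correct(df$ant_main, df$ant_low, df$ant_up,
                                  w_main, w_lower, w_upper)
  corr_post <- tew_scatter_correct(df$post_main, df$post_low, df$post_up,
                                   w_main, w_lower, w_upper)
  out <- df[base_cols]
  out$value <- NA_real_
  for (pid in unique(df$patient_id)) {
    sel <- df$patient_id == pid
    wb <- sel & df$organ == "whole_body"
    if (!any(wb)) stop("no 'whole_body' reference rows for patient ", pid)
    ref_i <- which(wb)[which.min(df$t_h[wb])]
    ref <- list(ant = corr_ant[ref_i], post = corr_post[ref_i])
    idx <- which(sel)
    out$value[idx] <- vapply(idx, function(i) {
      conjugate_view_fraction(list(ant = corr_ant[i], post = corr_post[i]), ref)
    }, numeric(1))
  }
  out
}

#' Write a time-activity CSV (value layout)
#'
#' @param tacs Data frame with columns `patient_id, organ, t_h, value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tac_csv <- function(tacs, path) {
  need <- c("patient_id", "organ", "t_h", "value")
  missing <- setdiff(need, names(tacs))
  if (length(missing)) {
    stop("TAC table missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(tacs[union(need, names(tacs))], path, row.names = FALSE)
  invisible(path)
}

#' Write fitted kinetics to JSON
#'
#' @param fits Named list of `exp_fit` objects (names are organ or
#'   patient/organ labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    stopifnot(inherits(f, "exp_fit"))
    list(model = f$model, amplitude = f$terms$amplitude,
         rate = f$terms$rate, rss = f$rss)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fitted kinetics from JSON
#'
#' @param path JSON path written by [write_fits_json()].
#' @return Named list of `exp_fit` objects.
#' @export
read_fits_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(payload, function(f) {
    structure(list(model = f$model,
                   terms = data.frame(amplitude = unlist(f$amplitude),
                                      rate = unlist(f$rate)),
                   rss = f$rss),
              class = "exp_fit")
  })
}
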