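#' Export weight events as JSON lines
#'
#' One JSON object per line: `{time_s, delta_lbs, person_label}`.
#'
#' @param events a data.frame from [detect_weight_events()] /
#'   [attribute_persons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(time_s = events$time_s[i],
                          delta_lbs = events$delta_lbs[i],
                          person_label = events$person_label[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export apnea events as JSON lines
#'
#' One JSON object per line: `{start_s, duration_s, kind}`.
#'
#' @param apneas a data.frame from [detect_apneas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_apneas_jsonl <- function(apneas, path) {
  lines <- vapply(seq_len(nrow(apneas)), function(i) {
    jsonlite::toJSON(list(start_s = apneas$start_s[i],
                          duration_s = apneas$duration_s[i],
                          kind = apneas$kind[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export rate epochs as CSV
#'
#' Columns `epoch_start_s, rate_bpm, valid, reason`.
#'
#' @param epochs a data.frame of rate epochs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  df <- data.frame(epoch_start_s = epochs$epoch_start_s,
                   rate_bpm = epochs$rate_bpm,
                   valid = epochs$valid,
                   reason = epochs$reason_invalid)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export daily weights as CSV
#'
#' Columns `date, weight_lbs, n_events`.
#'
#' @param weights a data.frame from [daily_weight()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_weights_csv <- function(weights, path) {
  write.csv(weights, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export demixed sources as CSV aligned to the input time base
#'
#' @param dm a `bed_demix` from [demix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_demix_csv <- function(dm, path) {
  df <- data.frame(t = dm$t, dm$sources)
  names(df) <- c("t", paste0("source", seq_len(ncol(dm$sources))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export fitted state-space parameters as JSON
#'
#' @param fit an `ssm_fit` from [fit_em()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssm_json <- function(fit, path) {
  p <- fit$params
  jsonlite::write_json(
    list(transition = p$transition, mixing = p$mixing,
         process_cov = p$process_cov, obs_cov_diag = p$obs_cov_diag,
         n_sources = p$n_sources, state_dim = p$state_dim,
         loglik = fit$loglik, n_iter = fit$n_iter),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
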