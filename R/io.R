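#' Read spike trains from CSV
#'
#' The file has a header `mn_id,time_s` and one row per discharge, times in
#' seconds.  Recruitment thresholds can be attached from a companion
#' threshold file via [read_thresholds()].
#'
#' @param path path to the CSV file.
#' @param sampling_rate grid rate attached to the trains (Hz).
#' @return A list of [spike_train()] objects ordered by `mn_id`.
#' @export
read_spike_trains <- function(path, sampling_rate = 2048) {
  df <- utils::read.csv(path)
  if (!all(c("mn_id", "time_s") %in% names(df)))
    stop("spike-train file must have columns mn_id,time_s")
  ids <- sort(unique(df$mn_id))
  lapply(ids, function(id)
    spike_train(sort(df$time_s[df$mn_id == id]), mn_id = id,
                sampling_rate = sampling_rate))
}

#' Write spike trains to CSV
#'
#' Mirrors [read_spike_trains()] bit-exactly on round trip.
#'
#' @param trains list of [spike_train()] objects.
#' @param path output path.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr)
    if (length(tr$firing_times))
      data.frame(mn_id = tr$mn_id, time_s = tr$firing_times) else NULL))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read recruitment thresholds from CSV (`mn_id,fth_percent_mvc`)
#' @param path path to the CSV file.
#' @return A data.frame with columns `mn_id`, `fth_percent_mvc`.
#' @export
read_thresholds <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mn_id", "fth_percent_mvc") %in% names(df)))
    stop("threshold file must have columns mn_id,fth_percent_mvc")
  df
}

#' Write recruitment thresholds to CSV
#' @param thresholds data.frame with columns `mn_id`, `fth_percent_mvc`.
#' @param path output path.
#' @export
write_thresholds <- function(thresholds, path) {
  utils::write.csv(thresholds[, c("mn_id", "fth_percent_mvc")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach recorded thresholds to spike trains
#' @param trains list of [spike_train()] objects.
#' @param thresholds data.frame as returned by [read_thresholds()].
#' @return The trains with `recruitment_threshold` filled in.
#' @export
attach_thresholds <- function(trains, thresholds) {
  lapply(trains, function(tr) {
    hit <- thresholds$fth_percent_mvc[thresholds$mn_id == tr$mn_id]
    if (length(hit) == 1) tr$recruitment_threshold <- hit
    tr
  })
}

#' Read a force trace from CSV (`time_s,force`)
#' @param path path to the CSV file.
#' @param role role of the returned signal (default `"force"`).
#' @return A [drive_signal()].
#' @export
read_force <- function(path, role = "force") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force") %in% names(df)))
    stop("force file must have columns time_s,force")
  drive_signal(df$time_s, df$force, role = role)
}

#' Write a signal to CSV (`time_s,force` or `time_s,current_A`)
#' @param x a [drive_signal()].
#' @param path output path.
#' @param value_col name of the value column (default by role).
#' @export
write_signal <- function(x, path, value_col = NULL) {
  if (is.null(value_col))
    value_col <- if (x$role == "current") "current_A" else "force"
  df <- data.frame(time_s = x$times, v = x$values)
  names(df)[2] <- value_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
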