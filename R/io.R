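#' Write a simulated session to disk in plain-text formats
#'
#' Writes `trials.tsv` (trial_index, cs, rewarded, onset_s), optionally
#' `licks.tsv` (time_s), `pupil.tsv` (time_s, pct_change), one
#' `units/<id>.tsv` per unit (trial_index, spike_time_s relative to odor
#' onset), and `truth.json` with the generative parameters.
#'
#' @param dir Output directory (created if needed).
#' @param seq Trial sequence.
#' @param licks Optional lick data frame.
#' @param pupil Optional pupil trace data frame (`time_s`, `pct_change`).
#' @param rasters Optional `unit_raster_set`.
#' @param truth Optional list of generative parameters.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, seq, licks = NULL, pupil = NULL,
                          rasters = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(data.frame(trial_index = seq$trial, cs = seq$cs,
                 rewarded = as.integer(seq$rewarded),
                 onset_s = seq$onset), "trials.tsv")
  if (!is.null(licks)) tsv(data.frame(time_s = licks$time_s), "licks.tsv")
  if (!is.null(pupil)) tsv(pupil, "pupil.tsv")
  if (!is.null(rasters)) {
    dir.create(file.path(dir, "units"), showWarnings = FALSE)
    for (u in rasters$units)
      utils::write.table(
        data.frame(trial_index = u$spikes$trial,
                   spike_time_s = u$spikes$time),
        file.path(dir, "units", paste0(u$id, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trial-event table
#'
#' @param path Path to a `trials.tsv` written by [write_session()].
#' @return Trial sequence data frame (`trial`, `cs`, `rewarded`, `onset`).
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path)
  data.frame(trial = d$trial_index, cs = d$cs,
             rewarded = as.logical(d$rewarded), onset = d$onset_s)
}

#' Read a lick-timestamp table
#'
#' @param path Path to a `licks.tsv`.
#' @return Data frame with column `time_s`.
#' @export
read_licks <- function(path) utils::read.delim(path)

#' Read the unit spike tables of a session
#'
#' @param dir Session directory containing `units/*.tsv` and `trials.tsv`.
#' @param window Raster window attached to the returned set.
#' @param region Region label.
#' @return A `unit_raster_set`.
#' @export
read_units <- function(dir, window = c(-3, 6), region = "Tu") {
  seq <- read_trials(file.path(dir, "trials.tsv"))
  files <- sort(list.files(file.path(dir, "units"), pattern = "\\.tsv$",
                           full.names = TRUE))
  units <- lapply(files, function(f) {
    d <- utils::read.delim(f)
    list(id = sub("\\.tsv$", "", basename(f)), archetype = NA_character_,
         tuning = NA_character_, pref_cs = NA_character_,
         baseline = NA_real_,
         spikes = data.frame(trial = d$trial_index, time = d$spike_time_s))
  })
  structure(list(units = units, seq = seq, window = window,
                 region = region),
            class = "unit_raster_set")
}
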