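#' Read a trial table from TSV
#'
#' Expected columns: `neuron_id`, `block_id`, `condition`, `trial_index`
#' (0-based within block), `tone`, `spike_count`, and optionally
#' `freq_label` and `spike_times` (semicolon-separated milliseconds relative
#' to stimulus onset).  Lines starting with `#` are treated as comments.
#'
#' @param path TSV file path.
#' @return A data frame.
#' @export
read_trials <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("block_id", "trial_index", "tone", "spike_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stop_param("trial table is missing columns: %s", paste(miss, collapse = ", "))
  if (any(df$spike_count < 0, na.rm = TRUE))
    .stop_param("spike counts must be nonnegative")
  df
}

#' Write a trial table to TSV
#'
#' @param trials a trial-table data frame.
#' @param path output path.
#' @param header optional character vector written as `#`-prefixed comment
#'   lines (e.g. a configuration echo).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(trials, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recompute spike counts from spike times in a counting window
#'
#' Counts spikes in the half-open window `[window[1], window[2])`
#' milliseconds after stimulus onset.  The default window (0-330 ms, for
#' 230 ms tones) captures onset, sustained and offset response components;
#' presets match the window analysis: `"onset"` (0-50 ms), `"sustained"`
#' (50-230 ms), `"offset"` (260-330 ms), `"full"` (0-330 ms).
#'
#' @param trials trial table with a `spike_times` column
#'   (semicolon-separated ms).
#' @param window numeric `c(t0, t1)` in ms, or a preset name.
#' @return The trial table with `spike_count` recomputed.
#' @export
count_in_window <- function(trials, window = c(0, 330)) {
  presets <- list(full = c(0, 330), onset = c(0, 50),
                  sustained = c(50, 230), offset = c(260, 330))
  if (is.character(window)) {
    if (!window %in% names(presets))
      .stop_param("unknown window preset '%s'", window)
    window <- presets[[window]]
  }
  if (length(window) != 2 || window[2] <= window[1])
    .stop_param("window must be c(t0, t1) with t1 > t0")
  if (!"spike_times" %in% names(trials))
    .stop_param("trial table has no spike_times column")
  trials$spike_count <- vapply(trials$spike_times, function(s) {
    if (is.na(s) || !nzchar(s)) return(0L)
    t <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    sum(t >= window[1] & t < window[2])
  }, 0L, USE.NAMES = FALSE)
  trials
}
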