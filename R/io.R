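#' Read and write binned activity CSV files
#'
#' The on-disk format is a two-column CSV, `time_h` (decimal hours from
#' recording start, bin left edge) and `counts`. Bins must be uniform and
#' gap-free; a missing bin is an error naming the first missing timestamp,
#' unless `fill_gaps = TRUE`, in which case missing bins are zero-filled
#' with a warning.
#'
#' @param path File path.
#' @param schedule A [light_schedule()].
#' @param start_zt ZT hour of the first bin.
#' @param animal_id Animal label.
#' @param fill_gaps Zero-fill missing bins instead of failing. Default FALSE.
#' @return An [activity_recording()].
#' @export
read_activity_csv <- function(path, schedule = light_schedule(),
                              start_zt = 0, animal_id = "animal",
                              fill_gaps = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "counts") %in% names(df)))
    stop_data("activity CSV must have columns `time_h` and `counts`")
  if (nrow(df) < 2L) stop_data("activity CSV must contain at least two bins")
  if (anyNA(df$counts) || any(df$counts < 0))
    stop_data("negative or missing counts in ", path)
  dt <- diff(df$time_h)
  bin_h <- min(dt)
  if (any(abs(dt / bin_h - round(dt / bin_h)) > 1e-6) ||
      any(dt <= 0))
    stop_data("non-uniform bin widths in ", path)
  if (any(round(dt / bin_h) > 1)) {
    gap_at <- df$time_h[which(round(dt / bin_h) > 1)[1]] + bin_h
    if (!fill_gaps)
      stop_data("missing bin at time_h = ", format(gap_at), " in ", path)
    warning("zero-filling missing bins in ", path, call. = FALSE)
    grid <- seq(df$time_h[1], df$time_h[nrow(df)], by = bin_h)
    counts <- numeric(length(grid))
    counts[match(round(df$time_h / bin_h), round(grid / bin_h))] <- df$counts
  } else {
    counts <- df$counts
  }
  bin_minutes <- round(bin_h * 60)
  activity_recording(counts, bin_minutes = bin_minutes, start_zt = start_zt,
                     schedule = schedule, animal_id = animal_id)
}

#' @rdname read_activity_csv
#' @param rec An [activity_recording()] to write.
#' @export
write_activity_csv <- function(rec, path) {
  df <- data.frame(
    time_h = (seq_along(rec$counts) - 1) * rec$bin_minutes / 60,
    counts = rec$counts
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' Each table is written twice: at full precision (`<name>.csv`) and as a
#' display copy rounded to `digits` significant figures
#' (`<name>_display.csv`). Column order is preserved as given, so repeated
#' writes of identical input are byte-identical.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if absent).
#' @param digits Significant digits for the display copy. Default 4.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir, digits = 4) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    p_full <- file.path(dir, paste0(nm, ".csv"))
    p_disp <- file.path(dir, paste0(nm, "_display.csv"))
    utils::write.csv(tab, p_full, row.names = FALSE, quote = FALSE)
    disp <- tab
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], signif, digits = digits)
    utils::write.csv(disp, p_disp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p_full, p_disp)
  }
  invisible(paths)
}
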