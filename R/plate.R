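# Fluorescence plate data and control-based normalization.

#' Fluorescence plate data
#'
#' Raw plate-reader kinetics for one fluorophore channel: a shared time grid
#' and one raw-signal series per well, with each well assigned a role. Every
#' channel needs at least one negative control (the initial structure, no
#' invader: the 0% level) and one positive control (the pre-annealed target
#' structure: the 100% level).
#'
#' @param time_s Shared time grid, seconds.
#' @param wells Named list (or data frame) of numeric raw-signal series.
#' @param roles Named character vector mapping well id to `"sample"`,
#'   `"negative_control"` or `"positive_control"`.
#' @param channel Fluorophore name (e.g. `"ROX"`, `"TYE563"`).
#' @return An object of class `plate_data`.
#' @export
plate_data <- function(time_s, wells, roles, channel = "ROX") {
  wells <- lapply(wells, as.numeric)
  if (is.null(names(wells)) || any(!nzchar(names(wells))))
    stop("wells must be named")
  lens <- vapply(wells, length, integer(1))
  if (any(lens != length(time_s)))
    stop("all well series must share the time grid")
  if (!all(names(wells) %in% names(roles)))
    stop("every well needs a role")
  roles <- roles[names(wells)]
  if (!all(roles %in% c("sample", "negative_control", "positive_control")))
    stop("roles must be sample/negative_control/positive_control")
  if (sum(roles == "negative_control") < 1L ||
      sum(roles == "positive_control") < 1L)
    stop("need at least one negative and one positive control well")
  structure(list(time_s = as.numeric(time_s), wells = wells, roles = roles,
                 channel = channel),
            class = "plate_data")
}

#' Normalize raw fluorescence to completion fractions
#'
#' The 0% level `L0` is the mean of the first 5 data points of the negative
#' control(s); the 100% level `L1` is the mean of the last 5 data points of
#' the positive control(s). Each sample well is mapped linearly,
#' `(raw - L0) / (L1 - L0)`. When experimental noise puts a sample's own
#' first-5 mean below `L0` (or last-5 mean above `L1`), the smaller (larger)
#' averaged value replaces that level for that sample, so normalized series
#' start at 0 (end at 1) rather than outside the range. The map is invariant
#' under any common positive affine transform of all raw series.
#'
#' @param plate A [plate_data()].
#' @return Data frame with `time_s` and one completion column per sample
#'   well.
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  if (length(plate$time_s) < 5L) stop("series length must be >= 5")
  negs <- plate$wells[plate$roles == "negative_control"]
  poss <- plate$wells[plate$roles == "positive_control"]
  n <- length(plate$time_s)
  L0 <- mean(vapply(negs, function(w) mean(w[1:5]), numeric(1)))
  L1 <- mean(vapply(poss, function(w) mean(w[(n - 4):n]), numeric(1)))
  if (L1 <= L0)
    stop("controls inverted: positive level (", format(L1),
         ") <= negative level (", format(L0), ")")
  out <- data.frame(time_s = plate$time_s)
  for (w in names(plate$wells)[plate$roles == "sample"]) {
    raw <- plate$wells[[w]]
    l0 <- min(L0, mean(raw[1:5]))
    l1 <- max(L1, mean(raw[(n - 4):n]))
    out[[w]] <- (raw - l0) / (l1 - l0)
  }
  out
}

#' Read/write plate data as delimited text
#'
#' Tab-separated columns `time_s`, then one column per well; roles and
#' channel are stored in a `#` comment prologue so a single file round-trips
#' the full object.
#'
#' @param plate A [plate_data()].
#' @param path File path.
#' @return `read_plate` returns a [plate_data()]; `write_plate` returns
#'   `path` invisibly.
#' @export
write_plate <- function(plate, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel: %s", plate$channel), con)
  for (w in names(plate$roles))
    writeLines(sprintf("# role: %s %s", w, plate$roles[[w]]), con)
  df <- data.frame(time_s = plate$time_s)
  for (w in names(plate$wells)) df[[w]] <- plate$wells[[w]]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  lines <- readLines(path)
  channel <- sub("^# channel: ", "", grep("^# channel: ", lines, value = TRUE))
  role_lines <- sub("^# role: ", "", grep("^# role: ", lines, value = TRUE))
  parts <- strsplit(role_lines, " ", fixed = TRUE)
  roles <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                           vapply(parts, `[`, character(1), 1L))
  df <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                          header = TRUE, check.names = FALSE)
  plate_data(df$time_s, as.list(df[setdiff(names(df), "time_s")]), roles,
             channel = channel)
}
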