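#' Read a WISDM v1.1 raw accelerometer file
#'
#' Parses lines of the form `user,Activity,timestamp,x,y,z;` (the trailing
#' semicolon is optional and stripped). Malformed lines — wrong field
#' count, non-numeric values, empty lines — are skipped and counted, never
#' fatal. Input order is preserved.
#'
#' @param source File path or connection, or a character vector of lines.
#' @param labels Known activity labels; samples with other labels are kept
#'   but flagged in the report. Default [har_activities()].
#' @return A list with components:
#'   \describe{
#'     \item{samples}{Data frame `user_id`, `activity`, `timestamp`,
#'       `x`, `y`, `z`, in file order.}
#'     \item{report}{List with `n_lines`, `n_parsed`, `n_skipped`,
#'       `skipped_lines` (1-based indices, capped at 100) and
#'       `unknown_labels` (labels seen outside `labels`).}
#'   }
#' @export
read_wisdm <- function(source, labels = har_activities()) {
  lines <- if (is.character(source) && length(source) > 1L) source
           else if (is.character(source) && !file.exists(source) &&
                    grepl(",", source, fixed = TRUE)) source
           else readLines(source, warn = FALSE)
  n <- length(lines)
  # strip trailing semicolon (and any stray whitespace)
  clean <- sub(";\\s*$", "", trimws(lines))
  parts <- strsplit(clean, ",", fixed = TRUE)
  ok <- lengths(parts) == 6L & nzchar(clean)
  fields <- matrix("", nrow = sum(ok), ncol = 6L)
  if (any(ok)) fields <- do.call(rbind, parts[ok])
  num <- function(j) suppressWarnings(as.numeric(fields[, j]))
  user <- suppressWarnings(as.integer(fields[, 1]))
  ts <- num(3); x <- num(4); y <- num(5); z <- num(6)
  good <- !is.na(user) & !is.na(ts) & !is.na(x) & !is.na(y) & !is.na(z)
  keep_idx <- which(ok)[good]
  samples <- data.frame(
    user_id = user[good], activity = fields[good, 2],
    timestamp = ts[good], x = x[good], y = y[good], z = z[good])
  skipped <- setdiff(seq_len(n), keep_idx)
  unknown <- setdiff(unique(samples$activity), labels)
  list(samples = samples,
       report = list(n_lines = n, n_parsed = nrow(samples),
                     n_skipped = length(skipped),
                     skipped_lines = head(skipped, 100L),
                     unknown_labels = unknown))
}

#' Remove all-zero sensor readings
#'
#' An accelerometer always senses gravity, so a sample whose three axes
#' all read exactly 0 is a sensor dropout and is removed. The test is
#' exact equality on the parsed values; rows with any nonzero axis are
#' kept and order is preserved. The filter is idempotent.
#'
#' @param samples Sample data frame (columns `x`, `y`, `z`).
#' @return List with `samples` (kept rows) and `removed` (count).
#' @export
eda_filter <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("x", "y", "z") %in% names(samples)))
  zero <- samples$x == 0 & samples$y == 0 & samples$z == 0
  kept <- samples[!zero, , drop = FALSE]
  rownames(kept) <- NULL
  list(samples = kept, removed = sum(zero))
}

#' Per-user and per-activity sample counts
#'
#' @param samples Sample data frame.
#' @return List with `by_user` (data frame `user_id`, `activity`, `n`) and
#'   `by_activity` (data frame `activity`, `n`, `pct`; percentages sum to
#'   100 up to rounding of the counts themselves).
#' @export
summarize_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L)
    return(list(by_user = data.frame(user_id = integer(), activity = character(),
                                     n = integer()),
                by_activity = data.frame(activity = character(), n = integer(),
                                         pct = numeric())))
  tab <- as.data.frame(table(user_id = samples$user_id,
                             activity = samples$activity),
                       responseName = "n", stringsAsFactors = FALSE)
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab$user_id <- as.integer(tab$user_id)
  tab <- tab[order(tab$user_id, tab$activity), , drop = FALSE]
  rownames(tab) <- NULL
  act <- as.data.frame(table(activity = samples$activity),
                       responseName = "n", stringsAsFactors = FALSE)
  act$pct <- 100 * act$n / sum(act$n)
  list(by_user = tab, by_activity = act)
}
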