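# Tidy culture time-series container shared by the generator, the physiology
# fitter and the isotopic fitter. One row per measured point:
#   replicate, time_h, quantity, label_state, value, sd

#' Known measurable quantities
#' @keywords internal
TS_QUANTITIES <- c("biomass", "glycerol", "ethanolamine", "ethanol",
                   "acetate", "acetaldehyde", "ammonium")

TS_LABEL_STATES <- c("total", "unlabeled", "U-13C")

#' Construct and validate a culture time series
#'
#' A `culture_timeseries` is a tidy data frame of replicated concentration and
#' biomass measurements from a batch culture, optionally split by isotopic
#' label state for tracer experiments. Biomass is in gDW/L, metabolites in mM.
#'
#' Invariants enforced: times strictly increasing within each
#' replicate/quantity/label series; values non-negative; positive `sd` for
#' every point; a quantity never mixes `"total"` with split label states
#' within one replicate.
#'
#' @param df data frame with columns `replicate`, `time_h`, `quantity`,
#'   `label_state`, `value` and (optionally) `sd`.
#' @return the validated data frame with class `culture_timeseries`.
#' @export
culture_timeseries <- function(df) {
  required <- c("replicate", "time_h", "quantity", "label_state", "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("time series is missing columns: ", paste(missing, collapse = ", "))
  if (!"sd" %in% names(df)) {
    warning("no 'sd' column: downstream weighted objectives will require one")
    df$sd <- NA_real_
  }
  df <- as.data.frame(df)[, c(required, "sd")]
  bad_q <- setdiff(unique(df$quantity), TS_QUANTITIES)
  if (length(bad_q))
    stop("unknown quantity: ", paste(bad_q, collapse = ", "))
  bad_l <- setdiff(unique(df$label_state), TS_LABEL_STATES)
  if (length(bad_l))
    stop("unknown label_state: ", paste(bad_l, collapse = ", "))
  if (any(!is.finite(df$value)))
    stop("non-finite values in time series")
  neg <- which(df$value < 0)
  if (length(neg))
    stop("negative concentration at row ", neg[1L],
         " (", df$quantity[neg[1L]], ", t = ", df$time_h[neg[1L]], " h)")
  if (any(!is.na(df$sd) & df$sd <= 0))
    stop("sd must be positive where present")
  key <- interaction(df$replicate, df$quantity, df$label_state, drop = TRUE)
  for (k in levels(key)) {
    tt <- df$time_h[key == k]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing within series ", k)
  }
  mix <- interaction(df$replicate, df$quantity, drop = TRUE)
  for (k in levels(mix)) {
    states <- unique(df$label_state[mix == k])
    if ("total" %in% states && length(states) > 1L)
      stop("quantity mixes 'total' with split label states: ", k)
  }
  class(df) <- c("culture_timeseries", "data.frame")
  df
}

#' Read / write culture time series as tidy CSV
#'
#' The on-disk dialect is a plain CSV with columns
#' `replicate,time_h,quantity,label_state,value,sd`. Reading validates all
#' container invariants and reports the offending row on failure.
#'
#' @param path file path.
#' @return `read_timeseries` returns a [culture_timeseries()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tryCatch(culture_timeseries(df),
           error = function(e) stop("malformed time series in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' @rdname read_timeseries
#' @param ts a [culture_timeseries()].
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "culture_timeseries") || is.data.frame(ts))
  write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
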