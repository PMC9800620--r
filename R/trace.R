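#' Construct a current trace
#'
#' A current trace is the raw signal recorded by the potentiostat: current
#' sampled at (typically) 30-s intervals, together with the projected anode
#' area and the liquid volume of the reactor. All electrochemical metrics
#' ([total_charge()], [peak_current()], [lag_time()], [coulombic_efficiency()])
#' consume this object.
#'
#' @param time_s numeric vector of sampling times in seconds, strictly
#'   increasing.
#' @param current_A numeric vector of currents in amperes, same length as
#'   `time_s`.
#' @param electrode_area_m2 projected electrode area in m^2 (> 0); used to
#'   express current as a density (A/m^2).
#' @param volume_L liquid volume of the reactor in litres (> 0); the `V` in
#'   the coulombic-efficiency denominator.
#' @return An object of class `mec_trace`: a list with elements `time_s`,
#'   `current_A`, `electrode_area_m2`, `volume_L`.
#' @examples
#' tr <- current_trace(seq(0, 300, by = 30), rep(2e-3, 11),
#'                     electrode_area_m2 = 8e-4, volume_L = 0.07)
#' tr
#' @export
current_trace <- function(time_s, current_A, electrode_area_m2, volume_L) {
  time_s <- as.numeric(time_s)
  current_A <- as.numeric(current_A)
  if (length(time_s) == 0L) stop("empty trace: no samples")
  if (length(time_s) != length(current_A))
    stop("time_s and current_A must have the same length")
  if (anyNA(time_s) || anyNA(current_A))
    stop("trace contains missing values")
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  if (!is.numeric(electrode_area_m2) || electrode_area_m2 <= 0)
    stop("electrode_area_m2 must be a positive number")
  if (!is.numeric(volume_L) || volume_L <= 0)
    stop("volume_L must be a positive number")
  structure(
    list(time_s = time_s, current_A = current_A,
         electrode_area_m2 = as.numeric(electrode_area_m2),
         volume_L = as.numeric(volume_L)),
    class = "mec_trace")
}

#' @export
print.mec_trace <- function(x, ...) {
  cat("Current trace:", length(x$time_s), "samples spanning",
      format(round((max(x$time_s) - min(x$time_s)) / 86400, 2)), "days\n")
  cat("  electrode area:", x$electrode_area_m2, "m^2; liquid volume:",
      x$volume_L, "L\n")
  cat("  current range: [", format(signif(min(x$current_A), 4)), ",",
      format(signif(max(x$current_A), 4)), "] A\n")
  invisible(x)
}

#' @export
plot.mec_trace <- function(x, ...) {
  plot(x$time_s / 86400, x$current_A / x$electrode_area_m2, type = "l",
       xlab = "Time (days)", ylab = expression(Current~density~(A/m^2)), ...)
  invisible(x)
}

#' Read / write a current trace as CSV
#'
#' The on-disk format is a two-column CSV with header `time_s,current_A`.
#' Area and volume are not part of the file; they are supplied by the caller
#' (or the pipeline configuration).
#'
#' @param path file path.
#' @param electrode_area_m2,volume_L reactor geometry passed through to
#'   [current_trace()].
#' @return `read_trace_csv` returns a `mec_trace`; `write_trace_csv`
#'   invisibly returns `path`.
#' @export
read_trace_csv <- function(path, electrode_area_m2, volume_L) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current_A") %in% names(df)))
    stop("trace CSV must have columns time_s, current_A: ", path)
  current_trace(df$time_s, df$current_A, electrode_area_m2, volume_L)
}

#' @rdname read_trace_csv
#' @param trace a `mec_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mec_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              current_A = trace$current_A),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
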