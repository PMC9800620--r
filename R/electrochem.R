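#' Faraday's constant
#'
#' Charge carried by one mole of electrons, 96,485.3 C/mol e-.
#' @export
FARADAY <- 96485.3

#' Electrons liberated by complete oxidation of a substrate to CO2
#'
#' The `b` coefficient of the coulombic-efficiency denominator, from the
#' balanced anodic half-reaction of each carboxylate to CO2:
#' acetate C2H3O2- + 2 H2O -> 2 CO2 + 7 H+ + 8 e-;
#' propionate yields 14 e-; butyrate 20 e-.
#'
#' @param substrate character vector among `"acetate"`, `"propionate"`,
#'   `"butyrate"`.
#' @return mol electrons per mol substrate.
#' @examples
#' electron_count("acetate")     # 8
#' electron_count(c("propionate", "butyrate"))
#' @export
electron_count <- function(substrate) {
  b <- c(acetate = 8, propionate = 14, butyrate = 20)
  bad <- setdiff(substrate, names(b))
  if (length(bad) > 0)
    stop("unknown substrate(s): ", paste(bad, collapse = ", "),
         " (expected acetate, propionate or butyrate)")
  unname(b[substrate])
}

#' Rebin a current trace by averaging fixed-size groups of samples
#'
#' Consecutive non-overlapping groups of `group_size` raw measurements
#' (10 samples at 30-s sampling = 5-min bins) are averaged; each bin is
#' timestamped at the midpoint (mean time) of its group. A trailing partial
#' group is averaged over the samples it has rather than dropped, so
#' end-of-cycle peaks are preserved.
#'
#' @param trace a [current_trace()].
#' @param group_size samples per bin (default 10).
#' @return a `mec_trace` of binned values.
#' @export
rebin_current <- function(trace, group_size = 10) {
  stopifnot(inherits(trace, "mec_trace"))
  if (group_size < 1) stop("group_size must be >= 1")
  n <- length(trace$time_s)
  grp <- (seq_len(n) - 1L) %/% group_size
  t_bin <- as.numeric(tapply(trace$time_s, grp, mean))
  i_bin <- as.numeric(tapply(trace$current_A, grp, mean))
  current_trace(t_bin, i_bin, trace$electrode_area_m2, trace$volume_L)
}

# clamp a window to the trace span, erroring when it lies outside
check_window <- function(trace, t1, t2) {
  if (!is.numeric(t1) || !is.numeric(t2) || t2 <= t1)
    stop("invalid time window: need t2 > t1")
  span <- range(trace$time_s)
  if (t2 < span[1] || t1 > span[2])
    stop("window [", t1, ", ", t2, "] lies outside the trace span [",
         span[1], ", ", span[2], "]")
  invisible(NULL)
}

#' Peak current within a time window
#'
#' The peak current for a period (for example a batch cycle) is the highest
#' binned (5-min average) current observed in it. The raw trace is rebinned
#' internally unless `rebin = FALSE`.
#'
#' @param trace a `mec_trace`.
#' @param t1,t2 window bounds in seconds.
#' @param rebin average into `group_size`-sample bins first (default TRUE).
#' @param group_size samples per bin when rebinning.
#' @return peak current in amperes.
#' @export
peak_current <- function(trace, t1, t2, rebin = TRUE, group_size = 10) {
  stopifnot(inherits(trace, "mec_trace"))
  check_window(trace, t1, t2)
  tr <- if (rebin) rebin_current(trace, group_size) else trace
  sel <- tr$time_s >= t1 & tr$time_s <= t2
  if (!any(sel)) stop("no binned samples inside the window")
  max(tr$current_A[sel])
}

#' Total charge transferred over a time window
#'
#' Trapezoidal integral of the raw current signal I(t) over [t1, t2], in
#' coulombs. Integration uses the raw samples, not the 5-min bins; values at
#' the window boundaries are obtained by linear interpolation when the
#' bounds fall between samples.
#'
#' @param trace a `mec_trace`.
#' @param t1,t2 integration limits in seconds (clamped to the trace span).
#' @return charge in coulombs.
#' @export
total_charge <- function(trace, t1, t2) {
  stopifnot(inherits(trace, "mec_trace"))
  check_window(trace, t1, t2)
  tt <- trace$time_s
  ii <- trace$current_A
  t1 <- max(t1, tt[1])
  t2 <- min(t2, tt[length(tt)])
  inside <- tt > t1 & tt < t2
  xs <- c(t1, tt[inside], t2)
  ys <- c(stats::approx(tt, ii, xout = t1)$y, ii[inside],
          stats::approx(tt, ii, xout = t2)$y)
  if (length(xs) < 2) stop("window contains fewer than 2 samples")
  pracma::trapz(xs, ys)
}

#' Coulombic efficiency over a time window
#'
#' Fraction of the electrons in the consumed substrate recovered as current:
#' integral of I(t) over [t1, t2] divided by F * V * sum(b * dC), where F is
#' Faraday's constant, V the liquid volume (L), dC the consumed
#' concentration of each substrate (mol/L, consumption positive) and b its
#' electron yield ([electron_count()]). Dimensionless; values above 1 on
#' inconsistent inputs are reported, not clipped.
#'
#' @param trace a `mec_trace` (provides V via `volume_L`).
#' @param t1,t2 window bounds in seconds.
#' @param deltas data.frame with columns `substrate` and `delta_mol_per_L`
#'   (consumed concentration, >= 0).
#' @param b optional named vector overriding the default electron yields.
#' @return coulombic efficiency (fraction).
#' @examples
#' tr <- current_trace(seq(0, 5403.2, length.out = 200), rep(1e-3, 200),
#'                     electrode_area_m2 = 8e-4, volume_L = 0.07)
#' deltas <- data.frame(substrate = "acetate", delta_mol_per_L = 1e-4)
#' coulombic_efficiency(tr, 0, 5403.2, deltas)  # ~1.0
#' @export
coulombic_efficiency <- function(trace, t1, t2, deltas, b = NULL) {
  stopifnot(inherits(trace, "mec_trace"), is.data.frame(deltas))
  if (!all(c("substrate", "delta_mol_per_L") %in% names(deltas)))
    stop("deltas needs columns substrate, delta_mol_per_L")
  if (any(deltas$delta_mol_per_L < 0))
    stop("delta_mol_per_L must be >= 0 (consumption is positive)")
  bvals <- if (is.null(b)) electron_count(deltas$substrate)
           else unname(b[deltas$substrate])
  denom_mol <- sum(bvals * deltas$delta_mol_per_L)
  if (denom_mol <= 0)
    stop("all substrate deltas are zero: coulombic efficiency undefined")
  q <- total_charge(trace, t1, t2)
  q / (FARADAY * trace$volume_L * denom_mol)
}

#' Lag time before substantial current production
#'
#' Time, in days from the start of the trace, of the first 5-min-average bin
#' whose current density exceeds `threshold_A_per_m2` (default 1 A/m^2).
#' A trace that never crosses the threshold returns `NA` with attribute
#' `crossed = FALSE`.
#'
#' @param trace a `mec_trace`.
#' @param threshold_A_per_m2 current-density threshold (default 1).
#' @param group_size samples per bin for the internal rebinning.
#' @return lag in days (numeric), or `NA` flagged `crossed = FALSE`.
#' @export
lag_time <- function(trace, threshold_A_per_m2 = 1.0, group_size = 10) {
  stopifnot(inherits(trace, "mec_trace"))
  tr <- rebin_current(trace, group_size)
  dens <- tr$current_A / tr$electrode_area_m2
  hit <- which(dens > threshold_A_per_m2)
  if (length(hit) == 0L)
    return(structure(NA_real_, crossed = FALSE))
  structure((tr$time_s[hit[1]] - trace$time_s[1]) / 86400, crossed = TRUE)
}
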