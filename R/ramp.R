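#' Staircase potential-ramp program
#'
#' Describes the potential program applied to the electrochemical flow cell:
#' a staircase from `e_start` to `e_end` in discrete `step_size` increments
#' at `scan_rate`, so each level is held `step_size / scan_rate` seconds
#' (0.5 s for the typical 5 mV step at 10 mV/s). `delay_s` is the transfer
#' delay between the cell and the ion source (tubing dead volume), applied
#' before mapping scan times to potentials.
#'
#' @param e_start,e_end start and end potential in mV (vs. the reference
#'   electrode); `e_end > e_start`.
#' @param scan_rate ramp speed in mV/s (> 0).
#' @param step_size staircase increment in mV (> 0); `e_end - e_start` must
#'   be an integer multiple of it.
#' @param delay_s transfer delay in seconds (>= 0); see
#'   [delay_from_geometry()].
#' @return a `potential_ramp`.
#' @export
#' @examples
#' r <- potential_ramp(0, 3500, scan_rate = 10, step_size = 5)
#' length(step_grid(r))           # 701 levels
#' potential_at_time(r, 175)      # 1750 mV
potential_ramp <- function(e_start, e_end, scan_rate, step_size, delay_s = 0) {
  stopifnot(e_end > e_start, scan_rate > 0, step_size > 0, delay_s >= 0)
  k <- (e_end - e_start) / step_size
  if (abs(k - round(k)) > 1e-9)
    stop("potential span (", e_end - e_start,
         " mV) is not an integer multiple of step_size (", step_size, " mV)")
  structure(list(e_start = e_start, e_end = e_end, scan_rate = scan_rate,
                 step_size = step_size, delay_s = delay_s),
            class = "potential_ramp")
}

#' @export
print.potential_ramp <- function(x, ...) {
  cat("<potential_ramp> ", x$e_start, " -> ", x$e_end, " mV @ ",
      x$scan_rate, " mV/s, step ", x$step_size, " mV",
      if (x$delay_s > 0) paste0(", delay ", x$delay_s, " s"), "\n", sep = "")
  invisible(x)
}

#' Ramp duration in seconds (excluding transfer delay)
#' @param r a `potential_ramp`.
#' @return seconds from ramp start until `e_end` is reached.
#' @export
ramp_duration <- function(r) (r$e_end - r$e_start) / r$scan_rate

#' Applied potential at an acquisition time
#'
#' Staircase mapping: `E = e_start + step_size * floor(scan_rate * max(0,
#' t - delay_s) / step_size)`, clamped to `[e_start, e_end]`. Scans arriving
#' before the delay-corrected ramp start map to `e_start`, scans after the
#' ramp end to `e_end` — the cell holds the rail potential there, so every
#' scan stays usable.
#'
#' @param r a `potential_ramp`.
#' @param t scan time(s) in seconds (>= 0); vectorised.
#' @return potential(s) in mV; non-decreasing in `t`.
#' @export
potential_at_time <- function(r, t) {
  stopifnot(all(t >= 0))
  e <- r$e_start + r$step_size *
    floor(r$scan_rate * pmax(0, t - r$delay_s) / r$step_size + 1e-9)
  pmin(pmax(e, r$e_start), r$e_end)
}

#' Transfer delay from capillary geometry
#'
#' Plug-flow dead time of the transfer capillary between the electrochemical
#' cell outlet and the ion source: `60 * volume / flow`.
#'
#' @param capillary_volume_ul inner capillary volume in microlitres (> 0).
#' @param flow_ul_min flow rate in microlitres per minute (> 0).
#' @return delay in seconds (10 uL at 20 uL/min gives 30 s).
#' @export
delay_from_geometry <- function(capillary_volume_ul, flow_ul_min) {
  if (capillary_volume_ul <= 0 || flow_ul_min <= 0)
    stop("capillary volume and flow rate must be positive")
  60 * capillary_volume_ul / flow_ul_min
}

#' Ordered grid of potential levels
#'
#' @param r a `potential_ramp`.
#' @return numeric vector `e_start, e_start + step, ..., e_end` (inclusive);
#'   length `(e_end - e_start)/step_size + 1`.
#' @export
step_grid <- function(r) seq(r$e_start, r$e_end, by = r$step_size)
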