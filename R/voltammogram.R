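#' @name mass-voltammogram
#' @title Mass voltammograms
#'
#' @description
#' A mass voltammogram is the EC-MS analogue of an LC-MS map: centroided MS1
#' spectra arranged along the applied-potential axis instead of retention
#' time. Internally it is a channel-by-level intensity matrix: `levels` is
#' the staircase potential grid (mV), and each channel is one m/z trace
#' (agglomerated across levels within a ppm tolerance).
NULL

new_mass_voltammogram <- function(levels, channel_mz, intensity, provenance = list()) {
  intensity <- matrix(intensity, nrow = length(channel_mz),
                      ncol = length(levels))
  stopifnot(!is.unsorted(levels, strictly = TRUE),
            all(intensity >= 0))
  if (length(channel_mz) > 1L && any(diff(channel_mz) <= 0))
    stop("channel m/z must be strictly ascending")
  structure(list(levels = levels, channel_mz = channel_mz,
                 intensity = intensity, provenance = provenance),
            class = "mass_voltammogram")
}

#' @export
print.mass_voltammogram <- function(x, ...) {
  cat("<mass_voltammogram> ", length(x$channel_mz), " channels x ",
      length(x$levels), " potential levels [",
      x$levels[1], ", ", x$levels[length(x$levels)], "] mV\n", sep = "")
  invisible(x)
}

# truncated-window centered moving average (edges use the points available)
.movavg <- function(x, window = 5L) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Centroid a profile-mode spectrum
#'
#' Local maxima above `noise_floor` become centroids; the centroid m/z is
#' the intensity-weighted mean over the peak's contiguous profile points
#' (between the flanking local minima) and the reported intensity is the
#' apex intensity.
#'
#' @param s an `ms_spectrum` in profile mode.
#' @param noise_floor minimum apex intensity for a centroid.
#' @return an `ms_spectrum` in centroid mode (possibly empty).
#' @export
centroid_spectrum <- function(s, noise_floor = 0) {
  stopifnot(inherits(s, "ms_spectrum"))
  if (s$mode == "centroid") return(s)
  y <- s$intensity; x <- s$mz; n <- length(y)
  out_mz <- numeric(0); out_int <- numeric(0)
  if (n) {
    for (i in seq_len(n)) {
      left_lower  <- i == 1L || y[i - 1L] < y[i]
      right_lower <- i == n  || y[i + 1L] < y[i]
      if (!(left_lower && right_lower) || y[i] <= noise_floor) next
      l <- i; while (l > 1L && y[l - 1L] < y[l]) l <- l - 1L
      r <- i; while (r < n && y[r + 1L] < y[r]) r <- r + 1L
      w <- y[l:r]
      out_mz <- c(out_mz, sum(x[l:r] * w) / sum(w))
      out_int <- c(out_int, y[i])
    }
  }
  new_spectrum(s$scan_time, out_mz, out_int, ms_level = s$ms_level,
               precursor_mz = s$precursor_mz,
               collision_energy = s$collision_energy, mode = "centroid")
}

# greedy ascending agglomeration of peaks into ppm clusters; returns cluster
# ids. A peak joins the open cluster while it is within tol of the running
# intensity-weighted mean m/z (i.e. of the nearest existing channel centre).
.ppm_cluster <- function(mz, intensity, tol_ppm) {
  n <- length(mz)
  if (!n) return(integer(0))
  o <- order(mz)
  id <- integer(n)
  cur <- 1L
  ref_mz <- mz[o[1]]; ref_w <- max(intensity[o[1]], .Machine$double.eps)
  id[o[1]] <- 1L
  for (k in seq_len(n)[-1]) {
    i <- o[k]
    if (.ppm_diff(mz[i], ref_mz) <= tol_ppm) {
      w <- max(intensity[i], .Machine$double.eps)
      ref_mz <- (ref_mz * ref_w + mz[i] * w) / (ref_w + w)
      ref_w <- ref_w + w
    } else {
      cur <- cur + 1L
      ref_mz <- mz[i]; ref_w <- max(intensity[i], .Machine$double.eps)
    }
    id[i] <- cur
  }
  id
}

#' Build a mass voltammogram from a raw run and a ramp
#'
#' Each MS1 spectrum is assigned to its staircase potential level via
#' [potential_at_time()]; profile spectra are centroided first. Spectra
#' sharing a level are combined by arithmetic mean (so level occupancy does
#' not bias intensity): centroids merged within `mz_tol_ppm` and the merged
#' intensity divided by the number of scans at the level. Per-level peaks
#' are then agglomerated across levels into channels within `mz_tol_ppm`
#' (channel m/z = intensity-weighted mean); levels without a measurement for
#' a channel hold zero.
#'
#' @param run a `raw_run` with at least one MS1 spectrum.
#' @param r a `potential_ramp`.
#' @param mz_tol_ppm m/z tolerance for merging centroids, in ppm.
#' @param min_intensity channels whose maximum intensity is below this are
#'   dropped (0 keeps everything, conserving total intensity).
#' @param noise_floor centroiding noise floor for profile spectra.
#' @return a `mass_voltammogram`.
#' @export
build_voltammogram <- function(run, r, mz_tol_ppm = 5, min_intensity = 0,
                               noise_floor = 0) {
  stopifnot(inherits(run, "raw_run"), inherits(r, "potential_ramp"))
  ms1 <- Filter(function(s) s$ms_level == 1L, run$spectra)
  if (!length(ms1)) stop("run contains no MS1 spectra")
  ms1 <- lapply(ms1, centroid_spectrum, noise_floor = noise_floor)

  grid <- step_grid(r)
  times <- vapply(ms1, `[[`, numeric(1), "scan_time")
  lev_idx <- round((potential_at_time(r, times) - r$e_start) / r$step_size) + 1L

  # within-level combination: merge within tol, mean over scans at the level
  pool_mz <- numeric(0); pool_int <- numeric(0); pool_lev <- integer(0)
  for (li in sort(unique(lev_idx))) {
    scans <- ms1[lev_idx == li]
    nsc <- length(scans)
    mzv <- unlist(lapply(scans, `[[`, "mz"))
    inv <- unlist(lapply(scans, `[[`, "intensity"))
    if (!length(mzv)) next
    cl <- .ppm_cluster(mzv, inv, mz_tol_ppm)
    csum <- tapply(inv, cl, sum)
    cmz <- tapply(mzv * inv, cl, sum) / pmax(tapply(inv, cl, sum),
                                             .Machine$double.eps)
    pool_mz <- c(pool_mz, as.numeric(cmz))
    pool_int <- c(pool_int, as.numeric(csum) / nsc)
    pool_lev <- c(pool_lev, rep.int(li, length(csum)))
  }
  if (!length(pool_mz)) stop("no peaks found in any MS1 spectrum")

  # across-level agglomeration into channels
  ch <- .ppm_cluster(pool_mz, pool_int, mz_tol_ppm)
  nch <- max(ch)
  wsum <- tapply(pool_int, ch, sum)
  chan_mz <- as.numeric(tapply(pool_mz * pool_int, ch, sum) /
                          pmax(wsum, .Machine$double.eps))
  mat <- matrix(0, nrow = nch, ncol = length(grid))
  for (k in seq_along(pool_mz))
    mat[ch[k], pool_lev[k]] <- mat[ch[k], pool_lev[k]] + pool_int[k]

  o <- order(chan_mz)
  chan_mz <- chan_mz[o]; mat <- mat[o, , drop = FALSE]
  keep <- apply(mat, 1L, max) >= min_intensity
  new_mass_voltammogram(
    grid, chan_mz[keep], mat[keep, , drop = FALSE],
    provenance = list(ramp = r, mz_tol_ppm = mz_tol_ppm,
                      min_intensity = min_intensity,
                      n_ms1 = length(ms1), level_aggregation = "mean"))
}

#' Extracted ion trace of a voltammogram
#'
#' @param vg a `mass_voltammogram`.
#' @param mz query m/z.
#' @param tol_ppm matching tolerance; all channels within it are summed.
#' @return numeric intensity vector, one entry per potential level (all
#'   zeros when no channel matches).
#' @export
ion_trace <- function(vg, mz, tol_ppm = 5) {
  stopifnot(inherits(vg, "mass_voltammogram"))
  hit <- .ppm_diff(vg$channel_mz, mz) <= tol_ppm
  if (!any(hit)) return(numeric(length(vg$levels)))
  colSums(vg$intensity[hit, , drop = FALSE])
}

#' Formation potential of an ion trace
#'
#' The potential at which a transformation product first appears: the lowest
#' level where the smoothed trace (centered moving average) reaches
#' `onset_fraction` of its maximum and stays there for `sustain_steps`
#' consecutive levels. A trace already at or above the threshold at the
#' start of the ramp (an educt, or a constant background) has no formation
#' potential and yields `NA`.
#'
#' @param trace intensity per level (same length as `levels`).
#' @param levels potential grid in mV.
#' @param onset_fraction fraction of the smoothed-trace maximum defining the
#'   onset (default 0.10).
#' @param sustain_steps number of consecutive levels the trace must hold the
#'   threshold (default 3), guarding against noise spikes.
#' @param ma_window moving-average window in levels (default 5).
#' @return formation potential in mV, or `NA_real_`.
#' @export
formation_potential <- function(trace, levels, onset_fraction = 0.10,
                                sustain_steps = 3L, ma_window = 5L) {
  stopifnot(length(trace) == length(levels))
  sm <- .movavg(trace, ma_window)
  top <- max(sm)
  if (top <= 0) return(NA_real_)
  thr <- onset_fraction * top
  if (sm[1] >= thr) return(NA_real_)  # present from the start: not "formed"
  ok <- sm >= thr
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  i <- which(runs$values & runs$lengths >= sustain_steps)
  if (!length(i)) return(NA_real_)
  levels[starts[i[1]]]
}

#' Annotate the most intense voltammogram signals
#'
#' @param vg a `mass_voltammogram`.
#' @param top_n number of channels to report (intensity-descending).
#' @param onset_fraction,sustain_steps,ma_window passed to
#'   [formation_potential()].
#' @return data.frame with columns `mz`, `max_intensity`,
#'   `formation_potential_mv` (NA for educts/backgrounds).
#' @export
annotate_signals <- function(vg, top_n = 10L, onset_fraction = 0.10,
                             sustain_steps = 3L, ma_window = 5L) {
  stopifnot(inherits(vg, "mass_voltammogram"))
  maxes <- apply(vg$intensity, 1L, max)
  o <- order(maxes, decreasing = TRUE)
  o <- o[seq_len(min(top_n, length(o)))]
  fp <- vapply(o, function(i)
    formation_potential(vg$intensity[i, ], vg$levels, onset_fraction,
                        sustain_steps, ma_window), numeric(1))
  data.frame(mz = vg$channel_mz[o], max_intensity = maxes[o],
             formation_potential_mv = fp)
}

#' Export a voltammogram as a table
#'
#' One row per channel; first column the channel m/z (4 decimals), one
#' column per potential level, header row carrying the potentials in mV.
#'
#' @param vg a `mass_voltammogram`.
#' @param path output path.
#' @param format `"csv"` (RFC 4180, "." decimal separator) or `"xlsx"`
#'   (requires the optional 'writexl' package).
#' @return `path`, invisibly.
#' @export
export_table <- function(vg, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  df <- voltammogram_table(vg)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    if (!requireNamespace("writexl", quietly = TRUE))
      stop("xlsx export requires the 'writexl' package; install it or use format = \"csv\"")
    writexl::write_xlsx(df, path)
  }
  invisible(path)
}

#' @rdname export_table
#' @return for `voltammogram_table`, the export data.frame itself.
#' @export
voltammogram_table <- function(vg) {
  stopifnot(inherits(vg, "mass_voltammogram"))
  df <- data.frame(mz = round_half_up(vg$channel_mz, 4))
  mat <- as.data.frame(vg$intensity)
  names(mat) <- as.character(vg$levels)
  cbind(df, mat)
}

#' Plot a mass voltammogram
#'
#' Static waterfall projection: each channel's trace drawn against potential,
#' vertically offset by its m/z, intensity scaled to the m/z axis.
#'
#' @param x a `mass_voltammogram`.
#' @param rel_height trace amplitude as a fraction of the m/z axis span.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot.mass_voltammogram <- function(x, rel_height = 0.08, ...) {
  span <- diff(range(x$channel_mz))
  if (span == 0) span <- 1
  top <- max(x$intensity)
  if (top == 0) top <- 1
  dfs <- lapply(seq_along(x$channel_mz), function(i) {
    data.frame(potential = x$levels,
               y = x$channel_mz[i] + x$intensity[i, ] / top * span * rel_height,
               channel = sprintf("%.4f", x$channel_mz[i]))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = potential, y = y, group = channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Potential / mV", y = "m/z",
                  title = "Mass voltammogram") +
    ggplot2::theme_minimal()
}

#' @rdname plot.mass_voltammogram
#' @param vg a `mass_voltammogram`.
#' @param path output file path.
#' @param format `"png"` or `"svg"`.
#' @param width,height,dpi figure geometry passed to [ggplot2::ggsave()].
#' @export
export_plot <- function(vg, path, format = c("png", "svg"),
                        width = 7, height = 5, dpi = 150) {
  format <- match.arg(format)
  p <- plot(vg)
  if (format == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    grDevices::png(path, width = width * dpi, height = height * dpi,
                   res = dpi)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
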