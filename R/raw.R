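#' @name raw-model
#' @title In-memory raw-run model
#'
#' @description
#' A `ms_spectrum` is one scan: acquisition time (seconds), MS level, an
#' m/z-sorted peak list, and for MS2 scans the precursor m/z and collision
#' energy. A `raw_run` is a time-ordered list of spectra plus minimal
#' metadata (source path, polarity). Potential, not retention time, is the
#' separating axis in EC-MS, so no chromatographic structures are kept.
NULL

#' Construct a spectrum
#'
#' @param scan_time acquisition time in seconds.
#' @param mz,intensity parallel numeric vectors; `mz` strictly ascending,
#'   positive; intensities non-negative. Unsorted input is sorted.
#' @param ms_level 1 or 2.
#' @param precursor_mz precursor m/z, required when `ms_level == 2`.
#' @param collision_energy collision energy in eV, optional.
#' @param mode `"centroid"` or `"profile"`.
#' @return an `ms_spectrum`.
#' @export
new_spectrum <- function(scan_time, mz, intensity, ms_level = 1L,
                         precursor_mz = NA_real_,
                         collision_energy = NA_real_,
                         mode = c("centroid", "profile")) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), scan_time >= 0,
            ms_level %in% c(1L, 2L))
  if (ms_level == 2L && is.na(precursor_mz))
    stop("MS2 spectrum requires a precursor m/z")
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(mz <= 0)) stop("non-positive m/z")
    if (any(diff(mz) <= 0)) stop("duplicate m/z in peak list")
    if (any(intensity < 0)) stop("negative intensity")
  }
  structure(list(scan_time = as.numeric(scan_time),
                 ms_level = as.integer(ms_level),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor_mz = as.numeric(precursor_mz),
                 collision_energy = as.numeric(collision_energy),
                 mode = mode),
            class = "ms_spectrum")
}

#' Construct a raw run from spectra
#'
#' @param spectra list of `ms_spectrum`, sorted by `scan_time` (re-sorted if
#'   not; ties keep input order).
#' @param metadata named list, e.g. `source`, `polarity`.
#' @return a `raw_run`.
#' @export
new_raw_run <- function(spectra, metadata = list()) {
  stopifnot(all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  times <- vapply(spectra, `[[`, numeric(1), "scan_time")
  spectra <- spectra[order(times)]
  structure(list(spectra = spectra, metadata = metadata), class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  lv <- vapply(x$spectra, `[[`, integer(1), "ms_level")
  cat("<raw_run> ", length(x$spectra), " spectra (",
      sum(lv == 1L), " MS1, ", sum(lv == 2L), " MS2)",
      if (!is.null(x$metadata$source)) paste0(" from ", x$metadata$source),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat("<ms_spectrum> MS", x$ms_level, " t=", x$scan_time, "s, ",
      length(x$mz), " peaks (", x$mode, ")",
      if (!is.na(x$precursor_mz)) paste0(", precursor ", x$precursor_mz),
      "\n", sep = "")
  invisible(x)
}

#' Read an mzML file into a raw run
#'
#' Scan times are normalised to seconds. Peak lists, MS level, precursor m/z,
#' collision energy and the centroid/profile flag are preserved.
#'
#' @param path path to an mzML 1.1 file (indexed or plain).
#' @return a `raw_run`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (nrow(hdr) == 0L) {
    warning("mzML file contains no spectra: ", path)
    return(new_raw_run(list(), metadata = list(source = path)))
  }
  if (any(is.na(hdr$retentionTime))) stop("mzML scan(s) without scan time")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  spectra <- lapply(seq_len(nrow(hdr)), function(i) {
    h <- hdr[i, ]
    cent <- isTRUE(h$centroided)
    new_spectrum(
      scan_time = h$retentionTime,  # mzR reports seconds
      mz = pk[[i]][, 1], intensity = pk[[i]][, 2],
      ms_level = h$msLevel,
      precursor_mz = if (h$msLevel >= 2L) h$precursorMZ else NA_real_,
      collision_energy = if (h$msLevel >= 2L) h$collisionEnergy else NA_real_,
      mode = if (cent) "centroid" else "profile")
  })
  pol <- if ("polarity" %in% names(hdr) && all(hdr$polarity == 1)) "positive"
         else if ("polarity" %in% names(hdr) && all(hdr$polarity == 0)) "negative"
         else "mixed"
  new_raw_run(spectra, metadata = list(source = path, polarity = pol))
}

#' Write a raw run to mzML
#'
#' Produces standards-conforming mzML readable back by [read_mzml()] with
#' m/z preserved to better than 1e-6 relative.
#'
#' @param run a `raw_run`.
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "raw_run"))
  n <- length(run$spectra)
  if (n == 0L) stop("cannot write an empty run to mzML")
  g <- function(fld, how) vapply(run$spectra, `[[`, how, fld)
  lv <- g("ms_level", integer(1))
  prec <- g("precursor_mz", numeric(1))
  ce <- g("collision_energy", numeric(1))
  npk <- vapply(run$spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(run$spectra, function(s) sum(s$intensity), numeric(1))
  bpi <- vapply(run$spectra, function(s)
    if (length(s$intensity)) max(s$intensity) else 0, numeric(1))
  bpmz <- vapply(run$spectra, function(s)
    if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1))
  pol <- if (identical(run$metadata$polarity, "negative")) 0L else 1L
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = pol, peaksCount = npk, totIonCurrent = tic,
    retentionTime = g("scan_time", numeric(1)),
    basePeakMZ = bpmz, basePeakIntensity = bpi,
    collisionEnergy = ce, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = ifelse(is.na(prec), 0, prec),
    precursorCharge = ifelse(lv >= 2L, 1L, 0L),
    precursorIntensity = ifelse(lv >= 2L, 1, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = g("mode", character(1)) == "centroid",
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is.na(prec), NA_real_, prec),
    isolationWindowLowerOffset = ifelse(lv >= 2L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lv >= 2L, 1, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  pks <- lapply(run$spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
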