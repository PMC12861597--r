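#' Subtract a reference run's voltammogram from a target voltammogram
#'
#' Feature-list-style blank subtraction on voltammogram channels: a target
#' channel is removed iff the reference voltammogram (acquired under the
#' same ramp, e.g. an interfering compound oxidised alone) holds a channel
#' within `mz_tol_ppm` whose maximum intensity is at least `1/fold` of the
#' target channel's maximum. Surviving channels pass through unchanged.
#' Structurally similar co-oxidised compounds can produce shared
#' transformation-product m/z; such shared channels are removed and a
#' warning is emitted.
#'
#' @param target,reference `mass_voltammogram`s built on the same potential
#'   grid (otherwise an error).
#' @param mz_tol_ppm channel matching tolerance in ppm.
#' @param fold intensity fold-change criterion (default 3, the common
#'   blank-subtraction heuristic): reference max >= target max / fold
#'   removes the channel.
#' @return the subtracted `mass_voltammogram`; the removal log (data.frame
#'   of `target_mz`, `reference_mz`, `target_max`, `reference_max`) is
#'   attached as attribute `"removed"`.
#' @export
subtract_reference <- function(target, reference, mz_tol_ppm = 5, fold = 3) {
  stopifnot(inherits(target, "mass_voltammogram"),
            inherits(reference, "mass_voltammogram"), fold >= 1)
  if (!isTRUE(all.equal(target$levels, reference$levels)))
    stop("target and reference voltammograms use different potential grids")
  t_max <- apply(target$intensity, 1L, max)
  r_max <- if (length(reference$channel_mz))
    apply(reference$intensity, 1L, max) else numeric(0)

  removed <- data.frame(target_mz = numeric(0), reference_mz = numeric(0),
                        target_max = numeric(0), reference_max = numeric(0))
  drop <- logical(length(target$channel_mz))
  for (i in seq_along(target$channel_mz)) {
    hit <- which(.ppm_diff(reference$channel_mz, target$channel_mz[i]) <= mz_tol_ppm)
    hit <- hit[r_max[hit] >= t_max[i] / fold]
    if (length(hit)) {
      drop[i] <- TRUE
      j <- hit[which.max(r_max[hit])]
      removed[nrow(removed) + 1L, ] <-
        list(target$channel_mz[i], reference$channel_mz[j], t_max[i], r_max[j])
    }
  }
  # a removed channel that rises during the ramp looks like a transformation
  # product shared with the reference compound (co-oxidation artefact)
  shared <- vapply(which(drop), function(i)
    !is.na(formation_potential(target$intensity[i, ], target$levels)),
    logical(1))
  if (any(shared))
    warning(sum(shared), " removed channel(s) have a formation potential and ",
            "may be transformation products shared with the reference compound")
  out <- new_mass_voltammogram(
    target$levels, target$channel_mz[!drop],
    target$intensity[!drop, , drop = FALSE],
    provenance = c(target$provenance,
                   list(subtraction = list(fold = fold, mz_tol_ppm = mz_tol_ppm,
                                           n_removed = sum(drop)))))
  attr(out, "removed") <- removed
  out
}

#' Group isotope satellites in a centroid spectrum
#'
#' Peaks are chained into an isotopologue cluster when spaced by the
#' 13C-12C mass gap divided by the charge (1.0033548378/z) within tolerance
#' and each satellite is less intense than its predecessor (which prevents
#' chaining unrelated peaks). When two chains compete for a satellite, the
#' higher-intensity predecessor wins. The lowest-m/z member of a cluster is
#' flagged monoisotopic.
#'
#' @param s a centroid `ms_spectrum`.
#' @param max_charge highest charge state to consider (tried from high to
#'   low so multiply charged patterns are not mistaken for singly charged).
#' @param mz_tol_ppm spacing tolerance in ppm of the satellite m/z.
#' @return list of clusters, each `list(indices, charge, monoisotopic)`
#'   where `monoisotopic` is the index of the lowest-m/z member. Singleton
#'   clusters have charge `NA`.
#' @export
group_isotopes <- function(s, max_charge = 1L, mz_tol_ppm = 10) {
  stopifnot(inherits(s, "ms_spectrum"), s$mode == "centroid", max_charge >= 1L)
  n <- length(s$mz)
  cluster_of <- rep(NA_integer_, n)
  charge_of <- rep(NA_integer_, n)
  nclust <- 0L
  # seed clusters from unassigned peaks in descending intensity so that
  # competing chains resolve toward the stronger predecessor
  for (z in seq(max_charge, 1L)) {
    gap <- .neutron_gap / z
    for (i in order(s$intensity, decreasing = TRUE)) {
      if (!is.na(cluster_of[i])) next
      chain <- i
      prev <- i
      repeat {
        target <- s$mz[prev] + gap
        cand <- which(is.na(cluster_of) &
                        abs(s$mz - target) <= mz_tol_ppm * 1e-6 * target &
                        s$intensity < s$intensity[prev])
        cand <- setdiff(cand, chain)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(s$mz[cand] - target))]
        chain <- c(chain, nxt)
        prev <- nxt
      }
      if (length(chain) > 1L) {  # singletons stay free for lower charges
        nclust <- nclust + 1L
        cluster_of[chain] <- nclust
        charge_of[chain] <- z
      }
    }
  }
  for (i in which(is.na(cluster_of))) {  # leftover peaks become singletons
    nclust <- nclust + 1L
    cluster_of[i] <- nclust
  }
  lapply(seq_len(nclust), function(k) {
    idx <- which(cluster_of == k)
    idx <- idx[order(s$mz[idx])]
    list(indices = idx,
         charge = if (length(idx) > 1L) charge_of[idx[1]] else NA_integer_,
         monoisotopic = idx[1])
  })
}

#' Collapse isotope-satellite channels of a voltammogram
#'
#' Treats the channel list (channel m/z, maximum intensity) as a pseudo
#' centroid spectrum, groups isotopologues with [group_isotopes()] and sums
#' each satellite's trace into its monoisotopic channel, level by level.
#' Total intensity is conserved exactly.
#'
#' @param vg a `mass_voltammogram`.
#' @param max_charge,mz_tol_ppm passed to [group_isotopes()].
#' @return a `mass_voltammogram` with satellites merged away.
#' @export
collapse_isotopes <- function(vg, max_charge = 1L, mz_tol_ppm = 10) {
  stopifnot(inherits(vg, "mass_voltammogram"))
  if (length(vg$channel_mz) < 2L) return(vg)
  pseudo <- new_spectrum(0, vg$channel_mz, apply(vg$intensity, 1L, max))
  clusters <- group_isotopes(pseudo, max_charge = max_charge,
                             mz_tol_ppm = mz_tol_ppm)
  keep_mz <- numeric(0)
  rows <- list()
  for (cl in clusters) {
    keep_mz <- c(keep_mz, vg$channel_mz[cl$monoisotopic])
    rows[[length(rows) + 1L]] <-
      colSums(vg$intensity[cl$indices, , drop = FALSE])
  }
  o <- order(keep_mz)
  new_mass_voltammogram(vg$levels, keep_mz[o],
                        do.call(rbind, rows)[o, , drop = FALSE],
                        provenance = c(vg$provenance,
                                       list(isotopes_collapsed = TRUE)))
}
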