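#' @name tp-annotation
#' @title Transformation-product and MS/MS annotation
#'
#' @description
#' After subtraction, the surviving voltammogram channels are classified
#' into educts (consumed with rising potential), transformation products
#' (formed at an onset potential) and background. Product m/z are annotated
#' against the parent ion formula by exact-mass difference matching, and
#' their DDA MS/MS spectra by chains of neutral losses.
NULL

#' Classify voltammogram channels as educt, product or background
#'
#' An educt's smoothed trace starts at its maximum and decays to half or
#' less by the end of the ramp. A product starts near zero (below
#' `onset_fraction` of its maximum) and has a defined formation potential.
#' Everything else (constant or erratic traces) is background.
#'
#' @param vg a `mass_voltammogram` with at least 3 potential levels.
#' @param onset_fraction,sustain_steps,ma_window onset parameters, see
#'   [formation_potential()].
#' @param educt_end_ratio maximum end/start ratio of the smoothed trace for
#'   an educt call (default 0.5).
#' @return data.frame with `mz`, `label` (`"educt"|"product"|"background"`),
#'   `max_intensity`, `formation_potential_mv`.
#' @export
classify_channels <- function(vg, onset_fraction = 0.10, sustain_steps = 3L,
                              ma_window = 5L, educt_end_ratio = 0.5) {
  stopifnot(inherits(vg, "mass_voltammogram"), length(vg$levels) >= 3L)
  n <- length(vg$channel_mz)
  label <- character(n); fp <- rep(NA_real_, n)
  maxes <- apply(vg$intensity, 1L, max)
  for (i in seq_len(n)) {
    tr <- vg$intensity[i, ]
    sm <- .movavg(tr, ma_window)
    top <- max(sm)
    fp[i] <- formation_potential(tr, vg$levels, onset_fraction,
                                 sustain_steps, ma_window)
    if (top > 0 && sm[1] >= 0.8 * top &&
        sm[length(sm)] <= educt_end_ratio * sm[1]) {
      label[i] <- "educt"
    } else if (!is.na(fp[i]) && sm[1] <= onset_fraction * top) {
      label[i] <- "product"
    } else {
      label[i] <- "background"
    }
  }
  data.frame(mz = vg$channel_mz, label = label, max_intensity = maxes,
             formation_potential_mv = fp)
}

#' Annotate a transformation product against its parent formula
#'
#' The observed mass difference `tp_mz - m/z(parent)` is matched against a
#' transformation library; the best match (smallest absolute error, ties to
#' fewer atoms changed) determines the product's ion formula, from which
#' the calculated m/z and ppm deviation are derived.
#'
#' @param parent parent ion `chem_formula` (charged) or formula string.
#' @param tp_mz recorded product m/z.
#' @param library transformation library; default
#'   [default_transformations()].
#' @param tol_da mass-difference matching tolerance in Da.
#' @param formation_potential_mv optional formation potential to carry
#'   through to the record.
#' @return a `tp_record`: list with `recorded_mz`, `transformation`,
#'   `ion_formula` (`chem_formula` or `NULL` when unannotated),
#'   `calculated_mz`, `ppm`, `formation_potential_mv`.
#' @export
#' @examples
#' annotate_tp("C20H28N3O3+", 374.2078)  # hydroxylation, calc 374.2074
annotate_tp <- function(parent, tp_mz, library = default_transformations(),
                        tol_da = 0.001, formation_potential_mv = NA_real_) {
  if (is.character(parent)) parent <- parse_formula(parent)
  stopifnot(inherits(parent, "chem_formula"))
  if (parent$charge == 0L) stop("parent formula must be charged")
  delta <- tp_mz - monoisotopic_mz(parent)
  cands <- match_mass_difference(delta, library, tol_da)
  # discard candidates whose removal is element-illegal for this parent
  cands <- Filter(function(d) !inherits(try(apply_delta(parent, d),
                                            silent = TRUE), "try-error"),
                  cands)
  if (!length(cands)) {
    rec <- list(recorded_mz = tp_mz, transformation = NA_character_,
                ion_formula = NULL, calculated_mz = NA_real_, ppm = NA_real_,
                formation_potential_mv = formation_potential_mv)
  } else {
    best <- cands[[1]]
    f <- apply_delta(parent, best)
    calc <- round_half_up(monoisotopic_mz(f), 4)
    rec <- list(recorded_mz = tp_mz, transformation = best$name,
                ion_formula = f, calculated_mz = calc,
                ppm = ppm_error(tp_mz, monoisotopic_mz(f)),
                formation_potential_mv = formation_potential_mv)
  }
  structure(rec, class = "tp_record")
}

#' @export
print.tp_record <- function(x, ...) {
  cat("<tp_record> m/z ", sprintf("%.4f", x$recorded_mz), ": ",
      if (is.null(x$ion_formula)) "unannotated" else
        paste0(format_formula(x$ion_formula), " (", x$transformation,
               "), calc ", sprintf("%.4f", x$calculated_mz),
               ", ", sprintf("%+.1f", x$ppm), " ppm"),
      "\n", sep = "")
  invisible(x)
}

#' Merge MS/MS spectra of the same precursor
#'
#' Sums DDA spectra acquired at different collision energies (typically 15
#' and 30 eV) into one composite spectrum: centroids within `mz_tol_ppm`
#' are merged, intensities summed, merged m/z the intensity-weighted mean.
#'
#' @param spectra list of MS2 `ms_spectrum`s sharing a precursor (checked
#'   within `precursor_tol_ppm`; mixed precursors are an error).
#' @param mz_tol_ppm fragment merging tolerance.
#' @param precursor_tol_ppm precursor consistency tolerance.
#' @return a merged centroid `ms_spectrum` (collision energy `NA`).
#' @export
merge_msms <- function(spectra, mz_tol_ppm = 5, precursor_tol_ppm = 20) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "ms_spectrum")))
  if (any(vapply(spectra, `[[`, integer(1), "ms_level") != 2L))
    stop("merge_msms expects MS2 spectra")
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  if (any(.ppm_diff(prec, prec[1]) > precursor_tol_ppm))
    stop("spectra have mixed precursor m/z")
  mzv <- unlist(lapply(spectra, `[[`, "mz"))
  inv <- unlist(lapply(spectra, `[[`, "intensity"))
  if (!length(mzv))
    return(new_spectrum(spectra[[1]]$scan_time, numeric(0), numeric(0),
                        ms_level = 2L, precursor_mz = prec[1]))
  cl <- .ppm_cluster(mzv, inv, mz_tol_ppm)
  ssum <- as.numeric(tapply(inv, cl, sum))
  smz <- as.numeric(tapply(mzv * inv, cl, sum)) / pmax(ssum, .Machine$double.eps)
  new_spectrum(spectra[[1]]$scan_time, smz, ssum, ms_level = 2L,
               precursor_mz = prec[1])
}

#' Default neutral-loss library for SCRA-type fragmentations
#'
#' Water (18.0106), methyl formate C2H4O2 (60.0211), pentene C5H8
#' (68.0626), C5H8O (84.0575), carbon monoxide (27.9949) and methanol
#' (32.0262) — the losses dominating collision-induced dissociation of
#' ester/indazole-carboxamide cannabinoids, plus two generic small losses.
#'
#' @return named list of neutral `chem_formula` objects.
#' @export
default_neutral_losses <- function() {
  list(H2O = parse_formula("H2O"),
       C2H4O2 = parse_formula("C2H4O2"),
       C5H8 = parse_formula("C5H8"),
       C5H8O = parse_formula("C5H8O"),
       CO = parse_formula("CO"),
       CH3OH = parse_formula("CH4O"))
}

# enumerate all element-legal fragments reachable from `precursor` by up to
# max_chain losses (unordered multisets; chains differing only in order give
# the same formula and are deduplicated). Depth 0 is the precursor itself.
.enumerate_fragments <- function(precursor, losses, max_chain) {
  out <- list(list(formula = precursor, chain = character(0)))
  if (!length(losses)) return(out)
  seen <- format_formula(precursor)
  frontier <- out
  loss_names <- names(losses)
  for (depth in seq_len(max_chain)) {
    nxt <- list()
    for (node in frontier) {
      last <- if (length(node$chain))
        match(node$chain[length(node$chain)], loss_names) else 1L
      # only extend with losses at or after the last one: enumerates
      # unordered multisets exactly once
      for (j in seq(last, length(losses))) {
        f <- try(formula_subtract(node$formula, losses[[j]]), silent = TRUE)
        if (inherits(f, "try-error")) next
        key <- format_formula(f)
        if (key %in% seen) next
        seen <- c(seen, key)
        nxt[[length(nxt) + 1L]] <-
          list(formula = f, chain = c(node$chain, loss_names[j]))
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
    if (!length(frontier)) break
  }
  out
}

#' Annotate MS/MS fragments by neutral-loss chains
#'
#' Candidate fragments are the precursor minus every element-legal multiset
#' of at most `max_chain` losses from the library. Each observed peak is
#' assigned the candidate with the smallest absolute ppm deviation within
#' `tol_ppm`; unmatched peaks are reported unannotated. The returned table
#' also carries a `water_loss_present` attribute — whether any peak matched
#' the plain water-loss fragment — a diagnostic separating free hydroxy
#' groups (water loss expected) from quinoid products (no water loss).
#'
#' @param precursor precursor ion `chem_formula` (charged) or string.
#' @param msms a centroid MS2 `ms_spectrum` (e.g. from [merge_msms()]).
#' @param losses named list of neutral `chem_formula`s; default
#'   [default_neutral_losses()].
#' @param max_chain maximum number of sequential losses (default 2).
#' @param tol_ppm MS2 matching tolerance in ppm (default 5).
#' @return data.frame with `observed_mz`, `fragment_formula`,
#'   `theoretical_mz` (4 decimals), `loss_chain` (`" + "`-joined, `""` for
#'   the precursor self-match), `ppm`; NA fields for unmatched peaks.
#' @export
annotate_fragments <- function(precursor, msms,
                               losses = default_neutral_losses(),
                               max_chain = 2L, tol_ppm = 5) {
  if (is.character(precursor)) precursor <- parse_formula(precursor)
  stopifnot(inherits(precursor, "chem_formula"), max_chain >= 1L,
            inherits(msms, "ms_spectrum"), msms$mode == "centroid")
  if (precursor$charge == 0L) stop("precursor formula must be charged")
  cands <- .enumerate_fragments(precursor, losses, max_chain)
  cand_mz <- vapply(cands, function(c) monoisotopic_mz(c$formula), numeric(1))

  rows <- lapply(seq_along(msms$mz), function(i) {
    obs <- msms$mz[i]
    ppms <- vapply(cand_mz, function(th) ppm_error(obs, th), numeric(1))
    j <- which.min(abs(ppms))
    if (length(j) && abs(ppms[j]) <= tol_ppm) {
      data.frame(observed_mz = obs,
                 fragment_formula = format_formula(cands[[j]]$formula),
                 theoretical_mz = round_half_up(cand_mz[j], 4),
                 loss_chain = paste(cands[[j]]$chain, collapse = " + "),
                 ppm = ppms[j])
    } else {
      data.frame(observed_mz = obs, fragment_formula = NA_character_,
                 theoretical_mz = NA_real_, loss_chain = NA_character_,
                 ppm = NA_real_)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(observed_mz = numeric(0), fragment_formula = character(0),
               theoretical_mz = numeric(0), loss_chain = character(0),
               ppm = numeric(0))
  water <- try(formula_subtract(precursor, parse_formula("H2O")),
               silent = TRUE)
  attr(out, "water_loss_present") <-
    !inherits(water, "try-error") &&
    any(!is.na(out$fragment_formula) &
          out$fragment_formula == format_formula(water))
  out
}

#' Tabular transformation-product report
#'
#' One row per compound (parent first): recorded m/z (4 decimals), ion
#' formula, calculated m/z (4 decimals), ppm deviation (1 decimal) and
#' formation potential. Unannotated records keep empty formula/calculated
#' fields.
#'
#' @param parent parent ion `chem_formula` or string.
#' @param parent_recorded_mz the parent's recorded m/z.
#' @param tp_records list of `tp_record`s, e.g. from [annotate_tp()].
#' @param parent_label label for the parent row (default `"parent"`).
#' @param path optional CSV output path.
#' @return the report data.frame (written to `path` when given).
#' @export
tp_report <- function(parent, parent_recorded_mz, tp_records = list(),
                      parent_label = "parent", path = NULL) {
  if (is.character(parent)) parent <- parse_formula(parent)
  rows <- list(data.frame(
    compound = parent_label,
    recorded_mz = round_half_up(parent_recorded_mz, 4),
    ion_formula = format_formula(parent),
    calculated_mz = round_half_up(monoisotopic_mz(parent), 4),
    ppm = ppm_error(parent_recorded_mz, monoisotopic_mz(parent)),
    formation_potential_mv = NA_real_,
    transformation = NA_character_))
  for (rec in tp_records) {
    rows[[length(rows) + 1L]] <- data.frame(
      compound = paste0("TP", round(rec$recorded_mz)),
      recorded_mz = round_half_up(rec$recorded_mz, 4),
      ion_formula = if (is.null(rec$ion_formula)) "" else
        format_formula(rec$ion_formula),
      calculated_mz = rec$calculated_mz,
      ppm = rec$ppm,
      formation_potential_mv = rec$formation_potential_mv,
      transformation = rec$transformation)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
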