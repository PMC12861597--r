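#' @name synthetic
#' @title Seeded synthetic EC-MS run generator
#'
#' @description
#' Generates raw runs with known ground truth so the whole pipeline —
#' voltammogram construction, reference subtraction, classification,
#' annotation — is testable without instrument data. Educt channels decay
#' and product channels form sigmoidally along the potential axis
#' (logistic response, whose 10%-crossing is available in closed form for
#' onset-recovery checks); each species carries a crude M+1 isotope
#' satellite (1.1% per carbon) and optional additive Gaussian baseline
#' noise.
NULL

#' Specify one synthetic species
#'
#' @param label species name used in the ground-truth sidecar.
#' @param ion_formula ion formula string or `chem_formula`; mutually
#'   exclusive with `mz`.
#' @param mz explicit channel m/z (for species whose formula is not part of
#'   the truth, e.g. an interferent).
#' @param profile `"educt"` (logistic decay) or `"product"` (logistic
#'   rise).
#' @param midpoint_mv logistic midpoint potential in mV.
#' @param width_mv logistic width in mV (> 0); the 10% crossing of a
#'   product sits at `midpoint_mv - width_mv * log(9)`.
#' @param max_intensity plateau intensity (> 0, arbitrary counts).
#' @param n_carbons carbon count used for the M+1 satellite (0.011 per
#'   carbon relative abundance); defaults to the formula's carbon count or
#'   0 when only `mz` is given.
#' @return a `species_spec`.
#' @export
species_spec <- function(label, ion_formula = NULL, mz = NULL,
                         profile = c("educt", "product"),
                         midpoint_mv, width_mv, max_intensity,
                         n_carbons = NULL) {
  profile <- match.arg(profile)
  stopifnot(width_mv > 0, max_intensity > 0)
  if (is.null(ion_formula) == is.null(mz))
    stop("give exactly one of ion_formula or mz")
  if (!is.null(ion_formula)) {
    if (is.character(ion_formula)) ion_formula <- parse_formula(ion_formula)
    mz <- monoisotopic_mz(ion_formula)
    if (is.null(n_carbons))
      n_carbons <- if ("C" %in% names(ion_formula$counts))
        ion_formula$counts[["C"]] else 0L
  }
  if (is.null(n_carbons)) n_carbons <- 0L
  structure(list(label = label, ion_formula = ion_formula, mz = mz,
                 profile = profile, midpoint_mv = midpoint_mv,
                 width_mv = width_mv, max_intensity = max_intensity,
                 n_carbons = as.integer(n_carbons)),
            class = "species_spec")
}

#' Ground truth for a synthetic run
#'
#' @param species list of [species_spec()]s.
#' @param ramp a [potential_ramp()].
#' @param scan_hz MS1 acquisition rate in Hz (default 2, i.e. one scan per
#'   5 mV level at 10 mV/s).
#' @param noise_sd additive Gaussian noise, as a fraction of each species'
#'   `max_intensity` (truncated at zero).
#' @param seed RNG seed; identical seeds give identical runs.
#' @return a `ground_truth`.
#' @export
ground_truth <- function(species, ramp, scan_hz = 2, noise_sd = 0,
                         seed = 1L) {
  stopifnot(all(vapply(species, inherits, logical(1), "species_spec")),
            inherits(ramp, "potential_ramp"), scan_hz > 0, noise_sd >= 0)
  structure(list(species = species, ramp = ramp, scan_hz = scan_hz,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Ground-truth table (the sidecar written next to simulated runs)
#'
#' @param gt a `ground_truth`.
#' @return data.frame of species label, m/z, satellite m/z, profile,
#'   midpoint, width, max intensity.
#' @export
truth_table <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  do.call(rbind, lapply(gt$species, function(sp) data.frame(
    label = sp$label, mz = sp$mz, satellite_mz = sp$mz + .neutron_gap,
    profile = sp$profile, midpoint_mv = sp$midpoint_mv,
    width_mv = sp$width_mv, max_intensity = sp$max_intensity,
    n_carbons = sp$n_carbons)))
}

.logistic <- function(x) 1 / (1 + exp(-x))

# species intensity response at potential E (mV)
.species_response <- function(sp, e) {
  s <- .logistic((e - sp$midpoint_mv) / sp$width_mv)
  sp$max_intensity * if (sp$profile == "educt") 1 - s else s
}

#' Analytic onset potential of a logistic product response
#'
#' Closed-form potential where a product's logistic response crosses
#' `fraction` of its plateau: `midpoint + width * log(fraction/(1 -
#' fraction))`. Used as the reference in onset-recovery tests.
#'
#' @param sp a product `species_spec`.
#' @param fraction crossing fraction (default 0.10).
#' @return potential in mV.
#' @export
analytic_onset <- function(sp, fraction = 0.10) {
  stopifnot(inherits(sp, "species_spec"), sp$profile == "product")
  sp$midpoint_mv + sp$width_mv * log(fraction / (1 - fraction))
}

# run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a raw EC-MS run from ground truth
#'
#' MS1 scans are generated at `scan_hz` over the delay plus ramp duration;
#' each species contributes its response intensity at the scan's applied
#' potential plus an M+1 satellite at +1.0033548 Th with relative abundance
#' `0.011 * n_carbons`. Gaussian noise (sd `noise_sd * max_intensity`,
#' truncated at zero) is added per peak. Deterministic under a fixed seed.
#'
#' @param gt a `ground_truth`.
#' @return a `raw_run`; `truth_table(gt)` is the matching sidecar.
#' @export
simulate_run <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  r <- gt$ramp
  times <- seq(0, r$delay_s + ramp_duration(r), by = 1 / gt$scan_hz)
  .with_seed(gt$seed, {
    spectra <- lapply(times, function(t) {
      e <- potential_at_time(r, t)
      mzv <- numeric(0); inv <- numeric(0)
      for (sp in gt$species) {
        base <- .species_response(sp, e)
        sat <- base * 0.011 * sp$n_carbons
        pair_mz <- c(sp$mz, sp$mz + .neutron_gap)
        pair_in <- c(base, sat)
        if (gt$noise_sd > 0)
          pair_in <- pmax(0, pair_in +
                            stats::rnorm(2, 0, gt$noise_sd * sp$max_intensity))
        keep <- pair_in > 0
        mzv <- c(mzv, pair_mz[keep]); inv <- c(inv, pair_in[keep])
      }
      new_spectrum(t, mzv, inv, ms_level = 1L)
    })
    new_raw_run(spectra, metadata = list(source = "simulated",
                                         polarity = "positive"))
  })
}

#' Simulate DDA MS/MS spectra of a precursor
#'
#' One MS2 spectrum per collision energy. Fragment m/z are theoretical
#' values computed from the precursor formula and the given loss chains;
#' intensities follow a simple energy model (precursor survival decays with
#' energy, fragment yield grows), sufficient to exercise spectrum merging
#' and neutral-loss annotation.
#'
#' @param precursor precursor ion `chem_formula` or string (charged).
#' @param fragments list of `list(chain = c(loss names), rel = relative
#'   intensity)`; chains must be element-legal; loss names must exist in
#'   `losses`.
#' @param collision_energies numeric eV vector (default `c(15, 30)`).
#' @param losses neutral-loss library; default [default_neutral_losses()].
#' @param base_intensity precursor intensity scale.
#' @param scan_time scan time of the first spectrum; subsequent spectra
#'   follow 0.1 s apart.
#' @return list of MS2 `ms_spectrum`s, one per energy.
#' @export
simulate_msms <- function(precursor, fragments = list(),
                          collision_energies = c(15, 30),
                          losses = default_neutral_losses(),
                          base_intensity = 1e5, scan_time = 0) {
  if (is.character(precursor)) precursor <- parse_formula(precursor)
  stopifnot(inherits(precursor, "chem_formula"))
  prec_mz <- monoisotopic_mz(precursor)
  frag_mz <- vapply(fragments, function(fr) {
    f <- precursor
    for (nm in fr$chain) {
      if (!nm %in% names(losses)) stop("unknown neutral loss '", nm, "'")
      f <- formula_subtract(f, losses[[nm]])  # errors on illegal chains
    }
    monoisotopic_mz(f)
  }, numeric(1))
  rels <- vapply(fragments, `[[`, numeric(1), "rel")
  lapply(seq_along(collision_energies), function(k) {
    e <- collision_energies[k]
    survive <- exp(-e / 20)         # precursor depletion with energy
    yield <- 1 - survive            # shared among fragments by rel
    mzv <- c(prec_mz, frag_mz)
    inv <- base_intensity * c(survive, yield * rels)
    new_spectrum(scan_time + 0.1 * (k - 1), mzv, inv, ms_level = 2L,
                 precursor_mz = prec_mz, collision_energy = e)
  })
}

#' Mixed-standard oxidation fixture with known ground truth
#'
#' Emulates the metabolism-simulation scenario for a synthetic cannabinoid:
#' a mixture run containing the parent SCRA (protonated ion C20H28N3O3+,
#' m/z 358.2125, decaying educt), a co-oxidised interferent (synthetic m/z
#' 401.1782, decaying educt; a stand-in, not any real compound's mass) and
#' the parent's two main oxidation products — hydroxylation (C20H28N3O4+)
#' and dehydrogenated dihydroxylation (C20H26N3O5+) — both forming with
#' logistic midpoint 1700 mV; plus a reference run containing only the
#' interferent under the identical ramp (0 to 3500 mV, 10 mV/s, 5 mV
#' steps). Subtracting the reference from the mixture must leave exactly
#' the parent and its products.
#'
#' @param seed RNG seed for both runs.
#' @param noise_sd noise level as a fraction of peak amplitude (default
#'   0.01).
#' @param scan_hz acquisition rate (default 2 Hz: one scan per level).
#' @return list with `mixture` and `reference` (`ground_truth` objects),
#'   `parent_formula`, and `truth` (the mixture's [truth_table()]).
#' @export
scra_fixture <- function(seed = 1L, noise_sd = 0.01, scan_hz = 2) {
  ramp <- potential_ramp(0, 3500, scan_rate = 10, step_size = 5)
  parent <- species_spec("parent", ion_formula = "C20H28N3O3+",
                         profile = "educt", midpoint_mv = 1700,
                         width_mv = 50, max_intensity = 1e6)
  interferent <- species_spec("interferent", mz = 401.1782,
                              profile = "educt", midpoint_mv = 1600,
                              width_mv = 60, max_intensity = 8e5,
                              n_carbons = 22L)
  tp_oh <- species_spec("TP374", ion_formula = "C20H28N3O4+",
                        profile = "product", midpoint_mv = 1700,
                        width_mv = 50, max_intensity = 2e5)
  tp_quinone <- species_spec("TP388", ion_formula = "C20H26N3O5+",
                             profile = "product", midpoint_mv = 1700,
                             width_mv = 50, max_intensity = 1.5e5)
  mixture <- ground_truth(list(parent, interferent, tp_oh, tp_quinone),
                          ramp, scan_hz = scan_hz, noise_sd = noise_sd,
                          seed = seed)
  reference <- ground_truth(list(interferent), ramp, scan_hz = scan_hz,
                            noise_sd = noise_sd, seed = seed + 1L)
  list(mixture = mixture, reference = reference,
       parent_formula = parse_formula("C20H28N3O3+"),
       truth = truth_table(mixture))
}
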