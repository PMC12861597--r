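# Shared fixtures and independent oracles for the test suite.

# independent monoisotopic masses (same IUPAC digit strings, but summation in
# the oracles below walks atom by atom rather than count-weighted)
oracle_masses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100, Cl = 34.96885268)
oracle_electron <- 0.00054857990

# naive per-atom summation oracle: one addition per atom, in element order
oracle_mass <- function(counts) {
  total <- 0
  for (el in names(counts))
    for (k in seq_len(counts[[el]])) total <- total + oracle_masses[[el]]
  total
}

oracle_mz <- function(counts, charge) {
  m <- oracle_mass(counts)
  if (charge == 0) m else (m - charge * oracle_electron) / abs(charge)
}

# random valid formula as a named count vector (CHNOS alphabet)
random_counts <- function(max_atoms = 10) {
  els <- sample(names(oracle_masses), sample(1:4, 1))
  n <- length(els)
  counts <- as.list(pmax(1L, stats::rmultinom(1, sample(n:max_atoms, 1),
                                              rep(1, n))[, 1]))
  names(counts) <- els
  counts
}

counts_to_string <- function(counts, charge = 0L) {
  body <- paste0(mapply(function(e, n) paste0(e, n), names(counts), counts),
                 collapse = "")
  paste0(body, strrep(if (charge >= 0) "+" else "-", abs(charge)))
}

# exhaustive ordered-sequence oracle for neutral-loss chains: every ordered
# sequence of <= max_chain losses, legality checked stepwise, deduplicated
# by resulting formula string
oracle_fragments <- function(precursor, losses, max_chain) {
  acc <- new.env()
  assign(format_formula(precursor), monoisotopic_mz(precursor), envir = acc)
  recurse <- function(f, depth) {
    if (depth == 0) return()
    for (nm in names(losses)) {
      g <- try(formula_subtract(f, losses[[nm]]), silent = TRUE)
      if (inherits(g, "try-error")) next
      assign(format_formula(g), monoisotopic_mz(g), envir = acc)
      recurse(g, depth - 1)
    }
  }
  recurse(precursor, max_chain)
  unlist(as.list(acc))
}

# raw run in which every MS1 scan holds the same peak list; scan times on a
# 2 Hz grid covering the given ramp
flat_run <- function(ramp, mz, intensity, scan_hz = 2) {
  times <- seq(0, ramp_duration(ramp) + ramp$delay_s, by = 1 / scan_hz)
  new_raw_run(lapply(times, function(t)
    new_spectrum(t, mz, intensity, ms_level = 1L)))
}

# raw run with per-scan intensities given by trace functions of potential
trace_run <- function(ramp, mzs, trace_funs, scan_hz = 2) {
  times <- seq(0, ramp_duration(ramp) + ramp$delay_s, by = 1 / scan_hz)
  new_raw_run(lapply(times, function(t) {
    e <- potential_at_time(ramp, t)
    ints <- vapply(trace_funs, function(f) f(e), numeric(1))
    keep <- ints > 0
    new_spectrum(t, mzs[keep], ints[keep], ms_level = 1L)
  }))
}

# minimal standards-conforming mzML file with zero spectra
write_empty_mzml <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <cvList count="1">',
    '    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '  </cvList>',
    '  <fileDescription><fileContent>',
    '    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
    '  </fileContent></fileDescription>',
    '  <softwareList count="1"><software id="sw" version="0.1"/></softwareList>',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic"/></instrumentConfigurationList>',
    '  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"/></dataProcessing></dataProcessingList>',
    '  <run id="r" defaultInstrumentConfigurationRef="ic">',
    '    <spectrumList count="0" defaultDataProcessingRef="dp"/>',
    '  </run>',
    '</mzML>'), path)
  path
}

logistic <- function(x) 1 / (1 + exp(-x))
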