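test_that("channels classify into educt, product and background", {
  r <- potential_ramp(0, 500, 10, 5)
  run <- trace_run(r, c(300.10, 350.20, 400.30),
                   list(function(e) 1000 * (1 - logistic((e - 250) / 30)),
                        function(e) 500 * logistic((e - 250) / 30),
                        function(e) 80))
  vg <- build_voltammogram(run, r)
  cls <- classify_channels(vg)
  expect_equal(cls$label, c("educt", "product", "background"))
  expect_true(is.na(cls$formation_potential_mv[1]))
  expect_false(is.na(cls$formation_potential_mv[2]))
})

test_that("transformation products annotate against the parent formula", {
  parent <- parse_formula("C20H28N3O3+")

  oh <- annotate_tp(parent, 374.2078)
  expect_equal(format_formula(oh$ion_formula), "C20H28N3O4+")
  expect_equal(oh$calculated_mz, 374.2074)
  expect_equal(oh$ppm, 1.1)
  expect_equal(oh$transformation, "hydroxylation")

  quin <- annotate_tp(parent, 388.1873)
  expect_equal(format_formula(quin$ion_formula), "C20H26N3O5+")
  expect_equal(quin$calculated_mz, 388.1867)
  expect_equal(quin$ppm, 1.5)

  # zero mass difference has no library entry -> unannotated record
  none <- annotate_tp(parent, monoisotopic_mz(parent))
  expect_null(none$ion_formula)
  expect_true(is.na(none$ppm))

  expect_error(annotate_tp(parse_formula("C6H6"), 100), "charged")
})

test_that("stored record fields are mutually consistent", {
  rec <- annotate_tp("C20H28N3O3+", 374.2078)
  expect_equal(rec$calculated_mz,
               round_half_up(monoisotopic_mz(rec$ion_formula), 4))
  expect_equal(rec$ppm, ppm_error(rec$recorded_mz,
                                  monoisotopic_mz(rec$ion_formula)))
})

test_that("MS/MS spectra of one precursor merge by summation", {
  a <- new_spectrum(0, c(100.1, 200.2), c(10, 20), ms_level = 2L,
                    precursor_mz = 374.2078, collision_energy = 15)
  b <- new_spectrum(1, c(100.1, 200.2), c(5, 7), ms_level = 2L,
                    precursor_mz = 374.2078, collision_energy = 30)
  m <- merge_msms(list(a, a))
  expect_equal(m$intensity, c(20, 40))     # identical lists double
  expect_equal(m$mz, a$mz, tolerance = 1e-9)

  d <- new_spectrum(1, c(150.15), c(9), ms_level = 2L,
                    precursor_mz = 374.2078)
  u <- merge_msms(list(a, d))              # disjoint lists union
  expect_equal(u$mz, c(100.1, 150.15, 200.2), tolerance = 1e-9)

  s <- merge_msms(list(a, b))              # shared peaks summed
  expect_equal(s$intensity, c(15, 27))

  mixed <- new_spectrum(1, 100.1, 5, ms_level = 2L, precursor_mz = 500.5)
  expect_error(merge_msms(list(a, mixed)), "mixed precursor")
  expect_error(merge_msms(list(new_spectrum(0, 1, 1))), "MS2")
})

test_that("fragments annotate by neutral-loss chains within tolerance", {
  frag <- annotate_fragments(
    "C20H28N3O4+",
    new_spectrum(0, c(230.1291, 356.1980), c(1e3, 5e3), ms_level = 2L,
                 precursor_mz = 374.2078))
  water <- frag[frag$observed_mz == 356.1980, ]
  expect_equal(water$loss_chain, "H2O")
  expect_equal(water$theoretical_mz, 356.1969)
  expect_equal(water$ppm, 3.1)
  expect_true(attr(frag, "water_loss_present"))

  chain <- frag[frag$observed_mz == 230.1291, ]
  expect_equal(chain$theoretical_mz, 230.1288)
  expect_setequal(strsplit(chain$loss_chain, " \\+ ")[[1]],
                  c("C2H4O2", "C5H8O"))

  # quinoid-type precursor: no water loss observed
  frag2 <- annotate_fragments(
    "C20H26N3O5+",
    new_spectrum(0, 260.1038, 1e3, ms_level = 2L, precursor_mz = 388.1873))
  expect_equal(frag2$theoretical_mz, 260.1030)
  expect_setequal(strsplit(frag2$loss_chain, " \\+ ")[[1]],
                  c("C2H4O2", "C5H8"))
  expect_false(attr(frag2, "water_loss_present"))

  # far-off peaks stay unannotated
  off <- annotate_fragments(
    "C20H28N3O4+",
    new_spectrum(0, 123.4567, 10, ms_level = 2L, precursor_mz = 374.2078))
  expect_true(is.na(off$fragment_formula))
})

test_that("empty loss library yields only the precursor self-match", {
  prec_mz <- monoisotopic_mz(parse_formula("C20H28N3O4+"))
  frag <- annotate_fragments(
    "C20H28N3O4+",
    new_spectrum(0, c(200.0, prec_mz), c(5, 100), ms_level = 2L,
                 precursor_mz = prec_mz),
    losses = list())
  expect_equal(frag$loss_chain, c(NA_character_, ""))
  expect_equal(frag$fragment_formula, c(NA_character_, "C20H28N3O4+"))
})

test_that("loss-chain search matches exhaustive ordered enumeration", {
  set.seed(3)
  losses_all <- default_neutral_losses()
  for (trial in 1:5) {
    losses <- losses_all[sample(seq_along(losses_all),
                                sample(3:6, 1))]
    prec <- parse_formula(sample(c("C20H28N3O4+", "C12H16NO3+",
                                   "C10H14N2O2+"), 1))
    max_chain <- sample(1:3, 1)
    oracle <- oracle_fragments(prec, losses, max_chain)
    # observe every oracle fragment exactly; all must annotate back to a
    # candidate at ~0 ppm with the same theoretical m/z
    obs <- sort(unname(oracle))
    frag <- annotate_fragments(
      prec, new_spectrum(0, obs, rep(1, length(obs)), ms_level = 2L,
                         precursor_mz = monoisotopic_mz(prec)),
      losses = losses, max_chain = max_chain, tol_ppm = 1)
    expect_false(any(is.na(frag$fragment_formula)))
    expect_equal(frag$theoretical_mz, round_half_up(obs, 4))
    expect_setequal(frag$fragment_formula, names(oracle))
  }
})

test_that("recomputing theoretical m/z from annotated formulas is stable", {
  frag <- annotate_fragments(
    "C20H28N3O4+",
    new_spectrum(0, c(230.1291, 290.1506, 314.1863, 356.1980), rep(1, 4),
                 ms_level = 2L, precursor_mz = 374.2078))
  ok <- !is.na(frag$fragment_formula)
  recomputed <- vapply(frag$fragment_formula[ok], function(f)
    round_half_up(monoisotopic_mz(parse_formula(f)), 4), numeric(1))
  expect_equal(unname(recomputed), frag$theoretical_mz[ok])
})

test_that("the product report table mirrors annotation records", {
  parent <- "C20H28N3O3+"
  recs <- list(annotate_tp(parent, 374.2078), annotate_tp(parent, 388.1873))
  path <- withr::local_tempfile(fileext = ".csv")
  rep <- tp_report(parent, 358.2129, recs, path = path)

  expect_equal(nrow(rep), 3)
  expect_equal(rep$recorded_mz, c(358.2129, 374.2078, 388.1873))
  expect_equal(rep$ion_formula,
               c("C20H28N3O3+", "C20H28N3O4+", "C20H26N3O5+"))
  expect_equal(rep$calculated_mz, c(358.2125, 374.2074, 388.1867))
  expect_equal(rep$ppm, c(1.1, 1.1, 1.5))
  expect_true(file.exists(path))

  # parent-only and unannotated rows
  solo <- tp_report(parent, 358.2129)
  expect_equal(nrow(solo), 1)
  un <- tp_report(parent, 358.2129, list(annotate_tp(parent, 500.0)))
  expect_equal(un$ion_formula[2], "")
  expect_true(is.na(un$calculated_mz[2]))
})
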