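test_that("centroiding finds weighted-mean apexes above the noise floor", {
  # symmetric triangular profile peak centered at 358.2129
  prof <- new_spectrum(0, 358.2129 + c(-2, -1, 0, 1, 2) * 0.001,
                       c(10, 40, 90, 40, 10), mode = "profile")
  cen <- centroid_spectrum(prof)
  expect_equal(cen$mode, "centroid")
  expect_length(cen$mz, 1)
  expect_equal(cen$mz, 358.2129, tolerance = 1e-9)
  expect_equal(cen$intensity, 90)

  # everything below the noise floor -> empty
  expect_length(centroid_spectrum(prof, noise_floor = 1000)$mz, 0)
  # flat spectrum has no local maxima
  flat <- new_spectrum(0, seq(100, 101, 0.1), rep(5, 11), mode = "profile")
  expect_length(centroid_spectrum(flat)$mz, 0)

  # two resolved peaks -> two centroids, m/z-sorted
  two <- new_spectrum(0, c(100.0, 100.1, 100.2, 200.0, 200.1, 200.2),
                      c(1, 10, 1, 2, 20, 2), mode = "profile")
  cen2 <- centroid_spectrum(two)
  expect_equal(cen2$intensity, c(10, 20))
  expect_false(is.unsorted(cen2$mz))
  # centroiding a centroid spectrum is the identity
  expect_equal(centroid_spectrum(cen2), cen2)
})

test_that("a constant single-ion run yields one flat channel", {
  r <- potential_ramp(0, 10, scan_rate = 10, step_size = 5)
  run <- flat_run(r, 250.1234, 100)
  vg <- build_voltammogram(run, r)
  expect_length(vg$levels, 3)
  expect_length(vg$channel_mz, 1)
  expect_equal(vg$channel_mz, 250.1234, tolerance = 1e-9)
  expect_equal(as.numeric(vg$intensity[1, ]), c(100, 100, 100))
})

test_that("voltammogram recovers species channels on the full step grid", {
  r <- potential_ramp(0, 3500, 10, 5)
  run <- trace_run(r, c(358.2129, 401.1782),
                   list(function(e) 1000 * (1 - logistic((e - 1700) / 50)),
                        function(e) 800 * logistic((e - 1700) / 50)))
  vg <- build_voltammogram(run, r)
  expect_length(vg$levels, 701)
  expect_equal(vg$levels, step_grid(r))
  expect_length(vg$channel_mz, 2)
  # channel m/z of a noiseless species lies within tolerance of the truth
  expect_lt(abs(vg$channel_mz[1] - 358.2129) / 358.2129 * 1e6, 5)
  expect_lt(abs(vg$channel_mz[2] - 401.1782) / 401.1782 * 1e6, 5)
  expect_error(build_voltammogram(new_raw_run(list()), r), "no MS1")
})

test_that("total intensity is conserved when nothing is filtered", {
  r <- potential_ramp(0, 200, 10, 5)
  run <- trace_run(r, c(150.05, 280.11),
                   list(function(e) 500 + e, function(e) 900 - e))
  vg <- build_voltammogram(run, r, min_intensity = 0)
  total_raw <- sum(vapply(run$spectra, function(s) sum(s$intensity),
                          numeric(1)))
  # one scan per level, so within-level averaging changes nothing
  expect_equal(sum(vg$intensity), total_raw, tolerance = 1e-6)
})

test_that("spectra sharing a level are averaged, not summed", {
  r <- potential_ramp(0, 10, 10, 5)
  # 4 Hz: two scans per 0.5 s level, constant intensity 100
  run <- flat_run(r, 250.1234, 100, scan_hz = 4)
  vg <- build_voltammogram(run, r)
  expect_equal(max(vg$intensity), 100, tolerance = 1e-9)
})

test_that("ion traces match, miss and sum channels by ppm", {
  r <- potential_ramp(0, 10, 10, 5)
  # two channels 3 ppm apart (kept separate with a 1 ppm build tolerance)
  times <- seq(0, 1, 0.5)
  run <- new_raw_run(lapply(times, function(t)
    new_spectrum(t, c(400.0000, 400.0012), c(50, 70))))
  vg <- build_voltammogram(run, r, mz_tol_ppm = 1)
  expect_length(vg$channel_mz, 2)

  expect_equal(ion_trace(vg, 400.0000, tol_ppm = 1), rep(50, 3))
  expect_equal(ion_trace(vg, 400.0412, tol_ppm = 5), rep(0, 3))  # ~100 ppm off
  expect_equal(ion_trace(vg, 400.0006, tol_ppm = 5), rep(120, 3))  # both in
})

test_that("formation potential recovers the sigmoid onset and rejects educts", {
  levels <- seq(0, 3500, 5)
  midpoint <- 1750; width <- 50
  tr <- logistic((levels - midpoint) / width)
  fp <- formation_potential(tr, levels)
  onset <- midpoint + width * log(0.1 / 0.9)   # analytic 10% crossing
  expect_true(fp >= 1600 && fp <= 1750)
  expect_lt(abs(fp - onset), 5 * 5)            # within 5 steps analytically
  expect_true(fp %in% levels)

  expect_true(is.na(formation_potential(rev(tr), levels)))  # decreasing educt
  expect_true(is.na(formation_potential(rep(0, length(levels)), levels)))
})

test_that("signal annotation reports top channels with onsets", {
  r <- potential_ramp(0, 3500, 10, 5)
  run <- trace_run(r, c(358.2129, 374.2078),
                   list(function(e) 1000 * (1 - logistic((e - 1700) / 50)),
                        function(e) 400 * logistic((e - 1700) / 50)))
  vg <- build_voltammogram(run, r)
  ann <- annotate_signals(vg, top_n = 2)
  expect_equal(nrow(ann), 2)
  expect_equal(ann$mz[1], 358.2129, tolerance = 1e-6)  # intensity-descending
  expect_true(is.na(ann$formation_potential_mv[1]))    # educt
  expect_false(is.na(ann$formation_potential_mv[2]))   # product
  expect_true(ann$formation_potential_mv[2] %in% vg$levels)

  expect_equal(nrow(annotate_signals(vg, top_n = 0)), 0)
  expect_equal(nrow(annotate_signals(vg, top_n = 99)), 2)
})

test_that("table export has channel rows, level columns and round-trips", {
  r <- potential_ramp(0, 10, 10, 5)
  times <- seq(0, 1, 0.5)
  run <- new_raw_run(lapply(times, function(t)
    new_spectrum(t, c(200.1111, 300.2222), c(10, 20))))
  vg <- build_voltammogram(run, r)

  path <- withr::local_tempfile(fileext = ".csv")
  export_table(vg, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(dim(back), c(2, 4))           # 2 channels x (mz + 3 levels)
  expect_equal(names(back), c("mz", "0", "5", "10"))
  expect_equal(back$mz, c(200.1111, 300.2222))
  expect_equal(unname(as.matrix(back[, -1])), unname(vg$intensity),
               tolerance = 1e-9)
})

test_that("plot export writes image files", {
  r <- potential_ramp(0, 10, 10, 5)
  run <- flat_run(r, c(250.1, 300.2), c(100, 50))
  vg <- build_voltammogram(run, r)
  png_path <- withr::local_tempfile(fileext = ".png")
  export_plot(vg, png_path, format = "png")
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  svg_path <- withr::local_tempfile(fileext = ".svg")
  export_plot(vg, svg_path, format = "svg")
  expect_true(file.exists(svg_path) && file.size(svg_path) > 0)
})
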