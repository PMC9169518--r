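test_that("retention index interpolates linearly between anchor ketones", {
  anc <- fx_anchors()
  # anchor identity: RI at the C_n ketone is exactly 100 n
  expect_equal(compute_retention_index(anc$rt_min, anc), 100 * (8:14))
  # before the first anchor (propiophenone) no index is defined
  expect_true(is.na(compute_retention_index(5.5, anc)))
  expect_true(is.na(compute_retention_index(anc$rt_min[7] + 1, anc)))
  # strictly increasing inside the ladder
  set.seed(1)
  rts <- sort(runif(50, anc$rt_min[1], anc$rt_min[7]))
  ris <- compute_retention_index(rts, anc)
  expect_true(all(diff(ris) > 0))
  expect_error(anchor_series(8:10, c(5, 4, 6)), "increase")
  expect_error(anchor_series(8L, 5), "at least two")
})

test_that("default anchors reproduce the catalogued candidate indices", {
  catg <- fx_catalog()
  cand <- catg[match(candidate_ids, catg$id), ]
  ri <- compute_retention_index(cand$rt_min, fx_anchors())
  expect_true(is.na(ri[1]))          # candidate I elutes before C8
  expect_true(all(abs(ri[-1] - cand$ri[-1]) <= 1))
})

test_that("back-fitted anchor bracket recovers published indices", {
  # least-squares line through four published (Rt, RI) pairs of one bracket
  rt <- c(26.8, 28.0, 31.1, 33.0); ri <- c(1006, 1018, 1049, 1067)
  anc <- backfit_anchor_bracket(rt, ri)
  expect_equal(anc$carbon_number, c(10L, 11L))
  # oracle: the same line evaluated directly
  line <- stats::lm(ri ~ rt)
  for (t in c(28.0, 29.0, 30.5)) {
    expect_equal(compute_retention_index(t, anc),
                 unname(predict(line, data.frame(rt = t))), tolerance = 1e-9)
  }
  expect_equal(round(compute_retention_index(29.0, anc)), 1028)
  expect_equal(round(compute_retention_index(28.0, anc)), 1018)
})

test_that("spectrum conformity scores shape agreement on the common grid", {
  g <- 210:400
  tr <- function(y) spectrum_trace("UV", g, y)
  band <- function(mu) exp(-(g - mu)^2 / 200)
  expect_equal(spectrum_conformity(tr(band(300)), tr(band(300))), 1.0)
  # anti-correlated monotone ramps clip to zero
  ramp <- (g - 210) / 190
  expect_equal(spectrum_conformity(tr(ramp), tr(rev(ramp))), 0.0)
  # two Gaussian bands offset by 30 nm: direct correlation oracle
  a <- band(290); b <- band(320)
  expect_equal(spectrum_conformity(tr(a), tr(b)),
               max(0, cor(a / max(a), b / max(b))), tolerance = 1e-12)
  # disjoint or mismatched supports fail loudly
  expect_error(spectrum_conformity(
    spectrum_trace("UV", 210:240, band(225)[1:31]),
    spectrum_trace("UV", 300:340, band(320)[91:131])), "disjoint")
  expect_error(spectrum_conformity(tr(a), emission_spectrum_from_max(450)),
               "different axes")
})

test_that("fluorescence peak-height ratio picks highest over second-highest", {
  r <- fl_peak_ratio(c("400" = 0.4, "450" = 2.3, "500" = 1.0))
  expect_equal(r, list(high = 450, second = 500, ratio = 2.3))
  # ties break toward the shorter wavelength
  expect_equal(fl_peak_ratio(c("400" = 5, "450" = 5, "500" = 1)),
               list(high = 400, second = 450, ratio = 1.0))
  r2 <- fl_peak_ratio(c(fl450 = 1, fl500 = 4.7))
  expect_equal(r2, list(high = 500, second = 450, ratio = 4.7))
  expect_error(fl_peak_ratio(c("400" = 0, "450" = 0, "500" = 0)),
               "non-fluorescing")
  expect_error(fl_peak_ratio(c("400" = 1)), "at least two")
})

test_that("spectral classification handles degenerate input", {
  expect_error(classify_spectrum(numeric(0), 450), "empty")
  expect_equal(classify_spectrum(c(230, 295, 347), 462), "6-OR,7-OH C")
  expect_equal(classify_spectrum(c(223, 251, 312), 476), "5-OR FC")
  # an unplaceable coumarin-like spectrum stays uncategorized
  expect_equal(classify_spectrum(c(224, 248, 295, 330), 431), "uncategorized C")
})

test_that("noiseless synthetic peaks identify back to their generating record", {
  catg <- fx_catalog()
  conc <- stats::setNames(rep(2, nrow(catg)), catg$name)
  vk <- stats::setNames(ifelse(grepl("^candidate", catg$name), "area",
                               "concentration"), catg$name)
  chrom <- synth_chromatogram(conc, catg, sim_config(seed = 3),
                              value_kind = vk)
  expect_length(chrom$peaks, 52L)
  got <- vapply(chrom$peaks, function(pk)
    identify_peak(pk, catg, fx_anchors())$matched_id, character(1))
  expected <- catg$id[match(chrom$table$compound, catg$name)]
  expect_identical(got, expected)
})

test_that("no match is reported for foreign or ambiguous peaks", {
  catg <- fx_catalog()
  # a spectrum unlike any library entry
  g <- 210:400
  alien <- chromatogram_peak(20, areas = c(uv250 = 1, uv270 = 1, uv330 = 1),
                             heights = c(fl400 = 0, fl450 = 0, fl500 = 0),
                             uv_spectrum = spectrum_trace("UV", g,
                               exp(-(g - 380)^2 / 50)))
  res <- identify_peak(alien, catg, fx_anchors())
  expect_true(is.na(res$matched_id))
  expect_false(res$ambiguous)
  # duplicate records force an ambiguity, reported as no match
  dup <- catg[c(10, 10), ]
  dup$id <- c("10", "10b")
  class(dup) <- class(catg)
  rec <- catg[10, ]
  pk <- chromatogram_peak(rec$rt_min,
                          areas = c(uv250 = 5, uv270 = 2, uv330 = 1),
                          heights = c(fl400 = 0.2, fl450 = 0.5, fl500 = 1),
                          uv_spectrum = uv_spectrum_from_maxima(rec$uv_maxima[[1]],
                                                                rec$family),
                          em_spectrum = emission_spectrum_from_max(rec$emission_max))
  res2 <- identify_peak(pk, dup, fx_anchors())
  expect_true(is.na(res2$matched_id))
  expect_true(res2$ambiguous)
  expect_setequal(res2$candidates, c("10", "10b"))
})
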