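test_that("blend generation obeys the count law and conserves mass", {
  a <- fx_profiles(cbind(x = c(1, 2), y = c(3, 1)), prefix = "o")
  b <- fx_profiles(cbind(x = c(10, 8, 6), y = c(0.5, 1, 2)),
                   species = "mandarin", prefix = "m")
  bl <- generate_blends(a, b, c(95, 90, 80))
  expect_equal(nrow(bl$X), 2 * 3 * 3 + 2 + 3)
  # every row reconstructs exactly from its provenance
  for (k in seq_len(nrow(bl$X))) {
    pv <- bl$provenance[k, ]
    f <- pv$purity / 100
    main <- if (is.na(pv$main_id)) 0 else a$values[pv$main_id, ]
    adu <- if (is.na(pv$adulterant_id)) 0 else b$values[pv$adulterant_id, ]
    expect_equal(unname(bl$X[k, ]), unname(f * main + (1 - f) * adu),
                 tolerance = 1e-12)
  }
  # 1 x 1, one level, both pure flags -> 3 rows with exact conservation
  a1 <- fx_profiles(cbind(x = 2, y = 6), prefix = "o")
  b1 <- fx_profiles(cbind(x = 10, y = 1), species = "mandarin", prefix = "m")
  bl1 <- generate_blends(a1, b1, 90)
  expect_equal(nrow(bl1$X), 3L)
  expect_equal(unname(bl1$X[1, ]), 0.9 * c(2, 6) + 0.1 * c(10, 1))
  expect_equal(bl1$y, c(90, 100, 0))
  expect_error(generate_blends(a, fx_profiles(cbind(z = 1:3)), 90),
               "identical variable columns")
  expect_error(generate_blends(a, b, c(90, 90)), "distinct")
  expect_error(generate_blends(a, b, 110), "between 0 and 100")
})

test_that("noiseless blends train an exact purity model", {
  main <- fx_profiles(matrix(c(0.02, 1.1, 0.015), 1, 3,
                             dimnames = list(NULL, scenario_spec("orange_vs_mandarin")$variables)),
                      prefix = "o")
  adu <- fx_profiles(matrix(c(0.9, 0.08, 1.4), 1, 3,
                            dimnames = list(NULL, scenario_spec("orange_vs_mandarin")$variables)),
                     species = "mandarin", prefix = "m")
  bl <- generate_blends(main, adu, c(95, 90, 80))
  model <- train_purity_model(bl, "orange_vs_mandarin")
  expect_lt(model$rmsecv, 1e-6)
  expect_equal(model$fit$r_squared[model$n_components], 1, tolerance = 1e-9)
  # pure main predicts 100, blends predict their exact purity
  expect_equal(predict_purity(model, main), 100, tolerance = 1e-6)
  pp <- predict_purity(model, bl)
  expect_equal(pp, bl$y, tolerance = 1e-6)
  # linearity: an unseen 85 % blend predicts 85
  x85 <- 0.85 * main$values + 0.15 * adu$values
  expect_equal(predict_purity(model, x85), 85, tolerance = 1e-6)
})

test_that("purity predictions are never clipped", {
  vars <- scenario_spec("orange_vs_mandarin")$variables
  main <- fx_profiles(matrix(c(0.02, 1.1, 0.015), 1, 3,
                             dimnames = list(NULL, vars)), prefix = "o")
  adu <- fx_profiles(matrix(c(0.9, 0.08, 1.4), 1, 3,
                            dimnames = list(NULL, vars)),
                     species = "mandarin", prefix = "m")
  model <- train_purity_model(generate_blends(main, adu, c(95, 90, 80)),
                              "orange_vs_mandarin")
  beyond <- 1.4 * main$values - 0.4 * adu$values   # richer than any orange
  expect_gt(predict_purity(model, beyond), 100)
  extreme <- -0.5 * main$values + 1.5 * adu$values
  expect_lt(predict_purity(model, extreme), 0)
  expect_error(predict_purity(model, matrix(1, 1, 1,
                                            dimnames = list(NULL, "x"))),
               "lacks model variable")
})

test_that("model evaluation reports RMSEP, R2 and per-level ranges", {
  vars <- scenario_spec("orange_vs_mandarin")$variables
  main <- fx_profiles(matrix(c(0.02, 1.1, 0.015), 1, 3,
                             dimnames = list(NULL, vars)), prefix = "o")
  adu <- fx_profiles(matrix(c(0.9, 0.08, 1.4), 1, 3,
                            dimnames = list(NULL, vars)),
                     species = "mandarin", prefix = "m")
  bl <- generate_blends(main, adu, c(95, 90, 80))
  model <- train_purity_model(bl, "orange_vs_mandarin")
  ev <- evaluate_model(model, bl)
  expect_equal(ev$rmsep, 0, tolerance = 1e-6)
  expect_equal(ev$r_squared, 1, tolerance = 1e-9)
  expect_equal(ev$level_ranges$purity, c(100, 95, 90, 80, 0))
  # a constant offset in the references shows up one-for-one in RMSEP
  shifted <- bl; shifted$y <- bl$y - 2
  ev2 <- evaluate_model(model, shifted)
  expect_equal(ev2$rmsep, 2, tolerance = 1e-6)
  expect_equal(ev2$r_squared, 1, tolerance = 1e-9)
  # single-row test set: RMSEP defined, R2 not
  single <- bl; single$X <- bl$X[1, , drop = FALSE]; single$y <- bl$y[1]
  ev3 <- evaluate_model(model, single)
  expect_true(is.finite(ev3$rmsep))
  expect_true(is.na(ev3$r_squared))
})

test_that("decision rules reproduce the published criteria", {
  orange <- scenario_spec("orange_vs_mandarin")$decision
  expect_equal(classify_label(95, orange), "authentic")
  expect_equal(classify_label(94, orange), "authentic")
  expect_equal(classify_label(93.9, orange), "indeterminate")
  expect_equal(classify_label(82, orange), "indeterminate")
  expect_equal(classify_label(81, orange), "fraudulent")
  sg <- scenario_spec("grapefruit_vs_SG")$decision
  expect_equal(classify_label(c(94, 86, 84), sg),
               c("authentic", "indeterminate", "fraudulent"))
  wg <- scenario_spec("grapefruit_vs_WG")$decision
  expect_equal(classify_label(c(95, 94.9, 86.9), wg),
               c("authentic", "indeterminate", "fraudulent"))
  expect_error(decision_rule(80, 90), "below")
  # monotone in predicted purity
  pp <- seq(-40, 120, by = 0.5)
  sev <- c(fraudulent = 1, indeterminate = 2, authentic = 3)
  expect_true(all(diff(sev[classify_label(pp, orange)]) >= 0))
})

test_that("unknown pomelo subgroup gets the conservative verdict", {
  expect_equal(classify_grapefruit_conservative(96, 96), "authentic")
  expect_equal(classify_grapefruit_conservative(96, 90), "indeterminate")
  expect_equal(classify_grapefruit_conservative(84, 96), "fraudulent")
  expect_equal(classify_grapefruit_conservative(90, 80), "fraudulent")
})

test_that("seeded scenario studies separate 90 % blends from pure juice", {
  # cross-validated predictions keep the 90 % cluster clear of the 100 %
  # cluster under the default generator noise
  ok <- logical(3)
  for (i in seq_along(ok)) {
    st <- simulate_purity_study("orange_vs_mandarin", n_train = 12,
                                n_test = 6, cv = 0.25, seed = 400 + i)
    pp <- predict_purity(st$model, st$test_blends)
    ref <- st$test_blends$y
    ok[i] <- max(pp[ref == 90]) < min(pp[ref == 100])
  }
  expect_true(mean(ok) >= 2 / 3)
})
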