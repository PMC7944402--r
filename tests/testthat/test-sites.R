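test_that("mutants map onto the constrained additive-model terms", {
  wt <- encode_mutant(mutant_config("WT"))
  expect_false(wt$s3s4_active)
  expect_identical(wt$pore_class, "WT_362_454")
  expect_true(wt$residual_active)

  m <- encode_mutant(mutant_config("2R/W454A", has_2R = TRUE, W454A = TRUE))
  expect_true(m$s3s4_active)
  expect_identical(m$pore_class, "W454A")

  # R365Q-containing mutants get extended pore classes, quietly
  expect_silent(
    e <- encode_mutant(mutant_config("R362Q/R365Q", R362Q = TRUE,
                                     R365Q = TRUE)))
  expect_identical(e$pore_class, "R362Q_R365Q")
  # combinations outside the registry are extended with a warning
  expect_warning(
    f <- encode_mutant(mutant_config("R362Q/W454A/F416A", R362Q = TRUE,
                                     W454A = TRUE, F416A = TRUE)),
    "outside the canonical")
  expect_identical(f$pore_class, "R362Q_W454A_F416A")
})

panel_configs <- list(
  mutant_config("WT"),
  mutant_config("2R", has_2R = TRUE),
  mutant_config("R362Q", R362Q = TRUE),
  mutant_config("W454A", W454A = TRUE))

test_that("the design matrix encodes active terms and exposes degeneracy", {
  tab <- gen_shift_table(panel_configs, s3s4_mV = -17,
                         pore_mV = c(WT_362_454 = -15, R362Q = -34,
                                     W454A = -6),
                         residual_mV = -10, noise_sd = 0)
  dm <- build_design_matrix(tab)
  # WT row: no S3/S4 term, WT pore class, residual always on
  expect_equal(unname(dm$X["WT", ]), c(0, 1, 0, 0, 1))
  expect_equal(unname(dm$X["2R", ]), c(1, 1, 0, 0, 1))
  # every row sums its active terms only
  expect_true(all(rowSums(dm$X[, -1]) == 2))
  # rank agrees with an SVD elimination oracle, and flags the
  # pore-vs-residual ridge (4 mutants, 5 parameters)
  sv <- svd(dm$X)$d
  expect_identical(dm$rank, sum(sv > 1e-10 * max(sv)))
  expect_lt(dm$rank, ncol(dm$X))
  # single-mutant dataset is rank 1
  dm1 <- build_design_matrix(tab[1, , drop = FALSE])
  expect_identical(dm1$rank, 1L)
  expect_error(build_design_matrix(tab[0, , drop = FALSE]), "empty")
})

test_that("least-squares site fit matches the normal equations closed form", {
  set.seed(33)
  # full-rank subcase: residual pinned, replicate measurements per mutant
  tab <- gen_shift_table(rep(panel_configs, 3), s3s4_mV = -17,
                         pore_mV = c(WT_362_454 = -15, R362Q = -34,
                                     W454A = -6),
                         residual_mV = -10, noise_sd = 2)
  fit <- fit_site_model(tab, fixed = c(residual = -10))
  dm <- build_design_matrix(tab)
  free <- setdiff(colnames(dm$X), "residual")
  X <- dm$X[, free]
  y <- tab$shift_mV - (-10)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients[free]), unname(drop(beta)),
               tolerance = 1e-9)
  # pinned parameters appear unchanged in the output
  expect_identical(unname(fit$coefficients["residual"]), -10)
})

test_that("weighted fits honour per-row weights", {
  tab <- gen_shift_table(panel_configs[c(1, 1)], s3s4_mV = 0,
                         pore_mV = c(WT_362_454 = 0), residual_mV = 0,
                         noise_sd = 0)
  tab$shift_mV <- c(-10, -20)
  f <- fit_site_model(tab, fixed = c(residual = 0), weights = c(3, 1))
  expect_equal(unname(f$coefficients["pore_WT_362_454"]),
               (3 * -10 + 1 * -20) / 4, tolerance = 1e-9)
})

test_that("solution ranges collapse for full-rank fits and match a grid scan", {
  # noiseless full-rank case: zero-width intervals
  tab <- gen_shift_table(panel_configs, s3s4_mV = -17,
                         pore_mV = c(WT_362_454 = -15, R362Q = -34,
                                     W454A = -6),
                         residual_mV = -10, noise_sd = 0)
  fit <- fit_site_model(tab, fixed = c(residual = -10))
  rng <- solution_ranges(fit)
  expect_false(any(rng$unbounded))
  expect_equal(rng$low, rng$high, tolerance = 1e-7)

  # redundant measurements: profile interval matches an exhaustive scan
  tab2 <- tab[c(1, 1), ]
  tab2$shift_mV <- c(-24, -27)
  fit2 <- fit_site_model(tab2, fixed = c(residual = -10))
  # the inactive s3s4 column is unbounded here by construction; the
  # pore parameter of interest is profiled
  rng2 <- suppressWarnings(solution_ranges(fit2, tolerance = 0.05))
  p_grid <- seq(-20, -10, by = 1e-4)
  sse_grid <- vapply(p_grid, function(p)
    sum((tab2$shift_mV - (p - 10))^2), numeric(1))
  ok <- p_grid[sse_grid <= min(sse_grid) * 1.05]
  i <- which(rng2$parameter == "pore_WT_362_454")
  expect_equal(rng2$low[i], min(ok), tolerance = 1e-3)
  expect_equal(rng2$high[i], max(ok), tolerance = 1e-3)
})

test_that("the residual-vs-pore gauge ridge is detected and exposed", {
  # no mutant carries the 2R motif and every row has a pore term, so a
  # constant can migrate between residual and the pore values without
  # changing any prediction
  tab <- gen_shift_table(panel_configs[c(1, 3, 4)], s3s4_mV = 0,
                         pore_mV = c(WT_362_454 = -15, R362Q = -34,
                                     W454A = -6),
                         residual_mV = -10, noise_sd = 0)
  fit <- fit_site_model(tab)
  expect_true(fit$degenerate)
  shifted <- fit$coefficients
  shifted["residual"] <- shifted["residual"] + 5
  pore_cols <- grep("^pore_", names(shifted))
  shifted[pore_cols] <- shifted[pore_cols] - 5
  expect_equal(drop(fit$design %*% shifted), fit$predicted,
               tolerance = 1e-9)
  expect_warning(rng <- solution_ranges(fit), "flat ridge")
  expect_true(all(rng$unbounded[rng$parameter != "s3s4"]))

  # a parameter backed by no observation is unbounded too
  tab2r <- gen_shift_table(panel_configs[2], s3s4_mV = -17,
                           pore_mV = c(WT_362_454 = -15), residual_mV = -10,
                           noise_sd = 0)
  fit2 <- fit_site_model(tab2r, fixed = c(residual = -10),
                         zero_pore_when_2R = TRUE)
  rng2 <- suppressWarnings(solution_ranges(fit2))
  expect_true(rng2$unbounded[rng2$parameter == "pore_WT_362_454"])
})

test_that("model predictions and their correlation behave", {
  pore <- c(WT_362_454 = -15, R362Q = -34, W454A = -6)
  tab <- gen_shift_table(panel_configs, s3s4_mV = -17, pore_mV = pore,
                         residual_mV = -10, noise_sd = 0)
  fit <- fit_site_model(tab, fixed = c(residual = -10))
  pc <- predict_and_correlate(fit)
  expect_equal(pc$pearson_r, 1, tolerance = 1e-9)
  expect_equal(unname(pc$predicted), tab$shift_mV, tolerance = 1e-9)

  # residual-only model on varied data: constant prediction, r undefined
  flat <- fit_site_model(tab, fixed = c(s3s4 = 0, pore_WT_362_454 = 0,
                                        pore_R362Q = 0, pore_W454A = 0))
  expect_message(pc_flat <- predict_and_correlate(flat), "undefined")
  expect_true(is.na(pc_flat$pearson_r))

  # hand-computed Pearson r on a 3-point panel
  tab3 <- tab[c(1, 2, 3), ]
  tab3$shift_mV <- c(-20, -40, -45)
  fit3 <- fit_site_model(tab3, fixed = c(residual = -10))
  pc3 <- predict_and_correlate(fit3, tab3)
  x <- unname(pc3$predicted); y <- tab3$shift_mV
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc3$pearson_r, r_hand, tolerance = 1e-12)
})

test_that("the strict-additivity variant can silence the pore term under 2R", {
  pore <- c(WT_362_454 = -15, W454A = -6)
  cfgs <- list(mutant_config("WT"),
               mutant_config("2R", has_2R = TRUE),
               mutant_config("W454A", W454A = TRUE))
  tab <- gen_shift_table(cfgs, s3s4_mV = -17, pore_mV = pore,
                         residual_mV = -10, noise_sd = 0)
  dm <- build_design_matrix(tab, zero_pore_when_2R = TRUE)
  expect_equal(unname(dm$X["2R", ]), c(1, 0, 0, 1))
  expect_equal(unname(dm$X["WT", ]), c(0, 1, 0, 1))
})
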