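test_that("two points define the exact line", {
  trees <- data.frame(D = c(1, sqrt(2)), H = c(1, 1), wt_above = c(3, 5))
  fit <- fit_allometry(trees, "aboveground")
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
})

test_that("noise-free synthetic trees are fitted to machine precision", {
  set.seed(8)
  D <- runif(20, 0.05, 0.2); H <- runif(20, 4, 10)
  trees <- data.frame(D = D, H = H, wt_above = 150 * D^2 * H + 2)
  fit <- fit_allometry(trees, "aboveground")
  expect_equal(fit$slope, 150, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
})

test_that("lm-based fit equals the normal-equation closed form", {
  set.seed(5)
  for (i in 1:10) {
    D <- runif(9, 0.03, 0.25); H <- runif(9, 3, 12)
    y <- runif(1, 50, 500) * D^2 * H + rnorm(9, 0, 2)
    trees <- data.frame(D = D, H = H, wt_below = y)
    fit <- fit_allometry(trees, "belowground")
    ora <- ols_oracle(D^2 * H, y)
    expect_equal(fit$intercept, ora[1], tolerance = 1e-9)
    expect_equal(fit$slope, ora[2], tolerance = 1e-9)
  }
})

test_that("leaf fits drop excluded trees and need two usable trees", {
  trees <- data.frame(D = c(0.1, 0.12, 0.14), H = 7,
                      wt_leaf = c(4, 5.8, 100),
                      leaf_excluded = c(FALSE, FALSE, TRUE))
  fit <- fit_allometry(trees, "leaf")
  expect_equal(fit$n_trees, 2)
  expect_error(fit_allometry(trees[3, ], "leaf"), "2 usable")
  same <- data.frame(D = c(0.1, 0.1), H = c(5, 7), wt_leaf = c(4, 5))
  expect_error(fit_allometry(same, "leaf"), "variance")
})

test_that("biomass prediction follows the fitted line and clips at zero", {
  fit <- structure(list(organ = "aboveground", form = "D2H_linear",
                        slope = 2, intercept = 1, n_trees = 5,
                        residual_sd = 0), class = "allometric_fit")
  expect_equal(predict_biomass(fit, D = sqrt(2), H = 1), 5)
  fit$intercept <- 3.2; fit$slope <- 373.5
  expect_equal(predict_biomass(fit, D = 1e-9, H = 1), 3.2,
               tolerance = 1e-6)
  expect_error(predict_biomass(fit, D = 0.1), "H is required")
  leaf <- structure(list(organ = "leaf", form = "D2_linear", slope = 392.3,
                         intercept = 0, n_trees = 6, residual_sd = 0),
                    class = "allometric_fit")
  expect_equal(predict_biomass(leaf, D = 0.1), 3.923)
  neg <- structure(list(organ = "leaf", form = "D2_linear", slope = 10,
                        intercept = -1, n_trees = 6, residual_sd = 0),
                   class = "allometric_fit")
  expect_warning(out <- predict_biomass(neg, D = 0.01), "clipped")
  expect_equal(out, 0)
})

test_that("single-quadrat reconstruction matches the hand computation", {
  # 2 trees with D^2 H = {1, 2} m3, slope 2, intercept 1, carbon 0.5,
  # area 10 m2: biomass 2*3 + 1*2 = 8 kg -> 0.4 kg-C/m2
  fits <- list(
    above = structure(list(organ = "aboveground", form = "D2H_linear",
                           slope = 2, intercept = 1, n_trees = 2,
                           residual_sd = 0), class = "allometric_fit"),
    below = structure(list(organ = "belowground", form = "D2H_linear",
                           slope = 0, intercept = 0, n_trees = 2,
                           residual_sd = 0), class = "allometric_fit"),
    leaf = structure(list(organ = "leaf", form = "D2_linear", slope = 0,
                          intercept = 0, n_trees = 2, residual_sd = 0),
                     class = "allometric_fit"))
  rings <- data.frame(tree_id = rep(c("a", "b"), each = 1), age = 1,
                      ring_D = c(1, sqrt(2)))
  hba <- data.frame(age = 1, H = 1)
  quad <- data.frame(quadrat_id = "Q1", area = 10,
                     tree_id = c("q1", "q2"), D = c(1, sqrt(2)),
                     H = c(1, 1))
  cs <- reconstruct_carbon_series(fits, rings, hba, quad,
                                  carbon_fraction_wood = 0.5,
                                  carbon_fraction_leaf = 0.5)
  expect_equal(cs$AC, 0.4)
  expect_equal(cs$BC, 0)
})

test_that("monotone rings give a nondecreasing reconstruction", {
  sv <- generate_survey(survey_gen_config(noise_cv = 0, seed = 6))
  fits <- list(above = fit_allometry(sv$harvest, "aboveground"),
               below = fit_allometry(sv$harvest, "belowground"),
               leaf = fit_allometry(sv$harvest, "leaf"))
  cs <- reconstruct_carbon_series(fits, sv$rings, sv$height_by_age,
                                  sv$quadrats)
  expect_true(all(diff(cs$AC) >= 0))
  expect_true(all(diff(cs$LC) >= 0))
  expect_true(all(cs$AC >= 0 & cs$BC >= 0 & cs$LC >= 0))
})

test_that("BC:AC mean ratio follows its definition", {
  s <- carbon_density_series(1:2, AC = c(1, 1), BC = c(0.4, 0.6),
                             LC = c(0.1, 0.1))
  expect_equal(bc_ac_mean_ratio(s), 0.5)
  s2 <- carbon_density_series(1:3, AC = c(1, 2, 3), BC = c(1, 2, 3),
                              LC = rep(0.1, 3))
  expect_equal(bc_ac_mean_ratio(s2), 1)
  s$AC[1] <- 0
  expect_error(bc_ac_mean_ratio(s), "positive")
})

test_that("cm diameters are converted before fitting and reconstruction", {
  sv <- generate_survey(survey_gen_config(noise_cv = 0, seed = 13))
  td <- tempfile(); dir.create(td)
  h <- sv$harvest; h$D <- h$D * 100
  r <- sv$rings; r$ring_D <- r$ring_D * 100
  q <- sv$quadrats; q$D <- q$D * 100
  write.csv(h, file.path(td, "h.csv"), row.names = FALSE)
  write.csv(r, file.path(td, "r.csv"), row.names = FALSE)
  write.csv(q, file.path(td, "q.csv"), row.names = FALSE)
  write.csv(sv$height_by_age, file.path(td, "hb.csv"), row.names = FALSE)
  back <- read_survey_csv(file.path(td, "h.csv"), file.path(td, "r.csv"),
                          file.path(td, "q.csv"), file.path(td, "hb.csv"),
                          d_unit = "cm")
  expect_equal(back$harvest$D, sv$harvest$D, tolerance = 1e-12)
  fit <- fit_allometry(back$harvest, "aboveground")
  expect_equal(fit$slope, 373.5, tolerance = 1e-6)
})
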