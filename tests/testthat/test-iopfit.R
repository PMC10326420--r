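test_that("relative normalization is anchored to the control baseline mean", {
  d <- data.frame(group = c("ctl", "ctl", "mut", "ctl"),
                  delta_iop_mmHg = c(0, 0, 0, -10),
                  volume_um3 = c(2, 4, 6, 9))
  out <- normalize_relative(d, "ctl", baseline_level = 0)
  expect_equal(out$value, c(2, 4, 6, 9) / 3) # mean control baseline is 3
  expect_equal(out$value[3], 2.0)
  # a control baseline measurement equal to the mean maps to 1
  expect_equal(normalize_relative(
    data.frame(group = "ctl", delta_iop_mmHg = 0, volume_um3 = 3),
    "ctl")$value, 1)
  expect_error(normalize_relative(d, "ctl", baseline_level = 5),
               "no ctl measurements")
})

test_that("per-eye normalization anchors every eye at the reference level", {
  d <- data.frame(eye_id = c(rep("e1", 4), rep("e2", 4)),
                  delta_iop_mmHg = rep(c(-10, -10, -10, 0), 2),
                  volume_um3 = c(10, 10, 10, 8, 20, 20, 20, 16))
  out <- normalize_per_eye(d, reference_level = -10)
  expect_equal(out$value[4], 0.8)
  # each eye's normalized mean at the reference level is exactly 1
  for (e in c("e1", "e2"))
    expect_identical(mean(out$value[out$eye_id == e &
                                      out$delta_iop_mmHg == -10]), 1)
  # identical fractional collapse gives identical normalized curves
  expect_identical(out$value[1:4], out$value[5:8])
  d2 <- d[d$eye_id == "e1" | d$delta_iop_mmHg == 0, ]
  expect_error(normalize_per_eye(d2, -10), "e2")
})

test_that("normalized outputs are invariant to global rescaling", {
  set.seed(2)
  d <- expand.grid(`repeat` = 1:3, delta_iop_mmHg = c(-10, -5, 0, 5, 10),
                   eye_id = c("c1", "c2", "m1", "m2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(grepl("^c", d$eye_id), "ctl", "mut")
  d$volume_um3 <- exp(rnorm(nrow(d), log(5e6), 0.2))
  # power-of-two rescaling is exact in floating point: bit-identical output
  dk <- d; dk$volume_um3 <- d$volume_um3 * 2^7
  expect_identical(normalize_relative(d, "ctl")$value,
                   normalize_relative(dk, "ctl")$value)
  expect_identical(normalize_per_eye(d)$value, normalize_per_eye(dk)$value)
  # arbitrary rescaling agrees to rounding error
  da <- d; da$volume_um3 <- d$volume_um3 * 17.3
  expect_equal(normalize_relative(d, "ctl")$value,
               normalize_relative(da, "ctl")$value, tolerance = 1e-12)
})

test_that("noiseless linear data are fitted exactly", {
  d <- data.frame(delta_iop_mmHg = rep(c(-10, -5, 0, 5, 10), 3))
  d$value <- 1 - 0.03 * d$delta_iop_mmHg
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(iop_response(value ~ delta_iop_mmHg, d))
  expect_equal(fit$slope, -0.03, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(diff(fit$ci), 0, tolerance = 1e-10) # zero-width CI
  expect_identical(fit$n_points, 15L)              # 5 levels x 3 repeats
  expect_identical(fit$residual_df, 13L)           # n - 2
  expect_equal(unname(coef(fit)), c(1, -0.03), tolerance = 1e-12)
  # methods are consistent with the underlying lm
  expect_equal(unname(predict(fit)[1]), d$value[1], tolerance = 1e-10)
  expect_equal(unname(suppressWarnings(confint(fit))["slope", 1]), fit$ci[1])
  expect_equal(sum(abs(residuals(fit))), 0, tolerance = 1e-10)
  expect_output(print(fit), "slope: -0.03")
  expect_output(print(suppressWarnings(summary(fit))), "least-squares")
})

test_that("degenerate designs are rejected", {
  expect_error(iop_response(value ~ delta_iop_mmHg,
                            data.frame(delta_iop_mmHg = c(1, 2),
                                       value = c(1, 2))),
               "at least 3")
  expect_error(iop_response(value ~ delta_iop_mmHg,
                            data.frame(delta_iop_mmHg = rep(0, 5),
                                       value = rnorm(5))),
               "one IOP offset")
})

test_that("t-based CI has nominal coverage on noisy linear data", {
  # 5 levels x 3 repeats, height slope -0.85 um/mmHg, noise SD 1 um:
  # the generating slope falls inside the 95% CI in >= 90% of simulations
  d0 <- rep(c(-10, -5, 0, 5, 10), each = 3)
  hits <- withr::with_seed(99, vapply(1:500, function(i) {
    y <- 25 - 0.85 * d0 + rnorm(length(d0), sd = 1)
    ci <- iop_response(y ~ d, data.frame(d = d0, y = y))$ci
    ci[1] <= -0.85 && -0.85 <= ci[2]
  }, logical(1)))
  expect_gte(mean(hits), 0.90)
})

test_that("slope comparison equals the difference of per-group fits", {
  set.seed(4)
  d <- expand.grid(delta_iop_mmHg = rep(c(-10, -5, 0, 5, 10), 3),
                   group = c("a", "b"), stringsAsFactors = FALSE)
  d$value <- ifelse(d$group == "a", 1 - 0.044 * d$delta_iop_mmHg,
                    0.5 - 0.022 * d$delta_iop_mmHg) +
    rnorm(nrow(d), sd = 0.05)
  cmp <- compare_slopes(value ~ delta_iop_mmHg, d)
  fa <- iop_response(value ~ delta_iop_mmHg, d[d$group == "a", ])
  fb <- iop_response(value ~ delta_iop_mmHg, d[d$group == "b", ])
  expect_equal(cmp$slope_a, fa$slope, tolerance = 1e-10)
  expect_equal(cmp$slope_b, fb$slope, tolerance = 1e-10)
  # the interaction estimate is exactly the per-group slope difference
  expect_equal(cmp$delta_slope, fa$slope - fb$slope, tolerance = 1e-10)
  # symmetry: swapping groups negates the difference, p unchanged
  d2 <- d; d2$group <- ifelse(d$group == "a", "b", "a")
  cmp2 <- compare_slopes(value ~ delta_iop_mmHg, d2)
  expect_equal(cmp2$delta_slope, -cmp$delta_slope, tolerance = 1e-10)
  expect_equal(cmp2$p_value, cmp$p_value, tolerance = 1e-10)
})

test_that("identical noiseless groups compare as no difference", {
  d <- expand.grid(delta_iop_mmHg = rep(c(-10, 0, 10), 2),
                   group = c("a", "b"), stringsAsFactors = FALSE)
  d$value <- 1 - 0.03 * d$delta_iop_mmHg
  cmp <- suppressWarnings(compare_slopes(value ~ delta_iop_mmHg, d))
  expect_equal(cmp$delta_slope, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1)
})

test_that("per-level contrasts use the Sidak adjustment", {
  expect_equal(sidak_adjust(0.01, 5), 1 - 0.99^5, tolerance = 1e-15)
  set.seed(6)
  d <- expand.grid(`repeat` = 1:3, delta_iop_mmHg = c(-10, -5, 0, 5, 10),
                   group = c("a", "b"), stringsAsFactors = FALSE)
  # identical groups: every adjusted p is 1 up to floating tolerance
  d$value <- rep(rnorm(15), 2)
  res <- per_level_comparison(d)
  expect_equal(res$p_adj, rep(1, 5), tolerance = 1e-8)
  expect_equal(res$diff, rep(0, 5), tolerance = 1e-12)
  # a 2x baseline offset with small noise is significant at every level
  d$value <- ifelse(d$group == "a", 2, 1) + rnorm(30, sd = 0.05)
  res2 <- per_level_comparison(d)
  expect_true(all(res2$p_adj < 0.05))
  expect_equal(res2$p_adj, sidak_adjust(res2$p_value, 5), tolerance = 1e-12)
  # a level missing from one group is skipped with a warning
  d3 <- d[!(d$group == "b" & d$delta_iop_mmHg == 10), ]
  expect_warning(res3 <- per_level_comparison(d3), "skipping")
  expect_identical(nrow(res3), 4L)
})

test_that("phantom groups at 1x and 0.5x control volume normalize to ~1 and ~0.5", {
  specs <- list(ctl = phantom_spec(n_bscans = 6, noise_px = 0.3),
                mut = phantom_spec(n_bscans = 6, noise_px = 0.3,
                                   height0_um = 12.5,
                                   slope_height_um_per_mmHg = -0.42))
  design <- iop_experiment_design(specs, delta_iop_levels_mmHg = c(-10, 0),
                                  repeats_per_level = 2)
  meas <- analyze_experiment(generate_experiment(design, seed = 21))
  rel <- normalize_relative(meas, "ctl")
  base <- tapply(rel$value[rel$delta_iop_mmHg == 0],
                 rel$group[rel$delta_iop_mmHg == 0], mean)
  expect_equal(unname(base["ctl"]), 1, tolerance = 0.02)
  expect_equal(unname(base["mut"]), 0.5, tolerance = 0.05)
})
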