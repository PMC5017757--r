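quiet <- trace_noise_model(noise_sd = 0)

test_that("peak detection handles flat, single-peak and two-peak traces", {
  flat <- electropherogram("pair43", seq(190, 230, 0.1),
                           rep(0, length(seq(190, 230, 0.1))))
  expect_equal(nrow(detect_peaks(flat)), 0L)

  grid <- seq(250, 290, 0.1)
  height <- 800
  tr <- electropherogram("pair5", grid, height * exp(-(grid - 272)^2 / (2 * 0.4^2)))
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$centroid - 272), 0.1)
  # trapezoid area matches the analytic Gaussian area within 1%
  expect_lt(abs(pk$area / (height * 0.4 * sqrt(2 * pi)) - 1), 0.01)

  pk2 <- detect_peaks(synth_electropherogram(sspal_pair43(), 0.5, quiet))
  expect_equal(nrow(pk2), 2L)
})

test_that("species assignment follows centroid proximity with area tie-break", {
  pk <- data.frame(centroid = c(150.0, 206.3, 211.1),
                   height = c(10, 400, 500), area = c(10, 420, 530),
                   left = c(149, 205, 210), right = c(151, 208, 213),
                   species = "unassigned", stringsAsFactors = FALSE)
  out <- assign_species(pk, sspal_pair43(), tol = 1.5)
  expect_equal(out$species, c("unassigned", "mouse", "human"))
  # two candidates near the mouse size: the larger area wins
  pk2 <- data.frame(centroid = c(205.4, 206.1), height = c(5, 300),
                    area = c(4, 310), left = c(205, 205.8),
                    right = c(205.8, 208), species = "unassigned")
  out2 <- assign_species(pk2, sspal_pair43(), tol = 1.5)
  expect_equal(out2$species, c("unassigned", "mouse"))
  expect_error(assign_species(pk, sspal_pair43(), tol = 2.5), "tol")
})

test_that("fraction estimation is the area ratio with absent peaks as zero", {
  pk <- function(areas, species) {
    data.frame(centroid = c(206, 211)[seq_along(areas)], height = areas,
               area = areas, left = 1, right = 2, species = species)
  }
  expect_equal(estimate_fraction(pk(c(50, 50), c("mouse", "human")))[["mouse"]], 0.5)
  expect_equal(estimate_fraction(pk(c(99.4, 0.6), c("mouse", "human")))[["mouse"]],
               0.994)
  only_human <- pk(80, "human")
  est <- estimate_fraction(only_human)
  expect_equal(est[["mouse"]], 0)
  expect_equal(est[["mouse"]] + est[["human"]], 1)
  expect_error(estimate_fraction(pk(7, "unassigned")), "no amplification")
})

test_that("pair combination averages, censors, and warns on missing pairs", {
  est <- combine_pairs(c(pair5 = 0.994, pair43 = 0.984))
  expect_equal(est$combined, 0.989)
  expect_equal(est$censor_flag, "none")
  expect_equal(combine_pairs(c(pair5 = 0.30))$combined, 0.30)
  expect_equal(combine_pairs(c(pair5 = 0.996, pair43 = 0.998))$censor_flag,
               "above_99pct")
  expect_equal(combine_pairs(c(pair5 = 0.004, pair43 = 0.002))$censor_flag,
               "below_1pct")
  expect_warning(combine_pairs(c(pair5 = 0.5),
                               expected_pairs = c("pair5", "pair43")),
                 "pair43")
  expect_error(combine_pairs(numeric(0)))
})

test_that("origin classification is a strict step function at the threshold", {
  expect_equal(classify_origin(0.989)$verdict, "suspect_mouse")
  expect_equal(classify_origin(0.50)$verdict, "human_tumor")
  expect_equal(classify_origin(0.95)$verdict, "human_tumor")   # strict >
  expect_equal(classify_origin(0.95 + 1e-9)$verdict, "suspect_mouse")
  expect_equal(classify_origin(0.95 - 1e-9)$verdict, "human_tumor")
  expect_error(classify_origin(0.5, threshold = 1), "threshold")
})

test_that("dilution series recovers degenerate and symmetric mixtures", {
  ds0 <- dilution_series(sspal_pair43(), 0, replicates = 3, noise = quiet,
                         seed = 1)
  expect_equal(ds0$mean_estimate, 0)
  expect_equal(ds0$detected_rate, 0)
  ds5 <- dilution_series(sspal_pair43(), 0.5, replicates = 3, noise = quiet,
                         seed = 1)
  expect_equal(ds5$mean_estimate, 0.5)
  expect_equal(ds5$detected_rate, 1)
  expect_error(dilution_series(sspal_pair43(), 0.5, replicates = 0, seed = 1),
               "replicates")
})

test_that("noise-free estimates are monotone in the true fraction", {
  grid <- seq(0.01, 0.99, by = 0.07)
  est <- vapply(grid, function(f)
    quant_trace(synth_electropherogram(sspal_pair43(), f, quiet),
                sspal_pair43())[["mouse"]], numeric(1))
  expect_true(all(diff(est) >= 0))
  expect_true(all(abs(est - grid) < 1e-3))  # noise-free round trip
})

test_that("per-pair fractions always sum to one", {
  for (f in c(0, 0.01, 0.37, 0.99, 1)) {
    est <- quant_trace(synth_electropherogram(sspal_pair5(), f, quiet),
                       sspal_pair5())
    expect_equal(unname(est[["mouse"]] + est[["human"]]), 1)
  }
})

test_that("passage stability summarizes constant, noisy and trending series", {
  const <- passage_series("LX1", 0:2, c(0.3, 0.3, 0.3))
  s <- passage_stability(const)
  expect_equal(s$sd, 0)
  expect_equal(s$range, 0)
  trend <- passage_stability(passage_series("LX2", 0:2, c(0.1, 0.2, 0.3)))
  expect_equal(trend$range, 0.2)
  expect_error(passage_stability(passage_series("LX3", 0, 0.5)), "two passages")
  expect_error(passage_series("LX4", c(0, 0), c(0.1, 0.2)), "increasing")
  # six passages measured at a true fraction of 0.4 under default trace noise
  f <- vapply(1:6, function(p) {
    pars <- vapply(c("pair5", "pair43"), function(pid) {
      loc <- if (pid == "pair5") sspal_pair5() else sspal_pair43()
      nm <- trace_noise_model(seed = derive_seed(2, p * 10 +
                                                   (pid == "pair43")))
      quant_trace(synth_electropherogram(loc, 0.4, nm), loc)[["mouse"]]
    }, numeric(1))
    combine_pairs(pars)$combined
  }, numeric(1))
  s6 <- passage_stability(passage_series("LX5", 1:6, f))
  expect_lte(s6$range, 0.05)
})

test_that("cohort summaries report per-line values and group means", {
  one <- cohort_summary(data.frame(line_id = "A", mouse_fraction = 0.4,
                                   histology = "LUAD"))
  expect_equal(nrow(one$lines), 1L)
  expect_equal(one$groups$mean_fraction, 0.4)
  two <- cohort_summary(data.frame(
    line_id = c("A", "B", "C", "D"),
    mouse_fraction = c(0.1, 0.2, 0.6, 0.8),
    histology = c("SCLC", "SCLC", "LUAD", "LUAD")))
  expect_equal(sort(two$groups$mean_fraction), c(0.15, 0.7))
  expect_s3_class(two$test, "htest")
})

test_that("the four-line origin panel all exceed 94% combined mouse fraction", {
  panel <- pdx_origin_panel()
  combined <- vapply(split(panel, panel$line_id), function(g)
    combine_pairs(setNames(g$mouse_fraction, g$pair_id))$combined, numeric(1))
  expect_equal(length(combined), 4L)
  expect_true(all(combined > 0.94))
})
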