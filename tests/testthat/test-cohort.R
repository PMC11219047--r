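test_that("cohort generation is fully determined by the configuration", {
  cfg <- cohort_preset("rat", seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  c2 <- generate_cohort(cohort_preset("rat", seed = 12))
  expect_false(identical(a, c2))
  # generation restores the caller's RNG state
  set.seed(500); before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(before, .Random.seed)
})

test_that("cohort structure matches the declared data model", {
  co <- generate_cohort(cohort_preset("mouse", seed = 3))
  expect_s3_class(co, "cavalus_cohort")
  expect_equal(nrow(co), 13 + 26)
  expect_equal(sum(co$group == "control"), 13)
  expect_true(all(co$group %in% c("control", "hf")))
  expect_true(all(co$sex %in% c("male", "female")))
  expect_true(all(co$ivc_diameter_max > 0, na.rm = TRUE))
  both <- is.finite(co$ivc_diameter_max) & is.finite(co$ivc_diameter_min)
  expect_true(all(co$ivc_diameter_min[both] <= co$ivc_diameter_max[both]))
  expect_true(all(co$b_line_profile %in% 0:3, na.rm = TRUE))
  expect_true(all(co$lung_sliding == "not_assessable"))  # mice
  expect_true(all(co$lvef >= 0 & co$lvef <= 100, na.rm = TRUE))
  expect_true(all(co$vcci >= 0 & co$vcci <= 1, na.rm = TRUE))
  expect_true(all(co$w2d > 1, na.rm = TRUE))
})

test_that("a null configuration plants no signal", {
  cfg <- cohort_preset("rat", seed = 5, severity_shift = 0,
                       hf_mixture_delta = 0, missingness = numeric(0),
                       n_control = 150, n_hf = 150)
  co <- generate_cohort(cfg)
  # finding distributions exchangeable between labels: the group comparison
  # of the composite should be unremarkable
  rub <- default_rubric("rat")
  sc <- composite_scores(co, rub, c("ivc", "b_line_profile", "pleural_defects"))
  g <- compare_groups(sc$total_points[sc$group == "control"],
                      sc$total_points[sc$group == "hf"])
  expect_gt(g$p_value, 0.001)
})

test_that("the rat preset plants an IVC diameter shift", {
  hits <- 0
  for (s in 1:20) {
    co <- generate_cohort(cohort_preset("rat", seed = s))
    mw <- mann_whitney(co$ivc_diameter_max[co$group == "hf"],
                       co$ivc_diameter_max[co$group == "control"])
    hits <- hits + (mw$U > 23 * 23 / 2 && mw$p_value / 2 < 0.05)
  }
  expect_gte(hits, 18)
})

test_that("expected component points rise with latent severity", {
  cfg <- cohort_preset("rat", seed = 77, n_control = 2000, n_hf = 2000,
                       missingness = numeric(0))
  co <- generate_cohort(cfg)
  rub <- default_rubric("rat")
  cal <- ivc_calibration(co)
  bins <- cut(co$latent_severity, quantile(co$latent_severity, 0:10 / 10),
              include.lowest = TRUE)
  for (comp in c("ivc", "b_line_profile", "pleural_defects",
                 "pleural_thickening")) {
    pts <- score_component(co, rub, comp, cal)
    means <- tapply(pts, bins, mean, na.rm = TRUE)
    # non-decreasing up to simulation noise
    expect_true(all(diff(means) > -0.02),
                info = sprintf("component %s", comp))
  }
})

test_that("apply_missingness is MCAR with the stated probabilities", {
  co <- generate_cohort(cohort_preset("rat", seed = 9, missingness = numeric(0)))
  # zero probabilities are a no-op
  expect_identical(apply_missingness(co, c(lvef = 0), seed = 1), co)
  # probability one wipes the field
  out <- apply_missingness(co, c(w2d = 1), seed = 1)
  expect_true(all(is.na(out$w2d)))
  # identity fields are protected
  out <- apply_missingness(co, c(animal_id = 1, lvef = 0.5), seed = 1)
  expect_false(anyNA(out$animal_id))
  expect_error(apply_missingness(co, c(lvef = 1.2), seed = 1), "\\[0, 1\\]")

  # binomial check: 1000 records at p = 0.3, count inside the central
  # 99.9% interval of Binomial(1000, 0.3)
  big <- cohort_preset("rat", seed = 10, n_control = 500, n_hf = 500,
                       missingness = numeric(0))
  bco <- generate_cohort(big)
  miss <- apply_missingness(bco, c(lw = 0.3), seed = 4)
  n_missing <- sum(is.na(miss$lw)) - sum(is.na(bco$lw))
  expect_gte(n_missing, qbinom(0.0005, 1000, 0.3))
  expect_lte(n_missing, qbinom(0.9995, 1000, 0.3))
})

test_that("observer rescoring reproduces the rubric at zero noise", {
  co <- generate_cohort(cohort_preset("rat", seed = 15))
  rub <- default_rubric("rat")
  comps <- c("ivc", "b_line_profile", "pleural_defects", "pleural_thickening")
  tab <- simulate_observer_rescoring(co, rub, n_observers = 3, noise_sd = 0,
                                     seed = 2, components = comps)
  # observer 1 has two passes; everyone else one
  expect_equal(sort(unique(tab$observer_id)), 1:3)
  expect_equal(sort(unique(tab$pass[tab$observer_id == 1])), 1:2)
  cal <- ivc_calibration(co)
  base <- score_component(co, rub, "b_line_profile", cal)
  for (obs in 1:3) {
    got <- tab$points[tab$observer_id == obs & tab$pass == 1 &
                        tab$component == "b_line_profile"]
    expect_equal(got, base)
  }
  tot <- observer_totals(tab, comps)
  rep <- agreement_report(tot)
  expect_true(all(rep$r == 1))
  expect_true(all(rep$bias == 0))
  expect_true(all(rep$loa_low == 0 & rep$loa_high == 0))
})

test_that("observer noise is clipped, deterministic, and centred", {
  co <- generate_cohort(cohort_preset("rat", seed = 16))
  rub <- default_rubric("rat")
  comps <- c("b_line_profile", "pleural_defects")
  t1 <- simulate_observer_rescoring(co, rub, 3, 0.5, seed = 3, components = comps)
  t2 <- simulate_observer_rescoring(co, rub, 3, 0.5, seed = 3, components = comps)
  expect_identical(t1, t2)
  expect_true(all(t1$points[t1$component == "b_line_profile"] %in% 0:3))
  expect_true(all(t1$points[t1$component == "pleural_defects"] %in% 0:2))
  expect_error(simulate_observer_rescoring(co, rub, 3, -0.1, seed = 1),
               "nonnegative")

  # intra-observer differences centred at zero (CLT band over pooled passes)
  tot <- observer_totals(
    simulate_observer_rescoring(co, rub, 1, 0.5, seed = 4, components = comps),
    comps)
  p1 <- tot$total_points[tot$pass == 1]
  p2 <- tot$total_points[tot$pass == 2]
  d <- p1 - p2
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1e-9)
})

test_that("config validation names the offending field", {
  expect_error(cohort_preset("rat", n_control = 1), "n_control")
  expect_error(cohort_preset("rat", observer_noise_sd = -1), "observer_noise_sd")
  expect_error(cohort_preset("rat", component_loadings = c(
    ivc = 1.5, b_line_profile = .5, pleural_effusion = 0, pleural_defects = .5,
    pleural_thickening = .5, lung_sliding = 0)), "component_loadings")
  expect_error(cohort_preset("rat", missingness = c(lvef = 2)), "missingness")
  expect_error(cohort_preset("rat", hf_mixture_delta = 1.2), "hf_mixture_delta")
})

test_that("cohorts round-trip through the delimited format exactly", {
  co <- generate_cohort(cohort_preset("mouse", seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(as.data.frame(back), as.data.frame(co))
})
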