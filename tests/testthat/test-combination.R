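test_that("enumerate_combinations counts and orders subsets canonically", {
  comps <- c("ivc", "b_line_profile", "pleural_effusion", "pleural_defects",
             "pleural_thickening", "lung_sliding")
  all63 <- enumerate_combinations(comps)
  expect_length(all63, 63)
  expect_length(enumerate_combinations("ivc"), 1)
  expect_length(enumerate_combinations(comps, must_include = "ivc"), 32)
  # canonical: sizes non-decreasing, singletons in input order first
  sizes <- vapply(all63, length, integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_identical(all63[[1]], "ivc")
  expect_identical(all63[[7]], c("ivc", "b_line_profile"))
  expect_error(enumerate_combinations(character(0)))
  expect_error(enumerate_combinations(comps, must_include = "nope"))
})

test_that("score_correlation_matrix matches a naive reimplementation exactly", {
  # four components, all 15 subsets, against four metrics
  cfg <- cohort_preset("rat", seed = 31, missingness = c(lvef = 0.2, lw = 0.3))
  co <- generate_cohort(cfg)
  rub <- default_rubric("rat")
  cal <- ivc_calibration(co)
  comps <- c("ivc", "b_line_profile", "pleural_defects", "pleural_thickening")
  subsets <- enumerate_combinations(comps)
  metrics <- c("lvef", "tapse", "lw", "w2d")
  m <- score_correlation_matrix(co, rub, subsets, metrics = metrics,
                                calibration = cal)

  score_list <- lapply(subsets, function(s) {
    sc <- composite_scores(co, rub, s, calibration = cal)
    ifelse(sc$valid, sc$total_points, NA_real_)
  })
  oracle <- oracle_corr_ranks(score_list, co[metrics])
  expect_equal(unname(m$r), unname(oracle$r), tolerance = 1e-12)
  expect_equal(unname(m$ranks), unname(oracle$ranks))
  expect_equal(unname(m$overall_rank), unname(oracle$overall))

  # midrank validity: computable ranks in each metric sum to n(n+1)/2
  for (j in seq_along(metrics)) {
    rk <- m$ranks[, j]
    rk <- rk[!is.na(rk)]
    expect_equal(sum(rk), length(rk) * (length(rk) + 1) / 2)
  }
})

test_that("a perfectly coupled singleton attains rank one everywhere", {
  # hand-built cohort: pleural_defects tracks severity deterministically and
  # one metric equals severity; all other findings are noise
  set.seed(41)
  n <- 60
  sev <- rnorm(n, 0, 2)
  co <- tiny_cohort(ivc = runif(n, 2.5, 3.5),
                    b = sample(0:3, n, TRUE),
                    eff = sample(0:2, n, TRUE),
                    def = pmin(pmax(floor(sev), 0), 2),
                    thick = sample(0:2, n, TRUE),
                    sliding = sample(c("present", "lung_pulse", "absent"),
                                     n, TRUE),
                    group = rep(c("control", "hf"), n / 2),
                    id = sprintf("x%03d", 1:n))
  co$sevmetric <- sev
  rub <- default_rubric("rat")
  subsets <- enumerate_combinations(names(rub$components))
  m <- score_correlation_matrix(co, rub, subsets, metrics = "sevmetric",
                                calibration = fixed_calibration,
                                min_metrics = 1)
  expect_equal(m$ranks["pleural_defects", "sevmetric"], 1)
})

test_that("degenerate metrics and record order do not disturb the matrix", {
  co <- generate_cohort(cohort_preset("rat", seed = 33, missingness = numeric(0)))
  co$flat <- 5  # zero-variance metric
  rub <- default_rubric("rat")
  cal <- ivc_calibration(co)
  subsets <- enumerate_combinations(c("ivc", "b_line_profile", "pleural_defects"))
  m <- score_correlation_matrix(co, rub, subsets, metrics = c("lvef", "flat"),
                                calibration = cal, min_metrics = 1)
  expect_true(all(is.na(m$r[, "flat"])))
  expect_true(all(m$n_metrics_used <= 1))

  shuffled <- co[sample(nrow(co)), ]
  m2 <- score_correlation_matrix(shuffled, rub, subsets,
                                 metrics = c("lvef", "flat"),
                                 calibration = cal, min_metrics = 1)
  expect_equal(m$r, m2$r)
  expect_equal(m$overall_rank, m2$overall_rank)
})

test_that("select_top_k is deterministic with documented tie-breaks", {
  co <- generate_cohort(cohort_preset("rat", seed = 34))
  rub <- default_rubric("rat")
  subsets <- enumerate_combinations(c("ivc", "b_line_profile", "pleural_defects"))
  m <- score_correlation_matrix(co, rub, subsets)
  all7 <- select_top_k(m, k = 7)
  expect_length(all7, 7)
  expect_warning(select_top_k(m, k = 50), "returning all")

  # hand-built matrix with a tie at the boundary: smaller subset kept
  fake <- structure(list(
    subsets = list("a", c("a", "b"), c("a", "b", "c")),
    labels = c("a", "a+b", "a+b+c"),
    metrics = "m",
    overall_rank = c(a = 2, `a+b+c` = 1.5, `a+b` = 1.5)[c("a", "a+b", "a+b+c")],
    n_metrics_used = c(1L, 1L, 1L)), class = "cavalus_corr_matrix")
  # at k = 1 the boundary tie between a+b and a+b+c resolves to the smaller
  picked <- select_top_k(fake, k = 1)
  expect_identical(vapply(picked, paste, character(1), collapse = "+"), "a+b")
  picked2 <- select_top_k(fake, k = 2)
  expect_identical(vapply(picked2, paste, character(1), collapse = "+"),
                   c("a+b", "a+b+c"))
})

test_that("select_winner maximizes Youden's J over the shortlist", {
  co <- generate_cohort(cohort_preset("rat", seed = 35))
  rub <- default_rubric("rat")
  cal <- ivc_calibration(co)
  pl4 <- c("ivc", "b_line_profile", "pleural_defects", "pleural_thickening")

  # shortlist of one wins trivially with its own cutoff
  sel1 <- select_winner(co, rub, list(pl4), calibration = cal)
  expect_identical(sel1$winner, pl4)
  roc1 <- roc_curve(
    composite_scores(co, rub, pl4, cal)$total_points,
    as.integer(co$group == "hf"))
  expect_equal(sel1$winner_j, roc1$j_at_optimal)
  expect_equal(sel1$winner_cutoff, roc1$optimal_cutoff)

  # winner J is the max over the shortlist
  shortlist <- list(pl4, c("ivc", "b_line_profile"), "pleural_defects")
  sel <- select_winner(co, rub, shortlist, calibration = cal)
  js <- vapply(shortlist, function(s) {
    sc <- composite_scores(co, rub, s, cal)
    roc_curve(sc$total_points[sc$valid],
              as.integer(sc$group[sc$valid] == "hf"))$j_at_optimal
  }, numeric(1))
  expect_equal(sel$winner_j, max(js))
})

test_that("subsets without valid scores are excluded with a reason", {
  co <- generate_cohort(cohort_preset("mouse", seed = 36))
  rub <- default_rubric("mouse")
  # lung sliding is not assessable in mice: any subset containing it has no
  # valid composite and must be dropped, not crash
  subsets <- list(c("ivc", "b_line_profile"), "lung_sliding")
  expect_message(
    m <- score_correlation_matrix(co, rub, subsets, min_metrics = 1),
    "lung_sliding")
  expect_true(is.na(m$overall_rank["lung_sliding"]))
  expect_message(
    sel <- select_winner(co, rub, subsets),
    "skipping lung_sliding")
  expect_identical(sel$winner, c("ivc", "b_line_profile"))
})

test_that("the full development pipeline recovers a strongly planted set", {
  # single-seed end-to-end sanity (the multi-seed recovery rates live in the
  # acceptance suite)
  co <- generate_cohort(cohort_preset("rat", seed = 2))
  rub <- default_rubric("rat")
  cal <- ivc_calibration(co)
  subsets <- enumerate_combinations(names(rub$components), must_include = "ivc")
  m <- score_correlation_matrix(co, rub, subsets, calibration = cal)
  sl <- select_top_k(m, 7)
  sel <- select_winner(co, rub, sl, calibration = cal)
  expect_gt(sel$winner_j, 0.5)
  expect_true(all(c("ivc", "b_line_profile") %in% sel$winner))
})
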