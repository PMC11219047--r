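#' Configuration for a synthetic congestion cohort
#'
#' The generator follows a single-factor latent model: each animal carries a
#' latent congestion severity (unit variance, group mean 0 for controls and
#' `severity_shift` for heart-failure animals). Every ultrasound component
#' and reference metric couples to severity through a loading in \[0, 1\]
#' (components) or a signed loading (metrics): the observed latent for a
#' component is `loading * severity + sqrt(1 - loading^2) * noise`, so the
#' control-group marginal stays standard normal regardless of the loading.
#' Ordinal grades arise by thresholding that latent at fixed cutpoints;
#' the IVC diameter is linear in it; reference metrics are
#' `mean + sd * (loading * severity + sqrt(1 - loading^2) * noise)`.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param n_control,n_hf group sizes (each >= 2).
#' @param severity_shift latent-severity mean difference (HF minus control)
#'   in latent SD units.
#' @param component_loadings named numeric vector in \[0, 1\] over the six
#'   ultrasound components.
#' @param cutpoints named list of ascending latent-scale cutpoints per
#'   ordinal/categorical component (grade g is assigned when the latent
#'   exceeds the g-th cutpoint).
#' @param ivc_mean_mm,ivc_beta_mm baseline maximum IVC diameter and its
#'   slope (mm per latent SD).
#' @param metric_baselines data frame with columns `metric`, `mean`, `sd`,
#'   `loading` for the echocardiographic and gravimetric reference metrics
#'   (VCCI is derived from the simulated diameters, not listed here).
#' @param hf_mixture_delta heterogeneity of the diseased group: HF severity
#'   is drawn from an equal two-component normal mixture centred at
#'   `severity_shift +/- hf_mixture_delta` with component SD
#'   `sqrt(1 - hf_mixture_delta^2)`, keeping unit total variance. `0`
#'   (default for plain configs) gives a homogeneous normal HF group; the
#'   species presets use a positive value to emulate cohorts pooling
#'   earlier- and later-stage disease.
#' @param lung_sliding_assessable if `FALSE`, lung sliding is recorded as
#'   `not_assessable` for every animal (the mouse situation).
#' @param missingness named probabilities in \[0, 1\] of each field being
#'   missing (missing completely at random); applied by [apply_missingness()].
#' @param female_prop proportion of females (metadata only).
#' @param observer_noise_sd default per-observer per-component jitter SD
#'   used by [simulate_observer_rescoring()].
#' @param n_observers default number of observers.
#' @param seed integer seed; fully determines the cohort.
#' @return An object of class `cavalus_config` (a validated list).
#' @seealso [cohort_preset()] for ready-made rat and mouse configurations.
#' @export
cohort_config <- function(species = c("rat", "mouse"),
                          n_control, n_hf, severity_shift,
                          component_loadings,
                          cutpoints = default_cutpoints(),
                          ivc_mean_mm, ivc_beta_mm,
                          metric_baselines,
                          hf_mixture_delta = 0,
                          lung_sliding_assessable = TRUE,
                          missingness = numeric(0),
                          female_prop = 0,
                          observer_noise_sd = 0.5,
                          n_observers = 3L,
                          seed = 1L) {
  species <- match.arg(species)
  if (!is.numeric(n_control) || n_control < 2 || n_control != floor(n_control)) {
    stop("n_control must be an integer >= 2")
  }
  if (!is.numeric(n_hf) || n_hf < 2 || n_hf != floor(n_hf)) {
    stop("n_hf must be an integer >= 2")
  }
  if (!is.finite(severity_shift)) stop("severity_shift must be finite")
  comps <- c("ivc", "b_line_profile", "pleural_effusion", "pleural_defects",
             "pleural_thickening", "lung_sliding")
  if (!all(comps %in% names(component_loadings))) {
    stop("component_loadings must name all of: ", paste(comps, collapse = ", "))
  }
  cl <- component_loadings[comps]
  if (any(!is.finite(cl)) || any(cl < 0 | cl > 1)) {
    stop("component_loadings must be finite and in [0, 1]")
  }
  check_prob(unlist(missingness), "missingness")
  check_prob(female_prop, "female_prop")
  if (!is.numeric(observer_noise_sd) || observer_noise_sd < 0) {
    stop("observer_noise_sd must be nonnegative")
  }
  if (n_observers < 1) stop("n_observers must be >= 1")
  stopifnot(is.data.frame(metric_baselines),
            all(c("metric", "mean", "sd", "loading") %in% names(metric_baselines)))
  if (any(!is.finite(metric_baselines$loading)) ||
      any(abs(metric_baselines$loading) > 1)) {
    stop("metric loadings must be finite and in [-1, 1]")
  }
  if (ivc_mean_mm <= 0 || ivc_beta_mm < 0) {
    stop("ivc_mean_mm must be positive and ivc_beta_mm nonnegative")
  }
  if (!is.finite(hf_mixture_delta) || hf_mixture_delta < 0 ||
      hf_mixture_delta >= 1) {
    stop("hf_mixture_delta must lie in [0, 1)")
  }
  structure(list(species = species, n_control = as.integer(n_control),
                 n_hf = as.integer(n_hf), severity_shift = severity_shift,
                 component_loadings = cl, cutpoints = cutpoints,
                 hf_mixture_delta = hf_mixture_delta,
                 ivc_mean_mm = ivc_mean_mm, ivc_beta_mm = ivc_beta_mm,
                 metric_baselines = metric_baselines,
                 lung_sliding_assessable = lung_sliding_assessable,
                 missingness = unlist(missingness),
                 female_prop = female_prop,
                 observer_noise_sd = observer_noise_sd,
                 n_observers = as.integer(n_observers),
                 seed = as.integer(seed)),
            class = "cavalus_config")
}

#' Default latent-scale cutpoints for ordinal findings
#'
#' Grade g is assigned when the component latent (standard normal in
#' controls) exceeds the g-th cutpoint. Under the defaults roughly 5% of
#' healthy animals show grade-1 B-lines, pleural defects or thickening
#' (grade 2 is essentially a diseased-animal finding), pleural effusion is
#' vanishingly rare in health, and lung sliding presents as a ubiquitous
#' lung pulse (its cutpoints put almost all animals in the middle
#' category).
#'
#' @return named list of ascending numeric cutpoints.
#' @export
default_cutpoints <- function() {
  list(b_line_profile = c(1.645, 2.6, 3.2),
       pleural_effusion = c(5, 6),
       pleural_defects = c(1.645, 2.6),
       pleural_thickening = c(1.645, 2.6),
       lung_sliding = c(-4, 5))
}

#' Reference-metric baseline tables for the species presets
#'
#' Typical resting values (mean, between-animal SD) for adult animals and
#' the signed severity loadings used by the presets. Systolic-function
#' metrics load negatively (they fall with congestion severity), volumes and
#' gravimetric congestion metrics positively. Magnitudes are the package's
#' own qualitative calibration: stronger and broader couplings in the
#' pressure-overload rat preset, attenuated right-heart couplings in the
#' mouse infarct preset.
#'
#' @param species `"rat"` or `"mouse"`.
#' @return data frame with columns `metric`, `mean`, `sd`, `loading`.
#' @export
metric_baseline_table <- function(species = c("rat", "mouse")) {
  species <- match.arg(species)
  if (species == "rat") {
    tab <- rbind(
      c("lvef",      70,   8,   -0.70),
      c("lvfs",      40,   6,   -0.65),
      c("sv",       210,  35,   -0.60),
      c("co",        75,  12,   -0.55),
      c("edv",      450,  80,    0.40),
      c("esv",      150,  60,    0.65),
      c("hr",       360,  35,   -0.15),
      c("lvds",       4.0, 0.8,  0.60),
      c("lvdd",       7.5, 0.8,  0.35),
      c("tapse",      2.4, 0.4, -0.60),
      c("rvfs",      45,   8,   -0.65),
      c("rvds",       2.2, 0.5,  0.50),
      c("rvdd",       3.6, 0.5,  0.40),
      c("asc_aov",  900, 150,   -0.30),
      c("desc_aov", 700, 150,    0.70),
      c("pat",       22,   4,   -0.50),
      c("pet",       70,   8,    0.30),
      c("lw",      1600, 250,    0.70),
      c("w2d",        4.9, 0.25, 0.65),
      c("hw_bw",      3.2, 0.4,  0.60),
      c("lv_bw",      2.2, 0.3,  0.55),
      c("rv_bw",      0.6, 0.12, 0.60),
      c("rv_lv",      0.27, 0.05, 0.50)
    )
  } else {
    tab <- rbind(
      c("lvef",      60,   8,   -0.70),
      c("lvfs",      32,   5,   -0.65),
      c("sv",        35,   6,   -0.50),
      c("co",        18,   3,   -0.45),
      c("edv",       60,  12,    0.65),
      c("esv",       25,  10,    0.70),
      c("hr",       480,  40,   -0.10),
      c("lvds",       2.8, 0.5,  0.60),
      c("lvdd",       4.0, 0.4,  0.50),
      c("tapse",      1.2, 0.2, -0.45),
      c("rvfs",      30,   6,   -0.40),
      c("rvds",       1.5, 0.3,  0.35),
      c("rvdd",       2.4, 0.3,  0.30),
      c("asc_aov", 1000, 150,   -0.30),
      c("desc_aov", 650, 100,   -0.25),
      c("pat",       15,   3,   -0.35),
      c("pet",       50,   6,    0.20),
      c("lw",       180,  30,    0.55),
      c("w2d",        4.8, 0.25, 0.60),
      c("hw_bw",      5.5, 0.7,  0.50),
      c("lv_bw",      3.5, 0.5,  0.45),
      c("rv_bw",      0.9, 0.15, 0.40),
      c("rv_lv",      0.26, 0.05, 0.30)
    )
  }
  data.frame(metric = tab[, 1],
             mean = as.numeric(tab[, 2]),
             sd = as.numeric(tab[, 3]),
             loading = as.numeric(tab[, 4]),
             stringsAsFactors = FALSE)
}

#' Species preset configurations
#'
#' Ready-made cohort configurations emulating the two study designs the
#' package targets. Both model the diseased group as a two-stage severity
#' mixture (earlier- and later-stage disease pooled in one cohort) and plant
#' a species-specific informative component set; the remaining components
#' carry realistic but diagnostically inert patterns (pleural effusion is a
#' rare late-stage finding, a lung pulse is near-ubiquitous in rats and lung
#' sliding is not assessable in mice), so that the planted combination is
#' the distinctly best-performing score.
#'
#' * `"rat"`: pressure-overload heart failure, 23 sham vs 23 banded
#'   animals, severity shift 4.75 with stage spread 0.9; informative set
#'   \{IVC dilation, B-line profile, pleural defects, pleural thickening\}.
#' * `"mouse"`: myocardial infarction, 13 controls vs 26 infarcted animals,
#'   attenuated congestion (shift 4, weaker IVC coupling); informative set
#'   \{IVC dilation, B-line profile, pleural defects\}; pleural thickening
#'   adds no diagnostic value and lung sliding is not assessable.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param ... overrides passed on to [cohort_config()] (e.g. `seed`,
#'   `severity_shift`, `n_control`).
#' @return A `cavalus_config`.
#' @examples
#' cfg <- cohort_preset("rat", seed = 42)
#' cohort <- generate_cohort(cfg)
#' @export
cohort_preset <- function(species = c("rat", "mouse"), ...) {
  species <- match.arg(species)
  echo_metrics <- c("lvef", "lvfs", "sv", "co", "edv", "esv", "hr", "lvds",
                    "lvdd", "tapse", "rvfs", "rvds", "rvdd", "asc_aov",
                    "desc_aov", "pat", "pet")
  miss <- c(stats::setNames(rep(0.10, length(echo_metrics)), echo_metrics),
            vcci = 0.15, ivc_diameter_min = 0.15,
            lw = 0.30, w2d = 0.30, hw_bw = 0.30, lv_bw = 0.30,
            rv_bw = 0.30, rv_lv = 0.30)
  if (species == "rat") {
    defaults <- list(
      species = "rat", n_control = 23L, n_hf = 23L, severity_shift = 4.75,
      hf_mixture_delta = 0.9,
      component_loadings = c(ivc = 0.40, b_line_profile = 0.50,
                             pleural_effusion = 0, pleural_defects = 0.50,
                             pleural_thickening = 0.50, lung_sliding = 0),
      ivc_mean_mm = 2.1, ivc_beta_mm = 0.65,
      metric_baselines = metric_baseline_table("rat"),
      lung_sliding_assessable = TRUE,
      missingness = miss, female_prop = 0)
  } else {
    defaults <- list(
      species = "mouse", n_control = 13L, n_hf = 26L, severity_shift = 4,
      hf_mixture_delta = 0.9,
      component_loadings = c(ivc = 0.35, b_line_profile = 0.50,
                             pleural_effusion = 0, pleural_defects = 0.50,
                             pleural_thickening = 0, lung_sliding = 0),
      ivc_mean_mm = 1.0, ivc_beta_mm = 0.15,
      metric_baselines = metric_baseline_table("mouse"),
      lung_sliding_assessable = FALSE,
      missingness = miss, female_prop = 0.6)
  }
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

#' Names of the reference-metric columns in a cohort
#'
#' @param cohort a cohort data frame.
#' @return character vector of echo/gravimetric metric columns present.
#' @export
reference_metrics <- function(cohort) {
  all_metrics <- c("lvef", "lvfs", "sv", "co", "edv", "esv", "hr", "lvds",
                   "lvdd", "tapse", "rvfs", "rvds", "rvdd", "vcci", "asc_aov",
                   "desc_aov", "pat", "pet",
                   "lw", "w2d", "hw_bw", "lv_bw", "rv_bw", "rv_lv")
  intersect(all_metrics, names(cohort))
}

#' Generate a synthetic cohort
#'
#' Draws `n_control + n_hf` animals under the latent single-factor model
#' described in [cohort_config()], then applies the configured MCAR
#' missingness. The seed in the configuration fully determines the output:
#' identical configurations yield identical cohorts.
#'
#' @param config a `cavalus_config`.
#' @return A data frame of class `cavalus_cohort`, one row per animal, with
#'   identity columns (`animal_id`, `species`, `sex`, `group`,
#'   `latent_severity`), ultrasound findings (`ivc_diameter_max`,
#'   `ivc_diameter_min`, `b_line_profile`, `pleural_effusion`,
#'   `pleural_defects`, `pleural_thickening`, `lung_sliding`) and the
#'   reference-metric columns of [reference_metrics()]. Missing values are
#'   `NA`, never zero.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cavalus_config"))
  n <- config$n_control + config$n_hf
  group <- rep(c("control", "hf"), c(config$n_control, config$n_hf))
  cohort <- with_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < config$female_prop, "female", "male")
    hf <- group == "hf"
    delta <- config$hf_mixture_delta
    # controls: standard normal; HF: unit-variance two-stage mixture around
    # the severity shift (delta = 0 collapses to a plain normal)
    stage <- ifelse(stats::runif(n) < 0.5, -delta, delta)
    severity <- ifelse(hf,
                       config$severity_shift + stage +
                         stats::rnorm(n, 0, sqrt(1 - delta^2)),
                       stats::rnorm(n))

    latent_of <- function(loading) {
      loading * severity + sqrt(max(0, 1 - loading^2)) * stats::rnorm(n)
    }
    grade_of <- function(latent, cutpoints) {
      findInterval(latent, cutpoints)
    }

    cl <- config$component_loadings
    lat_ivc <- latent_of(cl[["ivc"]])
    d_max <- pmax(config$ivc_mean_mm + config$ivc_beta_mm * lat_ivc,
                  0.2 * config$ivc_mean_mm)
    # congested IVC collapses less with respiration
    vcci <- clamp(0.45 - 0.10 * lat_ivc + stats::rnorm(n, 0, 0.07), 0.02, 0.90)
    d_min <- d_max * (1 - vcci)

    b_line <- grade_of(latent_of(cl[["b_line_profile"]]),
                       config$cutpoints$b_line_profile)
    eff <- grade_of(latent_of(cl[["pleural_effusion"]]),
                    config$cutpoints$pleural_effusion)
    def <- grade_of(latent_of(cl[["pleural_defects"]]),
                    config$cutpoints$pleural_defects)
    thick <- grade_of(latent_of(cl[["pleural_thickening"]]),
                      config$cutpoints$pleural_thickening)
    if (config$lung_sliding_assessable) {
      lat_ls <- latent_of(cl[["lung_sliding"]])
      sliding <- c("present", "lung_pulse", "absent")[
        1L + grade_of(lat_ls, config$cutpoints$lung_sliding)]
    } else {
      sliding <- rep("not_assessable", n)
    }

    out <- data.frame(
      animal_id = sprintf("%s_%03d", config$species, seq_len(n)),
      species = config$species, sex = sex, group = group,
      latent_severity = severity,
      ivc_diameter_max = d_max, ivc_diameter_min = d_min,
      b_line_profile = as.integer(b_line),
      pleural_effusion = as.integer(eff),
      pleural_defects = as.integer(def),
      pleural_thickening = as.integer(thick),
      lung_sliding = sliding,
      stringsAsFactors = FALSE)

    mb <- config$metric_baselines
    for (i in seq_len(nrow(mb))) {
      lam <- mb$loading[i]
      v <- mb$mean[i] + mb$sd[i] * (lam * severity +
                                      sqrt(max(0, 1 - lam^2)) * stats::rnorm(n))
      v <- switch(mb$metric[i],
                  lvef = , lvfs = , rvfs = clamp(v, 0.5, 100),
                  w2d = pmax(v, 1.01),
                  pmax(v, 0.01 * mb$mean[i]))
      out[[mb$metric[i]]] <- v
    }
    out$vcci <- compute_vcci(out$ivc_diameter_max, out$ivc_diameter_min)
    out
  })
  class(cohort) <- c("cavalus_cohort", "data.frame")
  if (length(config$missingness)) {
    cohort <- apply_missingness(cohort, config$missingness,
                                seed = derive_seed(config$seed, "missingness"))
  }
  cohort
}

#' Apply missing-completely-at-random field deletion
#'
#' Each eligible field is independently set missing with its stated
#' probability. Identity fields (`animal_id`, `species`, `group`) are never
#' removed. Deterministic given the seed.
#'
#' @param cohort a cohort data frame.
#' @param missingness named vector of probabilities in \[0, 1\]; names are
#'   cohort columns (unknown names are ignored with a warning).
#' @param seed integer seed.
#' @return The cohort with `NA`s inserted.
#' @export
apply_missingness <- function(cohort, missingness, seed) {
  missingness <- unlist(missingness)
  check_prob(missingness, "missingness")
  protected <- c("animal_id", "species", "group")
  fields <- setdiff(names(missingness), protected)
  unknown <- setdiff(fields, names(cohort))
  if (length(unknown)) {
    warning("missingness names not in cohort, ignored: ",
            paste(unknown, collapse = ", "))
    fields <- intersect(fields, names(cohort))
  }
  with_seed(seed, {
    for (f in sort(fields)) {  # fixed order => reproducible draws
      p <- missingness[[f]]
      if (p <= 0) next
      drop <- stats::runif(nrow(cohort)) < p
      cohort[[f]][drop] <- NA
    }
    cohort
  })
}

#' Simulate multi-observer rescoring of a cohort
#'
#' Emulates several observers independently re-grading the same recordings:
#' for each observer and animal, every component's rubric points are
#' perturbed by integer-rounded Gaussian noise and clipped to the
#' component's valid point range. Observer 1 is rescored twice (two passes
#' with independent noise) to support intra-observer agreement analysis.
#' Missing component points stay missing.
#'
#' @param cohort a cohort data frame.
#' @param rubric a `cavalus_rubric`.
#' @param n_observers number of observers (>= 2 for inter-observer use).
#' @param noise_sd nonnegative jitter SD on the point scale.
#' @param seed integer seed.
#' @param calibration IVC calibration; derived from the cohort's control
#'   group when needed and not supplied.
#' @param components components to rescore (default: all in the rubric).
#' @return Long-format data frame with columns `animal_id`, `observer_id`,
#'   `pass`, `component`, `points`.
#' @export
simulate_observer_rescoring <- function(cohort, rubric, n_observers = 3L,
                                        noise_sd = 0.5, seed = 1L,
                                        calibration = NULL,
                                        components = names(rubric$components)) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (n_observers < 1) stop("n_observers must be >= 1")
  if (is.null(calibration) && "ivc" %in% components &&
      rubric$components$ivc$rule$mode == "calibrated") {
    calibration <- ivc_calibration(cohort)
  }
  base <- lapply(components, function(cn) {
    score_component(cohort, rubric, cn, calibration)
  })
  names(base) <- components
  maxp <- vapply(rubric$components[components],
                 function(c) as.numeric(c$max_points), numeric(1))
  passes <- data.frame(observer_id = c(1L, rep(seq_len(n_observers), each = 1L)),
                       pass = c(2L, rep(1L, n_observers)))
  passes <- passes[order(passes$observer_id, passes$pass), ]
  n <- nrow(cohort)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(passes)), function(i) {
      obs <- passes$observer_id[i]; pass <- passes$pass[i]
      pts <- lapply(components, function(cn) {
        p <- base[[cn]]
        noisy <- round(p + stats::rnorm(n, 0, noise_sd))
        clamp(noisy, 0, maxp[[cn]])
      })
      data.frame(animal_id = rep(cohort$animal_id, times = length(components)),
                 observer_id = obs, pass = pass,
                 component = rep(components, each = n),
                 points = unlist(pts),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Aggregate an observer score table to composite totals
#'
#' Sums per-component points to one composite per (animal, observer, pass)
#' over a component subset; the composite is invalid (missing total) when
#' any subset component is missing for that animal/observer/pass.
#'
#' @param score_table long table from [simulate_observer_rescoring()] or
#'   [read_scores()].
#' @param subset component names to total over.
#' @return Data frame `animal_id`, `observer_id`, `pass`, `total_points`,
#'   `valid`, with the subset attached as attribute `"subset"`.
#' @export
observer_totals <- function(score_table, subset) {
  stopifnot(all(c("animal_id", "observer_id", "pass", "component", "points")
                %in% names(score_table)))
  tab <- score_table[score_table$component %in% subset, ]
  found <- unique(tab$component)
  if (!all(subset %in% found)) {
    stop("score table lacks component(s): ",
         paste(setdiff(subset, found), collapse = ", "))
  }
  key <- interaction(tab$animal_id, tab$observer_id, tab$pass, drop = TRUE)
  total <- tapply(tab$points, key, function(p) {
    if (anyNA(p)) NA_real_ else sum(p)
  })
  ids <- do.call(rbind, strsplit(names(total), ".", fixed = TRUE))
  out <- data.frame(animal_id = ids[, 1],
                    observer_id = as.integer(ids[, 2]),
                    pass = as.integer(ids[, 3]),
                    total_points = as.numeric(total),
                    valid = !is.na(as.numeric(total)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$observer_id, out$pass, out$animal_id), ]
  rownames(out) <- NULL
  attr(out, "subset") <- subset
  out
}

#' @export
print.cavalus_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %s, n = %d control / %d HF, severity shift %.2f\n",
              x$species, x$n_control, x$n_hf, x$severity_shift))
  cat("  component loadings:",
      paste(names(x$component_loadings),
            format(x$component_loadings, digits = 2), sep = "=", collapse = ", "),
      "\n")
  cat(sprintf("  seed %d; %d observers, rescoring noise SD %.2f\n",
              x$seed, x$n_observers, x$observer_noise_sd))
  invisible(x)
}
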