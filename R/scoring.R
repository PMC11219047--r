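#' IVC dilation calibration from the control group
#'
#' Summarizes the control group's maximum IVC diameter so that a calibrated
#' dilation rule (control mean + k * SD) can be evaluated. With a fixed-mm
#' rule the calibration is not needed.
#'
#' @param cohort a cohort data frame (see [generate_cohort()]); must contain
#'   `group` and `ivc_diameter_max` columns.
#' @return List with `mean`, `sd`, `n` over control animals with a measured
#'   diameter.
#' @export
ivc_calibration <- function(cohort) {
  stopifnot(all(c("group", "ivc_diameter_max") %in% names(cohort)))
  d <- cohort$ivc_diameter_max[cohort$group == "control"]
  d <- d[is.finite(d)]
  if (length(d) < 2L) stop("need >= 2 measured control IVC diameters to calibrate")
  list(mean = mean(d), sd = stats::sd(d), n = length(d))
}

ivc_threshold_mm <- function(comp, calibration) {
  if (comp$rule$mode == "fixed_mm") return(comp$rule$mm)
  if (is.null(calibration)) {
    stop("ivc component uses a calibrated rule; supply `calibration` ",
         "(see ivc_calibration())")
  }
  calibration$mean + comp$rule$k * calibration$sd
}

#' Score one component for every animal
#'
#' Maps a raw finding column to rubric points. Missing findings propagate to
#' missing points (never silently zero); the `not_assessable` lung-sliding
#' level maps to missing via the rubric. Finding values outside the rubric's
#' domain raise an error naming the value.
#'
#' @param cohort cohort data frame.
#' @param rubric a `cavalus_rubric`.
#' @param component component name present in the rubric.
#' @param calibration control-group IVC summary from [ivc_calibration()],
#'   required for a calibrated IVC rule.
#' @return numeric vector of points (NA where the finding is missing).
#' @export
score_component <- function(cohort, rubric, component, calibration = NULL) {
  stopifnot(inherits(rubric, "cavalus_rubric"))
  if (!component %in% names(rubric$components)) {
    stop(sprintf("unknown component '%s' (rubric has: %s)", component,
                 paste(names(rubric$components), collapse = ", ")))
  }
  comp <- rubric$components[[component]]
  col <- if (component == "ivc") "ivc_diameter_max" else component
  if (!col %in% names(cohort)) {
    stop(sprintf("cohort lacks column '%s' for component '%s'", col, component))
  }
  v <- cohort[[col]]

  if (comp$type == "ivc_threshold") {
    thr <- ivc_threshold_mm(comp, calibration)
    bad <- is.finite(v) & v <= 0
    if (any(bad)) stop("IVC diameters must be positive; got ", v[which(bad)[1L]])
    return(ifelse(is.na(v), NA_real_,
                  ifelse(v >= thr, comp$points_dilated, 0)))
  }

  pts_map <- comp$points
  key <- as.character(v)
  out <- rep(NA_real_, length(v))
  present <- !is.na(v)
  unknown <- present & !(key %in% names(pts_map))
  if (any(unknown)) {
    stop(sprintf("finding value '%s' for component '%s' is outside the rubric domain (%s)",
                 key[which(unknown)[1L]], component,
                 paste(names(pts_map), collapse = ", ")))
  }
  out[present] <- as.numeric(pts_map[key[present]])
  out
}

#' Composite congestion scores over a component subset
#'
#' Sums rubric points over the requested components for each animal. Under
#' the default `"invalidate"` policy a composite with any missing component
#' is marked invalid and its total is missing; the `"prorate"` policy instead
#' rescales the observed sum to the full subset's maximum attainable points
#' (rounded to the nearest integer), requiring at least one observed
#' component.
#'
#' @param cohort cohort data frame.
#' @param rubric a `cavalus_rubric`.
#' @param subset non-empty character vector of component names.
#' @param calibration IVC calibration (see [ivc_calibration()]); computed
#'   from the cohort's control group automatically when the subset needs one
#'   and none is supplied.
#' @param policy missing-component policy.
#' @return data frame with one row per animal: `animal_id`, `group`,
#'   `total_points`, `n_components_missing`, `valid`. The subset is attached
#'   as attribute `"subset"`.
#' @export
composite_scores <- function(cohort, rubric, subset,
                             calibration = NULL,
                             policy = c("invalidate", "prorate")) {
  policy <- match.arg(policy)
  if (length(subset) == 0L) {
    stop("subset must contain at least one component (a score over nothing is meaningless)")
  }
  subset <- unique(subset)
  missing_comp <- setdiff(subset, names(rubric$components))
  if (length(missing_comp)) {
    stop("subset components not in rubric: ", paste(missing_comp, collapse = ", "))
  }
  if ("ivc" %in% subset && is.null(calibration) &&
      rubric$components$ivc$rule$mode == "calibrated") {
    calibration <- ivc_calibration(cohort)
  }
  pts <- vapply(subset, function(cn) score_component(cohort, rubric, cn, calibration),
                numeric(nrow(cohort)))
  pts <- matrix(pts, nrow = nrow(cohort),
                dimnames = list(NULL, subset))
  n_missing <- rowSums(is.na(pts))
  if (policy == "invalidate") {
    valid <- n_missing == 0L
    total <- ifelse(valid, rowSums(pts), NA_real_)
  } else {
    observed_max <- rowSums((!is.na(pts)) *
                              matrix(vapply(rubric$components[subset],
                                            function(c) as.numeric(c$max_points),
                                            numeric(1)),
                                     nrow = nrow(cohort), ncol = length(subset),
                                     byrow = TRUE))
    valid <- n_missing < length(subset)
    total <- ifelse(valid,
                    round(rowSums(pts, na.rm = TRUE) *
                            max_points(rubric, subset) / pmax(observed_max, 1)),
                    NA_real_)
  }
  out <- data.frame(animal_id = cohort$animal_id,
                    group = cohort$group,
                    total_points = total,
                    n_components_missing = as.integer(n_missing),
                    valid = valid,
                    stringsAsFactors = FALSE)
  attr(out, "subset") <- subset
  out
}

#' Classify a composite score against an integer cutoff
#'
#' Positive when the composite is valid and its total meets or exceeds the
#' cutoff; negative when valid and below; indeterminate when the composite
#' is invalid (missing components).
#'
#' @param scores a data frame from [composite_scores()] (or any data frame
#'   with `total_points` and `valid` columns).
#' @param cutoff nonnegative integer cutoff.
#' @return factor with levels positive/negative/indeterminate.
#' @export
classify <- function(scores, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  lab <- ifelse(!scores$valid, "indeterminate",
                ifelse(scores$total_points >= cutoff, "positive", "negative"))
  factor(lab, levels = c("positive", "negative", "indeterminate"))
}

#' Vena cava collapsibility index
#'
#' VCCI = (Dmax - Dmin) / Dmax, the respiratory collapse fraction of the
#' inferior vena cava; 0 means no collapse, 1 full collapse.
#'
#' @param d_max,d_min maximum and minimum M-mode diameters in mm (vectorized).
#' @return numeric vector in \[0, 1\]; NA where either diameter is missing.
#' @examples
#' compute_vcci(2.0, 1.5)
#' @export
compute_vcci <- function(d_max, d_min) {
  bad <- is.finite(d_max) & d_max <= 0
  if (any(bad)) stop("d_max must be positive")
  bad <- is.finite(d_min) & is.finite(d_max) & (d_min < 0 | d_min > d_max)
  if (any(bad)) {
    stop(sprintf("d_min must satisfy 0 <= d_min <= d_max; got d_min=%g, d_max=%g",
                 d_min[which(bad)[1L]], d_max[which(bad)[1L]]))
  }
  (d_max - d_min) / d_max
}
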