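#' Scoring rubrics for ultrasound congestion components
#'
#' A rubric maps raw ultrasound findings to ordinal severity points, one map
#' per component. Ordinal components (B-line profile, pleural effusion,
#' defects, thickening) map each grade to a point value; the categorical
#' lung-sliding component maps its levels; the IVC component awards points
#' when the maximum diameter is dilated, either above a fixed millimetre
#' cutoff or above a calibrated threshold of the form
#' control mean + k * SD (boundary inclusive).
#'
#' The default point values shipped by [default_rubric()] are a pragmatic
#' reconstruction chosen for this package — severity grades map one-to-one
#' to points and IVC dilation scores 2 — and every value is configuration,
#' not a constant.
#'
#' @param species `"rat"` or `"mouse"`.
#' @param components named list of component definitions; see
#'   [default_rubric()] for the expected structure.
#' @return An object of class `cavalus_rubric`.
#' @export
score_rubric <- function(species = c("rat", "mouse"), components) {
  species <- match.arg(species)
  stopifnot(is.list(components), length(components) >= 1L)
  nm <- names(components)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("components must be a uniquely named list")
  }
  known <- c("ivc", "b_line_profile", "pleural_effusion", "pleural_defects",
             "pleural_thickening", "lung_sliding")
  unknown <- setdiff(nm, known)
  if (length(unknown)) {
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  }
  for (cn in nm) {
    comp <- components[[cn]]
    if (is.null(comp$type) || !comp$type %in% c("ordinal", "categorical", "ivc_threshold")) {
      stop(sprintf("component '%s' needs a type of ordinal/categorical/ivc_threshold", cn))
    }
    if (comp$type %in% c("ordinal", "categorical")) {
      pts <- unlist(comp$points)
      if (any(!is.na(pts) & (pts < 0 | pts != floor(pts)))) {
        stop(sprintf("component '%s': points must be nonnegative integers", cn))
      }
      if (is.null(comp$max_points)) {
        components[[cn]]$max_points <- max(pts, na.rm = TRUE)
      }
      if (any(!is.na(pts) & pts > components[[cn]]$max_points)) {
        stop(sprintf("component '%s': a point value exceeds max_points", cn))
      }
    } else {
      if (is.null(comp$points_dilated) || comp$points_dilated < 0) {
        stop(sprintf("component '%s': points_dilated must be nonnegative", cn))
      }
      if (is.null(comp$rule) || !comp$rule$mode %in% c("calibrated", "fixed_mm")) {
        stop(sprintf("component '%s': rule mode must be calibrated or fixed_mm", cn))
      }
      if (is.null(comp$max_points)) {
        components[[cn]]$max_points <- comp$points_dilated
      }
    }
  }
  structure(list(species = species, components = components),
            class = "cavalus_rubric")
}

#' Default congestion-scoring rubric
#'
#' Components and point maps used throughout the package unless overridden:
#' * `b_line_profile` grades 0..3 (A-lines through coalescent B-lines /
#'   "white lung") -> 0..3 points;
#' * `pleural_effusion`, `pleural_defects`, `pleural_thickening`
#'   grades 0..2 -> 0..2 points;
#' * `ivc`: not dilated -> 0, dilated -> 2 points, with the dilation
#'   threshold defaulting to control-group mean + 2 SD of the maximum IVC
#'   diameter (a fixed-mm override is available via the rule);
#' * `lung_sliding`: present -> 0, lung pulse -> 1, absent -> 2,
#'   not assessable -> missing.
#'
#' @param species `"rat"` or `"mouse"` (carried as metadata; the default
#'   point maps are shared).
#' @param ivc_rule either `list(mode = "calibrated", k = 2)` or
#'   `list(mode = "fixed_mm", mm = <cutoff>)`.
#' @return A `cavalus_rubric`.
#' @examples
#' r <- default_rubric("rat")
#' names(r$components)
#' @export
default_rubric <- function(species = c("rat", "mouse"),
                           ivc_rule = list(mode = "calibrated", k = 2)) {
  species <- match.arg(species)
  score_rubric(species, list(
    ivc = list(type = "ivc_threshold", rule = ivc_rule,
               points_dilated = 2L, max_points = 2L),
    b_line_profile = list(type = "ordinal",
                          points = c(`0` = 0L, `1` = 1L, `2` = 2L, `3` = 3L),
                          max_points = 3L),
    pleural_effusion = list(type = "ordinal",
                            points = c(`0` = 0L, `1` = 1L, `2` = 2L),
                            max_points = 2L),
    pleural_defects = list(type = "ordinal",
                           points = c(`0` = 0L, `1` = 1L, `2` = 2L),
                           max_points = 2L),
    pleural_thickening = list(type = "ordinal",
                              points = c(`0` = 0L, `1` = 1L, `2` = 2L),
                              max_points = 2L),
    lung_sliding = list(type = "categorical",
                        points = c(present = 0L, lung_pulse = 1L,
                                   absent = 2L, not_assessable = NA_integer_),
                        max_points = 2L)
  ))
}

#' @export
print.cavalus_rubric <- function(x, ...) {
  cat(sprintf("Congestion scoring rubric (%s): %d components\n",
              x$species, length(x$components)))
  for (cn in names(x$components)) {
    comp <- x$components[[cn]]
    if (comp$type == "ivc_threshold") {
      rule <- if (comp$rule$mode == "calibrated") {
        sprintf("dilated if Dmax >= control mean + %g SD", comp$rule$k)
      } else {
        sprintf("dilated if Dmax >= %g mm", comp$rule$mm)
      }
      cat(sprintf("  %s: %s -> %d pts\n", cn, rule, comp$points_dilated))
    } else {
      pts <- unlist(comp$points)
      cat(sprintf("  %s: %s\n", cn,
                  paste(names(pts), pts, sep = "->", collapse = ", ")))
    }
  }
  invisible(x)
}

#' Read / write a rubric as a YAML config file
#'
#' @param path file path.
#' @param rubric a `cavalus_rubric`.
#' @return `read_rubric()` returns a `cavalus_rubric`; `write_rubric()`
#'   returns `path` invisibly.
#' @export
write_rubric <- function(rubric, path) {
  stopifnot(inherits(rubric, "cavalus_rubric"))
  comps <- lapply(rubric$components, function(comp) {
    if (comp$type %in% c("ordinal", "categorical")) {
      comp$points <- as.list(comp$points)
    }
    comp
  })
  yaml::write_yaml(list(species = rubric$species, components = comps), path)
  invisible(path)
}

#' @rdname write_rubric
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  comps <- lapply(raw$components, function(comp) {
    if (comp$type %in% c("ordinal", "categorical")) {
      pts <- unlist(lapply(comp$points, function(p) if (is.null(p)) NA_integer_ else as.integer(p)))
      names(pts) <- names(comp$points)
      comp$points <- pts
    }
    comp
  })
  score_rubric(raw$species, comps)
}

#' Maximum attainable points for a component subset
#'
#' @param rubric a `cavalus_rubric`.
#' @param subset character vector of component names (default: all).
#' @return integer sum of per-component `max_points`.
#' @export
max_points <- function(rubric, subset = names(rubric$components)) {
  stopifnot(all(subset %in% names(rubric$components)))
  sum(vapply(rubric$components[subset], function(c) as.numeric(c$max_points),
             numeric(1)))
}
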