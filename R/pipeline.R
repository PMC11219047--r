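# Tabular I/O: comma-delimited UTF-8, "NA" missing token, full-precision
# doubles (17 significant digits) so a written cohort reads back exactly.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write / read a cohort table
#'
#' One row per animal, comma-delimited with an explicit `NA` missing token.
#' Numeric columns are written at full double precision, so
#' `read_cohort(write_cohort(x, f))` reproduces `x` exactly.
#'
#' @param cohort a cohort data frame.
#' @param path output file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   `cavalus_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  chr_cols <- c("animal_id", "species", "sex", "group", "lung_sliding")
  int_cols <- c("b_line_profile", "pleural_effusion", "pleural_defects",
                "pleural_thickening")
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  classes <- ifelse(hdr %in% chr_cols, "character",
                    ifelse(hdr %in% int_cols, "integer", "numeric"))
  cohort <- utils::read.csv(path, colClasses = classes, na.strings = "NA",
                            check.names = FALSE, fileEncoding = "UTF-8")
  class(cohort) <- c("cavalus_cohort", "data.frame")
  cohort
}

#' Write / read a long-format observer score table
#'
#' Columns: `animal_id`, `observer_id`, `pass`, `component`, `points`.
#'
#' @param scores long table from [simulate_observer_rescoring()].
#' @param path file path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  utils::read.csv(path, na.strings = "NA",
                  colClasses = c(animal_id = "character",
                                 observer_id = "integer", pass = "integer",
                                 component = "character", points = "numeric"),
                  fileEncoding = "UTF-8")
}

#' Per-group incidence of scored findings
#'
#' For each group and component, the fraction of assessed animals with a
#' positive finding (component points > 0). Animals with a missing finding
#' (including `not_assessable` lung sliding) are excluded from the
#' denominator; zero-denominator rows are flagged rather than dropped.
#'
#' @param cohort cohort data frame.
#' @param rubric a `cavalus_rubric`.
#' @param calibration IVC calibration (auto-derived when needed).
#' @return Data frame: `group`, `component`, `n_present`, `n_assessed`,
#'   `fraction`, `flagged`.
#' @export
compute_incidence <- function(cohort, rubric, calibration = NULL) {
  comps <- names(rubric$components)
  if ("ivc" %in% comps && is.null(calibration) &&
      rubric$components$ivc$rule$mode == "calibrated") {
    calibration <- ivc_calibration(cohort)
  }
  rows <- list()
  for (grp in unique(cohort$group)) {
    sub <- cohort[cohort$group == grp, , drop = FALSE]
    for (cn in comps) {
      pts <- score_component(sub, rubric, cn, calibration)
      n_assessed <- sum(!is.na(pts))
      n_present <- sum(pts > 0, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, component = cn,
        n_present = n_present, n_assessed = n_assessed,
        fraction = if (n_assessed > 0) n_present / n_assessed else NA_real_,
        flagged = n_assessed == 0L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for an end-to-end pipeline run
#'
#' @param species `"rat"` or `"mouse"` (selects the preset and default
#'   rubric when no paths are given).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param stages stages to run, in fixed order
#'   `simulate -> score -> incidence -> develop -> agree`.
#' @param cohort_path read the cohort from this table instead of simulating
#'   (required when `"simulate"` is toggled off).
#' @param rubric_path read the rubric from this YAML file instead of the
#'   species default.
#' @param top_k shortlist size for the combination search.
#' @param must_include components every candidate combination must contain.
#'   The default anchors every candidate score on the IVC component, since
#'   the development goal is a score combining IVC assessment with lung
#'   ultrasound findings; set to `character(0)` to search all subsets.
#' @param cohort_overrides named list of [cohort_preset()] overrides.
#' @param verbose emit stage-level log messages.
#' @return List of class `cavalus_run_config`.
#' @export
run_config <- function(species = c("rat", "mouse"), out_dir, seed = 1L,
                       stages = c("simulate", "score", "incidence",
                                  "develop", "agree"),
                       cohort_path = NULL, rubric_path = NULL,
                       top_k = 7L, must_include = "ivc",
                       cohort_overrides = list(),
                       verbose = TRUE) {
  species <- match.arg(species)
  known <- c("simulate", "score", "incidence", "develop", "agree")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (!"simulate" %in% stages && length(stages) && is.null(cohort_path)) {
    stop("without the simulate stage, cohort_path is required")
  }
  structure(list(species = species, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages,
                 cohort_path = cohort_path, rubric_path = rubric_path,
                 top_k = as.integer(top_k), must_include = must_include,
                 cohort_overrides = cohort_overrides, verbose = verbose),
            class = "cavalus_run_config")
}

stage_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
}

run_stage <- function(name, code) {
  tryCatch(force(code),
           error = function(e) {
             stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  call. = FALSE)
           })
}

#' Run the full score-development pipeline
#'
#' Executes the toggled stages in order: cohort simulation (or loading),
#' per-component scoring, incidence tabulation, combination search with
#' shortlist and Youden-optimal winner selection, and observer-agreement
#' analysis on the winning score. All artifacts are written to
#' `config$out_dir` as delimited text plus a JSON manifest recording the
#' configuration, seed, package version and an MD5 checksum per artifact;
#' identical configurations produce identical artifacts.
#'
#' @param config a `cavalus_run_config`.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `incidence`, `matrix`, `shortlist`, `selection`, `agreement`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cavalus_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  results <- list()

  rubric <- if (is.null(config$rubric_path)) {
    default_rubric(config$species)
  } else {
    read_rubric(config$rubric_path)
  }
  rubric_out <- file.path(config$out_dir, "rubric.yaml")
  write_rubric(rubric, rubric_out)
  artifacts <- c(artifacts, rubric_out)

  cohort <- NULL
  if ("simulate" %in% config$stages) {
    cohort <- run_stage("simulate", {
      cfg <- do.call(cohort_preset,
                     c(list(species = config$species, seed = config$seed),
                       config$cohort_overrides))
      generate_cohort(cfg)
    })
    stage_log(config, "simulate: %d animals (%d control / %d HF)",
              nrow(cohort), sum(cohort$group == "control"),
              sum(cohort$group == "hf"))
    p <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, p); artifacts <- c(artifacts, p)
  } else if (!is.null(config$cohort_path)) {
    cohort <- run_stage("load_cohort", read_cohort(config$cohort_path))
    stage_log(config, "loaded cohort: %d animals", nrow(cohort))
  }
  results$cohort <- cohort

  calibration <- NULL
  if (!is.null(cohort)) calibration <- ivc_calibration(cohort)

  if ("score" %in% config$stages) {
    pts <- run_stage("score", {
      comps <- names(rubric$components)
      do.call(rbind, lapply(comps, function(cn) {
        data.frame(animal_id = cohort$animal_id, component = cn,
                   points = score_component(cohort, rubric, cn, calibration),
                   stringsAsFactors = FALSE)
      }))
    })
    stage_log(config, "score: %d component scores (%d missing)",
              nrow(pts), sum(is.na(pts$points)))
    p <- file.path(config$out_dir, "component_points.csv")
    utils::write.csv(pts, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)
  }

  if ("incidence" %in% config$stages) {
    inc <- run_stage("incidence", compute_incidence(cohort, rubric, calibration))
    results$incidence <- inc
    stage_log(config, "incidence: %d group x finding rows", nrow(inc))
    p <- file.path(config$out_dir, "incidence.csv")
    utils::write.csv(inc, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)
  }

  winner_subset <- NULL
  if ("develop" %in% config$stages) {
    dev <- run_stage("develop", {
      subsets <- enumerate_combinations(names(rubric$components),
                                        must_include = config$must_include)
      m <- score_correlation_matrix(cohort, rubric, subsets,
                                    calibration = calibration)
      shortlist <- select_top_k(m, k = config$top_k)
      sel <- select_winner(cohort, rubric, shortlist, calibration = calibration)
      list(matrix = m, shortlist = shortlist, selection = sel)
    })
    results$matrix <- dev$matrix
    results$shortlist <- dev$shortlist
    results$selection <- dev$selection
    winner_subset <- dev$selection$winner
    stage_log(config, "develop: %d subsets evaluated; winner %s (cutoff %s, J = %.2f)",
              length(dev$matrix$subsets), dev$selection$winner_label,
              format(dev$selection$winner_cutoff), dev$selection$winner_j)

    m <- dev$matrix
    long <- data.frame(subset = rep(m$labels, times = length(m$metrics)),
                       metric = rep(m$metrics, each = length(m$labels)),
                       r = as.vector(m$r), n = as.vector(m$n),
                       rank = as.vector(m$ranks), stringsAsFactors = FALSE)
    p <- file.path(config$out_dir, "score_correlation_matrix.csv")
    utils::write.csv(long, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)

    sl <- data.frame(subset = vapply(dev$shortlist, subset_label, character(1)),
                     overall_rank = attr(dev$shortlist, "overall_rank"))
    p <- file.path(config$out_dir, "shortlist.csv")
    utils::write.csv(sl, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)

    wroc <- dev$selection$roc[[dev$selection$winner_label]]
    roc_tab <- data.frame(threshold = wroc$thresholds,
                          sensitivity = wroc$sensitivity,
                          specificity = wroc$specificity,
                          youden_j = wroc$youden_j)
    p <- file.path(config$out_dir, "winner_roc.csv")
    utils::write.csv(roc_tab, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)

    wn <- data.frame(winner = dev$selection$winner_label,
                     cutoff = dev$selection$winner_cutoff,
                     youden_j = dev$selection$winner_j,
                     sensitivity = dev$selection$winner_se,
                     specificity = dev$selection$winner_sp,
                     auc = wroc$auc)
    p <- file.path(config$out_dir, "winner.csv")
    utils::write.csv(wn, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)
  }

  if ("agree" %in% config$stages) {
    agr <- run_stage("agree", {
      cfg <- do.call(cohort_preset,
                     c(list(species = config$species, seed = config$seed),
                       config$cohort_overrides))
      subset <- winner_subset %||% setdiff(names(rubric$components), "lung_sliding")
      tab <- simulate_observer_rescoring(
        cohort, rubric, n_observers = cfg$n_observers,
        noise_sd = cfg$observer_noise_sd,
        seed = derive_seed(config$seed, "rescoring"),
        calibration = calibration, components = subset)
      totals <- observer_totals(tab, subset)
      list(scores = tab, report = agreement_report(totals))
    })
    results$agreement <- agr$report
    stage_log(config, "agree: %d observer pairs", nrow(agr$report))
    p <- file.path(config$out_dir, "observer_scores.csv")
    write_scores(agr$scores, p); artifacts <- c(artifacts, p)
    p <- file.path(config$out_dir, "agreement.csv")
    utils::write.csv(agr$report, p, row.names = FALSE, na = "NA")
    artifacts <- c(artifacts, p)
  }

  manifest <- list(
    package = "cavalus",
    version = as.character(utils::packageVersion("cavalus")),
    seed = config$seed,
    species = config$species,
    stages = config$stages,
    top_k = config$top_k,
    must_include = config$must_include,
    cohort_overrides = config$cohort_overrides,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest_path <- manifest_path
  stage_log(config, "wrote manifest: %s", manifest_path)
  invisible(results)
}
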