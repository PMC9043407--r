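#' Run the full analysis for one case
#'
#' Orchestrates: fiducial detection (filtering, activation, Wyatt
#' repolarization, ARI), the 10 percent beat-consistency filter, tissue
#' labeling (optionally transferred from a source geometry),
#' geodesic scar-interface distance with the 2 mm exclusion band, global
#' Shepard interpolation of ARI and repolarization time onto the shell,
#' local gradients, pacing-distance classification, and the per-region
#' summary. Deterministic: no randomness is used at the analysis stage.
#'
#' @param case A `map_case`.
#' @param detector A [detector_config()].
#' @param interp An [interp_config()].
#' @param source_labels Optional labeled source geometry (shell or data
#'   frame for [transfer_tags()]); by default the case shell's own labels
#'   are used.
#' @details After the interface band, the percentile outlier rule
#'   (strictly below the 10th or above the 90th percentile of each
#'   case x tissue-class site group) removes outlying ARI sites before
#'   summarization — the study's outlier exclusion operates on these
#'   site-level data groups, where fractionation-driven outliers arise.
#' @return List of class `ari_case_result`: `case_id`, `annotations`
#'   (per beat), `keep` (consistency-filter table), `sites` (retained
#'   site table with class, distance, ARI/RT and gradients), `shell`
#'   (with result fields attached), `pacing` (distance + class),
#'   `summary` (region-summary rows), `attrition` (site counts per
#'   stage).
#' @export
run_case <- function(case, detector = detector_config(),
                     interp = interp_config(), source_labels = NULL) {
  shell <- case$shell
  if (!is.null(source_labels)) {
    shell <- transfer_tags(source_labels, shell)
  }
  if (all(is.na(shell$node_data$label))) {
    abort("stage labeling: case shell has no tissue labels")
  }

  annotations <- egm_fiducials(case, detector)
  keep <- consistency_filter(annotations, detector$consistency_threshold)
  vals <- site_ari(annotations, detector)
  sites <- dplyr::inner_join(
    case$records[, c("site_id", "x", "y", "z")], vals, by = "site_id")
  if (nrow(sites) == 0) abort("stage fiducials: no sites survived the consistency filter")

  shell <- scar_interface_distance(shell, signed = TRUE)
  retained <- exclude_near_interface(sites, shell, band = interp$exclusion_band)
  if (nrow(retained) == 0) abort("stage exclusion: no sites outside the interface band")

  # percentile outlier exclusion per tissue-class data group (site level)
  n_band <- nrow(retained)
  keep_idx <- unlist(lapply(split(seq_len(n_band), retained$tissue_class),
                            function(ix) {
    if (length(ix) < 3) ix else ix[exclude_outliers(retained$ari_ms[ix])$keep]
  }), use.names = FALSE)
  retained <- retained[sort(keep_idx), , drop = FALSE]

  ari_field <- shepard_interpolate(
    dplyr::rename(retained[, c("x", "y", "z", "ari_ms")], value = "ari_ms"),
    shell, interp)
  rt_field <- shepard_interpolate(
    dplyr::rename(retained[, c("x", "y", "z", "rt_ms")], value = "rt_ms"),
    shell, interp)
  shell <- set_field(shell, "ari", ari_field)
  shell <- set_field(shell, "rt", rt_field)
  shell <- set_field(shell, "ari_gradient",
                     local_gradient(shell, ari_field, interp$gradient_mode))
  shell <- set_field(shell, "rt_gradient",
                     local_gradient(shell, rt_field, interp$gradient_mode))
  retained$ari_gradient_ms_mm <- get_field(shell, "ari_gradient")[retained$node_id]
  retained$rt_gradient_ms_mm <- get_field(shell, "rt_gradient")[retained$node_id]

  pacing <- pacing_distance_to_scar(case$pacing_site, shell)
  info <- tibble::tibble(
    case_id = case$case_id, pig = case$pig %||% NA_integer_,
    pacing_chamber = case$pacing_chamber, cycle_length = case$cycle_length,
    pacing_distance_mm = pacing$pacing_distance_mm,
    pacing_class = pacing$pacing_class)
  summary <- case_region_summary(retained, info)

  n_valid <- length(unique(annotations$site_id[annotations$valid]))
  attrition <- tibble::tibble(
    case_id = case$case_id,
    stage = c("recorded", "valid_beats", "consistency_kept",
              "interface_retained", "outlier_retained"),
    n_sites = c(nrow(case$records), n_valid, sum(keep$kept), n_band,
                nrow(retained)))

  structure(list(case_id = case$case_id, annotations = annotations,
                 keep = keep, sites = retained, shell = shell,
                 pacing = pacing, summary = summary, attrition = attrition),
            class = "ari_case_result")
}

#' @export
print.ari_case_result <- function(x, ...) {
  a <- x$attrition
  cat(sprintf("<ari_case_result> %s: %d -> %d sites (consistency %d, band %d, outliers %d)\n",
              x$case_id, a$n_sites[1], a$n_sites[5], a$n_sites[3], a$n_sites[4],
              a$n_sites[5]))
  invisible(x)
}

#' Run a multi-case study
#'
#' [run_case()] over every case, then the full statistical battery over
#' the pooled region summaries. A failing case is dropped with a warning;
#' the study continues.
#'
#' @param cases List of `map_case` objects (e.g. `make_study(cfg)$cases`).
#' @param detector A [detector_config()].
#' @param interp An [interp_config()].
#' @param exclude_outliers Additionally apply percentile outlier
#'   exclusion to the case-level arms in the statistics stage (default
#'   FALSE: the outlier rule has already been applied to the site-level
#'   data groups inside [run_case()], and trimming 6-value case groups
#'   would always remove each arm's extremes).
#' @param out_dir Optional directory: writes `region_summary.csv`,
#'   `stats.csv`, `attrition.csv` and one result VTK per case.
#' @return List of class `ari_study_result`: `case_results`, `summaries`,
#'   `stats`, `attrition`.
#' @export
run_study <- function(cases, detector = detector_config(),
                      interp = interp_config(), exclude_outliers = FALSE,
                      out_dir = NULL) {
  if (length(cases) < 2) abort("a study needs at least 2 cases.")
  results <- list()
  for (case in cases) {
    res <- tryCatch(run_case(case, detector, interp), error = function(e) {
      warn(sprintf("case %s failed and was skipped: %s",
                   case$case_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) results[[res$case_id]] <- res
  }
  if (!length(results)) abort("every case failed.")
  summaries <- dplyr::bind_rows(lapply(results, `[[`, "summary"))
  attrition <- dplyr::bind_rows(lapply(results, `[[`, "attrition"))
  stats_tbl <- run_study_stats(summaries, exclude = exclude_outliers)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(summaries, file.path(out_dir, "region_summary.csv"))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    readr::write_csv(attrition, file.path(out_dir, "attrition.csv"))
    for (res in results) {
      export_result_shell(res$shell,
                          file.path(out_dir, paste0(res$case_id, ".vtk")))
    }
  }
  structure(list(case_results = results, summaries = summaries,
                 stats = stats_tbl, attrition = attrition),
            class = "ari_study_result")
}

#' @export
print.ari_study_result <- function(x, ...) {
  cat(sprintf("<ari_study_result> %d cases, %d comparisons (%d significant at 0.05)\n",
              length(x$case_results), nrow(x$stats),
              sum(x$stats$significant, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.ari_study_result <- function(x, ...) x$stats

#' @export
glance.ari_study_result <- function(x, ...) {
  tibble::tibble(
    n_cases = length(x$case_results),
    n_comparisons = nrow(x$stats),
    n_significant = sum(x$stats$significant, na.rm = TRUE),
    n_failed = sum(!is.na(x$stats$note)))
}
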