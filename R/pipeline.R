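#' @title End-to-end five-stage pipeline
#' @name pipeline
#' @description
#' Orchestrates the fixed stage order — non-pedestrian removal, OD
#' validation, outlier clean-up, geomasking, 1 Hz interpolation — with
#' per-stage bookkeeping, reproducible seeding, and optional on-disk output
#' mirroring the processed / interpolated folder layout. Geomasking runs
#' before interpolation so interpolated files never contain masked-away
#' time. Files that fail a stage are quarantined with a reason; the run
#' continues.
NULL

#' Pipeline configuration
#'
#' @param schools School coordinate table (`school`, `latitude`,
#'   `longitude`).
#' @param cleaning A [cleaning_policy()].
#' @param geomask A [geomask_policy()].
#' @param directions Optional tibble (`school`, `direction`) forcing a
#'   per-school direction; trips without one fall back to endpoint
#'   inference.
#' @param seed Integer seed recorded in the manifest and used for the
#'   geomask draws.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("clean", "geomask", "interpolate")`.
#' @param output_dir Optional directory; when set, `_processed.csv` and
#'   `_interpolated.csv` files plus `manifest.json` are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(schools = synthetic_schools(),
                            cleaning = cleaning_policy(),
                            geomask = geomask_policy(),
                            directions = NULL,
                            seed = 1,
                            stages = c("clean", "geomask", "interpolate"),
                            output_dir = NULL) {
  structure(list(schools = schools, cleaning = cleaning, geomask = geomask,
                 directions = directions, seed = seed, stages = stages,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the five-stage pipeline
#'
#' @param input A cohort tibble (e.g. from [read_cohort()] or
#'   [simulate_cohort()]`$cohort`) or a directory of raw CSV files.
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `processed` (cohort after stages 1-4,
#'   10-column tracks), `interpolated` (after stage 5), `cleaning`
#'   (the `cleaning_result`), `mask_report`, `manifest` (per-school
#'   participant/record counts at each stage), `tables` (per-school and
#'   cohort-level summary tables), `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  quarantine <- NULL
  if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("no CSV files found in '", input, "'"))
    reads <- purrr::map(files, function(f) {
      tryCatch(read_track(f, dialect = "raw", quiet = TRUE),
               error = function(e) conditionMessage(e))
    })
    failed <- purrr::map_lgl(reads, is.character)
    quarantine <- tibble(file = basename(files[failed]),
                         reason = unlist(reads[failed], use.names = FALSE))
    cohort <- as_cohort(reads[!failed], filenames = files[!failed])
  } else {
    cohort <- input
  }
  raw_counts <- cohort %>%
    group_by(.data$school) %>%
    summarise(participants_raw = dplyr::n(),
              gps_raw = sum(purrr::map_int(.data$track, nrow)),
              .groups = "drop")

  if (!is.null(config$directions)) {
    idx <- match(cohort$school, config$directions$school)
    fill <- config$directions$direction[idx]
    cohort$direction <- ifelse(is.na(cohort$direction), fill,
                               cohort$direction)
  }
  cohort <- infer_direction(cohort, config$schools)

  cleaning <- NULL
  if ("clean" %in% config$stages) {
    cleaning <- clean_cohort(cohort, config$schools, config$cleaning)
    cohort <- cleaning$cohort
  }

  mask_report <- NULL
  pre_mask <- cohort
  if ("geomask" %in% config$stages) {
    gpol <- config$geomask
    if (is.null(gpol$rng_seed)) gpol$rng_seed <- config$seed
    masked <- geomask_cohort(cohort, gpol,
                             min_records = config$cleaning$min_records)
    cohort <- masked$cohort
    mask_report <- masked$mask_report
  }
  processed <- cohort
  processed$track <- purrr::map(processed$track, function(tr) {
    if (!all(c("dt", "d", "v") %in% names(tr))) add_steps(tr) else tr
  })

  interpolated <- NULL
  if ("interpolate" %in% config$stages) {
    interpolated <- interpolate_cohort(processed)
  }

  manifest <- .build_manifest(raw_counts, pre_mask, processed, interpolated,
                              config)
  tables <- list(
    per_school = if (nrow(processed) > 0) school_table(processed) else NULL,
    cohort = if (nrow(processed) > 0) cohort_quantiles(processed) else NULL,
    geomask = report_tables(pre_mask, processed, mask_report)
  )

  if (!is.null(config$output_dir)) {
    dir.create(file.path(config$output_dir, "processed"), recursive = TRUE,
               showWarnings = FALSE)
    write_cohort(processed, file.path(config$output_dir, "processed"),
                 "processed")
    if (!is.null(interpolated)) {
      dir.create(file.path(config$output_dir, "interpolated"),
                 recursive = TRUE, showWarnings = FALSE)
      write_cohort(interpolated, file.path(config$output_dir, "interpolated"),
                   "interpolated")
    }
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(processed = processed, interpolated = interpolated,
                 cleaning = cleaning, mask_report = mask_report,
                 manifest = manifest, tables = tables,
                 quarantine = quarantine, config = config),
            class = "pipeline_result")
}

.build_manifest <- function(raw_counts, pre_mask, processed, interpolated,
                            config) {
  count_by_school <- function(cohort, prefix) {
    if (is.null(cohort) || nrow(cohort) == 0) return(NULL)
    cohort %>%
      group_by(.data$school) %>%
      summarise("participants_{prefix}" := dplyr::n(),
                "gps_{prefix}" := sum(purrr::map_int(.data$track, nrow)),
                .groups = "drop")
  }
  out <- raw_counts
  for (x in list(count_by_school(processed, "processed"),
                 count_by_school(interpolated, "interpolated"))) {
    if (!is.null(x)) out <- left_join(out, x, by = "school")
  }
  out <- mutate(out, across(tidyselect::where(is.numeric),
                            ~ tidyr::replace_na(.x, 0)))
  list(seed = config$seed,
       stages = config$stages,
       per_school = out,
       totals = summarise(out, across(tidyselect::where(is.numeric), sum)))
}

#' Per-school geomask reduction table
#'
#' Per school: participants, GPS records before and after the spatial
#' k-anonymity stage with the integer percent reduction, and the mean trip
#' duration before and after, plus a totals row.
#'
#' @param pre_mask Cohort before geomasking (after cleaning).
#' @param post_mask Cohort after geomasking.
#' @param mask_report Mask report tibble (used for the per-trip draws;
#'   optional).
#' @return A tibble, last row `school = "Total"`.
#' @export
report_tables <- function(pre_mask, post_mask, mask_report = NULL) {
  if (is.null(pre_mask) || nrow(pre_mask) == 0) return(NULL)
  pre_sum <- cohort_summaries(pre_mask)
  per <- pre_mask %>%
    group_by(.data$school) %>%
    summarise(participants = dplyr::n(),
              gps_pre = sum(purrr::map_int(.data$track, nrow)),
              .groups = "drop")
  pre_T <- pre_sum %>% group_by(.data$school) %>%
    summarise(T_pre = mean(.data$T), .groups = "drop")
  per <- left_join(per, pre_T, by = "school")
  if (!is.null(post_mask) && nrow(post_mask) > 0) {
    post_sum <- cohort_summaries(post_mask)
    post <- post_mask %>%
      group_by(.data$school) %>%
      summarise(gps_post = sum(purrr::map_int(.data$track, nrow)),
                .groups = "drop")
    post_T <- post_sum %>% group_by(.data$school) %>%
      summarise(T_post = mean(.data$T), .groups = "drop")
    per <- per %>% left_join(post, by = "school") %>%
      left_join(post_T, by = "school")
    per$reduction_pct <- round(100 * (per$gps_pre - per$gps_post) /
                                 per$gps_pre)
  }
  totals <- tibble(
    school = "Total",
    participants = sum(per$participants),
    gps_pre = sum(per$gps_pre),
    T_pre = mean(pre_sum$T)
  )
  if ("gps_post" %in% names(per)) {
    totals$gps_post <- sum(per$gps_post, na.rm = TRUE)
    totals$T_post <- mean(cohort_summaries(post_mask)$T)
    totals$reduction_pct <- round(100 * (totals$gps_pre - totals$gps_post) /
                                    totals$gps_pre)
  }
  bind_rows(per, totals)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pedestrian GPS pipeline result\n")
  cat(sprintf("  trips kept: %d; records processed: %d",
              nrow(x$processed), sum(x$processed$n_records)))
  if (!is.null(x$interpolated)) {
    cat(sprintf("; interpolated: %d", sum(x$interpolated$n_records)))
  }
  cat("\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return One-row tibble of stage counts.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    trips_out = nrow(x$processed),
    records_processed = sum(x$processed$n_records),
    records_interpolated = if (!is.null(x$interpolated))
      sum(x$interpolated$n_records) else NA_integer_,
    seed = x$config$seed
  )
}
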