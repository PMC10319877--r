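#' @title Five-stage filtering: stages 1-3
#' @name cleaning
#' @description
#' The cleaning pipeline removes, in order: (1) non-pedestrian trips,
#' identified by their declared transport mode or — for trips with no
#' declared mode — by an abnormal effective speed; (2) invalid trips that do
#' not form a well-defined origin-destination trajectory anchored at the
#' school; (3) outlier fixes (GPS start-up bursts, accuracy failures,
#' terminal dwell inside the school building), discarding a whole trip when
#' too large a fraction of it is outliers. Every decision is recorded in a
#' disposition table so that record bookkeeping is exact.
NULL

.vehicle_modes <- c("bus", "car", "metro", "train", "bike", "scooter")

#' Cleaning thresholds
#'
#' The original processing applied these criteria by visual map inspection;
#' automating them requires explicit thresholds, all overridable here.
#' Defaults: `v_nonped = 2.5` m/s (kept pedestrian effective speeds top out
#' near 1.95 m/s), `v_outlier_max = 10` m/s (above any running pedestrian,
#' below vehicle-like jumps; observed start-up outliers reach 90 m/s),
#' `haccuracy_max = 100` m, `school_radius = 150` m (the protocol has
#' participants start/stop 5-150 m from the endpoint), `min_records = 30`,
#' `max_outlier_fraction = 0.3`, `endpoint_dwell_radius = 20` m,
#' `endpoint_dwell_min = 60` s.
#'
#' @param v_nonped Effective-speed cap (m/s) for unknown-mode trips.
#' @param v_outlier_max Instantaneous velocity cap (m/s).
#' @param haccuracy_max Maximum horizontal accuracy radius (m).
#' @param school_radius Endpoint-to-school distance (m) for OD validation.
#' @param min_records Minimum records for a valid trajectory.
#' @param max_outlier_fraction Outlier fraction above which the whole
#'   trajectory is discarded.
#' @param endpoint_dwell_radius Radius (m) defining a stationary end segment.
#' @param endpoint_dwell_min Minimum duration (s) for trimming that segment.
#' @return A `cleaning_policy` list.
#' @export
cleaning_policy <- function(v_nonped = 2.5, v_outlier_max = 10,
                            haccuracy_max = 100, school_radius = 150,
                            min_records = 30, max_outlier_fraction = 0.3,
                            endpoint_dwell_radius = 20,
                            endpoint_dwell_min = 60) {
  pol <- list(v_nonped = v_nonped, v_outlier_max = v_outlier_max,
              haccuracy_max = haccuracy_max, school_radius = school_radius,
              min_records = min_records,
              max_outlier_fraction = max_outlier_fraction,
              endpoint_dwell_radius = endpoint_dwell_radius,
              endpoint_dwell_min = endpoint_dwell_min)
  if (!all(vapply(pol, function(x) is.numeric(x) && length(x) == 1 && x > 0,
                  logical(1)))) {
    abort("all cleaning policy values must be positive scalars")
  }
  structure(pol, class = "cleaning_policy")
}

#' Stage 1: remove non-pedestrian trips
#'
#' Trips whose declared mode is a vehicle (`bus, car, metro, train, bike,
#' scooter`) are removed; trips with no declared mode are removed when their
#' effective speed exceeds `policy$v_nonped`. The screening effective speed
#' is computed on the accuracy-trustworthy fixes
#' (`haccuracy <= policy$haccuracy_max`) so that a start-up burst of
#' low-accuracy jumps cannot push a walker over the threshold. Declared
#' walkers are kept regardless of speed (they are handled by later stages if
#' broken).
#'
#' @param cohort Cohort tibble.
#' @param policy A [cleaning_policy()].
#' @return List with `kept` and `removed` cohort tibbles and a `dispositions`
#'   tibble (`id`, `removed`, `reason`).
#' @export
filter_non_pedestrian <- function(cohort, policy = cleaning_policy()) {
  v_eff <- purrr::map_dbl(cohort$track, function(tr) {
    ok <- is.finite(tr$haccuracy) & tr$haccuracy <= policy$haccuracy_max
    core <- if (sum(ok) >= 2) tr[ok, , drop = FALSE] else tr
    if (nrow(core) < 2) return(0)
    track_summary(core[, setdiff(names(core), c("dt", "d", "v"))])$v_eff
  })
  reason <- dplyr::case_when(
    cohort$mode %in% .vehicle_modes ~ paste0("mode=", cohort$mode),
    cohort$mode == "unknown" & v_eff > policy$v_nonped ~
      sprintf("unknown mode with v_eff %.2f > %.2f m/s", v_eff, policy$v_nonped),
    TRUE ~ NA_character_
  )
  removed <- !is.na(reason)
  list(kept = cohort[!removed, , drop = FALSE],
       removed = cohort[removed, , drop = FALSE],
       dispositions = tibble(id = cohort$id, removed = removed,
                             reason = reason))
}

#' Stage 2: validate an origin-destination trajectory
#'
#' A trip is valid iff (a) exactly one endpoint lies within
#' `policy$school_radius` of its school, (b) it has at least
#' `policy$min_records` records, and (c) its net displacement is at least
#' twice the school radius — which rejects short scatter blobs recorded
#' around the school. Endpoints are taken from the accuracy-trustworthy
#' records (`haccuracy <= policy$haccuracy_max`), so that start-up bursts of
#' low-accuracy fixes do not decide validity.
#'
#' @param track Record tibble.
#' @param school_latlon Numeric `c(latitude, longitude)` of the trip's school.
#' @param policy A [cleaning_policy()].
#' @return List `valid` (logical) and `reason` (string, `NA` when valid).
#' @export
validate_od <- function(track, school_latlon, policy = cleaning_policy()) {
  if (is.null(school_latlon) || any(is.na(school_latlon))) {
    abort("school coordinates are required for origin-destination validation")
  }
  ok <- is.finite(track$haccuracy) & track$haccuracy <= policy$haccuracy_max
  core <- if (any(ok)) track[ok, , drop = FALSE] else track
  n <- nrow(core)
  p_first <- c(core$latitude[[1]], core$longitude[[1]])
  p_last <- c(core$latitude[[n]], core$longitude[[n]])
  d_first <- haversine_m(p_first[[1]], p_first[[2]],
                         school_latlon[[1]], school_latlon[[2]])
  d_last <- haversine_m(p_last[[1]], p_last[[2]],
                        school_latlon[[1]], school_latlon[[2]])
  near <- c(d_first, d_last) <= policy$school_radius
  net <- haversine_m(p_first[[1]], p_first[[2]], p_last[[1]], p_last[[2]])
  if (nrow(track) < policy$min_records) {
    return(list(valid = FALSE,
                reason = sprintf("only %d records (< %d)", nrow(track),
                                 policy$min_records)))
  }
  if (net < 2 * policy$school_radius) {
    return(list(valid = FALSE,
                reason = sprintf("net displacement %.0f m < %.0f m (scatter)",
                                 net, 2 * policy$school_radius)))
  }
  if (sum(near) != 1) {
    return(list(valid = FALSE,
                reason = if (sum(near) == 0) "no endpoint at the school"
                         else "both endpoints at the school"))
  }
  list(valid = TRUE, reason = NA_character_)
}

# a record is outlier-implicated when BOTH its incoming and outgoing step
# velocities exceed the cap (a displaced fix spikes both adjacent steps), or
# it is terminal with its single adjacent step exceeding; this spares the
# good neighbour of a spike
.velocity_outlier_idx <- function(track, cap) {
  n <- nrow(track)
  v <- track$v
  v_in <- c(NA_real_, v[-n])   # step arriving at record i
  v_out <- v                   # step leaving record i (NA at the last row)
  exceeds_in <- !is.na(v_in) & v_in > cap
  exceeds_out <- !is.na(v_out) & v_out > cap
  flag <- (exceeds_in & exceeds_out)
  flag[1] <- exceeds_out[1]
  flag[n] <- exceeds_in[n]
  which(flag)
}

#' Stage 3: outlier clean-up for one track
#'
#' Iteratively removes records with `haccuracy` above the cap or with both
#' adjacent step velocities above `policy$v_outlier_max`, recomputing the
#' step series after each pass until a fixed point (at most 10 passes). A
#' stationary terminal segment (contiguous records within
#' `endpoint_dwell_radius` of the final position lasting longer than
#' `endpoint_dwell_min`) is collapsed to its first record. If the fraction
#' of velocity/accuracy outliers removed exceeds
#' `policy$max_outlier_fraction` the whole trajectory is discarded.
#'
#' @param track Record tibble.
#' @param policy A [cleaning_policy()].
#' @return List: `track` (cleaned tibble, or `NULL` when discarded),
#'   `removed` (tibble of removed records with a `removal` column:
#'   `"outlier"` or `"dwell"`), `discarded` (logical), `reason`.
#' @export
remove_outliers <- function(track, policy = cleaning_policy()) {
  n0 <- nrow(track)
  removed <- track[0, , drop = FALSE]
  removed$removal <- character(0)

  # accuracy cap first: these fixes are untrustworthy regardless of motion
  bad_acc <- which(!is.finite(track$haccuracy) |
                     track$haccuracy > policy$haccuracy_max)
  if (length(bad_acc) > 0) {
    rem <- track[bad_acc, , drop = FALSE]
    rem$removal <- "outlier"
    removed <- bind_rows(removed, rem)
    track <- track[-bad_acc, , drop = FALSE]
  }

  for (pass in seq_len(10)) {
    if (nrow(track) < 2) break
    track <- add_steps(track)
    idx <- .velocity_outlier_idx(track, policy$v_outlier_max)
    if (length(idx) == 0) break
    rem <- track[idx, , drop = FALSE]
    rem$removal <- "outlier"
    removed <- bind_rows(removed, rem)
    track <- track[-idx, , drop = FALSE]
  }

  n_outlier <- nrow(removed)
  if (n_outlier / n0 > policy$max_outlier_fraction) {
    return(list(track = NULL, removed = removed, discarded = TRUE,
                reason = sprintf("%d/%d records are outliers (> %.0f%%)",
                                 n_outlier, n0,
                                 100 * policy$max_outlier_fraction)))
  }

  # terminal dwell: fixes accumulate near the final position once indoors
  if (nrow(track) >= 2) {
    nn <- nrow(track)
    d_end <- haversine_m(track$latitude, track$longitude,
                         track$latitude[[nn]], track$longitude[[nn]])
    inside <- rev(cumprod(rev(d_end <= policy$endpoint_dwell_radius))) == 1
    seg <- which(inside)
    if (length(seg) > 1) {
      t_seg <- as.numeric(track$time[seg])
      if (max(t_seg) - min(t_seg) > policy$endpoint_dwell_min) {
        drop_idx <- seg[-1]
        rem <- track[drop_idx, , drop = FALSE]
        rem$removal <- "dwell"
        removed <- bind_rows(removed, rem)
        track <- track[-drop_idx, , drop = FALSE]
      }
    }
  }

  if (nrow(track) >= 2) track <- add_steps(track)
  list(track = track, removed = removed, discarded = FALSE,
       reason = NA_character_)
}

#' Run cleaning stages 1-3 on a cohort
#'
#' Applies [filter_non_pedestrian()], [validate_od()] and [remove_outliers()]
#' in that order and assembles a bookkeeping report in which
#' `records_in = records_kept + records_removed` holds exactly per stage.
#'
#' @param cohort Cohort tibble.
#' @param schools School coordinate table (`school`, `latitude`,
#'   `longitude`).
#' @param policy A [cleaning_policy()].
#' @return A `cleaning_result` list: `cohort` (kept trips, step columns
#'   attached), `dispositions` (per-trip `id`, `stage`, `outcome`, `reason`),
#'   `removed_records` (record rows removed at stage 3, with `removal`
#'   labels), `report` (per-stage trip/record counts), `policy`.
#' @export
clean_cohort <- function(cohort, schools, policy = cleaning_policy()) {
  records_in <- sum(purrr::map_int(cohort$track, nrow))
  disp <- list()

  # stage 1
  s1 <- filter_non_pedestrian(cohort, policy)
  disp[[1]] <- s1$dispositions %>%
    filter(.data$removed) %>%
    mutate(stage = "non_pedestrian", outcome = "removed") %>%
    select("id", "stage", "outcome", "reason")
  cur <- s1$kept
  rec_removed_1 <- sum(purrr::map_int(s1$removed$track, nrow))

  # stage 2
  od <- purrr::map2(cur$track, cur$school, function(tr, code) {
    sc <- schools[schools$school == code, ]
    if (nrow(sc) == 0) {
      abort(paste0("no school coordinates supplied for code '", code, "'"))
    }
    validate_od(tr, c(sc$latitude[[1]], sc$longitude[[1]]), policy)
  })
  od_valid <- purrr::map_lgl(od, "valid")
  disp[[2]] <- tibble(id = cur$id[!od_valid], stage = "od_validation",
                      outcome = "removed",
                      reason = purrr::map_chr(od[!od_valid], "reason"))
  rec_removed_2 <- sum(purrr::map_int(cur$track[!od_valid], nrow))
  cur <- cur[od_valid, , drop = FALSE]

  # stage 3
  out <- purrr::map(cur$track, remove_outliers, policy = policy)
  discarded <- purrr::map_lgl(out, "discarded")
  removed_records <- purrr::map2_dfr(out, cur$id, function(o, id) {
    if (nrow(o$removed) == 0) return(NULL)
    mutate(o$removed, id = id, .before = 1)
  })
  # removed records: all records of discarded trips + removed rows of kept trips
  kept_removed_rows <- if (nrow(removed_records) > 0) {
    removed_records[!removed_records$id %in% cur$id[discarded], , drop = FALSE]
  } else removed_records
  rec_removed_3 <- sum(purrr::map_int(cur$track[discarded], nrow)) +
    nrow(kept_removed_rows)
  disp[[3]] <- tibble(id = cur$id[discarded], stage = "outliers",
                      outcome = "removed",
                      reason = purrr::map_chr(out[discarded], "reason"))
  cur$track[!discarded] <- purrr::map(out[!discarded], "track")
  cur <- cur[!discarded, , drop = FALSE]
  cur$n_records <- purrr::map_int(cur$track, nrow)

  dispositions <- bind_rows(
    bind_rows(disp),
    tibble(id = cur$id, stage = "kept", outcome = "kept",
           reason = NA_character_)
  )
  records_kept <- sum(cur$n_records)
  report <- tibble(
    stage = c("non_pedestrian", "od_validation", "outliers"),
    trajectories_removed = c(nrow(s1$removed), sum(!od_valid), sum(discarded)),
    records_removed = c(rec_removed_1, rec_removed_2, rec_removed_3)
  )
  structure(list(cohort = cur, dispositions = dispositions,
                 removed_records = removed_records, report = report,
                 records_in = records_in, records_kept = records_kept,
                 policy = policy),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  cat("GPS trajectory cleaning result\n")
  cat(sprintf("  records in: %d, kept: %d\n", x$records_in, x$records_kept))
  print(x$report)
  invisible(x)
}

#' @importFrom broom tidy
#' @export
broom::tidy

#' @importFrom broom glance
#' @export
broom::glance

#' Tidy per-trip dispositions of a cleaning result
#' @param x A `cleaning_result`.
#' @param ... Unused.
#' @return Tibble of per-trip dispositions.
#' @method tidy cleaning_result
#' @export
tidy.cleaning_result <- function(x, ...) x$dispositions

#' One-row summary of a cleaning result
#' @param x A `cleaning_result`.
#' @param ... Unused.
#' @return One-row tibble of totals.
#' @method glance cleaning_result
#' @export
glance.cleaning_result <- function(x, ...) {
  tibble(
    records_in = x$records_in,
    records_kept = x$records_kept,
    records_removed = sum(x$report$records_removed),
    trajectories_kept = nrow(x$cohort),
    trajectories_removed = sum(x$report$trajectories_removed)
  )
}
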