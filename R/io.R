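#' @title Track CSV dialects, nicknames and filenames
#' @name trajectory-io
#' @description
#' Tracks travel as CSV files in three dialects: the 7-column raw dialect
#' collected by the mobile app (`course, haccuracy, latitude, longitude,
#' speed, time, nickname`), and the 10-column processed / interpolated
#' dialects which append the time-advanced step columns `dt`, `d`, `v`
#' (interval to the next fix in seconds, distance to the next fix in meters,
#' and their ratio in m/s; the last row carries no step values). The
#' participant nickname encodes trip metadata (`ZAF_0001_WALK_ALONE`), and
#' the filename prepends the trip date (`2018-11-05_sgv_2603.csv`).
NULL

.raw_cols <- c("course", "haccuracy", "latitude", "longitude",
               "speed", "time", "nickname")
.step_cols <- c("dt", "d", "v")

#' Known three-letter school codes
#' @return Character vector of the ten school codes.
#' @export
school_codes <- function() {
  c("OAK", "VER", "VIR", "SAN", "IPC", "BEL", "MON", "ZAF", "IFT", "SGV")
}

#' Transport-mode and companionship synonym table
#'
#' Nickname tokens are bilingual (English/Catalan); the shipped table maps
#' each token to a canonical mode or companionship value and can be replaced
#' by the user.
#'
#' @param path Optional path to a replacement CSV with columns
#'   `token,field,value`.
#' @return A tibble with columns `token`, `field` (`"mode"` or
#'   `"companionship"`) and `value`.
#' @export
mode_synonyms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mode_synonyms.csv", package = "pedtrack")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Parse a participant nickname into trip metadata
#'
#' Tokens are split on underscores and matched case-insensitively: the school
#' code against [school_codes()], a numeric token as the teacher-assigned
#' participant number, and the remaining tokens against the bilingual
#' [mode_synonyms()] table. Parsing is total: unknown tokens map to
#' `"unknown"` and an unmatched school code is flagged via `school_matched`
#' rather than raising, so malformed files can be routed to manual review.
#'
#' @param nickname Character vector of nicknames, e.g. `"ZAF_0001_WALK_ALONE"`.
#' @param synonyms Synonym table as returned by [mode_synonyms()].
#' @return A tibble with one row per nickname: `nickname`, `school`,
#'   `participant`, `mode`, `companionship`, `school_matched`.
#' @examples
#' parse_nickname("ZAF_0001_WALK_ALONE")
#' parse_nickname(c("sgv_0601_tren", "zaf_0067_peu", "xyz_0001"))
#' @export
parse_nickname <- function(nickname, synonyms = mode_synonyms()) {
  stopifnot(is.character(nickname))
  purrr::map_dfr(nickname, .parse_one_nickname, synonyms = synonyms)
}

.parse_one_nickname <- function(nick, synonyms) {
  out <- tibble(nickname = nick, school = NA_character_,
                participant = NA_character_, mode = "unknown",
                companionship = "unknown", school_matched = FALSE)
  if (is.na(nick) || !nzchar(nick)) return(out)
  tokens <- strsplit(nick, "_", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(out)
  up <- toupper(tokens)
  if (up[[1]] %in% school_codes()) {
    out$school <- up[[1]]
    out$school_matched <- TRUE
  } else {
    out$school <- up[[1]]
  }
  rest <- up[-1]
  num <- rest[grepl("^[0-9]+$", rest)]
  if (length(num) > 0) out$participant <- num[[1]]
  for (tok in rest) {
    hit <- synonyms[synonyms$token == tok, ]
    if (nrow(hit) == 1) {
      if (hit$field == "mode") out$mode <- hit$value
      if (hit$field == "companionship") out$companionship <- hit$value
    }
  }
  out
}

#' Parse a track filename into date, dialect and metadata
#'
#' Filenames look like `2018-11-05_sgv_2603.csv`, optionally with a
#' `_processed` or `_interpolated` suffix marking the 10-column dialects.
#'
#' @param filename Character vector of paths or basenames.
#' @return A tibble with `filename`, `trip_date` (Date), `dialect`
#'   (`raw`/`processed`/`interpolated`), `nickname`, plus the parsed
#'   nickname metadata columns.
#' @examples
#' parse_filename("2018-11-05_sgv_2603.csv")
#' parse_filename("2018-11-05_sgv_0802_peu_interpolated.csv")
#' @export
parse_filename <- function(filename) {
  purrr::map_dfr(filename, function(f) {
    base <- sub("\\.csv$", "", basename(f), ignore.case = TRUE)
    m <- regmatches(base, regexec("^(\\d{4}-\\d{2}-\\d{2})_(.*)$", base))[[1]]
    if (length(m) == 0) {
      abort(paste0("filename '", f, "' does not start with an ISO date"))
    }
    trip_date <- as.Date(m[[2]])
    rest <- m[[3]]
    dialect <- "raw"
    if (grepl("_processed$", rest, ignore.case = TRUE)) {
      dialect <- "processed"
      rest <- sub("_processed$", "", rest, ignore.case = TRUE)
    } else if (grepl("_interpolated$", rest, ignore.case = TRUE)) {
      dialect <- "interpolated"
      rest <- sub("_interpolated$", "", rest, ignore.case = TRUE)
    }
    meta <- parse_nickname(rest)
    dplyr::bind_cols(tibble(filename = f, trip_date = trip_date,
                            dialect = dialect), meta)
  })
}

.parse_time <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

.format_time <- function(x) {
  format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")
}

#' Read one GPS track CSV
#'
#' Records are time-sorted on read; duplicated timestamps keep the first
#' occurrence and out-of-range coordinates are dropped, both with a message.
#' Raw files in the wild may lack a header row or use decimal commas; both
#' are handled behind reader options (`col_names = "auto"` sniffs the first
#' line).
#'
#' @param path Path to a CSV file in one of the three dialects.
#' @param dialect `"auto"` (from the filename suffix), `"raw"`,
#'   `"processed"` or `"interpolated"`.
#' @param col_names `"auto"`, `TRUE` (header present) or `FALSE`.
#' @param decimal_mark `"."` or `","`.
#' @param quiet Suppress messages about dropped records.
#' @return A tibble of GPS records (7 or 10 columns, `time` as POSIXct)
#'   with attributes `dialect`, `source_filename` and `metadata`.
#' @export
read_track <- function(path, dialect = c("auto", "raw", "processed", "interpolated"),
                       col_names = "auto", decimal_mark = ".", quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- tryCatch(parse_filename(path)$dialect, error = function(e) "raw")
  }
  want <- if (dialect == "raw") .raw_cols else c(.raw_cols, .step_cols)
  if (identical(col_names, "auto")) {
    first_line <- readLines(path, n = 1L)
    col_names <- grepl("latitude", first_line, ignore.case = TRUE)
  }
  loc <- readr::locale(decimal_mark = decimal_mark,
                       grouping_mark = if (decimal_mark == ",") "." else ",")
  dat <- readr::read_csv(path, col_names = col_names, locale = loc,
                         show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA", "NaN"),
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(dat) != length(want)) {
    abort(paste0("'", basename(path), "': expected ", length(want),
                 " columns for the ", dialect, " dialect, found ", ncol(dat)))
  }
  names(dat) <- want
  num_cols <- setdiff(want, c("time", "nickname"))
  dat <- dplyr::mutate(dat, dplyr::across(dplyr::all_of(num_cols), as.numeric))
  dat$time <- .parse_time(dat$time)
  if (nrow(dat) == 0) abort(paste0("'", basename(path), "' contains no records"))

  bad_coord <- is.na(dat$latitude) | is.na(dat$longitude) |
    abs(dat$latitude) > 90 | abs(dat$longitude) > 180 | is.na(dat$time)
  if (any(bad_coord)) {
    if (!quiet) inform(paste0("'", basename(path), "': dropped ",
                              sum(bad_coord), " record(s) with invalid coordinates or time"))
    dat <- dat[!bad_coord, , drop = FALSE]
  }
  dat <- dplyr::arrange(dat, .data$time)
  dup <- duplicated(dat$time)
  if (any(dup)) {
    if (!quiet) inform(paste0("'", basename(path), "': kept first of ",
                              sum(dup), " duplicated timestamp(s)"))
    dat <- dat[!dup, , drop = FALSE]
  }
  meta <- tryCatch(parse_filename(path)[1, ],
                   error = function(e) parse_nickname(dat$nickname[[1]]))
  attr(dat, "dialect") <- dialect
  attr(dat, "source_filename") <- basename(path)
  attr(dat, "metadata") <- meta
  dat
}

#' Write one GPS track CSV
#'
#' Column order is exactly `course, haccuracy, latitude, longitude, speed,
#' time, nickname` plus, for the 10-column dialects, `dt, d, v`. Coordinates
#' are written with 6 decimal places and the last row's step fields are left
#' empty per the time-advanced convention.
#'
#' @param track Record tibble; for 10-column dialects the step columns must
#'   already be attached (see [add_steps()]).
#' @param path Output file path.
#' @param dialect `"raw"`, `"processed"` or `"interpolated"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path,
                        dialect = c("raw", "processed", "interpolated")) {
  dialect <- match.arg(dialect)
  if (nrow(track) == 0) abort("cannot write an empty trajectory")
  missing_raw <- setdiff(.raw_cols, names(track))
  if (length(missing_raw) > 0) {
    abort(paste0("track is missing column(s): ",
                 paste(missing_raw, collapse = ", ")))
  }
  want <- .raw_cols
  if (dialect != "raw") {
    if (!all(.step_cols %in% names(track))) {
      abort("step columns (dt, d, v) must be attached for 10-column dialects; see add_steps()")
    }
    want <- c(.raw_cols, .step_cols)
  }
  out <- track[, want, drop = FALSE]
  out$latitude <- sprintf("%.6f", out$latitude)
  out$longitude <- sprintf("%.6f", out$longitude)
  out$time <- .format_time(out$time)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Assemble a cohort tibble from track tibbles
#'
#' A cohort is the package's working container: one row per trip with parsed
#' metadata columns and the record table nested in the `track` list-column.
#'
#' @param tracks List of record tibbles.
#' @param filenames Optional character vector of source filenames (used to
#'   parse dates and metadata when present as attributes they are reused).
#' @return A cohort tibble with columns `id`, `source_filename`, `trip_date`,
#'   `nickname`, `school`, `participant`, `mode`, `companionship`,
#'   `school_matched`, `direction`, `n_records`, `track`.
#' @export
as_cohort <- function(tracks, filenames = NULL) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  rows <- purrr::imap_dfr(tracks, function(tr, i) {
    fn <- filenames[[i]] %||% attr(tr, "source_filename") %||% NA_character_
    meta <- attr(tr, "metadata")
    if (is.null(meta)) {
      meta <- if (!is.na(fn)) parse_filename(fn) else parse_nickname(tr$nickname[[1]])
    }
    tibble(
      id = i,
      source_filename = if (!is.na(fn)) basename(fn) else NA_character_,
      trip_date = if ("trip_date" %in% names(meta)) meta$trip_date[[1]] else as.Date(NA),
      nickname = tr$nickname[[1]],
      school = meta$school[[1]],
      participant = meta$participant[[1]],
      mode = meta$mode[[1]],
      companionship = meta$companionship[[1]],
      school_matched = meta$school_matched[[1]],
      direction = NA_character_,
      n_records = nrow(tr),
      track = list(as_tibble(as.data.frame(tr)))
    )
  })
  rows
}

#' Read a directory of track CSVs into a cohort
#'
#' @param dir Directory containing `DATE_NICKNAME[_suffix].csv` files.
#' @param dialect Dialect passed to [read_track()].
#' @param quiet Suppress per-file messages.
#' @return A cohort tibble (see [as_cohort()]).
#' @export
read_cohort <- function(dir, dialect = "auto", quiet = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) abort(paste0("no CSV files found in '", dir, "'"))
  tracks <- purrr::map(files, read_track, dialect = dialect, quiet = quiet)
  as_cohort(tracks, filenames = files)
}

#' Write a cohort to per-trip CSV files
#'
#' Filenames follow `DATE_NICKNAME[_processed|_interpolated].csv`. Columns
#' outside the dialect (e.g. the synthetic generator's `truth` labels) are
#' dropped on write.
#'
#' @param cohort Cohort tibble.
#' @param dir Output directory (created if needed).
#' @param dialect Output dialect.
#' @return Character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, dir,
                         dialect = c("raw", "processed", "interpolated")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  suffix <- switch(dialect, raw = "", processed = "_processed",
                   interpolated = "_interpolated")
  paths <- purrr::pmap_chr(
    list(cohort$track, cohort$trip_date, cohort$nickname),
    function(tr, date, nick) {
      date <- if (is.na(date)) "1970-01-01" else format(date)
      path <- file.path(dir, paste0(date, "_", nick, suffix, ".csv"))
      write_track(tr, path, dialect = dialect)
      path
    })
  invisible(paths)
}

#' Infer trip direction from endpoint proximity to the school
#'
#' When the direction (home-to-school vs school-to-home) is not supplied by
#' the run configuration it is inferred: the endpoint nearest the school is
#' taken as the destination, so a track whose last fix is closest to the
#' school is `home_to_school`.
#'
#' @param cohort Cohort tibble.
#' @param schools School coordinate table (`school`, `latitude`, `longitude`),
#'   e.g. [synthetic_schools()].
#' @param overwrite Re-infer even where `direction` is already set.
#' @return The cohort with its `direction` column filled in.
#' @export
infer_direction <- function(cohort, schools, overwrite = FALSE) {
  dirs <- purrr::pmap_chr(
    list(cohort$track, cohort$school, cohort$direction),
    function(tr, code, cur) {
      if (!overwrite && !is.na(cur)) return(cur)
      sc <- schools[schools$school == code, ]
      if (nrow(sc) == 0) return(NA_character_)
      d_first <- haversine_m(tr$latitude[[1]], tr$longitude[[1]],
                             sc$latitude, sc$longitude)
      d_last <- haversine_m(tr$latitude[[nrow(tr)]], tr$longitude[[nrow(tr)]],
                            sc$latitude, sc$longitude)
      if (d_last <= d_first) "home_to_school" else "school_to_home"
    })
  cohort$direction <- dirs
  cohort
}

#' Synthetic school coordinate table
#'
#' The study's real school locations are not part of this package; this table
#' places the ten school codes at synthetic but geographically plausible
#' coordinates in the Barcelona metropolitan area, for use with the synthetic
#' cohort generator and in examples.
#'
#' @return A tibble with columns `school`, `latitude`, `longitude`, `district`.
#' @export
synthetic_schools <- function() {
  readr::read_csv(system.file("extdata", "schools_synthetic.csv",
                              package = "pedtrack"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Export a cohort as GeoJSON LineStrings
#'
#' One LineString feature per trip, for quick inspection in any GIS viewer.
#'
#' @param cohort Cohort tibble.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(cohort, path) {
  features <- purrr::pmap(list(cohort$track, cohort$nickname, cohort$school),
                          function(tr, nick, school) {
    list(
      type = "Feature",
      properties = list(nickname = nick, school = school,
                        n_records = nrow(tr)),
      geometry = list(
        type = "LineString",
        coordinates = purrr::map2(tr$longitude, tr$latitude, c)
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
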