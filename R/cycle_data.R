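# Annual-cycle tracking records: I/O, validation and derived quantities.
#
# A tracking record describes one tracked individual (or a population
# average used as a proxy) over one full annual cycle: coordinates of
# the breeding site and of the first and last non-breeding sites, and
# the four key event dates -- departure from the non-breeding site
# (dep_nb), arrival at the breeding site (arr_b), departure from the
# breeding site (dep_b) and arrival at the non-breeding site (arr_nb).

TRACKING_COLUMNS <- c(
  "record_id", "species", "level", "paper_id", "year", "sex",
  "capture_site_class", "breed_lat", "breed_lon",
  "nb_first_lat", "nb_first_lon", "nb_last_lat", "nb_last_lon",
  "dep_nb", "arr_b", "dep_b", "arr_nb", "flight_mode"
)

TRAIT_COLUMNS <- c("species", "order", "family",
                   "min_mass_female", "min_mass_male")

LEVELS_LEVEL <- c("individual", "population")
LEVELS_SEX <- c("male", "female", "unknown")
LEVELS_CAPTURE <- c("breeding", "nonbreeding", "stopover")
LEVELS_FLIGHT <- c("soaring", "flapping")

#' Read and validate a tracking table
#'
#' Reads a delimited table of annual-cycle tracking records (one row
#' per tracked individual or population) and validates every row.
#' Rows violating a record invariant are rejected with a reason and
#' reported, never silently dropped; population-level rows are treated
#' identically to individual rows.
#'
#' Invariants enforced per row: coordinates within range; Northern-
#' Hemisphere breeding (`breed_lat > 0`); ISO-8601 parseable dates;
#' event order `dep_nb < arr_b < dep_b < arr_nb`, with `arr_nb` before
#' the next year's `dep_nb` so the cycle closes; `year` equal to the
#' calendar year of `dep_nb`; categorical fields among their allowed
#' levels.
#'
#' @param path path to a CSV/TSV file with header columns
#'   `record_id,species,level,paper_id,year,sex,capture_site_class,
#'   breed_lat,breed_lon,nb_first_lat,nb_first_lon,nb_last_lat,
#'   nb_last_lon,dep_nb,arr_b,dep_b,arr_nb,flight_mode`.
#' @param delim field delimiter (default comma).
#' @return a `track_table` data frame of validated records with Date
#'   columns; rejected rows (with row index and reason) are attached as
#'   `attr(, "rejected")` and summarised in a message.
#' @export
read_tracking_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("tracking table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_tracking(raw)
}

#' Validate an in-memory tracking table
#'
#' Same contract as [read_tracking_table()] but starting from a data
#' frame (columns may be character or already typed).
#'
#' @param raw data frame with the tracking columns.
#' @return a `track_table`; see [read_tracking_table()].
#' @export
validate_tracking <- function(raw) {
  missing_cols <- setdiff(TRACKING_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[TRACKING_COLUMNS]
  n <- nrow(raw)
  reasons <- character(n)
  add_reason <- function(bad, why) {
    bad <- which(bad & reasons == "")
    reasons[bad] <<- why
    invisible(NULL)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  year <- num(raw$year)
  lat_cols <- c("breed_lat", "nb_first_lat", "nb_last_lat")
  lon_cols <- c("breed_lon", "nb_first_lon", "nb_last_lon")
  lats <- lapply(raw[lat_cols], num)
  lons <- lapply(raw[lon_cols], num)

  add_reason(!raw$level %in% LEVELS_LEVEL, "invalid level")
  add_reason(!raw$sex %in% LEVELS_SEX, "invalid sex")
  add_reason(!raw$capture_site_class %in% LEVELS_CAPTURE,
             "invalid capture_site_class")
  add_reason(!raw$flight_mode %in% LEVELS_FLIGHT, "invalid flight_mode")
  add_reason(is.na(year) | year != floor(year), "invalid year")

  coord_bad <- Reduce(`|`, c(
    lapply(lats, function(x) is.na(x) | x < -90 | x > 90),
    lapply(lons, function(x) is.na(x) | x < -180 | x > 180)
  ))
  add_reason(coord_bad, "coordinate out of range")
  add_reason(!coord_bad & lats$breed_lat <= 0, "southern-hemisphere breeder")

  iso_date <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  dates <- lapply(raw[c("dep_nb", "arr_b", "dep_b", "arr_nb")], iso_date)
  date_bad <- Reduce(`|`, lapply(dates, is.na))
  add_reason(date_bad, "unparseable date")

  ok_dates <- !date_bad
  next_dep <- rep(as.Date(NA), n)
  next_dep[ok_dates] <- next_year_same_day(dates$dep_nb[ok_dates])
  order_bad <- ok_dates & !(dates$dep_nb < dates$arr_b &
                            dates$arr_b < dates$dep_b &
                            dates$dep_b < dates$arr_nb &
                            dates$arr_nb < next_dep)
  add_reason(order_bad, "event order")
  dep_year <- rep(NA_real_, n)
  dep_year[ok_dates] <-
    as.integer(format(dates$dep_nb[ok_dates], "%Y"))
  add_reason(ok_dates & !is.na(year) & dep_year != year,
             "year does not match dep_nb")

  bad <- reasons != ""
  rejected <- data.frame(row = which(bad),
                         record_id = raw$record_id[bad],
                         reason = reasons[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    msg("rejected ", nrow(rejected), " of ", n, " rows: ",
        paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
              collapse = "; "))
  }

  keep <- !bad
  out <- data.frame(
    record_id = raw$record_id[keep],
    species = raw$species[keep],
    level = raw$level[keep],
    paper_id = raw$paper_id[keep],
    year = as.integer(year[keep]),
    sex = raw$sex[keep],
    capture_site_class = raw$capture_site_class[keep],
    breed_lat = lats$breed_lat[keep], breed_lon = lons$breed_lon[keep],
    nb_first_lat = lats$nb_first_lat[keep],
    nb_first_lon = lons$nb_first_lon[keep],
    nb_last_lat = lats$nb_last_lat[keep],
    nb_last_lon = lons$nb_last_lon[keep],
    dep_nb = dates$dep_nb[keep], arr_b = dates$arr_b[keep],
    dep_b = dates$dep_b[keep], arr_nb = dates$arr_nb[keep],
    flight_mode = raw$flight_mode[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  class(out) <- c("track_table", "data.frame")
  out
}

#' Write a tracking table
#'
#' Inverse of [read_tracking_table()]: writes records at full floating
#' precision (17 significant digits) and ISO dates so that a write/read
#' round trip reproduces the records exactly.
#'
#' @param records a `track_table` or conforming data frame.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(records, path, delim = ",") {
  df <- as.data.frame(records)[TRACKING_COLUMNS]
  for (nm in names(df)) {
    x <- df[[nm]]
    df[[nm]] <- if (inherits(x, "Date")) format(x, "%Y-%m-%d")
                else if (is.double(x)) sprintf("%.17g", x)
                else as.character(x)
  }
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a species trait table
#'
#' @param path CSV with columns
#'   `species,order,family,min_mass_female,min_mass_male`; masses are
#'   minimum (lean) body masses in grams and must be positive.
#' @param delim field delimiter.
#' @return data frame of traits.
#' @export
read_trait_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop("trait table not found: ", path)
  tr <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRAIT_COLUMNS, names(tr))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tr$species)) stop("duplicate species in trait table")
  if (any(!is.finite(tr$min_mass_female) | tr$min_mass_female <= 0) ||
      any(!is.finite(tr$min_mass_male) | tr$min_mass_male <= 0)) {
    stop("trait masses must be positive")
  }
  tr[TRAIT_COLUMNS]
}

#' Resolve the body mass of a record from species traits
#'
#' Minimum (lean) body mass in grams: the female mass for females, the
#' male mass for males, and the arithmetic mean of the two when sex is
#' unknown.
#'
#' @param species,sex vectors (recycled to common length).
#' @param traits trait table from [read_trait_table()].
#' @return numeric vector of masses in grams.
#' @export
resolve_body_mass <- function(species, sex, traits) {
  i <- match(species, traits$species)
  if (anyNA(i)) {
    stop("species absent from trait table: ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  }
  f <- traits$min_mass_female[i]
  m <- traits$min_mass_male[i]
  ifelse(sex == "female", f, ifelse(sex == "male", m, (f + m) / 2))
}

# Same calendar day one year later; Feb 29 maps to Mar 1.
next_year_same_day <- function(d) {
  y <- as.integer(format(d, "%Y")) + 1L
  out <- as.Date(paste0(y, format(d, "-%m-%d")), optional = TRUE)
  if (anyNA(out)) {
    out[is.na(out)] <- as.Date(paste0(y[is.na(out)], "-03-01"))
  }
  out
}

#' Derive cycle durations, day indices and distances per record
#'
#' Computes, for every validated record:
#' * the four period durations in days -- spring (`dep_nb` to `arr_b`),
#'   breeding (`arr_b` to `dep_b`), autumn (`dep_b` to `arr_nb`) and
#'   non-breeding (`arr_nb` to the same calendar day as `dep_nb` one
#'   year later, i.e. arrival at the first non-breeding site to
#'   departure from the last). True calendar arithmetic is used, so the
#'   four durations sum to the record's cycle length (365 or 366).
#' * continuous day indices: days since Jan 1 of the tracking year
#'   (Jan 1 = 1); autumn events after Dec 31 continue past 365.
#' * great-circle migration distances: spring from the last
#'   non-breeding site to the breeding site, autumn from the breeding
#'   site to the first non-breeding site; `mig_dist` is their mean and
#'   is the single distance used in the structural model.
#' * `body_mass` in grams via [resolve_body_mass()], and `nb_lat_abs`,
#'   the mean absolute latitude of the two non-breeding sites.
#'
#' @param records a `track_table`.
#' @param traits trait table covering all species in `records`.
#' @return data frame of grouping variables, covariates and derived
#'   quantities, class `cycle_derived`.
#' @export
derive_cycle <- function(records, traits) {
  if (nrow(records) == 0) stop("no records to derive")
  body_mass <- resolve_body_mass(records$species, records$sex, traits)
  i <- match(records$species, traits$species)

  next_dep <- next_year_same_day(records$dep_nb)
  jan1 <- as.Date(paste0(records$year, "-01-01"))
  doy <- function(d) as.numeric(d - jan1) + 1

  spring <- as.numeric(records$arr_b - records$dep_nb)
  breeding <- as.numeric(records$dep_b - records$arr_b)
  autumn <- as.numeric(records$arr_nb - records$dep_b)
  nonbreeding <- as.numeric(next_dep - records$arr_nb)

  spring_distance <- great_circle_km(records$nb_last_lat,
                                     records$nb_last_lon,
                                     records$breed_lat, records$breed_lon)
  autumn_distance <- great_circle_km(records$breed_lat, records$breed_lon,
                                     records$nb_first_lat,
                                     records$nb_first_lon)

  out <- data.frame(
    record_id = records$record_id,
    species = records$species,
    order = traits$order[i],
    family = traits$family[i],
    level = records$level,
    paper_id = records$paper_id,
    year = records$year,
    sex = records$sex,
    capture_site_class = records$capture_site_class,
    flight_mode = records$flight_mode,
    body_mass = body_mass,
    breed_lat = records$breed_lat,
    nb_lat_abs = (abs(records$nb_first_lat) + abs(records$nb_last_lat)) / 2,
    spring_distance = spring_distance,
    autumn_distance = autumn_distance,
    mig_dist = (spring_distance + autumn_distance) / 2,
    dep_nb_doy = doy(records$dep_nb),
    arr_b_doy = doy(records$arr_b),
    dep_b_doy = doy(records$dep_b),
    arr_nb_doy = doy(records$arr_nb),
    spring_duration = spring,
    breeding_duration = breeding,
    autumn_duration = autumn,
    nonbreeding_duration = nonbreeding,
    cycle_length = as.numeric(next_dep - records$dep_nb),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cycle_derived", "data.frame")
  out
}

EVENT_VARS <- c("dep_nb_doy", "arr_b_doy", "dep_b_doy", "arr_nb_doy")
DURATION_VARS <- c("spring_duration", "breeding_duration",
                   "autumn_duration", "nonbreeding_duration")

# Calendar label for a mean day index, on a non-leap reference year.
doy_label <- function(doy) {
  format(as.Date(round(doy) - 1, origin = "2001-01-01"), "%d %B")
}

#' Two-stage timing summary
#'
#' Species means are taken first (so species tracked many times do not
#' dominate), then the unweighted mean and SD across species, for the
#' four event day indices and the four period durations. Mean events
#' are also reported as calendar dates, and mean durations as a
#' percentage of the mean cycle length.
#'
#' @param derived output of [derive_cycle()].
#' @return list with `species` (per-species means) and `overall`
#'   (across-species mean, SD, n, and for durations `pct_of_cycle`),
#'   class `timing_summary`. With a single species the across-species
#'   SD is `NA`.
#' @export
summarize_timing <- function(derived) {
  if (nrow(derived) == 0) stop("empty input")
  vars <- c(EVENT_VARS, DURATION_VARS)
  sp_means <- stats::aggregate(derived[vars],
                               by = list(species = derived$species), mean)
  sp_n <- as.data.frame(table(species = derived$species),
                        stringsAsFactors = FALSE)
  names(sp_n)[2] <- "n_records"
  species <- merge(sp_means, sp_n, by = "species", sort = TRUE)

  ns <- nrow(species)
  overall <- data.frame(
    variable = vars,
    mean = vapply(species[vars], mean, 0),
    sd = if (ns > 1) vapply(species[vars], stats::sd, 0)
         else rep(NA_real_, length(vars)),
    n_species = ns,
    stringsAsFactors = FALSE
  )
  overall$date <- NA_character_
  ev <- overall$variable %in% EVENT_VARS
  overall$date[ev] <- doy_label(overall$mean[ev])
  overall$pct_of_cycle <- NA_real_
  du <- overall$variable %in% DURATION_VARS
  overall$pct_of_cycle[du] <-
    100 * overall$mean[du] / sum(overall$mean[du])
  rownames(overall) <- NULL
  structure(list(species = species, overall = overall),
            class = "timing_summary")
}

#' @export
print.timing_summary <- function(x, ...) {
  ov <- x$overall
  cat("Timing summary across", ov$n_species[1], "species\n")
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-22s mean %7.1f  sd %6.1f%s\n", ov$variable[i],
                ov$mean[i], ov$sd[i],
                if (!is.na(ov$date[i])) paste0("  (", ov$date[i], ")")
                else sprintf("  (%.1f%% of cycle)", ov$pct_of_cycle[i])))
  }
  invisible(x)
}

#' Paired t test of autumn versus spring migration duration
#'
#' Classical paired t on per-record (autumn - spring) duration
#' differences; df = n - 1.
#'
#' @param derived output of [derive_cycle()].
#' @return list with `t`, `df`, `p_value`, `mean_diff` (days).
#' @export
paired_t_autumn_vs_spring <- function(derived) {
  if (nrow(derived) < 2) stop("need at least 2 records")
  d <- derived$autumn_duration - derived$spring_duration
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  # degenerate zero-variance differences: t = 0 when centred, +-Inf otherwise
  t_stat <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else {
    m / (s / sqrt(n))
  }
  list(t = t_stat, df = n - 1,
       p_value = 2 * stats::pt(-abs(t_stat), n - 1), mean_diff = m)
}
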