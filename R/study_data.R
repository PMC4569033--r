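#' Study data container for the two-season multistate design
#'
#' Assembles observed detection histories and covariates into the validated
#' structure the model consumes. Observed states are coded 1 (no
#' detection), 2 (adult detected), 3 (nest detected); `NA` marks surveys
#' not conducted (the single-survey year-1 design and removal-masked
#' visits). Snag density is log-transformed and standardized across sites;
#' ordinal dates have the year-2 phenology shift subtracted before pooled
#' standardization. Standardization uses the sample (n - 1) standard
#' deviation and the constants are stored in `$transform` so predictions
#' can be mapped back to the raw covariate scales.
#'
#' @param y integer array `N x J x T` of observed states (`NA` allowed).
#' @param snag_raw length-`N` snag densities (stems per hectare, >25 cm
#'   diameter).
#' @param date_raw numeric array `N x J x T` of ordinal dates (`NA` where no
#'   date exists).
#' @param log_offset offset `c` in `log(snag + c)`. The default `NULL`
#'   picks 0 when all densities are positive and 1 when zeros are present.
#' @param date_shift days subtracted from year-2 dates before pooling
#'   (default 8, the delayed-phenology correction).
#' @param site_names optional character vector of site labels.
#' @param validate logical; run [validate_study_data()] (default `TRUE`).
#' @return An object of class `"study_data"`: a list with elements `y`,
#'   `snag_raw`, `snag_std`, `date_raw`, `date_std`, `N`, `J`, `T`,
#'   `site_names` and `transform` (snag/date means, SDs, offset, shift).
#' @export
study_data <- function(y, snag_raw, date_raw, log_offset = NULL,
                       date_shift = 8, site_names = NULL, validate = TRUE) {
  stopifnot(is.array(y), length(dim(y)) == 3L, dim(y)[3] == 2L)
  N <- dim(y)[1]; J <- dim(y)[2]
  y <- array(as.integer(y), dim = dim(y))
  stopifnot(length(snag_raw) == N, all(dim(date_raw) == dim(y)))
  if (is.null(site_names)) site_names <- as.character(seq_len(N))

  if (is.null(log_offset)) log_offset <- if (any(snag_raw <= 0)) 1 else 0
  if (any(snag_raw + log_offset <= 0))
    stop("snag density + log_offset must be positive; set 'log_offset'")
  snag_log <- log(snag_raw + log_offset)
  snag_mean <- mean(snag_log)
  snag_sd <- stats::sd(snag_log)
  # degenerate covariate (single site or constant density): center only
  if (!is.finite(snag_sd) || snag_sd == 0) snag_sd <- 1
  snag_std <- (snag_log - snag_mean) / snag_sd

  shifted <- date_raw
  shifted[, , 2] <- shifted[, , 2] - date_shift
  dvals <- shifted[!is.na(shifted)]
  if (!length(dvals)) stop("no survey dates provided")
  date_mean <- mean(dvals)
  date_sd <- stats::sd(dvals)
  if (!is.finite(date_sd) || date_sd == 0) { date_sd <- 1 }
  date_std <- (shifted - date_mean) / date_sd

  obj <- structure(list(
    y = y, snag_raw = as.numeric(snag_raw), snag_std = as.numeric(snag_std),
    date_raw = date_raw, date_std = date_std,
    N = N, J = J, T = 2L, site_names = site_names,
    transform = list(snag_mean = snag_mean, snag_sd = snag_sd,
                     log_offset = log_offset, date_mean = date_mean,
                     date_sd = date_sd, date_shift = date_shift)),
    class = "study_data")
  if (validate) validate_study_data(obj)
  obj
}

#' Validate a study-data object
#'
#' Checks the structural invariants of the removal design: observed states
#' are in `{1,2,3,NA}`; within each site-year nothing follows the first
#' nest detection (visits stop once reproduction is confirmed); every site
#' has at least one non-missing observation; the stored standardized snag
#' covariate has mean 0 and unit sample variance (to 1e-9); and a
#' standardized date exists wherever an observation does.
#'
#' @param data a [study_data] object.
#' @return `data`, invisibly; errors describe the first violated invariant.
#' @export
validate_study_data <- function(data) {
  stopifnot(inherits(data, "study_data"))
  y <- data$y
  if (!all(y[!is.na(y)] %in% 1:3))
    stop("observed states must be 1, 2, 3 or missing")
  for (i in seq_len(data$N)) for (t in 1:2) {
    row <- y[i, , t]
    hit <- which(!is.na(row) & row == 3L)
    if (length(hit) && hit[1] < data$J &&
        any(!is.na(row[(hit[1] + 1):data$J])))
      stop(sprintf(paste0("site %s year %d: observations recorded after a ",
                          "nest detection violate the removal design"),
                   data$site_names[i], t))
  }
  if (any(apply(y, 1, function(r) all(is.na(r)))))
    stop("every site needs at least one non-missing observation")
  if (abs(mean(data$snag_std)) > 1e-9)
    stop("stored snag_std must have mean 0")
  if (length(unique(data$snag_raw)) > 1L &&
      abs(var(data$snag_std) - 1) > 1e-9)
    stop("stored snag_std must have unit sample variance")
  if (any(is.na(data$date_std[!is.na(y)])) ||
      any(!is.finite(data$date_std[!is.na(y)])))
    stop("date_std must be finite wherever an observation exists")
  invisible(data)
}

#' Apply the removal-design observation mask
#'
#' Reproduces the survey protocol on a complete observation array: year-1
#' surveys after the first (the pilot year had a single visit) and all
#' visits after the first nest detection within a site-year are set to
#' missing. The operation is idempotent.
#'
#' @param y_full integer array `N x J x T` of observed states.
#' @return The masked array.
#' @examples
#' y <- array(c(2, 3, 2, 3), dim = c(1, 4, 2))
#' apply_removal_mask(y)[1, , 2]  # 2 3 NA NA
#' @export
apply_removal_mask <- function(y_full) {
  stopifnot(is.array(y_full), length(dim(y_full)) == 3L)
  J <- dim(y_full)[2]
  y <- y_full
  if (J > 1L) y[, 2:J, 1] <- NA
  for (i in seq_len(dim(y)[1])) for (t in seq_len(dim(y)[3])) {
    row <- y[i, , t]
    hit <- which(!is.na(row) & row == 3L)
    if (length(hit) && hit[1] < J) y[i, (hit[1] + 1):J, t] <- NA
  }
  y
}

#' Read study data from long-format CSV
#'
#' Reads a delimited table with one row per (site, year, survey) and builds
#' a validated [study_data] object. The per-site snag covariate may be a
#' column of the same table (repeated within site) or a separate two-column
#' table mapping site to snag density.
#'
#' @param path CSV path with columns (default names) `site`, `year`,
#'   `survey`, `observed_state`, `ordinal_date`, and optionally
#'   `snag_density`.
#' @param snag_path optional CSV path with columns `site`, `snag_density`.
#' @param schema named list overriding any of the default column names
#'   (`site`, `year`, `survey`, `state`, `date`, `snag`).
#' @inheritParams study_data
#' @return A validated [study_data] object.
#' @export
load_study_data <- function(path, snag_path = NULL, schema = list(),
                            log_offset = NULL, date_shift = 8) {
  sc <- utils::modifyList(list(site = "site", year = "year",
                               survey = "survey", state = "observed_state",
                               date = "ordinal_date", snag = "snag_density"),
                          schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(sc$site, sc$year, sc$survey, sc$state, sc$date)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  st <- df[[sc$state]]
  if (!all(is.na(st) | st %in% 1:3))
    stop("observed_state values must be 1, 2, 3 or missing")
  key <- paste(df[[sc$site]], df[[sc$year]], df[[sc$survey]])
  if (anyDuplicated(key))
    stop("duplicate (site, year, survey) rows")

  sites <- unique(as.character(df[[sc$site]]))  # keep file order
  years <- sort(unique(df[[sc$year]]))
  if (length(years) != 2L) stop("exactly two years of data are required")
  J <- max(df[[sc$survey]])
  N <- length(sites)
  y <- array(NA_integer_, dim = c(N, J, 2))
  dt <- array(NA_real_, dim = c(N, J, 2))
  ii <- match(as.character(df[[sc$site]]), sites)
  tt <- match(df[[sc$year]], years)
  jj <- df[[sc$survey]]
  y[cbind(ii, jj, tt)] <- as.integer(st)
  dt[cbind(ii, jj, tt)] <- df[[sc$date]]

  if (!is.null(snag_path)) {
    sg <- utils::read.csv(snag_path, stringsAsFactors = FALSE)
    if (!all(c(sc$site, sc$snag) %in% names(sg)))
      stop("snag table must have columns ", sc$site, " and ", sc$snag)
    snag <- sg[[sc$snag]][match(sites, as.character(sg[[sc$site]]))]
  } else if (sc$snag %in% names(df)) {
    snag <- vapply(sites, function(s) {
      v <- unique(df[[sc$snag]][as.character(df[[sc$site]]) == s])
      if (length(v) != 1L) stop("snag density must be constant within site")
      v
    }, numeric(1))
  } else stop("missing required column(s): ", sc$snag)
  if (anyNA(snag)) stop("snag density missing for some sites")

  study_data(y, snag, dt, log_offset = log_offset, date_shift = date_shift,
             site_names = sites)
}

#' Write study data to CSV (with a JSON sidecar of transform constants)
#'
#' Serializes a [study_data] object back to the long CSV dialect read by
#' [load_study_data()]; a `load -> write -> load` round trip reproduces the
#' observation array exactly. Rows are written for every cell that has an
#' observation or a scheduled survey date.
#'
#' @param data a [study_data] object.
#' @param path output CSV path.
#' @param sidecar optional path for a JSON file of transformation constants
#'   (default: `path` with extension `.json`).
#' @return `path`, invisibly.
#' @export
write_study_data <- function(data, path, sidecar = NULL) {
  stopifnot(inherits(data, "study_data"))
  rows <- which(!is.na(data$y) | !is.na(data$date_raw), arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 3], rows[, 2]), , drop = FALSE]
  df <- data.frame(
    site = data$site_names[rows[, 1]],
    year = rows[, 3],
    survey = rows[, 2],
    observed_state = data$y[rows],
    ordinal_date = data$date_raw[rows],
    snag_density = data$snag_raw[rows[, 1]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(data$transform, sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.study_data <- function(x, ...) {
  nobs <- sum(!is.na(x$y))
  cat(sprintf("Multistate study data: %d sites, %d years, up to %d surveys\n",
              x$N, x$T, x$J))
  cat(sprintf("  %d observations (%d adult, %d nest detections)\n", nobs,
              sum(x$y == 2L, na.rm = TRUE), sum(x$y == 3L, na.rm = TRUE)))
  cat(sprintf("  snag density: %.1f-%.1f stems/ha (log offset %g)\n",
              min(x$snag_raw), max(x$snag_raw), x$transform$log_offset))
  invisible(x)
}
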