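# Interaction vocabulary for daily focal observation records. Only the first
# two types express positive association; agonistic and tree-foraging records
# are retained on read but excluded from network construction.
INTERACTION_TYPES <- c(
  "affiliative_contact", "coordinated_activity", "agonistic", "tree_foraging"
)

AGE_CLASSES <- c("pup", "juvenile", "adult")

#' Define a log-log weight-to-age calibration model
#'
#' Wild hyraxes not captured as pups are aged from body weight using a sex
#' specific log-log regression calibrated on known-age animals:
#' `log(age) = intercept + slope * log(weight)`, both logs taken in
#' `log_base`. The fitted age is `log_base^(intercept + slope * log(weight))`
#' in `age_unit`.
#'
#' @param intercept Regression intercept on the log-age scale.
#' @param slope Regression slope; must be positive (heavier animals are
#'   older over the calibrated range).
#' @param log_base Base of the logarithms in the published calibration
#'   (default 10).
#' @param age_unit Unit of the fitted age, `"days"` or `"years"`.
#'
#' @return An object of class `age_model`.
#' @seealso [hyrax_age_models()] for the default rock hyrax calibrations.
#' @export
age_model <- function(intercept, slope, log_base = 10,
                      age_unit = c("days", "years")) {
  age_unit <- match.arg(age_unit)
  if (!is.numeric(slope) || slope <= 0) {
    abort("`slope` must be a positive number: age must increase with weight.")
  }
  if (!is.numeric(log_base) || log_base <= 1) {
    abort("`log_base` must be a number greater than 1.")
  }
  structure(
    list(intercept = intercept, slope = slope, log_base = log_base,
         age_unit = age_unit),
    class = "age_model"
  )
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf(
    "<age_model> log%s(age [%s]) = %.7g + %.7g * log%s(weight [kg])\n",
    format(x$log_base), x$age_unit, x$intercept, x$slope, format(x$log_base)
  ))
  invisible(x)
}

#' Default weight-to-age calibrations for rock hyrax
#'
#' Sex-specific log-log body-weight regressions calibrated on known-age
#' (captured-as-pup) rock hyraxes, with age expressed in days and logarithms
#' in base 10 -- the only reading under which 3-4 kg adults map onto
#' biologically plausible ages of a few years.
#'
#' @return Named list with `male` and `female` [age_model()] objects.
#' @export
hyrax_age_models <- function() {
  list(
    male   = age_model(2.3250903, 1.3498142, log_base = 10, age_unit = "days"),
    female = age_model(2.3711934, 1.4997657, log_base = 10, age_unit = "days")
  )
}

#' Estimate age from body weight
#'
#' @param body_weight_kg Positive body weight(s) in kilograms.
#' @param sex `"male"` or `"female"`; selects the model when `models` is the
#'   sex-keyed default list.
#' @param models Either a single [age_model()] applied to all animals, or a
#'   named list of models keyed by sex (default [hyrax_age_models()]).
#'
#' @return Estimated age(s) in the model's `age_unit`.
#' @examples
#' estimate_age(3.5, "female")
#' @export
estimate_age <- function(body_weight_kg, sex = NULL,
                         models = hyrax_age_models()) {
  if (any(!is.finite(body_weight_kg)) || any(body_weight_kg <= 0)) {
    abort("`body_weight_kg` must be finite and positive.")
  }
  pick <- function(s) {
    if (inherits(models, "age_model")) return(models)
    m <- models[[s]]
    if (is.null(m)) abort(sprintf("No age model available for sex '%s'.", s))
    m
  }
  if (inherits(models, "age_model")) {
    m <- models
    m$log_base^(m$intercept + m$slope * log(body_weight_kg, base = m$log_base))
  } else {
    sex <- as.character(sex)
    if (length(sex) == 1L) sex <- rep(sex, length(body_weight_kg))
    vapply(seq_along(body_weight_kg), function(i) {
      m <- pick(sex[[i]])
      m$log_base^(m$intercept +
                    m$slope * log(body_weight_kg[[i]], base = m$log_base))
    }, numeric(1))
  }
}

#' Assign an age class from age in years
#'
#' Pups are animals up to and including one year old, juveniles are older
#' than one but younger than two, and adults are two years old or more.
#'
#' @param age_years Nonnegative age(s) in years.
#' @return Factor with levels `pup`, `juvenile`, `adult`.
#' @export
assign_age_class <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 0)) {
    abort("`age_years` must be finite and nonnegative.")
  }
  cls <- ifelse(age_years <= 1, "pup",
                ifelse(age_years < 2, "juvenile", "adult"))
  factor(cls, levels = AGE_CLASSES)
}

#' Reference birthdate for young animals captured at a known age class
#'
#' Breeding is synchronous, so pups are aged from March 1 of the capture
#' year and yearling juveniles from March 1 of the previous year. Adults
#' have no reference birthdate; their age comes from the weight model.
#'
#' @param capture_year Calendar year of first capture.
#' @param age_class_at_capture `"pup"` or `"juvenile"`; `"adult"` is an
#'   error directing the caller to [estimate_age()].
#' @return A `Date`.
#' @export
reference_birthdate <- function(capture_year, age_class_at_capture) {
  age_class_at_capture <- match.arg(age_class_at_capture, AGE_CLASSES)
  if (!is.numeric(capture_year) || capture_year < 1800) {
    abort("`capture_year` must be a plausible calendar year.")
  }
  if (age_class_at_capture == "adult") {
    abort(paste(
      "Adults have no reference birthdate;",
      "estimate age from body weight with `estimate_age()`."
    ), class = "socnetlong_use_age_model")
  }
  yr <- if (age_class_at_capture == "pup") capture_year else capture_year - 1
  as.Date(sprintf("%d-03-01", as.integer(yr)))
}

# ---- readers / writers -----------------------------------------------------

obs_required_cols <- c("date", "site", "event_id", "individual_id",
                       "interaction_type", "marked")

#' Read daily observation records
#'
#' Reads a long-format CSV with one row per individual per interaction
#' event: columns `date` (ISO-8601), `site`, `event_id`, `individual_id`,
#' `interaction_type` (one of `affiliative_contact`, `coordinated_activity`,
#' `agonistic`, `tree_foraging`) and `marked` (0/1). A `schema` mapping may
#' rename nonstandard columns, e.g. `c(individual_id = "animal")`.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping standard names to
#'   the file's column names.
#' @return A tibble of observation records with parsed dates and logical
#'   `marked`; duplicated (event, individual) rows are collapsed.
#' @export
read_observations <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw)) {
        abort(sprintf("Schema column '%s' (for '%s') not in file.",
                      schema[[std]], std))
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  missing <- setdiff(obs_required_cols, names(raw))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "socnetlong_schema_error")
  }
  if (nrow(raw) == 0) return(as_observation_tbl(raw[obs_required_cols]))

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(date))
  if (length(bad_date)) {
    abort(sprintf("Unparseable date(s) at data row(s): %s",
                  paste(head(bad_date, 10), collapse = ", ")),
          class = "socnetlong_row_error")
  }
  bad_type <- which(!raw$interaction_type %in% INTERACTION_TYPES)
  if (length(bad_type)) {
    abort(sprintf(
      "Unknown interaction_type '%s' at data row(s): %s",
      raw$interaction_type[bad_type[1]],
      paste(head(bad_type, 10), collapse = ", ")
    ), class = "socnetlong_row_error")
  }
  out <- tibble::tibble(
    date = date,
    site = raw$site,
    event_id = raw$event_id,
    individual_id = raw$individual_id,
    interaction_type = raw$interaction_type,
    marked = raw$marked %in% c("1", "TRUE", "true", "T")
  )
  dplyr::distinct(out, .data$event_id, .data$individual_id, .keep_all = TRUE)
}

as_observation_tbl <- function(x) {
  tibble::tibble(
    date = as.Date(character()),
    site = character(), event_id = character(),
    individual_id = character(), interaction_type = character(),
    marked = logical()
  )[seq_len(nrow(x)), ]
}

#' Write observation records
#'
#' Inverse of [read_observations()]; `marked` is written as 0/1.
#'
#' @param records Observation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  out <- dplyr::mutate(records,
                       date = format(.data$date, "%Y-%m-%d"),
                       marked = as.integer(.data$marked))
  readr::write_csv(out[obs_required_cols], path, progress = FALSE)
  invisible(path)
}

#' Read individual capture metadata
#'
#' Columns: `id`, `sex` (`female`/`male`/`unknown`), `first_capture_date`
#' (ISO-8601), `body_weight_kg` (optional, positive), `known_age` (0/1).
#'
#' @param path Path to the CSV file.
#' @return Tibble of individuals; `id` must be unique.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("id", "sex", "first_capture_date", "body_weight_kg", "known_age")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "socnetlong_schema_error")
  }
  out <- tibble::tibble(
    id = raw$id,
    sex = raw$sex,
    first_capture_date = as.Date(raw$first_capture_date),
    body_weight_kg = as.numeric(raw$body_weight_kg),
    known_age = raw$known_age %in% c("1", "TRUE", "true", "T")
  )
  if (anyDuplicated(out$id)) {
    abort("Individual `id` values must be unique.",
          class = "socnetlong_schema_error")
  }
  bad_sex <- which(!out$sex %in% c("female", "male", "unknown"))
  if (length(bad_sex)) {
    abort(sprintf("Invalid sex at data row(s): %s",
                  paste(head(bad_sex, 10), collapse = ", ")),
          class = "socnetlong_row_error")
  }
  bad_w <- which(!is.na(out$body_weight_kg) & out$body_weight_kg <= 0)
  if (length(bad_w)) {
    abort(sprintf("Nonpositive body weight at data row(s): %s",
                  paste(head(bad_w, 10), collapse = ", ")),
          class = "socnetlong_row_error")
  }
  out
}

#' @rdname read_individuals
#' @param individuals Individuals tibble.
#' @param path Output CSV path.
#' @export
write_individuals <- function(individuals, path) {
  out <- dplyr::mutate(individuals,
                       first_capture_date = format(.data$first_capture_date,
                                                   "%Y-%m-%d"),
                       known_age = as.integer(.data$known_age))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
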