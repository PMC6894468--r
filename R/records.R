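#' Read long-format time-use diary records
#'
#' Reads a delimited (comma or tab, auto-detected) diary file with one row
#' per recalled activity episode and validates it against a taxonomy.
#' Required columns: \code{person_id}, \code{day_id}, \code{day_type}
#' (\code{"weekday"} or \code{"weekend"}), \code{activity_code}; optional:
#' \code{duration} in minutes.
#'
#' @param path path to the diary file.
#' @param taxonomy an \code{activity_taxonomy}; every \code{activity_code}
#'   must be mapped by it.
#' @param quiet suppress the record-count message.
#' @return A validated data.frame of diary records (class
#'   \code{time_use_records}).
#' @export
read_records <- function(path, taxonomy, quiet = FALSE) {
  if (!file.exists(path)) stop("diary file not found: ", path)
  raw <- read_delim_auto(path)
  validate_records(raw, taxonomy, quiet = quiet)
}

#' Validate a data.frame of diary records
#'
#' @param records data.frame with the diary columns (see
#'   \code{\link{read_records}}).
#' @inheritParams read_records
#' @export
validate_records <- function(records, taxonomy, quiet = FALSE) {
  required <- c("person_id", "day_id", "day_type", "activity_code")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("diary is missing required column(s): ", paste(missing, collapse = ", "))
  }
  records$person_id <- as.character(records$person_id)
  records$day_id <- as.character(records$day_id)
  records$day_type <- as.character(records$day_type)
  records$activity_code <- as.character(records$activity_code)
  bad_type <- setdiff(unique(records$day_type), c("weekday", "weekend"))
  if (length(bad_type)) {
    stop("day_type must be 'weekday' or 'weekend'; found: ",
         paste(bad_type, collapse = ", "))
  }
  unknown <- setdiff(unique(records$activity_code),
                     taxonomy$activity_map$activity_code)
  if (length(unknown)) {
    stop("activity code(s) not in taxonomy: ",
         paste(sort(unknown), collapse = ", "))
  }
  if ("duration" %in% names(records)) {
    records$duration <- as.numeric(records$duration)
    if (any(records$duration < 0, na.rm = TRUE)) {
      stop("durations must be non-negative minutes")
    }
    day_tot <- tapply(records$duration,
                      paste(records$person_id, records$day_id, sep = "\r"),
                      sum, na.rm = TRUE)
    if (any(day_tot > 1440 + 1e-8)) {
      stop("person-day durations exceed 1440 minutes for ",
           sum(day_tot > 1440 + 1e-8), " person-day(s)")
    }
  }
  if (!quiet) message("read ", nrow(records), " diary records for ",
                      length(unique(records$person_id)), " persons")
  class(records) <- c("time_use_records", "data.frame")
  records
}

#' Age-group bins
#'
#' Deterministic half-open bins: [0,20), [20,40), [40,60), [60,Inf),
#' labelled \code{"<20"}, \code{"20-39"}, \code{"40-59"}, \code{"60+"}.
#'
#' @param age numeric vector of ages in years.
#' @return Factor of age-group labels.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(0, 20, 40, 60, Inf), right = FALSE,
      labels = c("<20", "20-39", "40-59", "60+"))
}

#' Read a demographics table
#'
#' Delimited file with columns \code{person_id}, \code{gender}
#' (\code{"male"}/\code{"female"}) and \code{age} (years); an
#' \code{age_group} column is derived with \code{\link{age_group}}.
#'
#' @param path path to the demographics file.
#' @return data.frame with person_id, gender, age, age_group.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop("demographics file not found: ", path)
  raw <- read_delim_auto(path)
  missing <- setdiff(c("person_id", "gender", "age"), names(raw))
  if (length(missing)) {
    stop("demographics file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  raw$person_id <- as.character(raw$person_id)
  raw$gender <- as.character(raw$gender)
  bad <- setdiff(unique(raw$gender), c("male", "female"))
  if (length(bad)) {
    stop("gender must be 'male' or 'female'; found: ", paste(bad, collapse = ", "))
  }
  raw$age <- as.numeric(raw$age)
  raw$age_group <- age_group(raw$age)
  raw[, c("person_id", "gender", "age", "age_group")]
}
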