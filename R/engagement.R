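#' Dichotomize diary records into a binary engagement matrix
#'
#' A person engages in an activity if they have at least one diary record
#' mapping to it anywhere in their recall window (all recalled days pooled,
#' unweighted); \code{window = "per_day"} instead treats each person-day as
#' the observation unit. At \code{level = "subdomain"} the base is first
#' restricted to persons with any Exercise and Sport engagement, and
#' penetration is relative to that engager base.
#'
#' @param records diary records (see \code{\link{read_records}}).
#' @param taxonomy an \code{activity_taxonomy}.
#' @param level aggregate to everyday domains or to the Exercise and Sport
#'   sub-domains.
#' @param window \code{"pooled"} (default: any record over the whole recall
#'   window) or \code{"per_day"} (units are person-days).
#' @param es_domain label of the domain that carries the sub-domains.
#' @return An \code{engagement_matrix}: a 0/1 integer matrix (persons in
#'   rows, activities in columns, columns sorted by descending penetration,
#'   ties alphabetical) with attributes \code{penetration} (percent) and
#'   \code{level}.
#' @export
dichotomize <- function(records, taxonomy, level = c("domain", "subdomain"),
                        window = c("pooled", "per_day"),
                        es_domain = "Exercise and Sport") {
  level <- match.arg(level)
  window <- match.arg(window)
  if (!nrow(records)) stop("no diary records to dichotomize")
  unit <- if (window == "pooled") records$person_id else
    paste(records$person_id, records$day_id, sep = "\r")
  all_units <- unique(unit)

  if (level == "subdomain") {
    dom <- map_activities(records$activity_code, taxonomy, "domain")
    engaged_units <- unique(unit[dom == es_domain])
    if (!length(engaged_units)) {
      stop("no ", es_domain, " engagers; sub-domain analysis impossible")
    }
    keep <- unit %in% engaged_units
    records <- records[keep, , drop = FALSE]
    unit <- unit[keep]
    all_units <- engaged_units
    lab <- map_activities(records$activity_code, taxonomy, "subdomain")
    keep <- !is.na(lab)
    records <- records[keep, , drop = FALSE]
    unit <- unit[keep]
    lab <- lab[keep]
  } else {
    lab <- map_activities(records$activity_code, taxonomy, "domain")
  }

  acts <- sort(unique(lab))
  mat <- matrix(0L, nrow = length(all_units), ncol = length(acts),
                dimnames = list(all_units, acts))
  mat[cbind(match(unit, all_units), match(lab, acts))] <- 1L
  as_engagement_matrix(mat, level = level)
}

#' Construct an engagement matrix from a binary matrix
#'
#' @param mat 0/1 matrix, persons in rows (rownames = ids), activities in
#'   columns (colnames = labels).
#' @param level label recorded on the object (\code{"domain"},
#'   \code{"subdomain"} or anything descriptive).
#' @return An \code{engagement_matrix} with columns sorted by descending
#'   penetration (ties alphabetical).
#' @export
as_engagement_matrix <- function(mat, level = "domain") {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) stop("engagement matrix needs activity column names")
  if (!all(mat %in% c(0L, 1L))) stop("engagement must be strictly 0/1")
  storage.mode(mat) <- "integer"
  pen <- 100 * colSums(mat) / nrow(mat)
  ord <- order_by_penetration(pen)
  mat <- mat[, ord, drop = FALSE]
  structure(mat, penetration = pen[ord], level = level,
            class = c("engagement_matrix", class(mat)))
}

#' Per-activity penetration of an engagement matrix
#'
#' Penetration (prevalence) is the percentage of the person base engaging
#' in the activity at least once in the window.
#'
#' @param x an \code{engagement_matrix}.
#' @return Named numeric vector of percentages in [0, 100].
#' @export
penetration <- function(x) {
  stopifnot(inherits(x, "engagement_matrix"))
  attr(x, "penetration")
}

#' @export
print.engagement_matrix <- function(x, ...) {
  cat("Engagement matrix (", attr(x, "level"), " level): ",
      nrow(x), " persons x ", ncol(x), " activities\n", sep = "")
  print(round(penetration(x), 1))
  invisible(x)
}

#' Weekday/weekend-weighted mean daily minutes per person and activity
#'
#' Mean daily minutes are computed separately over a person's recalled
#' weekdays and weekend days (days with no record of the activity count as
#' zero minutes) and combined as (5 x weekday mean + 2 x weekend mean) / 7
#' by default. A person who recalled only one day type gets that type's
#' mean unchanged. The weighting applies only to duration summaries; binary
#' engagement is never day-weighted.
#'
#' @param records diary records with a \code{duration} column.
#' @param taxonomy an \code{activity_taxonomy}.
#' @param level aggregate to domains or sub-domains.
#' @param weights length-2 numeric, weekday and weekend weights (default
#'   \code{c(weekday = 5, weekend = 2)}).
#' @return Numeric matrix of mean minutes/day, persons x activities.
#' @export
weighted_daily_minutes <- function(records, taxonomy,
                                   level = c("domain", "subdomain"),
                                   weights = c(weekday = 5, weekend = 2)) {
  level <- match.arg(level)
  if (!"duration" %in% names(records) || all(is.na(records$duration))) {
    stop("no durations present; use dichotomize() for binary engagement")
  }
  records <- records[!is.na(records$duration), , drop = FALSE]
  lab <- map_activities(records$activity_code, taxonomy, level)
  keep <- !is.na(lab)
  records <- records[keep, , drop = FALSE]
  lab <- lab[keep]

  persons <- sort(unique(records$person_id))
  acts <- sort(unique(lab))
  # recalled days per person and type (a day counts even if the activity
  # does not occur on it)
  day_key <- unique(records[, c("person_id", "day_id", "day_type")])
  n_days <- table(factor(day_key$person_id, persons), factor(day_key$day_type,
                  c("weekday", "weekend")))

  out <- matrix(0, length(persons), length(acts),
                dimnames = list(persons, acts))
  for (ty in c("weekday", "weekend")) {
    sel <- records$day_type == ty
    if (!any(sel)) next
    tot <- tapply(records$duration[sel],
                  list(factor(records$person_id[sel], persons),
                       factor(lab[sel], acts)),
                  sum)
    tot[is.na(tot)] <- 0
    nd <- as.numeric(n_days[, ty])
    mean_ty <- sweep(tot, 1, pmax(nd, 1), "/")
    mean_ty[nd == 0, ] <- 0
    w <- ifelse(ty == "weekday", weights[["weekday"]], weights[["weekend"]])
    # persons lacking the other type fall back to this type's mean alone
    other <- as.numeric(n_days[, setdiff(c("weekday", "weekend"), ty)])
    eff_w <- ifelse(other == 0, sum(weights), w)
    out <- out + sweep(mean_ty, 1, eff_w / sum(weights), "*")
  }
  out
}
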