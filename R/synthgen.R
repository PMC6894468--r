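#' Configuration for the synthetic diary generator
#'
#' Defaults emulate the study conditions the analysis was designed around:
#' 2307 adults, the eleven everyday domains at their observed prevalences,
#' an average of 3.1 recalled days per person with a 5:7 weekday mix, a
#' 44/56 male/female split and a 33/40/10/17 age-bin distribution. Under
#' the null configuration every person engages each activity independently
#' with its target prevalence; \code{partition_specs} tilt the joint
#' probability of a pair to \code{lambda * pA * pB} (lambda = 1 is
#' independence) and \code{segment_specs} multiply one group's prevalence
#' for one activity.
#'
#' @param n_persons number of persons.
#' @param activities named numeric vector: target prevalence percent per
#'   activity label, each in (0, 100].
#' @param days_per_person mean recalled days (>= 1; extra days beyond the
#'   first are Poisson).
#' @param weekday_fraction probability a recalled day is a weekday.
#' @param partition_specs list of \code{list(pair = c(A, B), lambda = x)}.
#' @param segment_specs list of \code{list(activity =, group =, multiplier =)}.
#' @param gender_split named proportions for male/female (percent or
#'   fractions).
#' @param age_distribution named proportions over the four age bins.
#' @param seed integer seed; identical config + seed gives identical output.
#' @return A \code{synthetic_config}.
#' @export
synthetic_config <- function(n_persons = 2307,
                             activities = c(
                               "Sleep" = 100, "Self-care" = 100,
                               "Social" = 94, "Passive Transport" = 93,
                               "Screen Time" = 92, "Chores" = 91,
                               "Work and Study" = 88, "Quiet Time" = 87,
                               "Active Transport" = 86,
                               "Exercise and Sport" = 55, "Cultural" = 14),
                             days_per_person = 3.1,
                             weekday_fraction = 5 / 7,
                             partition_specs = list(),
                             segment_specs = list(),
                             gender_split = c(male = 44, female = 56),
                             age_distribution = c("<20" = 33, "20-39" = 40,
                                                  "40-59" = 10, "60+" = 17),
                             seed = 1L) {
  if (!is.numeric(n_persons) || n_persons < 1) stop("n_persons must be positive")
  if (is.null(names(activities)) || any(!nzchar(names(activities)))) {
    stop("activities must be a named prevalence vector")
  }
  if (any(activities <= 0 | activities > 100)) {
    stop("target prevalences must lie in (0, 100]")
  }
  if (days_per_person < 1) stop("days_per_person must be >= 1")
  for (ps in partition_specs) {
    if (!all(ps$pair %in% names(activities))) {
      stop("partition pair names unknown activity: ",
           paste(setdiff(ps$pair, names(activities)), collapse = ", "))
    }
    if (ps$lambda < 0) stop("lambda must be >= 0")
  }
  for (ss in segment_specs) {
    if (!ss$activity %in% names(activities)) {
      stop("segment spec names unknown activity: ", ss$activity)
    }
    if (!ss$group %in% c(names(gender_split), names(age_distribution))) {
      stop("segment spec names unknown group: ", ss$group)
    }
  }
  structure(
    list(n_persons = as.integer(n_persons), activities = activities,
         days_per_person = days_per_person,
         weekday_fraction = weekday_fraction,
         partition_specs = partition_specs, segment_specs = segment_specs,
         gender_split = gender_split / sum(gender_split),
         age_distribution = age_distribution / sum(age_distribution),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Add a pairwise co-engagement tilt to a config
#'
#' Returns a new config in which the joint engagement probability of the
#' pair is \code{lambda * pA * pB} (clipped to the Frechet bounds with a
#' warning at generation time). \code{lambda > 1} produces above-independence
#' co-engagement that downstream deviation analysis should detect as a
#' positive partition; \code{lambda = 0} makes the pair mutually exclusive.
#'
#' @param config a \code{synthetic_config}.
#' @param pair character vector of two activity labels.
#' @param lambda joint-probability multiplier (>= 0).
#' @return A new \code{synthetic_config}.
#' @export
inject_partition <- function(config, pair, lambda) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- unclass(config)
  cfg$partition_specs <- c(cfg$partition_specs,
                           list(list(pair = pair, lambda = lambda)))
  do.call(synthetic_config, cfg)
}

#' Add a demographic prevalence skew to a config
#'
#' Multiplies one group's engagement probability for one activity, leaving
#' other groups at the target prevalence; downstream composition analysis
#' should flag the (activity, group) skew for multipliers well above 1.
#'
#' @param config a \code{synthetic_config}.
#' @param activity activity label.
#' @param group demographic group (a gender level or age bin).
#' @param multiplier prevalence multiplier (> 0).
#' @return A new \code{synthetic_config}.
#' @export
inject_segmentation <- function(config, activity, group, multiplier) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- unclass(config)
  cfg$segment_specs <- c(cfg$segment_specs,
                         list(list(activity = activity, group = group,
                                   multiplier = multiplier)))
  do.call(synthetic_config, cfg)
}

# typical daily minutes by domain for simulated durations (log-normal
# medians; arbitrary but plausible, carry no analysis weight)
duration_median <- function(labels) {
  med <- c("Sleep" = 480, "Self-care" = 60, "Social" = 60,
           "Passive Transport" = 40, "Screen Time" = 120, "Chores" = 60,
           "Work and Study" = 300, "Quiet Time" = 45,
           "Active Transport" = 30, "Exercise and Sport" = 45,
           "Cultural" = 60)
  out <- med[labels]
  out[is.na(out)] <- 45
  unname(out)
}

#' Generate a synthetic cohort
#'
#' Realizes person-level binary engagement from the config (independent
#' Bernoulli per activity, with pairwise tilts applied via a sequential
#' conditional construction and per-group prevalence multipliers), then
#' expands each engagement into 1-3 diary records spread over the person's
#' recalled days with log-normal durations (rescaled so no person-day
#' exceeds 1440 minutes).
#'
#' @param config a \code{synthetic_config}.
#' @return A \code{synthetic_cohort}: list with \code{records} (diary
#'   data.frame), \code{demographics}, \code{engagement} (the realized 0/1
#'   person x activity matrix) and \code{truth} (the engagement
#'   probabilities actually used, sufficient to recompute expected
#'   statistics analytically).
#' @export
generate_engagement <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_persons
  acts <- names(config$activities)
  p <- config$activities / 100

  ids <- sprintf("p%04d", seq_len(n))
  gender <- sample(names(config$gender_split), n, replace = TRUE,
                   prob = config$gender_split)
  bins <- names(config$age_distribution)
  bin <- sample(bins, n, replace = TRUE, prob = config$age_distribution)
  age_lo <- c("<20" = 16, "20-39" = 20, "40-59" = 40, "60+" = 60)[bin]
  age_hi <- c("<20" = 20, "20-39" = 40, "40-59" = 60, "60+" = 90)[bin]
  age <- floor(stats::runif(n, age_lo, age_hi))
  demographics <- data.frame(person_id = ids, gender = gender, age = age,
                             age_group = age_group(age),
                             stringsAsFactors = FALSE)

  # per-person engagement probability matrix, after segment multipliers
  prob <- matrix(rep(p, each = n), nrow = n, dimnames = list(ids, acts))
  clipped <- character()
  for (ss in config$segment_specs) {
    in_group <- gender == ss$group | bin == ss$group
    pa <- prob[in_group, ss$activity] * ss$multiplier
    if (any(pa > 1)) clipped <- c(clipped, ss$activity)
    prob[in_group, ss$activity] <- pmin(pa, 1)
  }
  if (length(clipped)) {
    warning("per-group prevalence clipped to 100% for: ",
            paste(unique(clipped), collapse = ", "))
  }

  engaged <- matrix(0L, n, length(acts), dimnames = list(ids, acts))
  tilted <- unlist(lapply(config$partition_specs, `[[`, "pair"))
  truth_joint <- list()
  for (a in acts) {
    if (a %in% tilted) next
    engaged[, a] <- as.integer(stats::runif(n) < prob[, a])
  }
  for (ps in config$partition_specs) {
    a <- ps$pair[1]; b <- ps$pair[2]
    pa <- prob[, a]; pb <- prob[, b]
    joint <- ps$lambda * pa * pb
    lo <- pmax(0, pa + pb - 1); hi <- pmin(pa, pb)
    if (any(joint < lo - 1e-12 | joint > hi + 1e-12)) {
      warning("joint probability for (", a, ", ", b,
              ") clipped to the Frechet bounds")
    }
    joint <- pmin(pmax(joint, lo), hi)
    ea <- stats::runif(n) < pa
    p_b_given <- ifelse(ea, joint / pa,
                        ifelse(pa < 1, (pb - joint) / (1 - pa), 0))
    engaged[, a] <- as.integer(ea)
    engaged[, b] <- as.integer(stats::runif(n) < p_b_given)
    truth_joint[[paste(a, b, sep = " & ")]] <-
      list(pair = c(a, b), lambda = ps$lambda, joint = unname(joint[1]))
  }

  # recall days: at least one, extras Poisson, types iid weekday/weekend
  n_days <- 1L + stats::rpois(n, config$days_per_person - 1)
  day_types <- lapply(n_days, function(k)
    ifelse(stats::runif(k) < config$weekday_fraction, "weekday", "weekend"))

  # expand each engagement into 1-3 records on distinct recalled days
  res_act <- vector("list", n)
  res_day <- vector("list", n)
  for (i in seq_len(n)) {
    on <- which(engaged[i, ] == 1L)
    if (!length(on)) next
    k <- n_days[i]
    n_rec <- pmin(sample(3L, length(on), replace = TRUE), k)
    res_day[[i]] <- unlist(lapply(n_rec, function(m) sample.int(k, m)),
                           use.names = FALSE)
    res_act[[i]] <- rep(on, n_rec)
  }
  if (!sum(lengths(res_act))) stop("no engagement realized in the cohort")
  pid <- rep(seq_len(n), lengths(res_act))
  act <- acts[unlist(res_act, use.names = FALSE)]
  day <- unlist(res_day, use.names = FALSE)
  dtype <- unlist(mapply(function(types, d) types[d], day_types, res_day,
                         SIMPLIFY = FALSE), use.names = FALSE)
  dur <- stats::rlnorm(length(act), log(duration_median(act)), 0.5)
  # keep each person-day within a 24 h budget; round down so the rescaled
  # sums cannot creep back over 1440
  tot <- stats::ave(dur, paste(pid, day), FUN = sum)
  dur <- ifelse(tot > 1440, dur * 1440 / tot, dur)
  records <- data.frame(person_id = ids[pid],
                        day_id = sprintf("d%d", day),
                        day_type = dtype, activity_code = act,
                        duration = floor(dur * 10) / 10,
                        stringsAsFactors = FALSE)

  truth <- list(target_prevalence = config$activities,
                group_prevalence = segment_truth(config),
                partitions = truth_joint,
                gender_split = config$gender_split,
                age_distribution = config$age_distribution,
                seed = config$seed)
  structure(list(records = records, demographics = demographics,
                 engagement = engaged, truth = truth, config = config),
            class = "synthetic_cohort")
}

# per-(activity, group) engagement probabilities implied by the config
segment_truth <- function(config) {
  p <- config$activities / 100
  out <- list()
  for (ss in config$segment_specs) {
    out[[paste(ss$activity, ss$group, sep = " & ")]] <-
      list(activity = ss$activity, group = ss$group,
           probability = min(1, p[[ss$activity]] * ss$multiplier))
  }
  out
}

#' Taxonomy implied by a synthetic config or cohort
#'
#' The generator works at domain/sub-domain level: each activity label in
#' the config doubles as its own diary activity code, using the
#' \code{"Domain/Subdomain"} slash convention of \code{\link{read_taxonomy}}.
#' This returns the matching \code{activity_taxonomy} so generated diaries
#' can be read back with \code{\link{read_records}} and
#' \code{\link{dichotomize}}.
#'
#' @param x a \code{synthetic_config} or \code{synthetic_cohort}.
#' @return An \code{activity_taxonomy}.
#' @export
synthetic_taxonomy <- function(x) {
  if (inherits(x, "synthetic_cohort")) x <- x$config
  stopifnot(inherits(x, "synthetic_config"))
  labels <- names(x$activities)
  parts <- strsplit(labels, "/", fixed = TRUE)
  map <- data.frame(
    activity_code = labels,
    domain = vapply(parts, `[`, character(1), 1L),
    subdomain = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                       character(1)),
    stringsAsFactors = FALSE
  )
  activity_taxonomy(map)
}

#' Write a synthetic cohort to delimited files
#'
#' Writes \code{diary.csv} and \code{demographics.csv} in the formats
#' \code{\link{read_records}} and \code{\link{read_demographics}} read, a
#' \code{taxonomy.tsv} mapping the diary codes (see
#' \code{\link{synthetic_taxonomy}}), and a machine-readable
#' \code{truth.json} sidecar with the generating probabilities.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(diary = file.path(dir, "diary.csv"),
             demographics = file.path(dir, "demographics.csv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(cohort$records, paths[["diary"]], row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(cohort$demographics[, c("person_id", "gender", "age")],
                   paths[["demographics"]], row.names = FALSE, quote = FALSE)
  tax <- data.frame(activity_code = names(cohort$config$activities),
                    domain = names(cohort$config$activities),
                    stringsAsFactors = FALSE)
  utils::write.table(tax, paths[["taxonomy"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(jsonlite::toJSON(cohort$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paths[["truth"]])
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$engagement), "persons,",
      ncol(x$engagement), "activities,", nrow(x$records), "diary records\n")
  invisible(x)
}
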