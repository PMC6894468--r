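#' Run configuration for the report entry points
#'
#' Bundles and validates every knob of a pipeline run. The configuration is
#' serialized into the output directory as \code{config.json} so a run can
#' be reproduced exactly.
#'
#' @param diary path to a diary file, or (in table mode) to a re-keyed
#'   duplication-table fixture.
#' @param demographics path to a demographics file (needed by
#'   \code{\link{cmd_segment}}).
#' @param taxonomy path to a taxonomy mapping file; \code{NULL} uses the
#'   packaged default.
#' @param level \code{"domain"} or \code{"subdomain"}.
#' @param mode \code{"raw"} (compute from diary records) or \code{"table"}
#'   (recompute summary statistics from an already-tabulated duplication
#'   table; \code{diary} then points at the table file).
#' @param reference deviation reference, \code{"column_average"} or
#'   \code{"expected"}.
#' @param threshold,near_band deviation flag thresholds in percentage
#'   points.
#' @param digits display rounding for table cells.
#' @param output_dir directory for written outputs.
#' @param seed seed for \code{\link{cmd_simulate}}.
#' @param n_persons cohort size for \code{\link{cmd_simulate}}.
#' @param verbose print progress messages.
#' @return A validated \code{run_config}.
#' @export
run_config <- function(diary = NULL, demographics = NULL, taxonomy = NULL,
                       level = c("domain", "subdomain"),
                       mode = c("raw", "table"),
                       reference = c("column_average", "expected"),
                       threshold = 5, near_band = 4, digits = 0,
                       output_dir = "dupbehav-output", seed = 1L,
                       n_persons = 2307L, verbose = TRUE) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (threshold <= 0) stop("threshold must be positive")
  if (near_band > threshold) stop("near_band must not exceed threshold")
  structure(
    list(diary = diary, demographics = demographics, taxonomy = taxonomy,
         level = level, mode = mode, reference = reference,
         threshold = threshold, near_band = near_band, digits = digits,
         output_dir = output_dir, seed = as.integer(seed),
         n_persons = as.integer(n_persons), verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

config_taxonomy <- function(config) {
  if (is.null(config$taxonomy)) default_taxonomy()
  else read_taxonomy(config$taxonomy)
}

save_config <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                              pretty = TRUE),
             file.path(config$output_dir, "config.json"))
}

say <- function(config, ...) if (config$verbose) message(...)

#' Run the duplication analysis and write its tables
#'
#' Reads the diary (or, in table mode, a re-keyed duplication table),
#' computes the duplication table, deviations and summary statistics, and
#' writes \code{duplication.csv}, \code{deviations.csv},
#' \code{summary.csv} and \code{report.md} (all prevalence-sorted, with
#' Average/Expected/Correlation, D-Coefficient and MAD footers) to the
#' output directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with the \code{duplication_table},
#'   \code{deviation_table} and the output paths.
#' @export
cmd_duplicate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$diary)) stop("config$diary is required")
  if (!file.exists(config$diary)) stop("input not found: ", config$diary)
  if (config$mode == "table") {
    raw <- read_delim_auto(config$diary)
    body <- raw[!raw$activity %in% c("Average", "Expected"), , drop = FALSE]
    mat <- as.matrix(body[, body$activity, drop = FALSE])
    rownames(mat) <- body$activity
    dup <- as_duplication_table(mat,
                                stats::setNames(as.numeric(body$prevalence),
                                                body$activity))
  } else {
    tax <- config_taxonomy(config)
    records <- read_records(config$diary, tax, quiet = !config$verbose)
    eng <- dichotomize(records, tax, level = config$level)
    say(config, "dichotomized ", nrow(eng), " persons x ", ncol(eng),
        " activities")
    dup <- duplication_table(eng)
  }
  dev <- deviations(dup, reference = config$reference,
                    threshold = config$threshold, near_band = config$near_band)
  save_config(config)
  paths <- c(duplication = file.path(config$output_dir, "duplication.csv"),
             deviations = file.path(config$output_dir, "deviations.csv"),
             summary = file.path(config$output_dir, "summary.csv"),
             report = file.path(config$output_dir, "report.md"))
  write_duplication_csv(dup, paths[["duplication"]], config$digits)
  write_deviation_csv(dev, paths[["deviations"]], config$digits)
  summary_df <- data.frame(
    statistic = c("n_activities", "D_coefficient", "MAD", "fit_correlation",
                  "n_partitions"),
    value = c(length(dup$activities),
              round_display(duplication_coefficient(dup), 1),
              round_display(mad_of_deviations(dev), 1),
              round_display(fit_correlation(dup), 2),
              nrow(dev$partitions)))
  utils::write.csv(summary_df, paths[["summary"]], row.names = FALSE,
                   quote = FALSE)
  writeLines(c(render_markdown(dup, config$digits), "",
               render_markdown(dev, config$digits)),
             paths[["report"]])
  say(config, "wrote ", length(paths), " files to ", config$output_dir)
  invisible(list(duplication = dup, deviation = dev, paths = paths))
}

#' Run the user-profile (MAD) segmentation analysis and write its tables
#'
#' Dichotomizes the diary at the configured level and writes a gender and
#' an age-bin composition table (proportions, deviations, Average row and
#' MAD footer) plus verdicts to the output directory.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list with both \code{composition_table}s, their
#'   verdicts and output paths.
#' @export
cmd_segment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$diary)) stop("config$diary is required")
  if (is.null(config$demographics)) stop("config$demographics is required")
  if (!file.exists(config$demographics)) {
    stop("demographics file not found: ", config$demographics)
  }
  tax <- config_taxonomy(config)
  records <- read_records(config$diary, tax, quiet = !config$verbose)
  demo <- read_demographics(config$demographics)
  eng <- dichotomize(records, tax, level = config$level)
  save_config(config)
  out <- list()
  paths <- character()
  md <- character()
  for (dim in c("gender", "age_group")) {
    comp <- composition_table(eng, demo, dimension = dim,
                              threshold = config$threshold)
    verdict <- interpret_segmentation(comp)
    fn <- file.path(config$output_dir, paste0("composition_", dim, ".csv"))
    write_composition_csv(comp, fn, config$digits)
    paths[dim] <- fn
    md <- c(md, render_markdown(comp, config$digits),
            paste0("Verdict: ", verdict$verdict, " (MAD = ",
                   round_display(verdict$mad, 1), ")"), "")
    out[[dim]] <- list(composition = comp, verdict = verdict)
  }
  report <- file.path(config$output_dir, "segmentation.md")
  writeLines(md, report)
  out$paths <- c(paths, report = report)
  say(config, "wrote segmentation tables to ", config$output_dir)
  invisible(out)
}

#' Generate and write a synthetic cohort
#'
#' Thin wrapper over \code{\link{synthetic_config}},
#' \code{\link{generate_engagement}} and \code{\link{write_cohort}}: the
#' generated diary, demographics, taxonomy and truth sidecar are written to
#' the output directory and can be fed straight back into
#' \code{\link{cmd_duplicate}} / \code{\link{cmd_segment}}.
#'
#' @param config a \code{\link{run_config}} (uses \code{n_persons},
#'   \code{seed}, \code{output_dir}).
#' @param ... passed on to \code{\link{synthetic_config}} (activities,
#'   partition_specs, ...).
#' @return Invisibly, the \code{synthetic_cohort} with a \code{paths}
#'   element.
#' @export
cmd_simulate <- function(config, ...) {
  stopifnot(inherits(config, "run_config"))
  scfg <- synthetic_config(n_persons = config$n_persons,
                           seed = config$seed, ...)
  cohort <- generate_engagement(scfg)
  save_config(config)
  cohort$paths <- write_cohort(cohort, config$output_dir)
  say(config, "wrote synthetic cohort (", nrow(cohort$records),
      " records) to ", config$output_dir)
  invisible(cohort)
}

# ---- table writers / renderers -------------------------------------------

write_duplication_csv <- function(x, path, digits = 0) {
  tab <- round_display(x$duplication, digits)
  df <- data.frame(activity = x$activities,
                   prevalence = round_display(x$penetration, digits), tab,
                   check.names = FALSE)
  footer <- data.frame(activity = c("Average", "Expected"),
                       prevalence = NA_real_,
                       rbind(round_display(x$column_average, digits),
                             round_display(expected_values(x), digits)),
                       check.names = FALSE)
  utils::write.csv(rbind(df, footer), path, row.names = FALSE, na = "")
}

write_deviation_csv <- function(x, path, digits = 0) {
  df <- data.frame(activity = rownames(x$deviation),
                   round_display(x$deviation, digits), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

write_composition_csv <- function(x, path, digits = 0) {
  dev <- round_display(x$deviation, digits)
  colnames(dev) <- paste0("dev_", colnames(dev))
  df <- data.frame(activity = x$activities, n = x$n,
                   round_display(x$composition, digits), dev,
                   check.names = FALSE)
  avg <- as.data.frame(t(round_display(x$group_average, digits)))
  footer <- data.frame(activity = "Average", n = NA_real_, avg,
                       t(rep(NA_real_, length(x$groups))),
                       check.names = FALSE)
  names(footer) <- names(df)
  utils::write.csv(rbind(df, footer), path, row.names = FALSE, na = "")
}

md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")

fmt_cell <- function(v, digits, threshold = NULL, near_band = NULL) {
  out <- ifelse(is.na(v), "", formatC(round_display(v, digits),
                                      format = "f", digits = digits))
  if (!is.null(threshold)) {
    bold <- !is.na(v) & abs(v) >= threshold
    out[bold] <- paste0("**", out[bold], "**")
    if (!is.null(near_band)) {
      near <- !is.na(v) & !bold & abs(v) >= near_band
      out[near] <- paste0(out[near], "*")
    }
  }
  out
}

#' Render an analysis table as markdown
#'
#' Produces a markdown table in the published layout: prevalence-sorted
#' rows/columns, Average/Expected/Correlation footers for duplication
#' tables, D-Coefficient and MAD footers, deviations at or beyond the
#' threshold bolded and near-threshold cells starred.
#'
#' @param x a \code{duplication_table}, \code{deviation_table} or
#'   \code{composition_table}.
#' @param digits display decimal places for cells.
#' @return Character vector of markdown lines.
#' @export
render_markdown <- function(x, digits = 0) UseMethod("render_markdown")

#' @export
render_markdown.duplication_table <- function(x, digits = 0) {
  header <- c("Activity", "Prevalence (%)", x$activities)
  lines <- c(md_row(header), md_row(rep("---", length(header))))
  for (i in seq_along(x$activities)) {
    lines <- c(lines, md_row(c(x$activities[i],
                               fmt_cell(x$penetration[i], digits),
                               fmt_cell(x$duplication[i, ], digits))))
  }
  lines <- c(lines,
             md_row(c("Average", "", fmt_cell(x$column_average, digits))),
             md_row(c("Expected", "", fmt_cell(expected_values(x), digits))),
             md_row(c("Correlation",
                      fmt_cell(fit_correlation(x), 2),
                      rep("", length(x$activities)))),
             md_row(c("D-Coefficient",
                      fmt_cell(duplication_coefficient(x), 1),
                      rep("", length(x$activities)))))
  lines
}

#' @export
render_markdown.deviation_table <- function(x, digits = 0) {
  acts <- colnames(x$deviation)
  header <- c("Activity", acts)
  lines <- c(md_row(header), md_row(rep("---", length(header))))
  for (i in seq_along(acts)) {
    lines <- c(lines, md_row(c(acts[i],
                               fmt_cell(x$deviation[i, ], digits,
                                        x$threshold, x$near_band))))
  }
  c(lines,
    md_row(c("MAD", fmt_cell(mad_of_deviations(x), 1),
             rep("", length(acts) - 1))),
    if (nrow(x$partitions)) {
      paste0("Partitions: ",
             paste(sprintf("%s & %s (%s)", x$partitions$A, x$partitions$B,
                           x$partitions$sign), collapse = "; "))
    } else "No partitions.")
}

#' @export
render_markdown.composition_table <- function(x, digits = 0) {
  header <- c("Activity", "n", x$groups, paste("dev", x$groups))
  lines <- c(md_row(header), md_row(rep("---", length(header))))
  for (i in seq_along(x$activities)) {
    lines <- c(lines, md_row(c(
      x$activities[i], format(x$n[i]),
      fmt_cell(x$composition[i, ], digits),
      fmt_cell(x$deviation[i, ], digits, x$threshold, x$threshold - 1))))
  }
  c(lines,
    md_row(c("Average", "", fmt_cell(x$group_average, digits),
             rep("", length(x$groups)))),
    md_row(c("MAD", fmt_cell(mad_of_composition(x), 1),
             rep("", 2 * length(x$groups)))))
}
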