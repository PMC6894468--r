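#' Re-keyed published study tables
#'
#' The package ships the printed summary tables of a 2307-adult
#' Australian/New Zealand time-use recall study, re-keyed as delimited
#' fixtures, so the summary statistics (column averages, D, expected
#' values, fit correlation, deviations, MAD, compositions) can be
#' recomputed from published values even though the underlying diaries are
#' not publicly deposited. Duplication and deviation fixtures become
#' table-mode \code{\link{duplication_table}} / \code{deviation_table}
#' objects; composition fixtures become table-mode
#' \code{composition_table} objects carrying the printed deviations.
#'
#' Available names: \code{"domain_duplication"}, \code{"domain_deviation"},
#' \code{"subdomain_duplication"}, \code{"subdomain_deviation"},
#' \code{"domain_gender"}, \code{"domain_age"}, \code{"subdomain_gender"},
#' \code{"subdomain_age"}.
#'
#' Duplication tables carry the published \code{Average} and
#' \code{Expected} footer rows as attributes \code{printed_average} and
#' \code{printed_expected}.
#'
#' @param name one of the fixture names above.
#' @return A table-mode analysis object (see Details).
#' @export
study_table <- function(name) {
  name <- match.arg(name, c(
    "domain_duplication", "domain_deviation",
    "subdomain_duplication", "subdomain_deviation",
    "domain_gender", "domain_age", "subdomain_gender", "subdomain_age"))
  path <- system.file("extdata", paste0("table_", name, ".csv"),
                      package = "dupbehav", mustWork = TRUE)
  raw <- read_delim_auto(path)
  base_n <- switch(name,
                   subdomain_duplication = 1261,
                   subdomain_deviation = 1261,
                   subdomain_gender = 2238,
                   subdomain_age = 2238,
                   2307)
  if (grepl("duplication|deviation", name)) {
    footer <- raw$activity %in% c("Average", "Expected")
    body <- raw[!footer, , drop = FALSE]
    acts <- body$activity
    mat <- as.matrix(body[, acts, drop = FALSE])
    rownames(mat) <- acts
    prevalence <- stats::setNames(as.numeric(body$prevalence), acts)
    if (grepl("duplication", name)) {
      out <- as_duplication_table(mat, prevalence, n_persons = base_n)
      for (f in c("Average", "Expected")) {
        row <- raw[raw$activity == f, acts, drop = FALSE]
        if (nrow(row)) {
          attr(out, paste0("printed_", tolower(f))) <-
            stats::setNames(as.numeric(row[1, ]), acts)[out$activities]
        }
      }
      out
    } else {
      as_deviation_table(mat[order_by_penetration(prevalence),
                             order_by_penetration(prevalence)])
    }
  } else {
    body <- raw[raw$activity != "Average", , drop = FALSE]
    groups <- grep("^dev_", names(raw), value = TRUE)
    groups <- sub("^dev_", "", groups)
    comp <- as.matrix(body[, groups, drop = FALSE])
    dev <- as.matrix(body[, paste0("dev_", groups), drop = FALSE])
    colnames(dev) <- groups
    rownames(comp) <- rownames(dev) <- body$activity
    avg_row <- raw[raw$activity == "Average", groups, drop = FALSE]
    avg <- if (nrow(avg_row)) stats::setNames(as.numeric(avg_row[1, ]), groups)
           else NULL
    as_composition_table(n = stats::setNames(as.numeric(body$n), body$activity),
                         composition = comp, deviation = dev,
                         group_average = avg, base_n = base_n)
  }
}
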