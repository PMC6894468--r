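#' Demographic composition of activity engagers (user-profile analysis)
#'
#' For each activity, the percentage of its engagers falling in each
#' demographic group (gender levels or age bins), compared with the
#' unweighted average composition across activities. Deviations are in
#' percentage points; cells with |deviation| >= threshold are flagged and
#' cells in [threshold-1, threshold) are near-flagged. Engagers without a
#' demographic record are dropped with a logged count.
#'
#' @param x an \code{engagement_matrix}.
#' @param demographics data.frame from \code{\link{read_demographics}}.
#' @param dimension \code{"gender"} or \code{"age_group"}.
#' @param threshold flag threshold in percentage points (default 5).
#' @return A \code{composition_table}: list with \code{n} (engager count
#'   per activity), \code{composition} (activities x groups, percent),
#'   \code{group_average}, \code{deviation}, \code{base_n} and flags.
#' @export
composition_table <- function(x, demographics,
                              dimension = c("gender", "age_group"),
                              threshold = 5) {
  stopifnot(inherits(x, "engagement_matrix"))
  dimension <- match.arg(dimension)
  if (ncol(x) < 2) stop("need at least two activities")
  persons <- rownames(x)
  idx <- match(persons, demographics$person_id)
  dropped <- sum(is.na(idx))
  if (dropped) {
    message("dropping ", dropped, " person(s) without a demographic record")
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no persons with demographic records")
  m <- unclass(x)[keep, , drop = FALSE]
  grp <- as.character(demographics[[dimension]][idx[keep]])
  levels <- if (dimension == "gender") c("male", "female") else
    c("<20", "20-39", "40-59", "60+")
  levels <- intersect(levels, unique(grp))
  if (length(levels) < 2) stop("dimension '", dimension, "' has a single level")
  g <- factor(grp, levels = levels)

  counts <- t(rowsum(m, g, reorder = FALSE))        # activities x groups
  counts <- counts[, levels, drop = FALSE]
  n <- rowSums(counts)
  zero <- n == 0
  if (any(zero)) {
    warning("dropping activity(ies) with zero engagers: ",
            paste(names(n)[zero], collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
    n <- n[!zero]
  }
  comp <- 100 * sweep(counts, 1, n, "/")
  new_composition_table(n, comp, base_n = sum(keep), threshold = threshold)
}

#' Construct a composition table from re-keyed values ("table mode")
#'
#' Rebuilds a \code{composition_table} from an already-tabulated composition
#' (and optionally its printed deviations), e.g. re-keyed from a published
#' user-profile table.
#'
#' @param n named vector of engager counts per activity.
#' @param composition activities x groups matrix of percentages.
#' @param deviation optional matrix of printed deviations in percentage
#'   points; when omitted, recomputed from the composition.
#' @param group_average optional printed average row; when omitted, the
#'   unweighted mean over activities.
#' @param base_n optional person base.
#' @param threshold flag threshold in percentage points.
#' @return A \code{composition_table}.
#' @export
as_composition_table <- function(n, composition, deviation = NULL,
                                 group_average = NULL, base_n = NULL,
                                 threshold = 5) {
  composition <- as.matrix(composition)
  new_composition_table(n, composition, base_n = base_n,
                        threshold = threshold,
                        deviation = if (is.null(deviation)) NULL else as.matrix(deviation),
                        group_average = group_average, source = "table")
}

new_composition_table <- function(n, comp, base_n, threshold,
                                  deviation = NULL, group_average = NULL,
                                  source = "raw") {
  if (is.null(group_average)) group_average <- colMeans(comp)
  if (is.null(deviation)) deviation <- sweep(comp, 2, group_average, "-")
  acts <- rownames(comp)
  idx <- which(abs(deviation) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(activity = acts[idx[, 1]],
                        group = colnames(comp)[idx[, 2]],
                        deviation = deviation[idx], stringsAsFactors = FALSE)
  idx_n <- which(abs(deviation) >= threshold - 1 &
                   abs(deviation) < threshold, arr.ind = TRUE)
  near_flagged <- data.frame(activity = acts[idx_n[, 1]],
                             group = colnames(comp)[idx_n[, 2]],
                             deviation = deviation[idx_n],
                             stringsAsFactors = FALSE)
  structure(
    list(activities = acts, groups = colnames(comp), n = n,
         composition = comp, group_average = group_average,
         deviation = deviation, threshold = threshold, base_n = base_n,
         flagged = flagged, near_flagged = near_flagged, source = source),
    class = "composition_table"
  )
}

#' Mean absolute deviation of a composition table
#'
#' Mean of |deviation| over all (activity, group) cells, in percentage
#' points.
#'
#' @param x a \code{composition_table}.
#' @return Numeric scalar (full precision).
#' @export
mad_of_composition <- function(x) {
  stopifnot(inherits(x, "composition_table"))
  mean(abs(x$deviation))
}

#' Segmentation verdict for a composition table
#'
#' A MAD below the verdict threshold (default 5 pp, an arbitrary but
#' conventional cut-off) is read as no practically meaningful segmentation.
#' The boundary belongs to "segmented" (MAD >= 5).
#'
#' @param x a \code{composition_table}.
#' @param verdict_threshold MAD cut-off in percentage points.
#' @return List with \code{mad}, \code{verdict} ("segmented" or
#'   "unsegmented") and \code{skews}: flagged (activity, group) cells with
#'   direction.
#' @export
interpret_segmentation <- function(x, verdict_threshold = 5) {
  stopifnot(inherits(x, "composition_table"))
  m <- mad_of_composition(x)
  skews <- x$flagged
  skews$direction <- ifelse(skews$deviation > 0, "towards", "away")
  list(mad = m,
       verdict = if (m >= verdict_threshold) "segmented" else "unsegmented",
       verdict_threshold = verdict_threshold,
       skews = skews)
}

#' @export
print.composition_table <- function(x, digits = 0, ...) {
  cat("Composition table: ", length(x$activities), " activities x ",
      length(x$groups), " groups", sep = "")
  if (!is.null(x$base_n)) cat(", base n = ", x$base_n, sep = "")
  cat("\n")
  print(cbind(n = x$n, round_display(x$composition, digits),
              round_display(x$deviation, digits)))
  cat("Average:", paste(round_display(x$group_average, digits), collapse = " "), "\n")
  cat(sprintf("MAD = %.1f\n", round_display(mad_of_composition(x), 1)))
  invisible(x)
}
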