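#' Duplication (sharing) table
#'
#' For every ordered pair of activities, the duplication d[A,B] is the
#' percentage of A's engagers who also engage in B. Rows and columns are
#' ordered by descending penetration; the diagonal is undefined and stored
#' as NA. Column averages are means of the off-diagonal entries of each
#' column.
#'
#' @param x an \code{engagement_matrix} (or 0/1 matrix coercible to one).
#' @return A \code{duplication_table}: list with \code{activities},
#'   \code{penetration}, \code{n_engagers}, \code{n_persons},
#'   \code{duplication} (matrix, percent, NA diagonal),
#'   \code{column_average}, and \code{source = "raw"}.
#' @export
duplication_table <- function(x) {
  if (!inherits(x, "engagement_matrix")) x <- as_engagement_matrix(x)
  m <- unclass(x)
  attr(m, "penetration") <- NULL
  attr(m, "level") <- NULL
  n_eng <- colSums(m)
  zero <- n_eng == 0
  if (any(zero)) {
    warning("dropping activity(ies) with zero engagers: ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    n_eng <- n_eng[!zero]
  }
  if (ncol(m) < 2) stop("need at least two activities with engagers")
  joint <- crossprod(m)                      # joint engager counts
  dup <- 100 * sweep(joint, 1, n_eng, "/")   # row A: share of A's engagers
  diag(dup) <- NA_real_
  pen <- 100 * n_eng / nrow(m)
  new_duplication_table(dup, pen, n_engagers = n_eng, n_persons = nrow(m),
                        source = "raw")
}

#' Construct a duplication table from re-keyed values ("table mode")
#'
#' Builds the same object as \code{\link{duplication_table}} from an
#' already-tabulated duplication matrix and prevalence vector, e.g. re-keyed
#' from a published summary table, so that the downstream summary statistics
#' (column averages, D, expected values, fit, deviations, MAD) can be
#' recomputed from printed values.
#'
#' @param duplication square numeric matrix in percent, NA (or anything) on
#'   the diagonal, dimnames = activity labels.
#' @param prevalence named numeric vector of penetrations in percent, same
#'   activities.
#' @param n_persons optional person base; when given, engager counts are
#'   reconstructed as \code{prevalence/100 * n_persons}.
#' @return A \code{duplication_table} with \code{source = "table"}.
#' @export
as_duplication_table <- function(duplication, prevalence, n_persons = NULL) {
  duplication <- as.matrix(duplication)
  if (nrow(duplication) != ncol(duplication)) stop("duplication matrix must be square")
  acts <- colnames(duplication)
  if (is.null(acts)) stop("duplication matrix needs activity dimnames")
  if (!setequal(acts, names(prevalence))) {
    stop("prevalence names must match duplication activities")
  }
  prevalence <- prevalence[acts]
  diag(duplication) <- NA_real_
  ord <- order_by_penetration(prevalence)
  duplication <- duplication[ord, ord, drop = FALSE]
  prevalence <- prevalence[ord]
  n_eng <- if (is.null(n_persons)) NULL else prevalence / 100 * n_persons
  new_duplication_table(duplication, prevalence, n_engagers = n_eng,
                        n_persons = n_persons, source = "table")
}

new_duplication_table <- function(dup, pen, n_engagers, n_persons, source) {
  ord <- order_by_penetration(pen)
  dup <- dup[ord, ord, drop = FALSE]
  pen <- pen[ord]
  if (!is.null(n_engagers)) n_engagers <- n_engagers[names(pen)]
  col_avg <- apply(dup, 2, mean, na.rm = TRUE)
  structure(
    list(activities = names(pen), penetration = pen,
         n_engagers = n_engagers, n_persons = n_persons,
         duplication = dup, column_average = col_avg, source = source),
    class = "duplication_table"
  )
}

#' Duplication coefficient D
#'
#' D is the mean of the per-activity column-average duplications divided by
#' the mean penetration. D = 1 means engaging in one activity leaves the
#' chance of engaging in others at the population average; D > 1 indicates
#' above-population co-engagement, D < 1 below.
#'
#' @param x a \code{duplication_table}.
#' @return Numeric scalar D (full precision; round for display).
#' @export
duplication_coefficient <- function(x) {
  stopifnot(inherits(x, "duplication_table"))
  mp <- mean(x$penetration)
  if (mp == 0) stop("mean penetration is zero; D undefined")
  mean(x$column_average) / mp
}

#' Expected duplication values
#'
#' The benchmark E[B] = D x p[B] for every activity B, using the
#' full-precision D.
#'
#' @param x a \code{duplication_table}.
#' @return Named numeric vector of expected duplications in percent.
#' @export
expected_values <- function(x) {
  stopifnot(inherits(x, "duplication_table"))
  duplication_coefficient(x) * x$penetration
}

#' Spearman fit between observed and expected duplication
#'
#' Rank correlation (average ranks for ties) between the observed column
#' averages and the expected values D x p.
#'
#' @param x a \code{duplication_table}.
#' @return Spearman rho in [-1, 1].
#' @export
fit_correlation <- function(x) {
  stopifnot(inherits(x, "duplication_table"))
  if (length(x$activities) < 3) {
    stop("need at least three activities for a meaningful rank correlation")
  }
  stats::cor(x$column_average, expected_values(x), method = "spearman")
}

#' Deviations from a duplication reference, flags and partitions
#'
#' The deviation delta[A,B] = d[A,B] - reference[B] in percentage points,
#' with positive values meaning more co-occurrence than the reference. The
#' reference is either each column's average duplication (the convention of
#' printed deviation tables) or the expected value D x p[B]. Cells with
#' |delta| >= threshold are flagged; cells in [near_band, threshold) are
#' near-flagged ("just short of the cut-off"). A partition is an unordered
#' pair whose two deviations both clear the threshold with the same sign.
#'
#' @param x a \code{duplication_table}.
#' @param reference \code{"column_average"} (default) or \code{"expected"}.
#' @param threshold flag threshold in percentage points (> 0; default 5).
#' @param near_band lower bound of the near-flag band (default 4).
#' @return A \code{deviation_table}: list with the deviation matrix,
#'   reference values, flag data.frames and \code{partitions}.
#' @export
deviations <- function(x, reference = c("column_average", "expected"),
                       threshold = 5, near_band = 4) {
  stopifnot(inherits(x, "duplication_table"))
  reference <- match.arg(reference)
  ref <- if (reference == "column_average") x$column_average else expected_values(x)
  delta <- sweep(x$duplication, 2, ref, "-")
  new_deviation_table(delta, reference, ref, threshold, near_band)
}

#' Construct a deviation table from re-keyed values ("table mode")
#'
#' @param deviation square numeric matrix of deviations in percentage
#'   points, NA diagonal, dimnames = activity labels.
#' @param reference label recording what the deviations were taken against.
#' @param reference_values optional named vector of the reference row.
#' @inheritParams deviations
#' @return A \code{deviation_table}.
#' @export
as_deviation_table <- function(deviation, reference = "column_average",
                               reference_values = NULL,
                               threshold = 5, near_band = 4) {
  deviation <- as.matrix(deviation)
  if (nrow(deviation) != ncol(deviation)) stop("deviation matrix must be square")
  if (is.null(colnames(deviation))) stop("deviation matrix needs activity dimnames")
  diag(deviation) <- NA_real_
  new_deviation_table(deviation, reference, reference_values, threshold, near_band)
}

new_deviation_table <- function(delta, reference, ref_values,
                                threshold, near_band) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number of percentage points")
  }
  if (near_band > threshold) stop("near_band must not exceed threshold")
  acts <- colnames(delta)
  idx <- which(!is.na(delta) & abs(delta) >= threshold, arr.ind = TRUE)
  flagged <- data.frame(A = acts[idx[, 1]], B = acts[idx[, 2]],
                        delta = delta[idx], stringsAsFactors = FALSE)
  idx_n <- which(!is.na(delta) & abs(delta) >= near_band &
                   abs(delta) < threshold, arr.ind = TRUE)
  near_flagged <- data.frame(A = acts[idx_n[, 1]], B = acts[idx_n[, 2]],
                             delta = delta[idx_n], stringsAsFactors = FALSE)
  parts <- list()
  if (length(acts) >= 2) {
    for (i in seq_len(length(acts) - 1)) {
      for (j in seq(i + 1, length(acts))) {
        ab <- delta[i, j]; ba <- delta[j, i]
        if (is.na(ab) || is.na(ba)) next
        if (ab >= threshold && ba >= threshold) {
          parts[[length(parts) + 1]] <- data.frame(
            A = acts[i], B = acts[j], sign = "positive",
            delta_AB = ab, delta_BA = ba, stringsAsFactors = FALSE)
        } else if (ab <= -threshold && ba <= -threshold) {
          parts[[length(parts) + 1]] <- data.frame(
            A = acts[i], B = acts[j], sign = "negative",
            delta_AB = ab, delta_BA = ba, stringsAsFactors = FALSE)
        }
      }
    }
  }
  partitions <- if (length(parts)) do.call(rbind, parts) else
    data.frame(A = character(), B = character(), sign = character(),
               delta_AB = numeric(), delta_BA = numeric())
  structure(
    list(reference = reference, reference_values = ref_values,
         deviation = delta, threshold = threshold, near_band = near_band,
         flagged = flagged, near_flagged = near_flagged,
         partitions = partitions),
    class = "deviation_table"
  )
}

#' Mean absolute deviation of a deviation table
#'
#' Mean of |delta| over all off-diagonal cells, in percentage points.
#'
#' @param x a \code{deviation_table}.
#' @return Numeric scalar (full precision; round to 1 dp for display).
#' @export
mad_of_deviations <- function(x) {
  stopifnot(inherits(x, "deviation_table"))
  mean(abs(x$deviation), na.rm = TRUE)
}

#' @export
print.duplication_table <- function(x, digits = 0, ...) {
  cat("Duplication table (", x$source, " mode): ", length(x$activities),
      " activities", sep = "")
  if (!is.null(x$n_persons)) cat(", base n = ", x$n_persons, sep = "")
  cat("\n")
  tab <- round_display(x$duplication, digits)
  print(cbind(`Prevalence (%)` = round_display(x$penetration, digits), tab),
        na.print = "")
  cat("Average:", paste(round_display(x$column_average, digits), collapse = " "), "\n")
  cat("Expected:", paste(round_display(expected_values(x), digits), collapse = " "), "\n")
  cat(sprintf("D-Coefficient %.1f  Correlation %.2f\n",
              round_display(duplication_coefficient(x), 1),
              round_display(fit_correlation(x), 2)))
  invisible(x)
}

#' @export
print.deviation_table <- function(x, digits = 0, ...) {
  cat("Deviation table (reference: ", x$reference, ", threshold ",
      x$threshold, " pp)\n", sep = "")
  print(round_display(x$deviation, digits), na.print = "")
  cat(sprintf("MAD %.1f\n", round_display(mad_of_deviations(x), 1)))
  if (nrow(x$flagged)) {
    cat("Flagged cells:\n"); print(x$flagged)
  }
  if (nrow(x$partitions)) {
    cat("Partitions:\n"); print(x$partitions)
  } else cat("No partitions.\n")
  invisible(x)
}
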