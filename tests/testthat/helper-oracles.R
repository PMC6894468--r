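# Brute-force oracles: direct enumeration over persons, independent of the
# package's vectorized implementations.

oracle_penetration <- function(m) {
  out <- numeric(ncol(m))
  names(out) <- colnames(m)
  for (a in colnames(m)) {
    k <- 0
    for (i in seq_len(nrow(m))) if (m[i, a] == 1) k <- k + 1
    out[a] <- 100 * k / nrow(m)
  }
  out
}

oracle_duplication <- function(m) {
  acts <- colnames(m)
  d <- matrix(NA_real_, length(acts), length(acts), dimnames = list(acts, acts))
  for (a in acts) {
    for (b in acts) {
      if (a == b) next
      na <- 0; nab <- 0
      for (i in seq_len(nrow(m))) {
        if (m[i, a] == 1) {
          na <- na + 1
          if (m[i, b] == 1) nab <- nab + 1
        }
      }
      d[a, b] <- 100 * nab / na
    }
  }
  d
}

# every duplication statistic from first principles on a binary matrix
oracle_stats <- function(m, reference = "column_average") {
  pen <- oracle_penetration(m)
  d <- oracle_duplication(m)
  acts <- colnames(m)
  colavg <- numeric(length(acts)); names(colavg) <- acts
  for (b in acts) {
    vals <- c()
    for (a in acts) if (a != b) vals <- c(vals, d[a, b])
    colavg[b] <- mean(vals)
  }
  D <- mean(colavg) / mean(pen)
  expected <- D * pen
  ref <- if (reference == "column_average") colavg else expected
  delta <- d
  for (a in acts) for (b in acts) if (a != b) delta[a, b] <- d[a, b] - ref[b]
  mad <- mean(abs(delta[!is.na(delta)]))
  list(penetration = pen, duplication = d, column_average = colavg,
       D = D, expected = expected, deviation = delta, mad = mad)
}

oracle_composition <- function(m, demo, dimension) {
  acts <- colnames(m)
  groups <- unique(as.character(demo[[dimension]]))
  groups <- groups[order(match(groups, c("male", "female",
                                         "<20", "20-39", "40-59", "60+")))]
  comp <- matrix(NA_real_, length(acts), length(groups),
                 dimnames = list(acts, groups))
  for (a in acts) {
    eng <- rownames(m)[m[, a] == 1]
    eng <- eng[eng %in% demo$person_id]
    for (g in groups) {
      k <- 0
      for (p in eng) {
        if (as.character(demo[[dimension]][demo$person_id == p]) == g) k <- k + 1
      }
      comp[a, g] <- 100 * k / length(eng)
    }
  }
  avg <- colMeans(comp)
  dev <- sweep(comp, 2, avg, "-")
  list(composition = comp, group_average = avg, deviation = dev,
       mad = mean(abs(dev)))
}

# per-person weighted mean daily minutes by direct looping
oracle_weighted_minutes <- function(records, labels_of, weights = c(weekday = 5, weekend = 2)) {
  records$label <- labels_of(records$activity_code)
  persons <- sort(unique(records$person_id))
  acts <- sort(unique(records$label))
  out <- matrix(0, length(persons), length(acts), dimnames = list(persons, acts))
  for (p in persons) {
    pr <- records[records$person_id == p, ]
    days <- unique(pr[, c("day_id", "day_type")])
    for (a in acts) {
      means <- c(weekday = NA_real_, weekend = NA_real_)
      for (ty in c("weekday", "weekend")) {
        dd <- days$day_id[days$day_type == ty]
        if (!length(dd)) next
        tot <- 0
        for (d in dd) {
          tot <- tot + sum(pr$duration[pr$day_id == d & pr$label == a])
        }
        means[ty] <- tot / length(dd)
      }
      if (is.na(means["weekday"])) out[p, a] <- means["weekend"]
      else if (is.na(means["weekend"])) out[p, a] <- means["weekday"]
      else out[p, a] <- (weights["weekday"] * means["weekday"] +
                           weights["weekend"] * means["weekend"]) / sum(weights)
    }
  }
  out
}

# random small binary engagement matrix with no empty activities
random_engagement <- function(n_persons, n_acts, p = 0.5) {
  repeat {
    m <- matrix(rbinom(n_persons * n_acts, 1, p), n_persons, n_acts,
                dimnames = list(sprintf("p%d", seq_len(n_persons)),
                                LETTERS[seq_len(n_acts)]))
    if (all(colSums(m) > 0)) return(m)
  }
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

toy_taxonomy <- function() {
  activity_taxonomy(data.frame(
    activity_code = c("sleep", "tv", "run", "football", "weights"),
    domain = c("Sleep", "Screen Time", rep("Exercise and Sport", 3)),
    subdomain = c(NA, NA, "Non-Team Sports", "Team Sports", "Gym"),
    stringsAsFactors = FALSE))
}
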