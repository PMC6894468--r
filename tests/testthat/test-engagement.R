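records_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  validate_records(df, toy_taxonomy(), quiet = TRUE)
}

test_that("engagement uses the any-record-over-the-window rule", {
  rec <- records_df(
    person_id = c("p1", "p1", "p2"),
    day_id = c("d2", "d2", "d1"),
    day_type = "weekday",
    activity_code = c("sleep", "run", "sleep"))
  eng <- dichotomize(rec, toy_taxonomy())
  expect_equal(eng["p1", "Exercise and Sport"], 1L)
  expect_equal(eng["p2", "Exercise and Sport"], 0L)
  expect_equal(unname(penetration(eng)["Sleep"]), 100)
})

test_that("penetration is invariant to duplicated records and matches its definition", {
  rec <- records_df(
    person_id = c("p1", "p2", "p3", "p1"),
    day_id = c("d1", "d1", "d1", "d2"),
    day_type = "weekday",
    activity_code = c("run", "run", "sleep", "run"))
  eng <- dichotomize(rec, toy_taxonomy())
  expect_equal(unname(penetration(eng)["Exercise and Sport"]), 100 * 2 / 3)
  # adding a second identical engagement record changes nothing
  rec2 <- records_df(
    person_id = c("p1", "p2", "p3", "p1", "p2"),
    day_id = c("d1", "d1", "d1", "d2", "d3"),
    day_type = "weekday",
    activity_code = c("run", "run", "sleep", "run", "run"))
  expect_equal(penetration(dichotomize(rec2, toy_taxonomy())),
               penetration(eng))
})

test_that("dichotomization of an already-binary structure is idempotent", {
  m <- random_engagement(8, 3)
  eng <- as_engagement_matrix(m)
  eng2 <- as_engagement_matrix(unclass(eng))
  expect_equal(unclass(eng2), unclass(eng))
  expect_equal(penetration(eng2), penetration(eng))
})

test_that("activities are sorted by descending penetration with alphabetical ties", {
  m <- cbind(Zeta = c(1, 1, 0, 0), Alpha = c(1, 1, 0, 0), Mid = c(1, 1, 1, 0))
  rownames(m) <- paste0("p", 1:4)
  eng <- as_engagement_matrix(m)
  expect_equal(colnames(eng), c("Mid", "Alpha", "Zeta"))
})

test_that("sub-domain analysis restricts the base to Exercise and Sport engagers", {
  rec <- records_df(
    person_id = c("p1", "p1", "p2", "p3", "p3"),
    day_id = "d1",
    day_type = "weekday",
    activity_code = c("sleep", "run", "sleep", "football", "weights"))
  dom <- dichotomize(rec, toy_taxonomy(), level = "domain")
  sub <- dichotomize(rec, toy_taxonomy(), level = "subdomain")
  expect_equal(nrow(sub), sum(dom[, "Exercise and Sport"]))
  expect_setequal(rownames(sub), c("p1", "p3"))
  # penetration relative to the engager base
  expect_equal(unname(penetration(sub)["Non-Team Sports"]), 50)
  rec_none <- records_df(person_id = "p1", day_id = "d1",
                         day_type = "weekday", activity_code = "sleep")
  expect_error(dichotomize(rec_none, toy_taxonomy(), level = "subdomain"),
               "engagers")
})

test_that("per-day mode treats person-days as units", {
  rec <- records_df(
    person_id = c("p1", "p1", "p1"),
    day_id = c("d1", "d2", "d2"),
    day_type = "weekday",
    activity_code = c("sleep", "sleep", "run"))
  eng <- dichotomize(rec, toy_taxonomy(), window = "per_day")
  expect_equal(nrow(eng), 2)
  expect_equal(unname(penetration(eng)["Exercise and Sport"]), 50)
})

test_that("empty record sets are rejected", {
  rec <- records_df(person_id = character(), day_id = character(),
                    day_type = character(), activity_code = character())
  expect_error(dichotomize(rec, toy_taxonomy()), "no diary records")
})

test_that("weighted daily minutes follow the 5:2 weekday:weekend rule", {
  rec <- records_df(
    person_id = rep("p1", 3),
    day_id = c("d1", "d2", "d3"),
    day_type = c("weekday", "weekday", "weekend"),
    activity_code = "tv",
    duration = c(50, 70, 130))
  w <- weighted_daily_minutes(rec, toy_taxonomy())
  expect_equal(w["p1", "Screen Time"], (5 * 60 + 2 * 130) / 7)
})

test_that("persons with a single day type fall back to that type's mean", {
  rec <- records_df(
    person_id = "p1", day_id = "d1", day_type = "weekday",
    activity_code = "tv", duration = 90)
  w <- weighted_daily_minutes(rec, toy_taxonomy())
  expect_equal(w["p1", "Screen Time"], 90)
  rec2 <- records_df(
    person_id = "p1", day_id = "d1", day_type = "weekend",
    activity_code = "tv", duration = 45)
  expect_equal(weighted_daily_minutes(rec2, toy_taxonomy())["p1", "Screen Time"],
               45)
})

test_that("weighted daily minutes match a brute-force per-person loop", {
  cohort <- generate_engagement(synthetic_config(n_persons = 40, seed = 7))
  tax <- synthetic_taxonomy(cohort)
  rec <- validate_records(cohort$records, tax, quiet = TRUE)
  w <- weighted_daily_minutes(rec, tax)
  oracle <- oracle_weighted_minutes(cohort$records, identity)
  expect_equal(w[rownames(oracle), colnames(oracle)], oracle)
})

test_that("duration-free diaries are rejected with guidance", {
  rec <- records_df(person_id = "p1", day_id = "d1", day_type = "weekday",
                    activity_code = "tv")
  expect_error(weighted_daily_minutes(rec, toy_taxonomy()), "dichotomize")
})
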