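toy_cohort <- function() {
  m <- cbind(Run = c(1, 1, 1, 1, 0, 0),
             Swim = c(1, 0, 1, 0, 1, 1))
  rownames(m) <- paste0("p", 1:6)
  demo <- data.frame(
    person_id = paste0("p", 1:6),
    gender = c("male", "male", "female", "female", "female", "female"),
    age = c(18, 25, 45, 70, 30, 50),
    stringsAsFactors = FALSE)
  demo$age_group <- age_group(demo$age)
  list(eng = as_engagement_matrix(m), demo = demo)
}

test_that("composition matches hand enumeration on a six-person cohort", {
  tc <- toy_cohort()
  comp <- composition_table(tc$eng, tc$demo, dimension = "gender")
  # Run engagers p1-p4: 2 male / 2 female; Swim engagers p1,p3,p5,p6: 1/3
  expect_equal(comp$composition["Run", ], c(male = 50, female = 50))
  expect_equal(comp$composition["Swim", ], c(male = 25, female = 75))
  expect_equal(comp$group_average, c(male = 37.5, female = 62.5))
  expect_equal(comp$deviation["Run", "male"], 12.5)
  o <- oracle_composition(unclass(tc$eng), tc$demo, "gender")
  expect_equal(comp$composition, o$composition[comp$activities, ])
  expect_equal(mad_of_composition(comp), o$mad)
})

test_that("composition rows sum to 100 at full precision and deviations to zero", {
  set.seed(5)
  cohort <- generate_engagement(synthetic_config(n_persons = 200, seed = 5))
  eng <- as_engagement_matrix(cohort$engagement)
  comp <- composition_table(eng, cohort$demographics, "age_group")
  expect_equal(unname(rowSums(comp$composition)),
               rep(100, length(comp$activities)))
  expect_equal(unname(colMeans(comp$deviation)), rep(0, length(comp$groups)))
})

test_that("identical composition in every activity gives zero MAD", {
  m <- cbind(A = rep(1, 8), B = rep(1, 8))
  rownames(m) <- paste0("p", 1:8)
  demo <- data.frame(person_id = paste0("p", 1:8),
                     gender = rep(c("male", "female"), 4),
                     age = rep(30, 8), stringsAsFactors = FALSE)
  demo$age_group <- age_group(demo$age)
  comp <- composition_table(as_engagement_matrix(m), demo, "gender")
  expect_equal(mad_of_composition(comp), 0)
  expect_true(all(comp$deviation == 0))
  expect_equal(interpret_segmentation(comp)$verdict, "unsegmented")
})

test_that("MAD is invariant to permuting activities and groups", {
  tc <- toy_cohort()
  comp <- composition_table(tc$eng, tc$demo, "gender")
  m2 <- unclass(tc$eng)[, c("Swim", "Run")]
  comp2 <- composition_table(as_engagement_matrix(m2), tc$demo, "gender")
  expect_equal(mad_of_composition(comp2), mad_of_composition(comp))
  # permuting group labels (relabelling genders) keeps the MAD
  demo_swap <- tc$demo
  demo_swap$gender <- ifelse(tc$demo$gender == "male", "female", "male")
  comp3 <- composition_table(tc$eng, demo_swap, "gender")
  expect_equal(mad_of_composition(comp3), mad_of_composition(comp))
})

test_that("persons without demographics are dropped with a logged count", {
  tc <- toy_cohort()
  expect_message(
    comp <- composition_table(tc$eng, tc$demo[1:4, ], "gender"),
    "2 person")
  expect_equal(comp$base_n, 4)
  expect_error(
    suppressMessages(composition_table(tc$eng, tc$demo[0, ], "gender")),
    "no persons")
})

test_that("degenerate dimensions and empty activities are handled", {
  tc <- toy_cohort()
  demo_one <- tc$demo
  demo_one$gender <- "female"
  expect_error(composition_table(tc$eng, demo_one, "gender"), "single level")
  m <- cbind(A = rep(1, 4), B = rep(0, 4), C = c(1, 1, 0, 0))
  rownames(m) <- paste0("p", 1:4)
  demo <- tc$demo[1:4, ]
  expect_warning(comp <- composition_table(as_engagement_matrix(m), demo,
                                           "gender"), "B")
  expect_setequal(comp$activities, c("A", "C"))
})

test_that("the segmentation verdict assigns the MAD = 5 boundary to 'segmented'", {
  comp <- as_composition_table(
    n = c(A = 10, B = 10),
    composition = matrix(c(55, 45, 45, 55), 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), c("male", "female"))))
  expect_equal(mad_of_composition(comp), 5)
  v <- interpret_segmentation(comp)
  expect_equal(v$verdict, "segmented")
  expect_true(all(c("A", "B") %in% v$skews$activity))
  expect_equal(v$skews$direction[v$skews$deviation > 0][1], "towards")
})

test_that("an injected demographic skew produces a growing positive deviation", {
  devs <- vapply(c(1, 1.5, 2), function(k) {
    cfg <- synthetic_config(
      n_persons = 2000,
      activities = c("Sleep" = 100, "Gym" = 60, "Dance" = 10),
      seed = 99)
    if (k > 1) cfg <- inject_segmentation(cfg, "Dance", "female", k)
    cohort <- generate_engagement(cfg)
    comp <- composition_table(as_engagement_matrix(cohort$engagement),
                              cohort$demographics, "gender")
    comp$deviation["Dance", "female"]
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})
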