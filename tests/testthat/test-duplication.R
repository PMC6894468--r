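test_that("a hand-enumerated toy matrix gives the expected sharing", {
  m <- cbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 0))
  rownames(m) <- paste0("p", 1:4)
  dup <- duplication_table(m)
  expect_equal(dup$duplication["A", "B"], 100 * 2 / 3)
  expect_equal(dup$duplication["B", "A"], 100)
  expect_equal(unname(dup$penetration), c(75, 50))
})

test_that("a universal activity is duplicated by 100% of every other activity's engagers", {
  m <- cbind(U = rep(1, 6), X = rbinom(6, 1, 0.5), Y = c(1, rep(0, 5)))
  rownames(m) <- paste0("p", 1:6)
  dup <- duplication_table(m)
  expect_true(all(dup$duplication[c("X", "Y"), "U"] == 100))
})

test_that("degenerate inputs are rejected or dropped with a warning", {
  m <- cbind(A = c(1, 1), B = c(0, 0))
  rownames(m) <- c("p1", "p2")
  expect_warning(expect_error(duplication_table(m), "two activities"), "B")
  m3 <- cbind(A = c(1, 0, 1), B = c(0, 0, 0), C = c(1, 1, 0))
  rownames(m3) <- paste0("p", 1:3)
  expect_warning(dup <- duplication_table(m3), "B")
  expect_setequal(dup$activities, c("A", "C"))
})

test_that("joint-count symmetry d[A,B]*n_A == d[B,A]*n_B holds exactly", {
  set.seed(11)
  for (rep in 1:10) {
    m <- random_engagement(sample(5:40, 1), sample(2:6, 1))
    dup <- duplication_table(m)
    n <- dup$n_engagers
    for (a in dup$activities) for (b in dup$activities) {
      if (a == b) next
      expect_equal(dup$duplication[a, b] * n[[a]],
                   dup$duplication[b, a] * n[[b]])
    }
  }
})

test_that("every statistic matches the brute-force enumeration oracle", {
  set.seed(21)
  for (rep in 1:15) {
    m <- random_engagement(sample(4:10, 1), sample(3:5, 1))
    o <- oracle_stats(m)
    dup <- duplication_table(m)
    acts <- dup$activities
    expect_equal(dup$penetration, o$penetration[acts])
    expect_equal(dup$duplication, o$duplication[acts, acts])
    expect_equal(dup$column_average, o$column_average[acts])
    expect_equal(duplication_coefficient(dup), o$D)
    expect_equal(expected_values(dup), o$expected[acts])
    dev <- deviations(dup)
    expect_equal(dev$deviation, o$deviation[acts, acts])
    expect_equal(mad_of_deviations(dev), o$mad)
    oe <- oracle_stats(m, reference = "expected")
    deve <- deviations(dup, reference = "expected")
    expect_equal(deve$deviation, oe$deviation[acts, acts])
  }
})

test_that("duplication is monotone in the joint engager count at fixed base", {
  # A's engagers fixed at persons 1-4; grow the overlap with B
  base <- cbind(A = c(rep(1, 4), rep(0, 4)), B = c(rep(0, 4), rep(1, 4)))
  rownames(base) <- paste0("p", 1:8)
  d_prev <- -Inf
  for (overlap in 0:4) {
    m <- base
    if (overlap > 0) m[seq_len(overlap), "B"] <- 1
    d <- duplication_table(m)$duplication["A", "B"]
    expect_gte(d, d_prev)
    d_prev <- d
  }
})

test_that("expected values reduce to penetration when D = 1", {
  # constant-column duplication equal to penetration makes D exactly 1
  pen <- c(A = 80, B = 60, C = 40)
  dup <- matrix(rep(pen, each = 3), 3, dimnames = list(names(pen), names(pen)))
  tab <- as_duplication_table(dup, pen)
  expect_equal(duplication_coefficient(tab), 1)
  expect_equal(expected_values(tab), tab$penetration)
})

test_that("the Spearman fit is 1 for identical rankings and -1 for reversal", {
  pen <- c(A = 50, B = 40, C = 30, D = 20, E = 10)
  # columns constant => column averages equal that constant
  asc <- matrix(rep(c(50, 40, 30, 20, 10), each = 5), 5,
                dimnames = list(names(pen), names(pen)))
  expect_equal(fit_correlation(as_duplication_table(asc, pen)), 1)
  rev <- matrix(rep(c(10, 20, 30, 40, 50), each = 5), 5,
                dimnames = list(names(pen), names(pen)))
  expect_equal(fit_correlation(as_duplication_table(rev, pen)), -1)
  two <- as_duplication_table(matrix(c(NA, 50, 50, NA), 2,
                                     dimnames = list(c("A", "B"), c("A", "B"))),
                              c(A = 60, B = 40))
  expect_error(fit_correlation(two), "three activities")
})

test_that("deviations against the column average sum to zero per column", {
  set.seed(31)
  m <- random_engagement(30, 4)
  dev <- deviations(duplication_table(m))
  sums <- colSums(dev$deviation, na.rm = TRUE)
  expect_equal(unname(sums), rep(0, 4))
})

test_that("deviation flags, near-flags and partitions follow the threshold rules", {
  acts <- c("A", "B", "C")
  delta <- matrix(c(NA, 6, 0,
                    6, NA, -4.5,
                    0, 2, NA), 3, byrow = TRUE,
                  dimnames = list(acts, acts))
  dev <- as_deviation_table(delta)
  # both directions of {A,B} clear +5 -> positive partition
  expect_equal(nrow(dev$partitions), 1)
  expect_equal(dev$partitions$sign, "positive")
  expect_setequal(c(dev$partitions$A, dev$partitions$B), c("A", "B"))
  # flagged contains every partition member cell
  expect_true(all(c("A", "B") %in% dev$flagged$A))
  # |delta| in [4,5) is near-flagged only
  expect_equal(nrow(dev$near_flagged), 1)
  expect_equal(dev$near_flagged$delta, -4.5)
  # one-sided large deviation is flagged but not a partition
  delta2 <- matrix(c(NA, 8, 1, NA), 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  dev2 <- as_deviation_table(delta2)
  expect_equal(nrow(dev2$flagged), 1)
  expect_equal(nrow(dev2$partitions), 0)
  expect_error(deviations(duplication_table(random_engagement(5, 3)),
                          threshold = 0), "positive")
})

test_that("raising the reference lowers deviations by the same amount", {
  set.seed(41)
  m <- random_engagement(20, 3)
  dup <- duplication_table(m)
  dev <- deviations(dup)
  shifted <- dup
  shifted$column_average["A"] <- shifted$column_average["A"] + 3
  dev2 <- deviations(shifted)
  expect_equal(dev2$deviation[, "A"], dev$deviation[, "A"] - 3)
  expect_equal(dev2$deviation[, "B"], dev$deviation[, "B"])
})

test_that("the MAD of an all-zero deviation matrix is zero", {
  delta <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  expect_equal(mad_of_deviations(as_deviation_table(delta)), 0)
  # constant columns produce zero deviations, no flags, no partitions
  pen <- c(A = 80, B = 50, C = 20)
  dup <- matrix(rep(c(70, 50, 30), each = 3), 3,
                dimnames = list(names(pen), names(pen)))
  dev <- deviations(as_duplication_table(dup, pen))
  expect_true(all(dev$deviation == 0, na.rm = TRUE))
  expect_equal(nrow(dev$flagged), 0)
  expect_equal(nrow(dev$partitions), 0)
})
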