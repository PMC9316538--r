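test_that("clean_values strips comparator prefixes and parses literals", {
  expect_identical(clean_values("<0.2"), 0.2)
  expect_identical(clean_values("3.42"), 3.42)
  expect_identical(clean_values(" >1.5 "), 1.5)

  set.seed(4)
  vals <- matrix(round(runif(24, 0, 10), 3), 4, 6)
  cells <- matrix(paste0(sample(c("", "<", ">"), 24, replace = TRUE), vals),
                  4, 6)
  cleaned <- clean_values(cells)
  for (i in 1:4) for (j in 1:6)
    expect_equal(cleaned[i, j], oracle_clean_cell(cells[i, j]))

  # stripping is idempotent: re-cleaning the formatted result is a no-op
  expect_equal(clean_values(format(cleaned)), cleaned)
})

test_that("clean_values rejects unparseable cells, naming the position", {
  m <- matrix(c("1.0", "oops", "3.0", "4.0"), 2, 2)
  expect_error(clean_values(m), "row 2, column 1")
  expect_error(clean_values("<abc"), "unparseable")
})

test_that("indicator spec invariants are enforced", {
  df <- data.frame(name = "x", unit = "u", bound_kind = "min_limit",
                   lo = 1, hi = 2, standard_ref = "")
  expect_error(indicator_specs(df), "inconsistent bounds")
  df$bound_kind <- "interval"; df$lo <- 3; df$hi <- 2
  expect_error(indicator_specs(df), "inconsistent bounds")
  df$bound_kind <- "between"
  expect_error(indicator_specs(df), "unknown bound_kind")
})

test_that("the packaged sterilized-milk table carries the legal limits", {
  specs <- milk_indicator_specs()
  expect_s3_class(specs, "indicator_specs")
  expect_equal(nrow(specs), 6)
  lim <- function(nm) specs[specs$name == nm, ]
  expect_equal(lim("protein")$lo, 3.1)
  expect_equal(lim("fat")$lo, 3.7)
  expect_equal(lim("nms")$lo, 8.5)
  expect_equal(lim("lactose")$hi, 2.0)
  expect_equal(lim("am1")$hi, 0.5)
  expect_equal(c(lim("acidity")$lo, lim("acidity")$hi), c(11, 16))
  expect_setequal(specs$bound_kind[specs$name %in% c("protein", "fat", "nms")],
                  "min_limit")
  expect_setequal(specs$bound_kind[specs$name %in% c("lactose", "am1")],
                  "max_limit")
})

test_that("a routine milk sample qualifies; a single bound violation fails", {
  specs <- milk_indicator_specs()
  row <- c(lactose = 1.74, acidity = 12, nms = 8.79, fat = 4.16,
           protein = 3.42, am1 = 0.2)
  b <- inspection_batch(matrix(row, 1, dimnames = list(NULL, specs$name)),
                        specs)
  q <- qualify(b)
  expect_equal(q$labels, "qualified")
  expect_length(q$violated[[1]], 0)

  row["protein"] <- 3.0
  b2 <- inspection_batch(matrix(row, 1, dimnames = list(NULL, specs$name)),
                         specs)
  q2 <- qualify(b2)
  expect_equal(q2$labels, "unqualified")
  expect_equal(q2$violated[[1]], "protein")
})

test_that("qualification bounds are inclusive", {
  specs <- milk_indicator_specs()
  at_limits <- c(lactose = 2.0, acidity = 11, nms = 8.5, fat = 3.7,
                 protein = 3.1, am1 = 0.5)
  b <- inspection_batch(matrix(at_limits, 1,
                               dimnames = list(NULL, specs$name)), specs)
  expect_equal(qualify(b)$labels, "qualified")
})

test_that("qualify agrees with a rule-by-rule checker on random batches", {
  b <- random_toy_batch(200, seed = 9)
  got <- qualify(b)
  want <- oracle_qualify(b)
  expect_equal(got$labels, want$labels)
  expect_equal(got$violated, want$violated)
  # unqualified exactly when at least one indicator is violated
  expect_equal(got$labels == "unqualified", lengths(got$violated) > 0)
})

test_that("qualify is idempotent and order-independent across rows", {
  b <- random_toy_batch(60, seed = 2)
  q1 <- qualify(b)
  expect_identical(qualify(b), q1)
  perm <- sample(60)
  bp <- inspection_batch(b$values[perm, ], b$specs,
                         sample_id = b$sample_id[perm], date = b$date[perm])
  expect_identical(qualify(bp)$labels, q1$labels[perm])
})

test_that("qualify refuses incomplete rows", {
  b <- random_toy_batch(5, seed = 1)
  b$values[2, 3] <- NA
  expect_error(qualify(b), "missing value")
})

test_that("drop_indicators removes columns with their specs", {
  b <- random_toy_batch(10, seed = 3)
  expect_identical(drop_indicators(b, character(0)), b)
  d <- drop_indicators(b, "b_max")
  expect_equal(ncol(d$values), 2)
  expect_equal(d$specs$name, c("a_min", "c_int"))
  expect_equal(nrow(d$values), 10)
  d2 <- drop_indicators(b, c("a_min", "b_max"))
  expect_equal(ncol(d2$values), 1)
  expect_equal(nrow(d2$specs), 1)
  expect_error(drop_indicators(b, "melamine"), "melamine")
})
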