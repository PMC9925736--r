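# Record cleaning, row normalization, correlation, variance selection and
# the model feature sets.

make_records <- function() {
  data.frame(
    breed = c("S21", "S21", "S23", "S21"),
    gender = c("female", "male", "female", "female"),
    determination_date = as.Date(c("2020-07-12", "2019-05-01", "2020-02-02",
                                   "2018-12-31")),
    birth_date = as.Date(c("2020-01-01", "2018-11-01", "2019-08-01",
                           "2018-06-30")),
    chest = c(110, 105, 109, 105),
    abdominal = c(115, 116, 120, 112),
    waist = c(107, 106, 104, 100),
    length = c(120, 119, 125, 123),
    height = c(60, NA, 66, 63),
    weight = c(113.5, 111.4, 114.6, 111.8),
    stringsAsFactors = FALSE)
}

test_that("clean_records derives age, one-hots and median-imputes height", {
  tab <- clean_records(make_records())
  expect_equal(tab$age[1], 193L)               # calendar-day difference
  expect_equal(tab[1, c("female", "male")], data.frame(female = 1, male = 0),
               ignore_attr = TRUE)
  expect_equal(tab[3, c("s21", "s23")], data.frame(s21 = 0, s23 = 1),
               ignore_attr = TRUE)
  expect_equal(tab$height[2], 63)              # median of {60, 66, 63}
  expect_named(tab, c("chest", "abdomen", "waist", "length", "height",
                      "female", "male", "s21", "s23", "age", "weight"))
  expect_identical(clean_records(make_records()), tab)   # idempotent inputs
  bad <- make_records(); bad$birth_date[1] <- as.Date("2021-01-01")
  expect_error(clean_records(bad), "invalid record")
  allmiss <- make_records(); allmiss$height <- NA_real_
  expect_error(clean_records(allmiss), "imputation impossible")
})

test_that("row normalization reproduces the printed normalized records", {
  tab <- example_feature_table()
  norm <- normalize_rows(tab)
  got <- round(as.matrix(as.data.frame(norm)[, colnames(example_records_normalized)]), 4)
  dev <- abs(got - example_records_normalized)
  expect_lte(max(dev), 1e-4 + 1e-12)   # one source cell off by a print ulp
  expect_gte(sum(dev < 1e-12), 49L)
  # weight column stays on the kg scale
  expect_equal(norm$weight, tab$weight)
  # multiplying by the stored norms restores the raw rows
  restored <- as.matrix(as.data.frame(norm)[, 1:10]) * attr(norm, "row_norms")
  expect_equal(restored, as.matrix(as.data.frame(tab)[, 1:10]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a row of unit 11-norm passes through unchanged
  u <- rep(1 / sqrt(11), 11)
  one <- structure(as.data.frame(as.list(setNames(u, names(tab)))),
                   normalized = FALSE, class = c("feature_table", "data.frame"))
  expect_equal(as.numeric(normalize_rows(one)[1, 1:10]), u[1:10],
               tolerance = 1e-12)
  zero <- one; zero[1, ] <- 0
  expect_error(normalize_rows(zero), "zero-norm")
})

test_that("correlation matrix is symmetric with unit diagonal and exact one-hots", {
  h <- generate_herd_records(300, seed = 4, missing_height_frac = 0)
  tab <- clean_records(h)
  cm <- correlation_matrix(tab)
  expect_equal(dim(cm), c(11L, 11L))
  expect_equal(unname(diag(cm)), rep(1, 11))
  expect_equal(cm, t(cm))
  expect_equal(cm["female", "male"], -1)
  expect_equal(cm["s21", "s23"], -1)
  # definition oracle
  x <- tab$chest; y <- tab$weight
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm["chest", "weight"], r, tolerance = 1e-12)
  const <- tab; const$waist <- 1
  expect_error(correlation_matrix(const), "undefined correlation")
})

test_that("variance filter retains exactly the above-threshold features", {
  norm <- normalize_rows(example_feature_table())
  sel0 <- variance_filter(norm, 0)
  expect_true(all(c("chest", "abdomen", "age") %in% sel0$retained))
  expect_false("male" %in% sel0$retained)     # constant zero column
  # population variance oracle
  v_age <- mean(norm$age^2) - mean(norm$age)^2
  expect_equal(unname(sel0$variances["age"]), v_age, tolerance = 1e-15)
  # constructed table where exactly {age, abdomen} clear the threshold,
  # mirroring a high-variance-pair selection outcome
  set.seed(12)
  n <- 200
  built <- data.frame(
    chest = 107 + rnorm(n, 0, 0.3), abdomen = 116 + rnorm(n, 0, 8),
    waist = 105 + rnorm(n, 0, 0.3), length = 120 + rnorm(n, 0, 0.3),
    height = 63 + rnorm(n, 0, 0.2), female = 1, male = 0, s21 = 1, s23 = 0,
    age = round(190 + rnorm(n, 0, 25)), weight = 112 + rnorm(n, 0, 1))
  builtn <- normalize_rows(structure(built, normalized = FALSE,
                                     class = c("feature_table",
                                               "data.frame")))
  v <- variance_filter(builtn, 0)$variances
  thr <- max(v[setdiff(names(v), c("age", "abdomen"))])
  sel <- variance_filter(builtn, thr)
  expect_setequal(sel$retained, c("age", "abdomen"))
})

test_that("the four model variants use the printed feature lists", {
  expect_length(feature_set(1), 10L)
  expect_setequal(feature_set(2), c("height", "chest", "abdomen", "waist"))
  expect_setequal(feature_set(3), c("abdomen", "age"))
  expect_setequal(feature_set(4), c("length", "age", "chest", "abdomen",
                                    "waist"))
  expect_error(feature_set(5), "invalid parameter")
})
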