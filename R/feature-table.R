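# Tabular pipeline: record cleaning (age derivation, one-hot encoding,
# median height imputation), per-row normalization, correlation matrix,
# variance-threshold feature selection, and the four model feature sets.

FEATURE_COLS <- c("chest", "abdomen", "waist", "length", "height",
                  "female", "male", "s21", "s23", "age")

#' Clean raw herd records into a feature table
#'
#' Derives \code{age} in whole days as determination date minus birth date,
#' one-hot encodes gender and breed, imputes missing heights with the
#' median of the observed heights over the whole table, and orders the
#' columns as chest, abdomen, waist, length, height, female, male, s21,
#' s23, age, with the weight label (kg) as the final column.
#'
#' @param records data.frame with columns breed, gender,
#'   determination_date, birth_date, chest, abdominal, waist, length,
#'   height, weight (dates as \code{Date} or parseable strings).
#' @return a \code{feature_table}: data.frame of the 10 features plus
#'   \code{weight}, with attribute \code{normalized = FALSE}.
#' @export
clean_records <- function(records) {
  if (!nrow(records)) stop("invalid parameter: empty record table")
  det <- as.Date(records$determination_date)
  birth <- as.Date(records$birth_date)
  if (any(det < birth))
    stop("invalid record: determination date before birth date")
  gender <- as.character(records$gender)
  breed <- as.character(records$breed)
  if (!all(gender %in% c("female", "male")))
    stop("invalid record: gender must be 'female' or 'male'")
  if (!all(breed %in% c("S21", "S23")))
    stop("invalid record: breed must be 'S21' or 'S23'")
  height <- records$height
  if (all(is.na(height)))
    stop("imputation impossible: all heights missing")
  height[is.na(height)] <- stats::median(height, na.rm = TRUE)
  tab <- data.frame(
    chest = records$chest,
    abdomen = records$abdominal,
    waist = records$waist,
    length = records$length,
    height = height,
    female = as.numeric(gender == "female"),
    male = as.numeric(gender == "male"),
    s21 = as.numeric(breed == "S21"),
    s23 = as.numeric(breed == "S23"),
    age = as.integer(det - birth),
    weight = records$weight)
  if (any(tab$age < 0)) stop("invalid record: negative age")
  structure(tab, normalized = FALSE, class = c("feature_table", "data.frame"))
}

as_feature_table <- function(tab, normalized = FALSE, row_norms = NULL) {
  structure(tab, normalized = normalized, row_norms = row_norms,
            class = c("feature_table", "data.frame"))
}

#' Row-normalize a feature table
#'
#' Divides each feature value by the Euclidean norm of its raw row computed
#' over all 11 values including the weight; the weight label column itself
#' is kept on the kg scale for training. This is the sample-wise L2
#' normalization whose output matches the study's normalized record sheet
#' at 4-decimal rounding. The row norms are stored in the
#' \code{row_norms} attribute, so multiplying each normalized row by its
#' norm restores the raw table.
#'
#' @param table a raw \code{feature_table} from \code{\link{clean_records}}.
#' @return normalized \code{feature_table}.
#' @export
normalize_rows <- function(table) {
  if (isTRUE(attr(table, "normalized")))
    stop("invalid parameter: table is already normalized")
  mat <- as.matrix(table[c(FEATURE_COLS, "weight")])
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stop("normalization error: zero-norm row")
  out <- as.data.frame(mat[, FEATURE_COLS, drop = FALSE] / norms)
  out$weight <- table$weight
  as_feature_table(out, normalized = TRUE, row_norms = norms)
}

#' Pearson correlation matrix of features and weight
#'
#' @param table a raw \code{feature_table}.
#' @return symmetric 11 x 11 correlation matrix with unit diagonal
#'   (features plus weight).
#' @export
correlation_matrix <- function(table) {
  mat <- as.matrix(table[c(FEATURE_COLS, "weight")])
  if (nrow(mat) < 2L) stop("invalid parameter: need at least 2 rows")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: constant column(s) ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  stats::cor(mat)
}

#' Variance-threshold feature selection
#'
#' Computes the population variance (divide by n) of each normalized
#' feature and retains the features whose variance strictly exceeds the
#' threshold.
#'
#' @param table a normalized \code{feature_table}.
#' @param threshold variance threshold.
#' @return object of class \code{feature_selection}: list with
#'   \code{variances} (named), \code{threshold} and \code{retained}.
#' @export
variance_filter <- function(table, threshold) {
  mat <- as.matrix(table[FEATURE_COLS])
  v <- colMeans(mat^2) - colMeans(mat)^2
  structure(list(variances = v, threshold = threshold,
                 retained = names(v)[v > threshold]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("feature_selection (threshold ", format(x$threshold), ")\n", sep = "")
  for (nm in names(x$variances))
    cat(sprintf("  %-8s %.6e %s\n", nm, x$variances[[nm]],
                if (nm %in% x$retained) "retained" else "dropped"))
  invisible(x)
}

#' Feature sets of the four weight models
#'
#' Model 1 uses all ten features; model 2 the height and the three
#' circumferences; model 3 only the abdominal circumference and age; model
#' 4 the length, age and the three circumferences.
#'
#' @param model_id integer in 1..4.
#' @return character vector of feature column names.
#' @export
feature_set <- function(model_id) {
  if (!length(model_id) == 1L || !model_id %in% 1:4)
    stop("invalid parameter: model_id must be 1, 2, 3 or 4")
  switch(model_id,
         FEATURE_COLS,
         c("height", "chest", "abdomen", "waist"),
         c("abdomen", "age"),
         c("length", "age", "chest", "abdomen", "waist"))
}
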