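# Synthetic herd records emulating the marginal statistics of a grower
# herd of S21/S23 Duroc lines: correlated girth/length/height measures
# driven by a latent body-size factor that is itself partly age-driven,
# with weight a configurable linear-plus-smooth function of the features
# plus Gaussian noise.

herd_params <- function() {
  list(
    age_mean = 190, age_sd = 10,
    size_age_loading = 0.35,            # latent size = 0.35 age_z + rest
    breed_probs = c(S21 = 8068, S23 = 1912) / 9980,
    gender_probs = c(female = 5438, male = 4542) / 9980,
    means = c(chest = 107, abdominal = 116, waist = 105,
              length = 120, height = 63),
    loadings = c(chest = 3.5, abdominal = 4.5, waist = 4.0,
                 length = 5.0, height = 2.5),
    resid_sd = c(chest = 1.5, abdominal = 2.0, waist = 2.0,
                 length = 2.5, height = 1.2))
}

#' Theoretical column moments of the herd generator
#'
#' Returns the mean and standard deviation each measured column is drawn
#' with, for use in distributional checks of generated herds.
#' @return data.frame with columns \code{feature}, \code{mean}, \code{sd}.
#' @export
herd_moments <- function() {
  p <- herd_params()
  sds <- sqrt(p$loadings^2 + p$resid_sd^2)
  rbind(data.frame(feature = names(p$means), mean = unname(p$means),
                   sd = unname(sds)),
        data.frame(feature = "age_days", mean = p$age_mean, sd = p$age_sd))
}

#' Default weight model of the herd generator
#'
#' Weight (kg) is a linear function of abdominal circumference and age plus
#' a mild quadratic term in the abdominal circumference; the remaining
#' features influence weight only through their correlation with these two.
#'
#' @return list with \code{coefficients} (named vector, includes
#'   \code{intercept}) and \code{smooth} (function of the record
#'   data.frame returning a per-record additive term).
#' @export
herd_effects <- function() {
  list(coefficients = c(intercept = -102.1, abdominal = 1.1, age_days = 0.45),
       smooth = function(df) 0.02 * (df$abdominal - 116)^2)
}

#' Generate synthetic herd records
#'
#' @param n number of pigs (>= 1).
#' @param seed integer seed; identical seeds give identical tables.
#' @param effect_spec weight model as returned by \code{\link{herd_effects}}:
#'   named coefficients over record columns (plus \code{intercept}) and an
#'   optional \code{smooth} function.
#' @param noise_sd_kg standard deviation of the additive weight noise, kg.
#' @param missing_height_frac fraction of height values set missing (to be
#'   median-imputed downstream).
#' @return data.frame with columns breed, gender, determination_date,
#'   birth_date, chest, abdominal, waist, length, height, weight.
#' @export
generate_herd_records <- function(n, seed = 1, effect_spec = herd_effects(),
                                  noise_sd_kg = 2,
                                  missing_height_frac = 0.05) {
  if (n < 1) stop("invalid parameter: need n >= 1")
  p <- herd_params()
  with_seed(seed, {
    age <- round(stats::rnorm(n, p$age_mean, p$age_sd))
    age <- pmax(age, 120)
    age_z <- (age - p$age_mean) / p$age_sd
    lam <- p$size_age_loading
    size <- lam * age_z + sqrt(1 - lam^2) * stats::rnorm(n)
    meas <- sapply(names(p$means), function(f)
      p$means[[f]] + p$loadings[[f]] * size + stats::rnorm(n, 0, p$resid_sd[[f]]))
    meas <- as.data.frame(meas)
    breed <- sample(names(p$breed_probs), n, replace = TRUE,
                    prob = p$breed_probs)
    gender <- sample(names(p$gender_probs), n, replace = TRUE,
                     prob = p$gender_probs)
    det_date <- as.Date("2016-01-01") +
      sample.int(as.integer(as.Date("2020-12-31") - as.Date("2016-01-01")) + 1L,
                 n, replace = TRUE) - 1L
    df <- data.frame(breed = breed, gender = gender,
                     determination_date = det_date,
                     birth_date = det_date - age,
                     chest = meas$chest, abdominal = meas$abdominal,
                     waist = meas$waist, length = meas$length,
                     height = meas$height, stringsAsFactors = FALSE)
    df$age_days <- age
    df$female <- as.numeric(gender == "female")
    df$male <- as.numeric(gender == "male")
    df$S21 <- as.numeric(breed == "S21")
    df$S23 <- as.numeric(breed == "S23")
    co <- effect_spec$coefficients
    weight <- if ("intercept" %in% names(co)) rep(co[["intercept"]], n) else numeric(n)
    for (nm in setdiff(names(co), "intercept")) {
      if (!nm %in% names(df))
        stop("invalid parameter: unknown effect feature '", nm, "'")
      weight <- weight + co[[nm]] * df[[nm]]
    }
    if (!is.null(effect_spec$smooth)) weight <- weight + effect_spec$smooth(df)
    if (noise_sd_kg > 0) weight <- weight + stats::rnorm(n, 0, noise_sd_kg)
    df$weight <- weight
    if (missing_height_frac > 0) {
      nmiss <- round(missing_height_frac * n)
      if (nmiss > 0) df$height[sample.int(n, nmiss)] <- NA_real_
    }
    df[c("breed", "gender", "determination_date", "birth_date", "chest",
         "abdominal", "waist", "length", "height", "weight")]
  })
}

#' Read/write herd record CSVs
#'
#' CSV columns follow the study's record sheet: breed, gender,
#' determination date, birth date, chest, abdominal, waist, length, height,
#' weight.
#' @param records herd record data.frame.
#' @param path file path.
#' @export
write_herd_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_herd_csv
#' @export
read_herd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$determination_date <- as.Date(df$determination_date)
  df$birth_date <- as.Date(df$birth_date)
  df
}
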