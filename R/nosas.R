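#' NoSAS sleep-apnea risk score
#'
#' Additive risk score from Neck circumference, obesity (BMI), Snoring, Age
#' and Sex: 4 points for neck circumference >= 40 cm, 3 points for
#' 25 <= BMI < 30 kg/m^2 or 5 points for BMI >= 30 kg/m^2, 2 points for
#' reported snoring, 4 points for age >= 55 years and 2 points for male sex.
#' The score ranges 0-17; a score >= 8 flags high probability of obstructive
#' sleep apnea.
#'
#' BMI is recomputed from `height_m` and `weight_kg` when both are supplied,
#' and is rounded to one decimal before banding (band edges evaluated on the
#' rounded value, the usual clinical convention).
#'
#' @param neck_circumference Neck circumference in cm.
#' @param bmi Body-mass index in kg/m^2 (ignored if height and weight given).
#' @param snoring Logical, reported snoring.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param height_m,weight_kg Optional height (m) and weight (kg) from which
#'   BMI is computed.
#' @return A list of class `nosas_result` with `score` (integer 0-17),
#'   `high_risk` (logical) and `components` (named integer vector of the five
#'   criterion points: `nc`, `bmi`, `snoring`, `age`, `sex`).
#' @examples
#' nosas_score(41, 31, TRUE, 56, "M")$score  # 17, every criterion at maximum
#' @export
nosas_score <- function(neck_circumference, bmi = NULL, snoring, age, sex,
                        height_m = NULL, weight_kg = NULL) {
  if (!is.null(height_m) && !is.null(weight_kg)) {
    bmi <- weight_kg / height_m^2
  }
  args <- list(neck_circumference = neck_circumference, bmi = bmi,
               snoring = snoring, age = age, sex = sex)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || length(args[[nm]]) != 1 || is.na(args[[nm]]))
      stop("nosas_score: missing or invalid field '", nm, "'")
  }
  stopifnot(bmi > 0, neck_circumference > 0)
  sex <- match.arg(toupper(as.character(sex)), c("M", "F"))
  bmi_r <- round(bmi, 1)
  components <- c(
    nc      = if (neck_circumference >= 40) 4L else 0L,
    bmi     = if (bmi_r >= 30) 5L else if (bmi_r >= 25) 3L else 0L,
    snoring = if (isTRUE(as.logical(snoring))) 2L else 0L,
    age     = if (age >= 55) 4L else 0L,
    sex     = if (sex == "M") 2L else 0L
  )
  score <- sum(components)
  structure(list(score = score, high_risk = score >= 8L, components = components),
            class = "nosas_result")
}

#' @export
print.nosas_result <- function(x, ...) {
  cat("NoSAS score:", x$score,
      if (x$high_risk) "(high risk of OSA, >= 8)" else "(low risk, < 8)", "\n")
  invisible(x)
}

#' Score a demographics table
#'
#' Applies [nosas_score()] to each row of a demographics data.frame with
#' columns `neck_circumference`, `bmi` (or `height_m` + `weight_kg`),
#' `snoring`, `age`, `sex`, keeping any `participant_id` column.
#'
#' @param demographics A data.frame, one row per participant.
#' @return data.frame with `score`, `high_risk` and the five component
#'   columns prefixed `pts_`.
#' @export
nosas_table <- function(demographics) {
  d <- demographics
  res <- lapply(seq_len(nrow(d)), function(i) {
    r <- nosas_score(
      neck_circumference = d$neck_circumference[i],
      bmi = if ("bmi" %in% names(d)) d$bmi[i] else NULL,
      snoring = d$snoring[i], age = d$age[i], sex = d$sex[i],
      height_m = if ("height_m" %in% names(d)) d$height_m[i] else NULL,
      weight_kg = if ("weight_kg" %in% names(d)) d$weight_kg[i] else NULL
    )
    c(score = r$score, high_risk = as.integer(r$high_risk), r$components)
  })
  res <- as.data.frame(do.call(rbind, res))
  names(res) <- c("score", "high_risk", paste0("pts_", c("nc", "bmi", "snoring", "age", "sex")))
  res$high_risk <- as.logical(res$high_risk)
  if ("participant_id" %in% names(d))
    res <- cbind(participant_id = d$participant_id, res)
  res
}
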