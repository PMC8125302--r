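# Categorization of tumor immune infiltrate measurements: fixed cutpoints
# for stromal TIL percentages, cohort-level quartile cutpoints for CD3/CD8
# densities.

#' Categorize stromal TIL percentages
#'
#' Fixed clinical cutpoints: `< 10`% is `low`, `10--40`% `intermediate`,
#' `> 40`% `high` (boundary values 10 and 40 are intermediate); missing
#' measurements become `absent`.
#'
#' @param stil_pct numeric vector in \[0, 100\] (NA allowed).
#' @return factor with levels `low`, `intermediate`, `high`, `absent`.
#' @export
categorize_stil <- function(stil_pct) {
  bad <- which(!is.na(stil_pct) & (stil_pct < 0 | stil_pct > 100))
  if (length(bad))
    stop("sTIL percentage outside [0, 100] at position ", bad[1])
  out <- ifelse(is.na(stil_pct), "absent",
                ifelse(stil_pct < 10, "low",
                       ifelse(stil_pct > 40, "high", "intermediate")))
  factor(out, levels = c("low", "intermediate", "high", "absent"))
}

#' Categorize immune-cell densities by cohort quartiles
#'
#' Cutpoints are the 25th and 75th percentiles (linear-interpolation, type-7
#' quantiles) of the non-missing densities across the whole cohort:
#' `v <= q1` is `low`, `v >= q3` `high`, the rest `intermediate`; missing
#' becomes `absent`. Cutpoints are computed once on the full vector passed
#' in — re-running on a patient subset changes them, so callers must
#' categorize on the cohort and subset afterwards.
#'
#' @param densities numeric vector (>= 4 non-missing values).
#' @return list with `category` (factor as in [categorize_stil()]), `q1`,
#'   `q3`.
#' @export
categorize_density <- function(densities) {
  obs <- densities[!is.na(densities)]
  if (length(obs) < 4)
    stop("need at least 4 non-missing densities to compute quartiles")
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2])
    message("degenerate quartiles (q1 == q3): all observed values ",
            "assigned 'low'")
  out <- ifelse(is.na(densities), "absent",
                ifelse(densities <= q[1], "low",
                       ifelse(densities >= q[2], "high", "intermediate")))
  list(category = factor(out, levels = c("low", "intermediate", "high",
                                         "absent")),
       q1 = q[1], q3 = q[2])
}

#' Infiltrate category labels for a whole cohort
#'
#' Applies [categorize_stil()] to `stil_pct` and [categorize_density()] to
#' the four CD3/CD8 density columns of a cohort table.
#'
#' @param cohort cohort data.frame (see [generate_cohort()]).
#' @return data.frame with `patient_id` and one category column per
#'   infiltrate variable; attribute `"cutoffs"` holds the q1/q3 per density
#'   variable.
#' @export
infiltrate_labels <- function(cohort) {
  dens_vars <- c("cd3_whole", "cd3_front", "cd8_whole", "cd8_front")
  out <- data.frame(patient_id = cohort$patient_id,
                    stil = categorize_stil(cohort$stil_pct),
                    stringsAsFactors = FALSE)
  cutoffs <- list()
  for (v in dens_vars) {
    cd <- categorize_density(cohort[[v]])
    out[[v]] <- cd$category
    cutoffs[[v]] <- c(q1 = cd$q1, q3 = cd$q3)
  }
  attr(out, "cutoffs") <- cutoffs
  out
}

#' Class labels for a contrast
#'
#' Maps a cohort to the label vector a contrast compares: `age` (younger vs
#' older, all patients), `frailty` (fit vs frailer, only older patients
#' with a G8 score), or one of the five infiltrate variables (three ordered
#' categories low / intermediate / high; patients without the measurement
#' get `NA` and drop out of the complete-case analysis).
#'
#' @param cohort cohort data.frame.
#' @param contrast one of `"age"`, `"frailty"`, `"stil"`, `"cd3_whole"`,
#'   `"cd3_front"`, `"cd8_whole"`, `"cd8_front"`.
#' @return factor aligned with the cohort rows; the group of interest
#'   (older / frailer) is the last level for the binary contrasts.
#' @export
contrast_labels <- function(cohort, contrast) {
  contrast <- match.arg(contrast, c("age", "frailty", "stil", "cd3_whole",
                                    "cd3_front", "cd8_whole", "cd8_front"))
  if (contrast == "age")
    return(factor(cohort$age_group, levels = c("younger", "older")))
  if (contrast == "frailty") {
    lab <- ifelse(cohort$frailty_group %in% c("fit", "frailer"),
                  cohort$frailty_group, NA_character_)
    return(factor(lab, levels = c("fit", "frailer")))
  }
  lab <- if (contrast == "stil") categorize_stil(cohort$stil_pct)
  else categorize_density(cohort[[contrast]])$category
  lab <- as.character(lab)
  lab[lab == "absent"] <- NA_character_
  factor(lab, levels = c("low", "intermediate", "high"))
}
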