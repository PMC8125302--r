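# Export of plot-ready discriminant coordinates (LD1 densities for binary
# contrasts; LD1/LD2 score coordinates with confidence ellipsoids for
# three-class contrasts) and of formatted panel tables.

#' Export discriminant projection coordinates
#'
#' For a binary contrast the export is the per-sample LD1 coordinate with
#' its group label (the input of a density plot). For a three-class
#' contrast it is the (LD1, LD2) score coordinates, plus per-group 66% and
#' 95% confidence ellipsoid parameters: group mean, 2 x 2 covariance of the
#' LD coordinates, and the squared radii `r2 = q * eigenvalues` with `q`
#' the chi-square quantile with 2 degrees of freedom
#' (`qchisq(0.66, 2) = 2.158`, `qchisq(0.95, 2) = 5.991`).
#'
#' @param model fitted [fit_lda()] model.
#' @param x feature matrix the model was fitted on (complete cases).
#' @param y class labels.
#' @return list with `coords` (data.frame `group`, `LD1`\[, `LD2`\]) and,
#'   for three classes, `ellipsoids`: per group a list with `center`,
#'   `cov`, `radii2` (matrix with rows `level66` / `level95`), and `angle`
#'   (radians, orientation of the major axis).
#' @export
export_projection <- function(model, x, y) {
  stopifnot(inherits(model, "senopanel_lda"))
  pr <- predict(model, x)
  k <- length(model$class_labels)
  m <- ncol(pr$ld)
  coords <- data.frame(group = as.character(y), pr$ld,
                       stringsAsFactors = FALSE)
  if (k == 2 || m < 2) return(list(coords = coords[, c("group", "LD1")]))

  q <- stats::qchisq(c(0.66, 0.95), df = 2)
  ell <- lapply(model$class_labels, function(g) {
    pts <- pr$ld[y == g, 1:2, drop = FALSE]
    ctr <- colMeans(pts)
    cv <- stats::cov(pts)
    ev <- eigen(cv, symmetric = TRUE)
    radii2 <- rbind(level66 = q[1] * ev$values, level95 = q[2] * ev$values)
    list(center = ctr, cov = cv, radii2 = radii2,
         angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
  })
  names(ell) <- model$class_labels
  list(coords = coords, ellipsoids = ell)
}

#' Format a panel table to one decimal place
#'
#' Rounds the numeric performance columns the way the published tables are
#' printed (one decimal).
#'
#' @param top a `top` table from [run_search()].
#' @return data.frame with accuracy / loss columns formatted as characters.
#' @export
format_panel_table <- function(top) {
  out <- top
  for (cn in grep("^(accuracy|loss)", names(out), value = TRUE))
    out[[cn]] <- formatC(out[[cn]], format = "f", digits = 1)
  out
}

#' Write a ranked panel table
#'
#' Writes the one-decimal CSV mirror of the published tables plus a
#' full-precision JSON alongside it.
#'
#' @param top a `top` (or full `results`) table from [run_search()].
#' @param path CSV output path; the JSON goes to the same path with
#'   extension `.json`.
#' @return the two paths, invisibly.
#' @export
write_panel_table <- function(top, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(format_panel_table(top), path, row.names = FALSE,
                   quote = FALSE)
  json_path <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(top, json_path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = path, json = json_path))
}
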