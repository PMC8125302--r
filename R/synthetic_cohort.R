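# Synthetic cohort generator: emulates the structure of a two-age-group
# breast-cancer cohort with G8-based frailty subgroups, a heterogeneous
# blood biomarker matrix with block-wise missingness, and tumor immune
# infiltrate measurements.

#' Biomarker family layout
#'
#' Partitions `n_biomarkers` into the assay families the generator simulates:
#' plasma proteins (cytokines, chemokines, checkpoint proteins; log-normal),
#' plasma miRNAs (Gaussian on a qPCR-like scale), a single T-cell P16INK4a
#' expression marker (log2-normal), and PBMC subset percentages
#' (logit-normal, bounded in \[0, 100\]).
#'
#' @param n_biomarkers total number of biomarkers (>= 4 so that every family
#'   is represented).
#' @return data.frame with columns `name` and `family`
#'   (`plasma`, `mirna`, `p16`, `pbmc`).
#' @export
biomarker_families <- function(n_biomarkers) {
  stopifnot(is.numeric(n_biomarkers), n_biomarkers >= 4)
  n <- as.integer(n_biomarkers)
  n_plasma <- max(1L, round(0.28 * n))
  n_mirna <- max(1L, round(0.20 * n))
  n_p16 <- 1L
  n_pbmc <- n - n_plasma - n_mirna - n_p16
  if (n_pbmc < 1L) { # tiny matrices: shrink plasma first
    n_plasma <- max(1L, n_plasma + n_pbmc - 1L)
    n_pbmc <- n - n_plasma - n_mirna - n_p16
  }
  fam <- c(rep("plasma", n_plasma), rep("mirna", n_mirna),
           rep("p16", n_p16), rep("pbmc", n_pbmc))
  name <- c(sprintf("plasma_%02d", seq_len(n_plasma)),
            sprintf("mirna_%02d", seq_len(n_mirna)),
            "tcell_p16",
            sprintf("pbmc_%02d", seq_len(n_pbmc)))
  data.frame(name = name, family = fam, stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Collects and validates every knob of the cohort generator. The defaults
#' reproduce the study structure the pipeline targets: 34 younger patients
#' (35--45 / 55--65 years), 31 older patients (>= 70 years) of whom 19 are
#' fit (G8 > 14), 10 frailer (G8 <= 14) and 2 without a G8 score; roughly
#' 100 biomarkers across four assay families; the PBMC flow-cytometry block
#' missing for ~12% of patients and the T-cell P16INK4a assay missing for
#' ~30%, so that complete-case panel sizes vary the way multi-assay panels
#' do; 3 patients without tumor tissue and hence without infiltrate
#' measurements.
#'
#' @param n_young,n_old group sizes for the younger / older age groups.
#' @param n_fit,n_frail older patients with G8 > 14 / G8 <= 14
#'   (`n_fit + n_frail <= n_old`; the remainder have no G8 score).
#' @param n_biomarkers number of blood biomarkers.
#' @param planted data.frame with columns `index` (biomarker column),
#'   `contrast` (`"age"` or `"frailty"`) and `d` (standardized effect size in
#'   pooled-SD units on the latent scale): the group of interest (older /
#'   frailer) is shifted by `d`, so the expected two-group AUC is
#'   `pnorm(d / sqrt(2))`.
#' @param block_missing list of `list(block = <integer indices>, prob = p)`
#'   entries; each patient loses the whole block independently with
#'   probability `p`. `NULL` uses the default PBMC / P16 pattern above;
#'   use `list()` for no missingness.
#' @param infiltrate_assoc data.frame with columns `index`, `variable` (one
#'   of `stil`, `cd3_whole`, `cd3_front`, `cd8_whole`, `cd8_front`) and
#'   `strength` in \[0, 1): the biomarker's latent value is mixed with the
#'   infiltrate variable's latent value at that correlation, making it
#'   monotonically predictive of the infiltrate category.
#' @param rho_within_block equicorrelation of latent values within an assay
#'   family, approximating the nesting of flow-cytometry subsets.
#' @param n_no_tissue patients without tumor material (all five infiltrate
#'   measurements missing).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `senopanel_config` (a validated list).
#' @export
synthetic_config <- function(n_young = 34, n_old = 31, n_fit = 19,
                             n_frail = 10, n_biomarkers = 100,
                             planted = NULL, block_missing = NULL,
                             infiltrate_assoc = NULL,
                             rho_within_block = 0, n_no_tissue = 3,
                             seed = 1L) {
  counts <- c(n_young = n_young, n_old = n_old, n_fit = n_fit,
              n_frail = n_frail, n_biomarkers = n_biomarkers,
              n_no_tissue = n_no_tissue)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all counts must be finite and >= 0")
  if (n_fit + n_frail > n_old)
    stop("inconsistent counts: n_fit + n_frail > n_old")
  if (n_no_tissue > n_young + n_old)
    stop("n_no_tissue exceeds the cohort size")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("index", "contrast", "d") %in% names(planted)))
    if (any(planted$index < 1 | planted$index > n_biomarkers))
      stop("planted biomarker index out of range")
    if (!all(planted$contrast %in% c("age", "frailty")))
      stop("planted contrast must be 'age' or 'frailty'")
    if (any(!is.finite(planted$d))) stop("planted effect sizes must be finite")
  }
  if (!is.null(infiltrate_assoc)) {
    infiltrate_assoc <- as.data.frame(infiltrate_assoc)
    stopifnot(all(c("index", "variable", "strength") %in%
                    names(infiltrate_assoc)))
    ok_var <- c("stil", "cd3_whole", "cd3_front", "cd8_whole", "cd8_front")
    if (!all(infiltrate_assoc$variable %in% ok_var))
      stop("infiltrate_assoc variable must be one of: ",
           paste(ok_var, collapse = ", "))
    if (any(infiltrate_assoc$strength < 0 | infiltrate_assoc$strength >= 1))
      stop("infiltrate association strength must be in [0, 1)")
  }
  if (!is.null(block_missing)) {
    for (bm in block_missing) {
      if (!all(c("block", "prob") %in% names(bm)))
        stop("each block_missing entry needs fields 'block' and 'prob'")
      if (bm$prob < 0 || bm$prob > 1)
        stop("missing probability must be in [0, 1]")
      if (any(bm$block < 1 | bm$block > n_biomarkers))
        stop("block_missing index out of range")
    }
  }
  if (rho_within_block < 0 || rho_within_block >= 1)
    stop("rho_within_block must be in [0, 1)")
  structure(list(
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    n_fit = as.integer(n_fit), n_frail = as.integer(n_frail),
    n_biomarkers = as.integer(n_biomarkers), planted = planted,
    block_missing = block_missing, infiltrate_assoc = infiltrate_assoc,
    rho_within_block = rho_within_block,
    n_no_tissue = as.integer(n_no_tissue), seed = as.integer(seed)
  ), class = "senopanel_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path file whose extension decides the parser (`.yaml`/`.yml` or
#'   `.json`). Fields are passed to [synthetic_config()]; `planted`,
#'   `infiltrate_assoc` may be given as lists of records.
#' @return `senopanel_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (fld in c("planted", "infiltrate_assoc")) {
    if (!is.null(raw[[fld]]) && !is.data.frame(raw[[fld]]))
      raw[[fld]] <- do.call(rbind, lapply(raw[[fld]], as.data.frame))
  }
  do.call(synthetic_config, raw)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

default_block_missing <- function(fams) {
  pbmc <- which(fams$family == "pbmc")
  p16 <- which(fams$family == "p16")
  out <- list()
  if (length(pbmc)) out <- c(out, list(list(block = pbmc, prob = 0.12)))
  if (length(p16)) out <- c(out, list(list(block = p16, prob = 0.30)))
  out
}

#' Generate a synthetic cohort and biomarker matrix
#'
#' Draws latent standard-normal biomarker values per patient (optionally
#' equicorrelated within assay families), mixes selected biomarkers with the
#' latent tumor-infiltrate variables, shifts planted biomarkers by `d`
#' pooled SDs in the group of interest, then maps each family onto its
#' natural measurement scale through a strictly increasing transform (so the
#' latent effect size controls the observable AUC exactly:
#' `AUC = pnorm(d / sqrt(2))`). Block-wise missingness then removes whole
#' assay blocks per patient.
#'
#' @param config a [synthetic_config()] object.
#' @return list with `cohort` (data.frame; one row per patient with age,
#'   age_group, g8, frailty_group, tumor and infiltrate variables) and
#'   `matrix` (numeric patients x biomarkers matrix, `NA` = missing,
#'   rownames = patient ids).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "senopanel_config"))
    config <- do.call(synthetic_config, as.list(config))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_young + config$n_old
  p <- config$n_biomarkers
  fams <- biomarker_families(p)
  ids <- sprintf("P%03d", seq_len(n))

  ## --- clinical table -------------------------------------------------
  age_young <- sample(c(35:45, 55:65), config$n_young, replace = TRUE)
  age_old <- sample(70:89, config$n_old, replace = TRUE)
  age <- c(age_young, age_old)
  age_group <- rep(c("younger", "older"), c(config$n_young, config$n_old))

  g8 <- rep(NA_integer_, n)
  frailty <- rep("n/a", n)
  old_idx <- which(age_group == "older")
  scored <- sample(old_idx, config$n_fit + config$n_frail)
  fit_idx <- scored[seq_len(config$n_fit)]
  frail_idx <- setdiff(scored, fit_idx)
  g8[fit_idx] <- sample(15:17, config$n_fit, replace = TRUE)
  g8[frail_idx] <- sample(12:14, config$n_frail, replace = TRUE)
  frailty[fit_idx] <- "fit"
  frailty[frail_idx] <- "frailer"

  tumor_size <- round(pmax(10, exp(rnorm(n, log(28), 0.40))), 1)
  tumor_grade <- sample(1:3, n, replace = TRUE, prob = c(0.02, 0.61, 0.37))
  node_stage <- sample(paste0("pN", 0:3), n, replace = TRUE,
                       prob = c(0.49, 0.45, 0.045, 0.015))

  ## --- latent infiltrate variables ------------------------------------
  u_cd3 <- rnorm(n); u_cd8 <- rnorm(n)
  infil_latent <- cbind(
    stil = rnorm(n),
    cd3_whole = 0.85 * u_cd3 + sqrt(1 - 0.85^2) * rnorm(n),
    cd3_front = 0.85 * u_cd3 + sqrt(1 - 0.85^2) * rnorm(n),
    cd8_whole = 0.85 * u_cd8 + sqrt(1 - 0.85^2) * rnorm(n),
    cd8_front = 0.85 * u_cd8 + sqrt(1 - 0.85^2) * rnorm(n))

  ## --- latent biomarker matrix ----------------------------------------
  z <- matrix(rnorm(n * p), n, p)
  rho <- config$rho_within_block
  if (rho > 0) {
    for (f in unique(fams$family)) {
      cols <- which(fams$family == f)
      shared <- rnorm(n)
      z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
    }
  }
  ia <- config$infiltrate_assoc
  if (!is.null(ia)) {
    for (i in seq_len(nrow(ia))) {
      s <- ia$strength[i]; j <- ia$index[i]
      z[, j] <- s * infil_latent[, ia$variable[i]] + sqrt(1 - s^2) * z[, j]
    }
  }
  pl <- config$planted
  if (!is.null(pl)) {
    for (i in seq_len(nrow(pl))) {
      grp <- switch(pl$contrast[i],
                    age = age_group == "older",
                    frailty = frailty == "frailer")
      z[grp, pl$index[i]] <- z[grp, pl$index[i]] + pl$d[i]
    }
  }

  ## --- family-specific measurement scales (strictly monotone) ---------
  values <- matrix(NA_real_, n, p, dimnames = list(ids, fams$name))
  for (f in unique(fams$family)) {
    cols <- which(fams$family == f)
    for (j in cols) {
      values[, j] <- switch(
        f,
        plasma = exp(runif(1, log(5), log(500)) + runif(1, 0.4, 1.2) * z[, j]),
        mirna = runif(1, 20, 30) + runif(1, 0.8, 2.0) * z[, j],
        p16 = 2^(0.8 * z[, j]),
        pbmc = 100 * stats::plogis(stats::qlogis(runif(1, 0.01, 0.4)) +
                                     runif(1, 0.5, 1.5) * z[, j]))
    }
  }

  ## --- block-wise missingness ------------------------------------------
  bm <- config$block_missing
  if (is.null(bm)) bm <- default_block_missing(fams)
  for (blk in bm) {
    drop <- stats::runif(n) < blk$prob
    values[drop, blk$block] <- NA_real_
  }

  ## --- observable infiltrate measurements -------------------------------
  stil_pct <- round(100 * stats::plogis(-2.6 + 1.4 * infil_latent[, "stil"]), 1)
  cd3_whole <- round(exp(5.0 + 0.9 * infil_latent[, "cd3_whole"]), 1)
  cd3_front <- round(exp(5.4 + 0.9 * infil_latent[, "cd3_front"]), 1)
  cd8_whole <- round(exp(4.4 + 1.0 * infil_latent[, "cd8_whole"]), 1)
  cd8_front <- round(exp(4.8 + 1.0 * infil_latent[, "cd8_front"]), 1)
  if (config$n_no_tissue > 0) {
    no_tissue <- sample(n, config$n_no_tissue)
    stil_pct[no_tissue] <- NA_real_
    cd3_whole[no_tissue] <- NA_real_; cd3_front[no_tissue] <- NA_real_
    cd8_whole[no_tissue] <- NA_real_; cd8_front[no_tissue] <- NA_real_
  }

  cohort <- data.frame(
    patient_id = ids, age = as.integer(age), age_group = age_group,
    g8 = g8, frailty_group = frailty, tumor_size = tumor_size,
    tumor_grade = as.integer(tumor_grade), node_stage = node_stage,
    stil_pct = stil_pct, cd3_whole = cd3_whole, cd3_front = cd3_front,
    cd8_whole = cd8_whole, cd8_front = cd8_front,
    stringsAsFactors = FALSE)
  list(cohort = cohort, matrix = values)
}

#' Write / read a cohort and biomarker matrix as CSV
#'
#' `write_cohort()` writes `cohort.csv` and `biomarkers.csv` (patients in
#' rows, `patient_id` first column, empty cell = missing) into `dir`;
#' numeric cells are printed with 17 significant digits so the round trip is
#' exact. `read_cohort()` reads them back and validates that every
#' non-empty biomarker cell is numeric.
#'
#' @param cohort,matrix as returned by [generate_cohort()].
#' @param dir directory (created if needed).
#' @return `write_cohort()` the two file paths, invisibly; `read_cohort()` a
#'   list with `cohort` and `matrix`.
#' @export
write_cohort <- function(cohort, matrix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, digits = 17,
                                                    format = "g"))
    else ifelse(is.na(x), "", as.character(x))
  }
  coh_path <- file.path(dir, "cohort.csv")
  mat_path <- file.path(dir, "biomarkers.csv")
  coh_out <- as.data.frame(lapply(cohort, fmt), stringsAsFactors = FALSE,
                           check.names = FALSE)
  utils::write.csv(coh_out, coh_path, row.names = FALSE, quote = FALSE,
                   na = "")
  mat_out <- data.frame(patient_id = rownames(matrix),
                        apply(matrix, 2, fmt), check.names = FALSE,
                        stringsAsFactors = FALSE)
  utils::write.csv(mat_out, mat_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(c(cohort = coh_path, matrix = mat_path))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  coh_path <- file.path(dir, "cohort.csv")
  mat_path <- file.path(dir, "biomarkers.csv")
  for (pth in c(coh_path, mat_path))
    if (!file.exists(pth)) stop("missing file: ", pth)

  coh <- utils::read.csv(coh_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("patient_id", "age", "age_group", "g8", "frailty_group")
  if (!all(needed %in% names(coh)))
    stop("malformed cohort header; expected columns: ",
         paste(needed, collapse = ", "))
  chr_cols <- c("patient_id", "age_group", "frailty_group", "node_stage")
  int_cols <- c("age", "g8", "tumor_grade")
  for (cn in names(coh)) {
    if (cn %in% chr_cols) {
      coh[[cn]][coh[[cn]] == ""] <- NA_character_
      if (cn == "frailty_group") coh[[cn]][is.na(coh[[cn]])] <- "n/a"
    } else {
      blank <- coh[[cn]] == ""
      num <- suppressWarnings(as.numeric(coh[[cn]]))
      bad <- which(!blank & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     coh[[cn]][bad[1]], bad[1], cn))
      coh[[cn]] <- if (cn %in% int_cols) as.integer(round(num)) else num
    }
  }

  mat_raw <- utils::read.csv(mat_path, stringsAsFactors = FALSE,
                             colClasses = "character", check.names = FALSE)
  if (names(mat_raw)[1] != "patient_id")
    stop("malformed matrix header: first column must be 'patient_id'")
  ids <- mat_raw$patient_id
  vals <- as.matrix(mat_raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(vals != "" & is.na(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  list(cohort = coh, matrix = num)
}
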