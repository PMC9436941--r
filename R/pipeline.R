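# End-to-end procedure: best-match labelling against measured GFR, 70/30
# train/test split, selector training, dispatch estimation, artifact output.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps all package randomness local and
# reproducible without clobbering the user's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Add derived anthropometric columns
#'
#' Computes Du Bois body surface area (`bsa`, m^2) and body mass index
#' (`bmi`, kg/m^2) from `height` and `weight` where those columns are not
#' already present.
#'
#' @param cohort Cohort data frame with `height` (cm) and `weight` (kg).
#' @return The cohort with `bsa` and `bmi` columns.
#' @export
add_derived <- function(cohort) {
  if (is.null(cohort$bsa)) cohort$bsa <- du_bois_bsa(cohort$weight, cohort$height)
  if (is.null(cohort$bmi)) cohort$bmi <- cohort$weight / (cohort$height / 100)^2
  cohort
}

#' Best-matched equation per patient
#'
#' For each row, computes eGFR under every candidate equation and returns the
#' equation whose estimate deviates least from the measured GFR normalised to
#' 1.73 m^2 (`sgfr_abs * 1.73 / BSA`).  Deviation is the absolute difference
#' on the normalised scale by default.  Ties are broken by the fixed
#' candidate priority order ([egfr_candidates()]).
#'
#' @param cohort Cohort data frame with biomarkers, `height`, `weight` and
#'   `sgfr_abs` (measured GFR, mL/min).
#' @param candidates Equations to choose among.
#' @param deviation `"absolute"` (default, difference in mL/min per 1.73 m^2)
#'   or `"relative"` (absolute difference divided by measured GFR).
#' @return Character vector of chosen equation ids.
#' @export
assign_best_equation <- function(cohort, candidates = egfr_candidates(),
                                 deviation = c("absolute", "relative")) {
  deviation <- match.arg(deviation)
  if (is.null(cohort$sgfr_abs) || anyNA(cohort$sgfr_abs)) {
    stop("sgfr_abs (measured GFR) is required for labelling", call. = FALSE)
  }
  cohort <- add_derived(cohort)
  sgfr_norm <- normalize_gfr(cohort$sgfr_abs, cohort$bsa)
  est <- vapply(candidates, function(eq) estimate_egfr(cohort, eq),
                numeric(nrow(cohort)))
  if (is.null(dim(est))) est <- matrix(est, nrow = 1, dimnames = list(NULL, candidates))
  dev <- abs(est - sgfr_norm)
  if (deviation == "relative") dev <- dev / sgfr_norm
  # which.min on each row honours column order => candidate priority on ties
  candidates[apply(dev, 1, which.min)]
}

#' Label a cohort with its best-matched equations
#'
#' Adds `bsa`, `bmi`, `sgfr_norm` (measured GFR per 1.73 m^2) and
#' `best_equation` columns.
#'
#' @inheritParams assign_best_equation
#' @return The augmented cohort data frame.
#' @export
label_cohort <- function(cohort, candidates = egfr_candidates(),
                         deviation = "absolute") {
  cohort <- add_derived(cohort)
  cohort$sgfr_norm <- normalize_gfr(cohort$sgfr_abs, cohort$bsa)
  cohort$best_equation <- assign_best_equation(cohort, candidates, deviation)
  cohort
}

#' Random train/test split
#'
#' Assigns `floor(n * train_fraction)` rows to the training set by a uniform
#' random permutation; the remainder form the test set.  Deterministic per
#' seed.  At the study's size this reproduces the 362/156 partition of a
#' 518-row cohort at fraction 0.7.
#'
#' @param n Number of rows (or a data frame, whose row count is used).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed.
#' @return Character vector of `"train"`/`"test"`, length `n`.
#' @export
split_cohort <- function(n, train_fraction = 0.7, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- floor(n * train_fraction)
  perm <- with_seed(seed, sample.int(n))
  out <- rep("test", n)
  out[perm[seq_len(n_train)]] <- "train"
  out
}

#' Default covariate list for selector training
#'
#' The 28 demographic, comorbidity, medication, pathology and laboratory
#' variables offered to the classification tree.  Kidney-biopsy pathology
#' enters as the biopsy-confirmed diabetic-nephropathy indicator rather than
#' the raw multi-level pathology category: most pathology levels are sparse
#' (under 4% each) and many-level categorical variables enjoy a well-known
#' spurious split-gain advantage in greedy trees, so the dominant indicator
#' is the more stable representation.  Pass an explicit `covariates` vector
#' to [train_selector()] to offer `renal_pathology` instead.
#'
#' @return Character vector of 28 covariate names.
#' @export
selector_covariates <- function() {
  c("age", "sex", "bsa", "bmi", "unilateral_nephrectomy",
    "hypertension_grade", "diabetes", "cardiovascular_disease",
    "cerebral_infarction", "cerebral_hemorrhage", "cancer", "hyperuricemia",
    "gout", "edema", "calcium_dobesilate", "sglt2i", "rasi", "beraprost",
    "glucocorticoid", "immunosuppressor", "diuretic", "smoking", "drinking",
    "diabetic_nephropathy", "scr", "cysc", "urine_volume_24h",
    "urine_protein_24h")
}

#' Train the equation selector
#'
#' Fits a classification tree ([fit_tree()]) on the training rows of a
#' labelled cohort, using `best_equation` as the class and the configured
#' covariates as predictors.
#'
#' @param cohort A labelled cohort (see [label_cohort()]) with a `split`
#'   column of `"train"`/`"test"` values (see [split_cohort()]); if absent,
#'   all rows are used for training.
#' @param params A [tree_params()] object.
#' @param covariates Covariate names to offer the tree; defaults to the
#'   intersection of [selector_covariates()] with the cohort's columns.
#' @return A list of class `egfr_selector` with elements `tree` (the fitted
#'   `egfr_tree`), `importance` (from [variable_importance()]), `covariates`
#'   and `params`.
#' @export
train_selector <- function(cohort, params = tree_params(), covariates = NULL) {
  if (is.null(cohort$best_equation)) {
    stop("cohort is not labelled; run label_cohort() first", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- intersect(selector_covariates(), names(cohort))
  }
  absent <- setdiff(covariates, names(cohort))
  if (length(absent)) {
    stop("covariates not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  train <- if (is.null(cohort$split)) cohort else cohort[cohort$split == "train", ]
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  tree <- fit_tree(train[, covariates, drop = FALSE], train$best_equation,
                   params)
  structure(list(tree = tree, importance = variable_importance(tree),
                 covariates = covariates, params = params),
            class = "egfr_selector")
}

#' @export
print.egfr_selector <- function(x, ...) {
  cat("eGFR equation selector over", length(x$covariates), "covariates\n")
  print(x$tree)
  invisible(x)
}

#' Dispatch eGFR estimation through the selector
#'
#' Predicts the optimal equation for each row with the fitted tree, then
#' evaluates that equation on the row's biomarkers.
#'
#' @param selector An `egfr_selector` (or bare `egfr_tree`).
#' @param cohort Cohort data frame with routing covariates and biomarkers.
#' @return Data frame with columns `equation` (chosen per row) and `egfr`
#'   (mL/min per 1.73 m^2).
#' @export
dispatch_estimate <- function(selector, cohort) {
  tree <- if (inherits(selector, "egfr_selector")) selector$tree else selector
  cohort <- add_derived(cohort)
  eq <- predict_tree(tree, cohort)
  egfr <- rep(NA_real_, nrow(cohort))
  for (e in unique(eq)) {
    idx <- eq == e
    egfr[idx] <- estimate_egfr(cohort[idx, , drop = FALSE], e)
  }
  data.frame(equation = eq, egfr = egfr)
}

# --- cohort I/O -------------------------------------------------------------

#' Read / write a cohort table
#'
#' The delimited-text cohort contract: one row per patient; column names as
#' in the package's record fields; `sex` coded `male`/`female`; boolean
#' covariates coded `0`/`1`; missing values empty.  Creatinine is in the unit
#' given by `scr_unit` (default `umol/L`).
#'
#' @param path CSV file path.
#' @return `read_cohort` returns a data frame; `write_cohort` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("age", "sex", "height", "weight", "scr")
  absent <- setdiff(required, names(cohort))
  if (length(absent)) {
    stop("cohort is missing required columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(!cohort$sex %in% c("male", "female"))) {
    stop("sex must be coded 'male'/'female'", call. = FALSE)
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort Cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# --- orchestration ----------------------------------------------------------

.require_keys <- function(config, keys, where = "config") {
  for (k in keys) {
    if (is.null(config[[k]])) {
      stop("malformed ", where, ": missing key '", k, "'", call. = FALSE)
    }
  }
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a cohort, labels each patient with the
#' best-matched candidate equation, splits 70/30, trains the
#' classification-tree selector on the training rows, and writes the
#' labelled cohort, the serialised tree, the variable-importance table, the
#' per-method accuracy metrics and the Bland--Altman pair data.
#'
#' @param config A named list (or path to a JSON file) with keys:
#'   \describe{
#'     \item{input}{path to a cohort CSV -- or instead \code{synthetic}, a
#'       list of [synthetic_config()] arguments}
#'     \item{seed}{integer; drives the split (and simulation if synthetic)}
#'     \item{train_fraction}{optional, default 0.7}
#'     \item{tree}{optional list of [tree_params()] arguments}
#'     \item{covariates}{optional covariate subset for the tree}
#'     \item{outdir}{output directory, created if needed}
#'   }
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the labelled `cohort`, the `selector`, the
#'   `metrics` data frame and the output file `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("malformed config: not a list", call. = FALSE)
  .require_keys(config, c("seed", "outdir"))
  if (is.null(config$input) && is.null(config$synthetic)) {
    stop("malformed config: need key 'input' or 'synthetic'", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  seed <- as.integer(config$seed)
  train_fraction <- if (is.null(config$train_fraction)) 0.7 else config$train_fraction

  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input)
    say("loaded cohort: ", nrow(cohort), " rows from ", config$input)
  } else {
    sc <- do.call(synthetic_config, c(config$synthetic,
                                      list(seed = seed)[is.null(config$synthetic$seed)]))
    cohort <- generate_cohort(sc)
    say("simulated cohort: ", nrow(cohort), " rows (seed ", sc$seed, ")")
  }

  cohort <- label_cohort(cohort)
  say("labelled cohort: ", paste(names(table(cohort$best_equation)),
      table(cohort$best_equation), sep = "=", collapse = ", "))
  cohort$split <- split_cohort(nrow(cohort), train_fraction, seed)
  say("split: ", sum(cohort$split == "train"), " train / ",
      sum(cohort$split == "test"), " test")

  params <- do.call(tree_params, if (is.null(config$tree)) list() else config$tree)
  selector <- train_selector(cohort, params, config$covariates)
  say("fitted selector tree with ",
      length(tree_split_variables(selector$tree)), " split variables")

  metrics <- comparison_report(cohort, selector, split = "test")

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    cohort = file.path(outdir, "cohort_labeled.csv"),
    tree = file.path(outdir, "tree.json"),
    importance = file.path(outdir, "importance.csv"),
    metrics = file.path(outdir, "metrics.csv"),
    bland_altman = file.path(outdir, "bland_altman_pairs.csv"))
  write_cohort(cohort, paths$cohort)
  write_tree(selector$tree, paths$tree)
  utils::write.csv(selector$importance, paths$importance, row.names = FALSE)
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(attr(metrics, "pairs"), paths$bland_altman,
                   row.names = FALSE)
  say("wrote ", length(paths), " artifacts to ", outdir)

  invisible(list(cohort = cohort, selector = selector, metrics = metrics,
                 paths = paths))
}
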