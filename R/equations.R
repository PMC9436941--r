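# eGFR estimation equation library.
#
# All equations take creatinine in mg/dL internally except Xiangya, which was
# published with creatinine in umol/L.  Cockcroft-Gault is computed in mL/min
# and normalised to 1.73 m^2 via the patient's Du Bois body surface area; all
# other equations are already indexed to 1.73 m^2.

#' The thirteen supported eGFR estimation equations
#'
#' Returns the identifiers of the estimation equations implemented by
#' [estimate_egfr()], in a fixed canonical order.
#'
#' @return Character vector of equation identifiers.
#' @seealso [egfr_candidates()] for the four-equation subset the selector
#'   chooses among.
#' @export
#' @examples
#' egfr_equations()
egfr_equations <- function() {
  c("cockcroft_gault", "mdrd", "mdrd_abbrev", "mdrd_cn", "mdrd_cn_abbrev",
    "ckd_epi_cr", "ckd_epi_cysc", "ckd_epi_cr_cysc", "ckd_epi_cr_asian",
    "bis2", "macisaac", "ruijin", "xiangya")
}

#' The four candidate equations of the selector
#'
#' The classification tree chooses among BIS-2, CKD-EPI(CysC),
#' CKD-EPI(Cr-CysC) and Ruijin -- the equations most widely validated in
#' Chinese CKD cohorts.  The order returned here is also the fixed
#' tie-breaking priority used throughout the package (labelling ties, leaf
#' prediction ties).
#'
#' @return Character vector of length 4.
#' @export
egfr_candidates <- function() {
  c("bis2", "ckd_epi_cysc", "ckd_epi_cr_cysc", "ruijin")
}

#' Human-readable equation names
#'
#' @param id Character vector of equation identifiers.
#' @return Character vector of display names.
#' @export
egfr_equation_label <- function(id) {
  labels <- c(
    cockcroft_gault  = "Cockcroft-Gault",
    mdrd             = "MDRD",
    mdrd_abbrev      = "Abbreviated MDRD",
    mdrd_cn          = "Chinese modification MDRD",
    mdrd_cn_abbrev   = "Chinese modification abbreviated MDRD",
    ckd_epi_cr       = "CKD-EPI(Cr)",
    ckd_epi_cysc     = "CKD-EPI(CysC)",
    ckd_epi_cr_cysc  = "CKD-EPI(Cr-CysC)",
    ckd_epi_cr_asian = "Asian modified CKD-EPI(Cr)",
    bis2             = "BIS-2",
    macisaac         = "MacIsaac",
    ruijin           = "Ruijin",
    xiangya          = "Xiangya",
    tree_selector    = "Decision tree classifier")
  unname(labels[id])
}

# Conversion factor between creatinine units: 1 mg/dL = 88.4 umol/L.
CREATININE_MGDL_TO_UMOLL <- 88.4

.normalize_cr_unit <- function(unit) {
  u <- tolower(gsub("μ", "u", unit))  # accept the Greek mu
  u[u %in% c("umol/l", "umoll", "umol_l")] <- "umol/L"
  u[u %in% c("mg/dl", "mgdl", "mg_dl")] <- "mg/dL"
  bad <- !(u %in% c("umol/L", "mg/dL"))
  if (any(bad)) {
    stop("unknown creatinine unit: ", paste(unique(unit[bad]), collapse = ", "),
         " (expected 'mg/dL' or 'umol/L')", call. = FALSE)
  }
  u
}

#' Convert serum creatinine between mg/dL and umol/L
#'
#' Uses the exact factor 1 mg/dL = 88.4 umol/L.
#'
#' @param value Positive numeric vector of creatinine concentrations.
#' @param from,to Unit labels, each one of `"mg/dL"` or `"umol/L"`
#'   (the Greek-mu spelling is also accepted).
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' convert_creatinine(1, "mg/dL", "umol/L")   # 88.4
#' convert_creatinine(88.4, "umol/L", "mg/dL") # 1
convert_creatinine <- function(value, from, to) {
  if (any(!is.finite(value) | value <= 0)) {
    stop("creatinine values must be positive and finite", call. = FALSE)
  }
  from <- .normalize_cr_unit(from)
  to <- .normalize_cr_unit(to)
  out <- value
  up <- from == "mg/dL" & to == "umol/L"
  dn <- from == "umol/L" & to == "mg/dL"
  out[up] <- value[up] * CREATININE_MGDL_TO_UMOLL
  out[dn] <- value[dn] / CREATININE_MGDL_TO_UMOLL
  out
}

#' Du Bois body surface area
#'
#' \deqn{BSA = 0.007184 \times weight^{0.425} \times height^{0.725}}
#'
#' @param weight Body weight in kg.
#' @param height Body height in cm.
#' @return Body surface area in m^2.
#' @export
#' @examples
#' du_bois_bsa(70, 170)
du_bois_bsa <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0) ||
      any(!is.finite(height) | height <= 0)) {
    stop("weight and height must be positive and finite", call. = FALSE)
  }
  0.007184 * weight^0.425 * height^0.725
}

#' Normalise an absolute GFR to 1.73 m^2 body surface area
#'
#' @param gfr_abs GFR in mL/min.
#' @param bsa Body surface area in m^2.
#' @return GFR in mL/min per 1.73 m^2.
#' @seealso [denormalize_gfr()] for the inverse.
#' @export
normalize_gfr <- function(gfr_abs, bsa) {
  if (any(!is.finite(bsa) | bsa <= 0)) stop("bsa must be positive", call. = FALSE)
  if (any(gfr_abs < 0, na.rm = TRUE)) stop("gfr_abs must be non-negative", call. = FALSE)
  gfr_abs * 1.73 / bsa
}

#' @rdname normalize_gfr
#' @param gfr_norm GFR in mL/min per 1.73 m^2.
#' @export
denormalize_gfr <- function(gfr_norm, bsa) {
  if (any(!is.finite(bsa) | bsa <= 0)) stop("bsa must be positive", call. = FALSE)
  gfr_norm * bsa / 1.73
}

# Columns each equation needs beyond age/sex.  `scr` is serum creatinine,
# `cysc` cystatin C (mg/L), `bun` urea nitrogen, `alb` serum albumin.
.equation_inputs <- list(
  cockcroft_gault  = c("scr", "height", "weight"),
  mdrd             = c("scr", "bun", "alb"),
  mdrd_abbrev      = "scr",
  mdrd_cn          = c("scr", "bun", "alb"),
  mdrd_cn_abbrev   = "scr",
  ckd_epi_cr       = "scr",
  ckd_epi_cysc     = "cysc",
  ckd_epi_cr_cysc  = c("scr", "cysc"),
  ckd_epi_cr_asian = "scr",
  bis2             = c("scr", "cysc"),
  macisaac         = "cysc",
  ruijin           = "scr",
  xiangya          = "scr")

#' Required input columns of an eGFR equation
#'
#' @param equation An equation identifier (see [egfr_equations()]).
#' @return Character vector of required cohort columns (in addition to
#'   `age` and `sex`).
#' @export
equation_inputs <- function(equation) {
  equation <- match.arg(equation, egfr_equations())
  .equation_inputs[[equation]]
}

# piecewise CKD-EPI core: coef * (marker/knot)^exp * base^age, exponent
# switching at the knot.  Vectorised; continuous at the knot by construction.
.ckd_epi_piece <- function(marker, knot, exp_low, exp_high) {
  ex <- ifelse(marker <= knot, exp_low, exp_high)
  (marker / knot)^ex
}

#' Estimate GFR under one equation
#'
#' Computes eGFR (mL/min per 1.73 m^2) for every row of a cohort table under
#' a single estimation equation.  Creatinine is converted internally to the
#' unit each published formula expects (mg/dL everywhere except Xiangya,
#' which uses umol/L; the conversion factor is exactly 88.4).
#'
#' Cockcroft-Gault is evaluated in absolute mL/min and then normalised to
#' 1.73 m^2 with the row's Du Bois body surface area.  The formula is
#' classically written with weight in the numerator; `cg_numerator =
#' "height_as_printed"` evaluates the height-in-numerator variant instead.
#'
#' MDRD and its Chinese modification use urea nitrogen and albumin.  With
#' `si_units = TRUE` (default) the cohort's SI values (`bun` in mmol/L,
#' `alb` in g/L) are converted to the conventional units of the published
#' coefficients (mg/dL and g/dL); with `FALSE` values pass through as-is.
#'
#' @param cohort Data frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `scr` plus optional `scr_unit` (default
#'   `"umol/L"`), and whichever of `cysc`, `bun`, `alb`, `height`, `weight`
#'   the equation requires (see [equation_inputs()]).
#' @param equation Equation identifier, one of [egfr_equations()].
#' @param cg_numerator `"weight"` (classical Cockcroft-Gault) or
#'   `"height_as_printed"`.
#' @param si_units Logical; convert `bun` (mmol/L) and `alb` (g/L) to
#'   conventional units for the MDRD family.
#' @return Numeric vector of eGFR values, mL/min per 1.73 m^2.
#' @export
#' @examples
#' d <- data.frame(age = 60, sex = "male", scr = 2, scr_unit = "mg/dL", cysc = 2)
#' estimate_egfr(d, "ruijin")
#' estimate_egfr(d, "bis2")
estimate_egfr <- function(cohort, equation,
                          cg_numerator = c("weight", "height_as_printed"),
                          si_units = TRUE) {
  equation <- match.arg(equation, egfr_equations())
  cg_numerator <- match.arg(cg_numerator)
  need <- c("age", "sex", .equation_inputs[[equation]])
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("missing required input for ", equation, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  age <- cohort$age
  sex <- as.character(cohort$sex)
  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be coded 'male'/'female'", call. = FALSE)
  }
  if (any(!is.finite(age) | age < 18)) {
    stop("age must be finite and >= 18 (adult equations only)", call. = FALSE)
  }
  female <- sex == "female"

  .pos <- function(x, what) {
    if (any(!is.na(x) & x <= 0)) stop("non-positive ", what, call. = FALSE)
    x
  }

  if ("scr" %in% need) {
    unit <- if ("scr_unit" %in% names(cohort)) cohort$scr_unit else "umol/L"
    scr <- .pos(cohort$scr, "creatinine")
    cr <- convert_creatinine(scr, unit, "mg/dL")       # mg/dL
    cr_umol <- convert_creatinine(scr, unit, "umol/L") # umol/L (Xiangya)
  }
  if ("cysc" %in% need) cysc <- .pos(cohort$cysc, "cystatin C")
  if ("bun" %in% need) {
    bun <- .pos(cohort$bun, "urea nitrogen")
    if (si_units) bun <- bun * 2.801  # mmol/L -> mg/dL
  }
  if ("alb" %in% need) {
    alb <- .pos(cohort$alb, "albumin")
    if (si_units) alb <- alb / 10     # g/L -> g/dL
  }

  switch(equation,
    cockcroft_gault = {
      num <- if (cg_numerator == "weight") .pos(cohort$weight, "weight")
             else .pos(cohort$height, "height")
      abs_ml_min <- (140 - age) * num / (cr * 72) * ifelse(female, 0.85, 1)
      bsa <- du_bois_bsa(cohort$weight, cohort$height)
      normalize_gfr(abs_ml_min, bsa)
    },
    mdrd = 170 * cr^-0.999 * age^-0.176 * bun^-0.170 * alb^0.318 *
      ifelse(female, 0.762, 1),
    mdrd_abbrev = 175 * cr^-1.154 * age^-0.203 * ifelse(female, 0.742, 1),
    mdrd_cn = 170 * cr^-0.999 * age^-0.176 * bun^-0.170 * alb^0.318 * 1.202 *
      ifelse(female, 0.762, 1),
    mdrd_cn_abbrev = 170 * cr^-0.999 * age^-0.176 * 1.202 *
      ifelse(female, 0.762, 1),
    ckd_epi_cr = ifelse(female,
      144 * .ckd_epi_piece(cr, 0.7, -0.329, -1.209) * 0.993^age,
      141 * .ckd_epi_piece(cr, 0.9, -0.411, -1.209) * 0.993^age),
    ckd_epi_cysc = 133 * .ckd_epi_piece(cysc, 0.8, -0.499, -1.328) *
      0.996^age * ifelse(female, 0.932, 1),
    ckd_epi_cr_cysc = ifelse(female,
      130 * .ckd_epi_piece(cr, 0.7, -0.248, -0.601),
      135 * .ckd_epi_piece(cr, 0.9, -0.207, -0.601)) *
      .ckd_epi_piece(cysc, 0.8, -0.375, -0.711) * 0.995^age,
    ckd_epi_cr_asian = ifelse(female,
      151 * .ckd_epi_piece(cr, 0.7, -0.328, -1.210) * 0.993^age,
      149 * .ckd_epi_piece(cr, 0.9, -0.415, -1.210) * 0.993^age),
    bis2 = 767 * cysc^-0.610 * cr^-0.400 * age^-0.570 *
      ifelse(female, 0.870, 1),
    macisaac = 86.700 / cysc - 4.200,
    ruijin = 234.960 * cr^-0.926 * age^-0.280 * ifelse(female, 0.828, 1),
    xiangya = 2374.780 * cr_umol^-0.54753 * age^-0.25011 *
      ifelse(female, 0.8526126, 1))
}

#' Estimate GFR under every computable equation
#'
#' Applies each of the thirteen equations to a cohort.  Equations whose
#' required inputs are absent from the table are reported as missing (all-NA
#' column) with a reason, not as errors.
#'
#' @inheritParams estimate_egfr
#' @param ... Passed on to [estimate_egfr()].
#' @return A numeric matrix (rows = cohort rows, columns = equations) with
#'   attribute `"reasons"`: a named character vector for equations that could
#'   not be computed.
#' @export
estimate_all <- function(cohort, ...) {
  eqs <- egfr_equations()
  out <- matrix(NA_real_, nrow = nrow(cohort), ncol = length(eqs),
                dimnames = list(NULL, eqs))
  reasons <- character(0)
  for (eq in eqs) {
    absent <- setdiff(.equation_inputs[[eq]], names(cohort))
    if (length(absent)) {
      reasons[eq] <- paste(paste(absent, collapse = ", "), "missing")
      next
    }
    out[, eq] <- estimate_egfr(cohort, eq, ...)
  }
  attr(out, "reasons") <- reasons
  out
}
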