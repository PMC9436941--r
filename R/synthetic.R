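# Synthetic CKD cohort generator.
#
# Emulates the marginal covariate structure of a hospital CKD cohort (age,
# sex, anthropometry, comorbidity prevalences, 24-h urine protein, measured
# GFR) and plants a known covariate -> optimal-equation mechanism so that
# the labelling, tree-fitting and dispatch stages can be tested end to end
# without patient data.  Biomarkers are produced by inverting the monotone
# estimation equations: the planted equation's estimate lands close to the
# measured GFR (small multiplicative noise) while non-planted equations are
# pushed off by a signed log-offset, so the best-matched equation is
# identifiable by construction.

#' Default planted selection rules
#'
#' An ordered, exhaustive first-match rule list mapping covariates to the
#' optimal candidate equation: diabetic nephropathy -> BIS-2; RAS-inhibitor
#' use in patients over `age_cut` -> Ruijin; low body surface area or BMI ->
#' CKD-EPI(Cr-CysC); everyone else -> CKD-EPI(CysC).
#'
#' @param bsa_cut BSA threshold (m^2) below which CKD-EPI(Cr-CysC) is planted.
#' @param bmi_cut BMI threshold (kg/m^2), same role.
#' @param age_cut Age threshold (years) for the RASi rule.
#' @return List of rules, each `list(when = function(df) logical, equation)`.
#' @export
default_plant_rules <- function(bsa_cut = 1.65, bmi_cut = 22, age_cut = 65) {
  list(
    list(when = function(df) df$diabetic_nephropathy == 1,
         equation = "bis2"),
    list(when = function(df) df$rasi == 1 & df$age > age_cut,
         equation = "ruijin"),
    list(when = function(df) df$bsa < bsa_cut | df$bmi < bmi_cut,
         equation = "ckd_epi_cr_cysc"),
    list(when = function(df) rep(TRUE, nrow(df)),
         equation = "ckd_epi_cysc"))
}

#' Synthetic cohort configuration
#'
#' Bundles every distributional parameter of the generator.  The defaults
#' emulate a severe Chinese CKD cohort: mean age 60.6 y, 63.3% male, median
#' measured GFR 27.7 mL/min/1.73 m^2 (IQR 15.2--36.8), diabetic nephropathy
#' prevalence 14.3%, RASi use 31.3%, 24-h urine protein IQR 224--2782 mg.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution (years).
#' @param male_fraction Bernoulli probability of male sex.
#' @param bsa_mean,bsa_sd,bsa_range Truncated-normal body surface area (m^2);
#'   height and weight are back-solved from BSA and BMI via Du Bois.
#' @param bmi_mean,bmi_sd,bmi_range Truncated-normal BMI (kg/m^2).
#' @param prevalence Named vector of Bernoulli prevalences for the boolean
#'   clinical covariates.
#' @param hypertension_probs Probabilities of hypertension grades 0--3.
#' @param urine_protein_iqr P25/P75 (mg) of the log-normal 24-h urine protein.
#' @param urine_volume_iqr P25/P75 (L) of the log-normal 24-h urine volume.
#' @param sgfr_median,sgfr_iqr,sgfr_range Log-normal measured GFR on the
#'   normalised scale (mL/min per 1.73 m^2), truncated to `sgfr_range`.
#' @param bun_iqr P25/P75 (mmol/L) of log-normal urea nitrogen.
#' @param alb_mean,alb_sd Normal serum albumin (g/L), truncated positive.
#' @param noise_planted SD of the zero-mean log-scale noise applied to the
#'   planted equation's target (small: the planted equation nearly matches
#'   the measured GFR).
#' @param noise_other_bias,noise_other_sd Non-planted biomarker targets are
#'   offset by `sign * |N(bias, sd)|` on the log scale with a random sign,
#'   i.e. typically ~30% off in either direction.  Setting `bias = 0` and
#'   `sd = noise_planted` removes the planted signal (degenerate control).
#' @param rules Planted rule list, see [default_plant_rules()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 518L, seed = 1L,
                             age_mean = 60.6, age_sd = 12,
                             age_range = c(18, 95),
                             male_fraction = 0.633,
                             bsa_mean = 1.7, bsa_sd = 0.15,
                             bsa_range = c(1.2, 2.4),
                             bmi_mean = 25, bmi_sd = 3.5,
                             bmi_range = c(15, 40),
                             prevalence = c(
                               diabetic_nephropathy = 0.143, rasi = 0.313,
                               diabetes = 0.317, smoking = 0.193,
                               drinking = 0.139, unilateral_nephrectomy = 0.027,
                               edema = 0.382, gout = 0.127,
                               hyperuricemia = 0.183,
                               cardiovascular_disease = 0.137,
                               cerebral_infarction = 0.071,
                               cerebral_hemorrhage = 0.010, cancer = 0.050,
                               calcium_dobesilate = 0.081, sglt2i = 0.017,
                               beraprost = 0.030, glucocorticoid = 0.085,
                               immunosuppressor = 0.118, diuretic = 0.390),
                             hypertension_probs = c(0.139, 0.191, 0.203, 0.467),
                             urine_protein_iqr = c(224, 2782),
                             urine_volume_iqr = c(1.2, 2.1),
                             sgfr_median = 27.7, sgfr_iqr = c(15.2, 36.8),
                             sgfr_range = c(2, 120),
                             bun_iqr = c(9.1, 21.9),
                             alb_mean = 35.1, alb_sd = 5,
                             noise_planted = 0.05,
                             noise_other_bias = 0.30, noise_other_sd = 0.10,
                             rules = default_plant_rules()) {
  stopifnot(n >= 1, all(prevalence >= 0 & prevalence <= 1),
            noise_planted > 0, noise_other_sd > 0, noise_other_bias >= 0,
            abs(sum(hypertension_probs) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

# log-normal parameters from a median/IQR statement
.lnorm_from_quartiles <- function(p25, p75) {
  list(meanlog = log(sqrt(p25 * p75)),
       sdlog = log(p75 / p25) / (2 * stats::qnorm(0.75)))
}

# inverse-CDF truncated sampling keeps draw counts fixed => per-seed
# determinism regardless of truncation bounds
.rtnorm <- function(n, mean, sd, lo, hi) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

.rtlnorm <- function(n, meanlog, sdlog, lo, hi) {
  stats::qlnorm(stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                             stats::plnorm(hi, meanlog, sdlog)),
                meanlog, sdlog)
}

.sample_covariates_impl <- function(n, config) {
  cfg <- config
  age <- .rtnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$male_fraction, "male", "female")
  bsa <- .rtnorm(n, cfg$bsa_mean, cfg$bsa_sd, cfg$bsa_range[1], cfg$bsa_range[2])
  bmi <- .rtnorm(n, cfg$bmi_mean, cfg$bmi_sd, cfg$bmi_range[1], cfg$bmi_range[2])
  # back-solve height/weight so Du Bois BSA and BMI are met exactly:
  # BSA = 0.007184 * (bmi*1e-4)^0.425 * height^1.575
  height <- (bsa / (0.007184 * (bmi * 1e-4)^0.425))^(1 / 1.575)
  weight <- bmi * (height / 100)^2

  out <- data.frame(patient_id = sprintf("S%05d", seq_len(n)),
                    age = age, sex = sex, height = height, weight = weight,
                    bsa = bsa, bmi = bmi)
  for (v in names(cfg$prevalence)) {
    out[[v]] <- as.integer(stats::runif(n) < cfg$prevalence[[v]])
  }
  out$hypertension_grade <- sample(0:3, n, replace = TRUE,
                                   prob = cfg$hypertension_probs)
  up <- .lnorm_from_quartiles(cfg$urine_protein_iqr[1], cfg$urine_protein_iqr[2])
  out$urine_protein_24h <- stats::rlnorm(n, up$meanlog, up$sdlog)
  uv <- .lnorm_from_quartiles(cfg$urine_volume_iqr[1], cfg$urine_volume_iqr[2])
  out$urine_volume_24h <- stats::rlnorm(n, uv$meanlog, uv$sdlog)
  # pathology category: DN flag wins; others drawn among non-DN patients
  other_path <- sample(c("none", "igan", "other_glomerular"), n,
                       replace = TRUE, prob = c(0.76, 0.08, 0.16))
  out$renal_pathology <- ifelse(out$diabetic_nephropathy == 1,
                                "diabetic_nephropathy", other_path)
  out
}

#' Sample the covariate table of a synthetic cohort
#'
#' Demographics, anthropometry and clinical covariates only (no biomarkers,
#' no measured GFR); see [generate_cohort()] for the full record.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param config A [synthetic_config()]; its `n`/`seed` are overridden by the
#'   explicit arguments.
#' @return Data frame of covariates; deterministic per seed.
#' @export
sample_covariates <- function(n, seed, config = synthetic_config()) {
  with_seed(seed, .sample_covariates_impl(n, config))
}

#' Apply planted selection rules to covariates
#'
#' First-match-wins evaluation of an ordered rule list; errors if any row is
#' matched by no rule (the rule set must be exhaustive).
#'
#' @param covariates Covariate data frame (must carry every variable the rule
#'   predicates read).
#' @param rules Rule list as produced by [default_plant_rules()].
#' @return Character vector of planted equation ids.
#' @export
plant_equation_label <- function(covariates, rules = default_plant_rules()) {
  n <- nrow(covariates)
  label <- rep(NA_character_, n)
  for (rule in rules) {
    hit <- rule$when(covariates) & is.na(label)
    label[hit] <- rule$equation
  }
  if (anyNA(label)) {
    stop("planted rule set is not exhaustive: ", sum(is.na(label)),
         " unmatched rows", call. = FALSE)
  }
  label
}

# --- equation inversion -----------------------------------------------------

# piecewise inverse of coef*(x/knot)^exp * rest: value at the knot decides
# the branch; exact at the knot by construction
.invert_piece <- function(target, knot_value, knot, exp_low, exp_high) {
  ifelse(target >= knot_value,
         knot * (target / knot_value)^(1 / exp_low),
         knot * (target / knot_value)^(1 / exp_high))
}

#' Solve an estimation equation for a biomarker
#'
#' Returns the serum creatinine (mg/dL) or cystatin C (mg/L) value at which
#' the given equation reproduces `target` (mL/min per 1.73 m^2).  For
#' two-biomarker equations (BIS-2, CKD-EPI(Cr-CysC), MDRD family) the other
#' inputs must be supplied and the remaining one is solved for.  Piecewise
#' CKD-EPI equations are inverted per branch, with the branch chosen by
#' comparing the target against the equation's value at the knot.
#'
#' @param equation Equation id; every equation except Cockcroft-Gault is
#'   supported.  Creatinine is returned in mg/dL except for Xiangya
#'   (umol/L, the unit of its published formula).
#' @param target Positive target eGFR, mL/min per 1.73 m^2 (MacIsaac only
#'   requires `target > -4.2`).
#' @param age,sex Demographics (vectors recycled against `target`).
#' @param cr Fixed creatinine in mg/dL, when cystatin C is being solved.
#' @param cysc Fixed cystatin C in mg/L, when creatinine is being solved.
#' @param bun,alb Fixed urea nitrogen (mmol/L) and albumin (g/L) for the
#'   full MDRD equations.
#' @return Numeric vector of biomarker values.
#' @export
#' @examples
#' invert_equation("macisaac", 39.15)            # cystatin C 2.0
#' invert_equation("ruijin", 39.3, age = 60, sex = "male")
invert_equation <- function(equation, target, age = NULL, sex = NULL,
                            cr = NULL, cysc = NULL, bun = NULL, alb = NULL) {
  equation <- match.arg(equation, setdiff(egfr_equations(), "cockcroft_gault"))
  if (equation != "macisaac" && any(target <= 0)) {
    stop("target eGFR must be positive", call. = FALSE)
  }
  female <- if (!is.null(sex)) as.character(sex) == "female" else NULL

  switch(equation,
    macisaac = {
      if (any(target <= -4.2)) {
        stop("MacIsaac target must exceed -4.2", call. = FALSE)
      }
      86.700 / (target + 4.200)
    },
    ruijin = {
      s <- ifelse(female, 0.828, 1)
      (234.960 * age^-0.280 * s / target)^(1 / 0.926)
    },
    xiangya = {
      s <- ifelse(female, 0.8526126, 1)
      (2374.780 * age^-0.25011 * s / target)^(1 / 0.54753)
    },
    mdrd_abbrev = {
      s <- ifelse(female, 0.742, 1)
      (175 * age^-0.203 * s / target)^(1 / 1.154)
    },
    mdrd_cn_abbrev = {
      s <- ifelse(female, 0.762, 1)
      (170 * age^-0.176 * 1.202 * s / target)^(1 / 0.999)
    },
    mdrd = ,
    mdrd_cn = {
      if (is.null(bun) || is.null(alb)) {
        stop(equation, " inversion needs bun and alb", call. = FALSE)
      }
      s <- ifelse(female, 0.762, 1) * if (equation == "mdrd_cn") 1.202 else 1
      base <- 170 * age^-0.176 * (bun * 2.801)^-0.170 * (alb / 10)^0.318 * s
      (base / target)^(1 / 0.999)
    },
    ckd_epi_cysc = {
      knot_value <- 133 * 0.996^age * ifelse(female, 0.932, 1)
      .invert_piece(target, knot_value, 0.8, -0.499, -1.328)
    },
    ckd_epi_cr = {
      coef <- ifelse(female, 144, 141)
      knot <- ifelse(female, 0.7, 0.9)
      exp_low <- ifelse(female, -0.329, -0.411)
      knot_value <- coef * 0.993^age
      ifelse(target >= knot_value,
             knot * (target / knot_value)^(1 / exp_low),
             knot * (target / knot_value)^(1 / -1.209))
    },
    ckd_epi_cr_asian = {
      coef <- ifelse(female, 151, 149)
      knot <- ifelse(female, 0.7, 0.9)
      exp_low <- ifelse(female, -0.328, -0.415)
      knot_value <- coef * 0.993^age
      ifelse(target >= knot_value,
             knot * (target / knot_value)^(1 / exp_low),
             knot * (target / knot_value)^(1 / -1.210))
    },
    bis2 = {
      s <- ifelse(female, 0.870, 1)
      base <- 767 * age^-0.570 * s
      if (!is.null(cr)) (base * cr^-0.400 / target)^(1 / 0.610)
      else if (!is.null(cysc)) (base * cysc^-0.610 / target)^(1 / 0.400)
      else stop("bis2 inversion needs cr or cysc fixed", call. = FALSE)
    },
    ckd_epi_cr_cysc = {
      coef <- ifelse(female, 130, 135)
      cr_knot <- ifelse(female, 0.7, 0.9)
      cr_exp_low <- ifelse(female, -0.248, -0.207)
      if (!is.null(cr)) {
        cr_exp <- ifelse(cr <= cr_knot, cr_exp_low, -0.601)
        knot_value <- coef * (cr / cr_knot)^cr_exp * 0.995^age
        .invert_piece(target, knot_value, 0.8, -0.375, -0.711)
      } else if (!is.null(cysc)) {
        cys_exp <- ifelse(cysc <= 0.8, -0.375, -0.711)
        knot_value <- coef * (cysc / 0.8)^cys_exp * 0.995^age
        ifelse(target >= knot_value,
               cr_knot * (target / knot_value)^(1 / cr_exp_low),
               cr_knot * (target / knot_value)^(1 / -0.601))
      } else stop("ckd_epi_cr_cysc inversion needs cr or cysc fixed",
                  call. = FALSE)
    })
}

#' Generate a full synthetic cohort
#'
#' Draws covariates ([sample_covariates()]), a normalised measured GFR per
#' row, and a planted optimal equation ([plant_equation_label()]); then
#' back-solves serum creatinine (via the Ruijin equation, or the planted
#' creatinine-bearing equation) and cystatin C (via CKD-EPI(CysC) or the
#' planted cystatin-bearing equation) so that the planted equation's
#' estimate deviates from the measured GFR only by the small planted noise,
#' while the other candidates are pushed off by the larger signed offset.
#' Urea nitrogen and albumin are drawn from plausible marginals (no planted
#' signal) so the MDRD family is computable.  The absolute measured GFR is
#' derived as `sgfr_norm * BSA / 1.73`.
#'
#' @param config A [synthetic_config()].
#' @return Cohort data frame following the package's record contract plus a
#'   `hidden_label` column carrying the planted truth.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n
    cov <- .sample_covariates_impl(n, config)

    sg <- .lnorm_from_quartiles(config$sgfr_iqr[1], config$sgfr_iqr[2])
    sgfr_norm <- .rtlnorm(n, log(config$sgfr_median), sg$sdlog,
                          config$sgfr_range[1], config$sgfr_range[2])
    label <- plant_equation_label(cov, config$rules)

    eps_planted <- stats::rnorm(n, 0, config$noise_planted)
    off_mag <- abs(stats::rnorm(n, config$noise_other_bias,
                                config$noise_other_sd))
    t_planted <- sgfr_norm * exp(eps_planted)

    age <- cov$age; sex <- cov$sex
    candidates <- egfr_candidates()

    # Two biomarkers can pin only two of the four candidate equations: the
    # planted one at its target and one other at a signed log-offset; the
    # remaining two are derived.  The offset sign is chosen per row to
    # maximise the smallest deviation of the non-planted candidates from the
    # measured GFR, so systematic inter-equation offsets cannot cancel the
    # planted separation (see the methods vignette).
    solve_markers <- function(lab, i, offset) {
      t_other <- sgfr_norm[i] * exp(offset)
      if (lab == "ruijin") {
        cr <- invert_equation("ruijin", t_planted[i], age[i], sex[i])
        cysc <- invert_equation("ckd_epi_cysc", t_other, age[i], sex[i])
      } else if (lab == "ckd_epi_cysc") {
        cysc <- invert_equation("ckd_epi_cysc", t_planted[i], age[i], sex[i])
        cr <- invert_equation("ruijin", t_other, age[i], sex[i])
      } else {
        # two-biomarker planted equation: creatinine carries the offset via
        # Ruijin, cystatin C is solved so the planted equation hits target
        cr <- invert_equation("ruijin", t_other, age[i], sex[i])
        cysc <- invert_equation(lab, t_planted[i], age[i], sex[i], cr = cr)
      }
      list(cr = cr, cysc = cysc)
    }

    min_other_dev <- function(lab, i, mk) {
      d <- data.frame(age = age[i], sex = sex[i], scr = mk$cr,
                      scr_unit = "mg/dL", cysc = mk$cysc)
      devs <- vapply(setdiff(candidates, lab), function(eq) {
        abs(estimate_egfr(d, eq) - sgfr_norm[i])
      }, numeric(length(i)))
      if (is.null(dim(devs))) devs <- matrix(devs, nrow = 1)
      apply(devs, 1, min)
    }

    cr <- numeric(n); cysc <- numeric(n)
    rnd_sign <- sample(c(-1, 1), n, replace = TRUE)
    for (lab in unique(label)) {
      i <- which(label == lab)
      up <- solve_markers(lab, i, off_mag[i])
      dn <- solve_markers(lab, i, -off_mag[i])
      take_up <- if (config$noise_other_bias > 0) {
        min_other_dev(lab, i, up) >= min_other_dev(lab, i, dn)
      } else {
        rnd_sign[i] > 0  # no planted separation requested: symmetric noise
      }
      cr[i] <- ifelse(take_up, up$cr, dn$cr)
      cysc[i] <- ifelse(take_up, up$cysc, dn$cysc)
    }

    bn <- .lnorm_from_quartiles(config$bun_iqr[1], config$bun_iqr[2])
    cov$scr <- convert_creatinine(cr, "mg/dL", "umol/L")
    cov$scr_unit <- "umol/L"
    cov$cysc <- cysc
    cov$bun <- stats::rlnorm(n, bn$meanlog, bn$sdlog)
    cov$alb <- .rtnorm(n, config$alb_mean, config$alb_sd, 15, 60)
    cov$sgfr_abs <- denormalize_gfr(sgfr_norm, cov$bsa)
    cov$hidden_label <- label
    cov
  })
}
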