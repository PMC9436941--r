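# Equation library: worked values, unit handling, piecewise continuity,
# monotonicity, and equivalence with the direct-formula oracle.

test_that("creatinine conversion applies the exact 88.4 factor", {
  expect_equal(convert_creatinine(1.0, "mg/dL", "umol/L"), 88.4)
  expect_equal(convert_creatinine(88.4, "umol/L", "mg/dL"), 1.0)
  expect_equal(convert_creatinine(2.5, "mg/dL", "mg/dL"), 2.5)
  expect_equal(convert_creatinine(c(1, 2), "mg/dL", "umol/L"), c(88.4, 176.8))
  expect_error(convert_creatinine(-1, "mg/dL", "umol/L"), "positive")
  expect_error(convert_creatinine(1, "mg/dL", "mmol/L"), "unknown")
})

test_that("Du Bois BSA matches hand computation and is a power law", {
  expect_equal(du_bois_bsa(70, 170), 0.007184 * 70^0.425 * 170^0.725,
               tolerance = 1e-12)
  expect_equal(du_bois_bsa(70, 170), 1.8097, tolerance = 1e-4)
  # doubling weight scales BSA by 2^0.425
  expect_equal(du_bois_bsa(140, 170) / du_bois_bsa(70, 170), 2^0.425,
               tolerance = 1e-12)
  b <- du_bois_bsa(55.6, 158)
  expect_gt(b, 1.4); expect_lt(b, 1.8)
  expect_error(du_bois_bsa(0, 170), "positive")
})

test_that("GFR normalisation is exact arithmetic and round-trips", {
  expect_equal(normalize_gfr(50, 1.73), 50)
  expect_equal(normalize_gfr(50, 2.0), 43.25)
  for (bsa in c(1.3, 1.73, 2.2)) {
    expect_equal(denormalize_gfr(normalize_gfr(37.5, bsa), bsa), 37.5,
                 tolerance = 1e-14)
  }
  expect_error(normalize_gfr(50, 0), "positive")
})

test_that("worked single-equation values match hand computation", {
  rec <- data.frame(age = 60, sex = "male", scr = 2, scr_unit = "mg/dL",
                    cysc = 2)
  expect_equal(estimate_egfr(rec, "macisaac"), 86.700 / 2 - 4.200)  # 39.15
  expect_equal(estimate_egfr(rec, "ruijin"),
               234.960 * 2^-0.926 * 60^-0.280, tolerance = 1e-12)   # ~39.30
  bis <- data.frame(age = 70, sex = "male", scr = 2, scr_unit = "mg/dL",
                    cysc = 2)
  expect_equal(estimate_egfr(bis, "bis2"),
               767 * 2^-0.610 * 2^-0.400 * 70^-0.570, tolerance = 1e-12)
  knot <- data.frame(age = 50, sex = "male", scr = 0.9, scr_unit = "mg/dL")
  expect_equal(estimate_egfr(knot, "ckd_epi_cr"), 141 * 0.993^50,
               tolerance = 1e-12)                                   # ~99.24
})

test_that("every equation matches the direct-formula oracle on random inputs", {
  pats <- random_patients(1000, seed = 42)
  for (eq in egfr_equations()) {
    got <- estimate_egfr(pats, eq)
    want <- vapply(seq_len(nrow(pats)), function(i) {
      oracle_egfr(eq, pats$age[i], pats$sex[i] == "female",
                  cr = if (eq == "xiangya") pats$scr[i] * 88.4 else pats$scr[i],
                  cysc = pats$cysc[i], bun = pats$bun[i] * 2.801,
                  alb = pats$alb[i] / 10, weight = pats$weight[i],
                  height = pats$height[i])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-9, info = eq)
    expect_true(all(got > 0), info = eq)
  }
})

test_that("CKD-EPI branches are continuous at their knots", {
  eps <- 1e-9
  grid <- expand.grid(age = c(20, 55, 85), sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cr_knot <- if (g$sex == "female") 0.7 else 0.9
    for (eq in c("ckd_epi_cr", "ckd_epi_cr_asian")) {
      lo <- estimate_egfr(data.frame(g, scr = cr_knot - eps, scr_unit = "mg/dL"), eq)
      hi <- estimate_egfr(data.frame(g, scr = cr_knot + eps, scr_unit = "mg/dL"), eq)
      expect_equal(lo, hi, tolerance = 1e-6, info = eq)
    }
    lo <- estimate_egfr(data.frame(g, cysc = 0.8 - eps), "ckd_epi_cysc")
    hi <- estimate_egfr(data.frame(g, cysc = 0.8 + eps), "ckd_epi_cysc")
    expect_equal(lo, hi, tolerance = 1e-6)
    for (cys in c(0.6, 1.4)) {
      lo <- estimate_egfr(data.frame(g, scr = cr_knot - eps, scr_unit = "mg/dL",
                                     cysc = cys), "ckd_epi_cr_cysc")
      hi <- estimate_egfr(data.frame(g, scr = cr_knot + eps, scr_unit = "mg/dL",
                                     cysc = cys), "ckd_epi_cr_cysc")
      expect_equal(lo, hi, tolerance = 1e-6)
    }
  }
})

test_that("results are invariant to the creatinine input unit", {
  pats <- random_patients(200, seed = 7)
  pats_umol <- transform(pats, scr = scr * 88.4, scr_unit = "umol/L")
  for (eq in egfr_equations()) {
    expect_equal(estimate_egfr(pats, eq), estimate_egfr(pats_umol, eq),
                 tolerance = 1e-12, info = eq)
  }
})

test_that("equations are strictly decreasing in their biomarkers", {
  cr_grid <- seq(0.5, 8, length.out = 25)
  cys_grid <- seq(0.5, 6, length.out = 25)
  base <- data.frame(age = 60, sex = "female", height = 160, weight = 60,
                     bun = 15, alb = 35, scr_unit = "mg/dL")
  cr_eqs <- c("cockcroft_gault", "mdrd", "mdrd_abbrev", "mdrd_cn",
              "mdrd_cn_abbrev", "ckd_epi_cr", "ckd_epi_cr_cysc",
              "ckd_epi_cr_asian", "bis2", "ruijin", "xiangya")
  for (eq in cr_eqs) {
    d <- cbind(base[rep(1, 25), ], scr = cr_grid, cysc = 1.5)
    expect_true(all(diff(estimate_egfr(d, eq)) < 0), info = eq)
  }
  for (eq in c("ckd_epi_cysc", "ckd_epi_cr_cysc", "bis2", "macisaac")) {
    d <- cbind(base[rep(1, 25), ], scr = 2, cysc = cys_grid)
    expect_true(all(diff(estimate_egfr(d, eq)) < 0), info = eq)
  }
})

test_that("Cockcroft-Gault numerator switch reproduces the printed variant", {
  rec <- data.frame(age = 50, sex = "male", scr = 1, scr_unit = "mg/dL",
                    height = 170, weight = 80)
  w <- estimate_egfr(rec, "cockcroft_gault")
  h <- estimate_egfr(rec, "cockcroft_gault", cg_numerator = "height_as_printed")
  expect_equal(h / w, 170 / 80, tolerance = 1e-12)
})

test_that("estimate_all reports absent equations with reasons", {
  full <- data.frame(age = 60, sex = "male", scr = 2, scr_unit = "mg/dL",
                     cysc = 2, bun = 15, alb = 35, height = 170, weight = 70)
  m <- estimate_all(full)
  expect_equal(dim(m), c(1, 13))
  expect_true(all(m > 0))
  expect_length(attr(m, "reasons"), 0)

  no_bun <- full[, setdiff(names(full), "bun")]
  m2 <- estimate_all(no_bun)
  expect_true(all(is.na(m2[, c("mdrd", "mdrd_cn")])))
  expect_match(attr(m2, "reasons")[["mdrd"]], "bun missing")
  expect_true(all(!is.na(m2[, c("mdrd_abbrev", "ruijin", "bis2")])))
})

test_that("missing required inputs raise errors naming the field", {
  expect_error(estimate_egfr(data.frame(age = 60, sex = "male"), "ruijin"),
               "scr")
  expect_error(estimate_egfr(data.frame(age = 60, sex = "male", scr = 2),
                             "bis2"), "cysc")
  expect_error(estimate_egfr(data.frame(age = 60, sex = "male", scr = -1,
                                        scr_unit = "mg/dL"), "ruijin"),
               "positive")
})
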