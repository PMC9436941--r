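# Independent oracles, deliberately coded as plain scalar transcriptions of
# the published formulas and as naive enumerations -- separate code paths
# from the package implementation.

# Direct-formula eGFR oracle: one scalar at a time, creatinine in mg/dL
# (xiangya takes umol/L), bun in mg/dL, alb in g/dL.
oracle_egfr <- function(eq, age, female, cr = NA, cysc = NA,
                        bun = NA, alb = NA, weight = NA, height = NA) {
  if (eq == "cockcroft_gault") {
    v <- (140 - age) * weight / (cr * 72)
    if (female) v <- v * 0.85
    return(v * 1.73 / (0.007184 * weight^0.425 * height^0.725))
  }
  if (eq == "mdrd") {
    v <- 170 * cr^-0.999 * age^-0.176 * bun^-0.170 * alb^0.318
    return(if (female) v * 0.762 else v)
  }
  if (eq == "mdrd_abbrev") {
    v <- 175 * cr^-1.154 * age^-0.203
    return(if (female) v * 0.742 else v)
  }
  if (eq == "mdrd_cn") {
    v <- 170 * cr^-0.999 * age^-0.176 * bun^-0.170 * alb^0.318 * 1.202
    return(if (female) v * 0.762 else v)
  }
  if (eq == "mdrd_cn_abbrev") {
    v <- 170 * cr^-0.999 * age^-0.176 * 1.202
    return(if (female) v * 0.762 else v)
  }
  if (eq == "ckd_epi_cr") {
    if (female) {
      if (cr <= 0.7) return(144 * (cr / 0.7)^-0.329 * 0.993^age)
      return(144 * (cr / 0.7)^-1.209 * 0.993^age)
    }
    if (cr <= 0.9) return(141 * (cr / 0.9)^-0.411 * 0.993^age)
    return(141 * (cr / 0.9)^-1.209 * 0.993^age)
  }
  if (eq == "ckd_epi_cysc") {
    e <- if (cysc <= 0.8) -0.499 else -1.328
    v <- 133 * (cysc / 0.8)^e * 0.996^age
    return(if (female) v * 0.932 else v)
  }
  if (eq == "ckd_epi_cr_cysc") {
    knot <- if (female) 0.7 else 0.9
    coef <- if (female) 130 else 135
    ecr <- if (cr <= knot) (if (female) -0.248 else -0.207) else -0.601
    ecy <- if (cysc <= 0.8) -0.375 else -0.711
    return(coef * (cr / knot)^ecr * (cysc / 0.8)^ecy * 0.995^age)
  }
  if (eq == "ckd_epi_cr_asian") {
    if (female) {
      if (cr <= 0.7) return(151 * (cr / 0.7)^-0.328 * 0.993^age)
      return(151 * (cr / 0.7)^-1.210 * 0.993^age)
    }
    if (cr <= 0.9) return(149 * (cr / 0.9)^-0.415 * 0.993^age)
    return(149 * (cr / 0.9)^-1.210 * 0.993^age)
  }
  if (eq == "bis2") {
    v <- 767 * cysc^-0.610 * cr^-0.400 * age^-0.570
    return(if (female) v * 0.870 else v)
  }
  if (eq == "macisaac") return(86.700 / cysc - 4.200)
  if (eq == "ruijin") {
    v <- 234.960 * cr^-0.926 * age^-0.280
    return(if (female) v * 0.828 else v)
  }
  if (eq == "xiangya") {
    v <- 2374.780 * cr^-0.54753 * age^-0.25011  # cr in umol/L here
    return(if (female) v * 0.8526126 else v)
  }
  stop("unknown equation ", eq)
}

# Random valid biomarker/demographic draws for the oracle-equivalence check
random_patients <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = runif(n, 18, 92),
    sex = sample(c("male", "female"), n, replace = TRUE),
    height = runif(n, 145, 190),
    weight = runif(n, 40, 110),
    scr = exp(runif(n, log(0.4), log(12))),  # mg/dL
    scr_unit = "mg/dL",
    cysc = exp(runif(n, log(0.4), log(8))),
    bun = exp(runif(n, log(3), log(40))),    # mmol/L
    alb = runif(n, 20, 50))                  # g/L
}

# Exhaustive brute-force best-split oracle: enumerates every admissible
# numeric midpoint and categorical subset split and every gain by direct
# counting.  Mirrors the package tie-break (max gain; ties by variable name,
# then smallest threshold / lexicographically smallest left-level key).
oracle_best_split <- function(x, y, params) {
  n <- nrow(x)
  if (n < params$min_samples_split) return(NULL)
  counts_of <- function(yy) table(factor(yy, levels = sort(unique(y))))
  ent <- function(cnt) {
    p <- cnt / sum(cnt); p <- p[p > 0]
    -sum(p * log2(p))
  }
  parent <- counts_of(y)
  if (ent(parent) <= 0) return(NULL)
  gain_of <- function(go_left) {
    nl <- sum(go_left)
    if (nl < params$min_samples_leaf || n - nl < params$min_samples_leaf) {
      return(NULL)
    }
    ent(parent) - (nl * ent(counts_of(y[go_left])) +
                   (n - nl) * ent(counts_of(y[!go_left]))) / n
  }
  best <- NULL
  consider <- function(variable, kind, thr, lev, gain, key) {
    if (is.null(gain)) return()
    if (is.null(best) || gain > best$gain + 1e-12 ||
        (abs(gain - best$gain) <= 1e-12 &&
         (variable < best$variable ||
          (variable == best$variable && key < best$key)))) {
      best <<- list(variable = variable, kind = kind, threshold = thr,
                    left_levels = lev, gain = gain, key = key)
    }
  }
  for (var in sort(names(x))) {
    v <- x[[var]]
    if (is.numeric(v) || is.logical(v)) {
      vv <- sort(unique(as.numeric(v)))
      if (length(vv) >= 2) {
        for (k in seq_len(length(vv) - 1)) {
          thr <- (vv[k] + vv[k + 1]) / 2
          consider(var, "numeric_threshold", thr, NULL,
                   gain_of(as.numeric(v) <= thr), sprintf("%.17g", thr))
        }
      }
    } else {
      levs <- sort(unique(as.character(v)))
      L <- length(levs)
      if (L >= 2) {
        for (m in seq_len(2^(L - 1) - 1)) {
          s <- levs[which(bitwAnd(m, 2^(seq_len(L - 1) - 1)) > 0)]
          consider(var, "categorical_subset", NULL, s,
                   gain_of(as.character(v) %in% s),
                   paste(s, collapse = "\x1f"))
        }
      }
    }
  }
  if (is.null(best) || best$gain < params$min_gain) return(NULL)
  best
}

# Serialise a fitted tree to a canonical string (structure equality checks)
tree_signature <- function(tree) {
  walk <- function(node) {
    if (is.null(node$split)) {
      paste0("L(", paste(node$class_counts, collapse = ","), ")")
    } else {
      rule <- if (node$split$kind == "numeric_threshold") {
        paste0(node$split$variable, "<=", sprintf("%.17g", node$split$threshold))
      } else {
        paste0(node$split$variable, "in{",
               paste(node$split$left_levels, collapse = ","), "}")
      }
      paste0("N(", rule, ")[", walk(node$left), "|", walk(node$right), "]")
    }
  }
  walk(tree$root)
}
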