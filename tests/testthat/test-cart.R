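# Classification tree: impurity closed forms, split search vs brute force,
# fitting behaviour, prediction, importance, serialization.

test_that("entropy closed forms are exact", {
  expect_identical(entropy(c(A = 2, B = 2)), 1)
  expect_identical(entropy(c(A = 4, B = 0)), 0)
  expect_identical(entropy(c(A = 1, B = 1, C = 1, D = 1)), 2)
  expect_error(entropy(numeric(0)), "positive total")
})

test_that("information gain closed forms and validation", {
  expect_equal(information_gain(c(A = 2, B = 2), c(A = 2, B = 0), c(A = 0, B = 2)), 1)
  expect_equal(information_gain(c(A = 2, B = 2), c(A = 1, B = 1), c(A = 1, B = 1)), 0)
  # any split of a pure parent gains nothing
  expect_equal(information_gain(c(A = 6, B = 0), c(A = 2, B = 0), c(A = 4, B = 0)), 0)
  expect_error(information_gain(c(A = 3, B = 2), c(A = 1, B = 1), c(A = 1, B = 1)),
               "sum to parent")
  expect_error(information_gain(c(A = 2), c(A = 2), c(A = 0)), "nonempty")
})

test_that("gain is non-negative for every admissible split of random tables", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    y <- sample(LETTERS[1:3], n, replace = TRUE)
    left <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(left) || all(left)) next
    cnt <- function(idx) vapply(LETTERS[1:3], function(l) sum(y[idx] == l), numeric(1))
    g <- information_gain(cnt(TRUE), cnt(left), cnt(!left))
    expect_gte(g, -1e-12)
  }
})

test_that("best_split finds the perfect binary separator", {
  x <- data.frame(flag = c(0, 0, 0, 1, 1, 1))
  y <- c("a", "a", "a", "b", "b", "b")
  p <- tree_params(min_samples_split = 2, min_samples_leaf = 1)
  sp <- best_split(x, y, p)
  expect_equal(sp$variable, "flag")
  expect_equal(sp$threshold, 0.5)
  expect_equal(sp$gain, 1)
  # pure labels: nothing to gain
  expect_null(best_split(x, rep("a", 6), p))
})

test_that("best_split agrees with exhaustive brute-force enumeration", {
  set.seed(99)
  p <- tree_params(min_samples_split = 2, min_samples_leaf = 1, max_depth = 1)
  for (rep in 1:250) {
    n <- sample(4:8, 1)
    ncov <- sample(1:3, 1)
    x <- as.data.frame(lapply(seq_len(ncov), function(j) {
      if (runif(1) < 0.5) round(runif(n, 0, 4))           # numeric, tie-prone
      else sample(letters[1:4], n, replace = TRUE)        # categorical <= 4 levels
    }))
    names(x) <- paste0("v", seq_len(ncov))
    y <- sample(c("a", "b", "c")[seq_len(sample(2:3, 1))], n, replace = TRUE)
    got <- best_split(x, y, p)
    want <- oracle_best_split(x, y, p)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$variable, want$variable)
      expect_equal(got$kind, want$kind)
      if (want$kind == "numeric_threshold") {
        expect_equal(got$threshold, want$threshold)
      } else {
        expect_equal(sort(got$left_levels), sort(want$left_levels))
      }
      expect_equal(got$gain, want$gain, tolerance = 1e-9)
    }
  }
})

test_that("min_samples_leaf restricts admissible splits", {
  x <- data.frame(v = 1:10)
  y <- c("a", rep("b", 9))
  p <- tree_params(min_samples_split = 2, min_samples_leaf = 3)
  sp <- best_split(x, y, p)
  # the perfect split (1 | rest) is inadmissible; children must have >= 3 rows
  expect_true(is.null(sp) || (sp$threshold >= 3.5 && sp$threshold <= 7.5))
})

test_that("fit_tree memorises an XOR table at depth 2", {
  x <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  y <- c("p", "q", "q", "p")
  p <- tree_params(max_depth = 2, min_samples_split = 2, min_samples_leaf = 1)
  tree <- fit_tree(x, y, p)
  expect_equal(max_tree_depth <- (function(nd) {
    if (is.null(nd$split)) nd$depth else max(Recall(nd$left), Recall(nd$right))
  })(tree$root), 2)
  expect_identical(predict_tree(tree, x), y)
})

test_that("pure-label input yields a single leaf", {
  tree <- fit_tree(data.frame(v = rnorm(30)), rep("bis2", 30))
  expect_null(tree$root$split)
  expect_equal(tree$root$prediction, "bis2")
  expect_identical(predict_tree(tree, data.frame(v = 0)), "bis2")
  expect_equal(nrow(variable_importance(tree)), 0)
})

test_that("class counts are conserved at every internal node", {
  set.seed(5)
  x <- data.frame(u = rnorm(300), v = sample(letters[1:5], 300, TRUE),
                  w = rbinom(300, 1, 0.4))
  y <- ifelse(x$u + x$w > 0.5, "bis2", sample(c("ruijin", "ckd_epi_cysc"), 300, TRUE))
  tree <- fit_tree(x, y, tree_params(max_depth = 4, min_samples_split = 10,
                                     min_samples_leaf = 3))
  check <- function(node) {
    if (is.null(node$split)) return(invisible())
    expect_identical(node$class_counts,
                     node$left$class_counts + node$right$class_counts)
    expect_equal(node$n, node$left$n + node$right$n)
    check(node$left); check(node$right)
  }
  check(tree$root)
})

test_that("fitting is deterministic and overfits monotonically with depth", {
  set.seed(21)
  x <- data.frame(u = rnorm(200), v = rnorm(200),
                  c = sample(letters[1:4], 200, TRUE))
  y <- sample(egfr_candidates(), 200, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  p <- tree_params(max_depth = 4, min_samples_split = 10, min_samples_leaf = 3)
  expect_identical(tree_signature(fit_tree(x, y, p)),
                   tree_signature(fit_tree(x, y, p)))
  err <- vapply(1:6, function(d) {
    pp <- tree_params(max_depth = d, min_samples_split = 10, min_samples_leaf = 3)
    mean(predict_tree(fit_tree(x, y, pp), x) != y)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12))
})

test_that("prediction ties and missing covariates behave as documented", {
  # forced 2-2 leaf: tie broken by candidate priority order
  x <- data.frame(v = c(1, 2, 3, 4))
  y <- c("ruijin", "bis2", "ruijin", "bis2")
  tree <- fit_tree(x, y, tree_params(max_depth = 1, min_samples_split = 10))
  expect_null(tree$root$split)
  expect_equal(tree$root$prediction, "bis2")  # bis2 precedes ruijin in priority

  x2 <- data.frame(a = c(rep(0, 30), rep(1, 10)))
  y2 <- c(rep("bis2", 30), rep("ruijin", 10))
  t2 <- fit_tree(x2, y2, tree_params(min_samples_split = 2, min_samples_leaf = 1))
  expect_error(predict_tree(t2, data.frame(b = 1)), "missing covariate.*a")
  # NA routed to the larger (left, n=30) child
  expect_equal(predict_tree(t2, data.frame(a = NA_real_)), "bis2")
})

test_that("variable importance scores and ranks splits", {
  x <- data.frame(bsa = c(rep(1.5, 20), rep(1.9, 20)), junk = rnorm(40))
  y <- c(rep("ruijin", 20), rep("bis2", 20))
  tree <- fit_tree(x, y, tree_params(min_samples_split = 2, min_samples_leaf = 1))
  imp <- variable_importance(tree)
  expect_equal(imp$variable[1], "bsa")
  expect_equal(imp$importance[1], 100)
  expect_false("junk" %in% imp$variable)
})

test_that("JSON serialization round-trips the tree exactly", {
  set.seed(31)
  x <- data.frame(u = rnorm(150), lev = sample(c("aa", "bb", "cc"), 150, TRUE),
                  f = rbinom(150, 1, 0.3))
  y <- ifelse(x$f == 1, "bis2",
              ifelse(x$lev %in% c("aa", "bb") & x$u > 0, "ruijin", "ckd_epi_cysc"))
  tree <- fit_tree(x, y, tree_params(max_depth = 4, min_samples_split = 5,
                                     min_samples_leaf = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_identical(tree_signature(back), tree_signature(tree))
  expect_identical(predict_tree(back, x), predict_tree(tree, x))
  expect_identical(back$labels, tree$labels)
  expect_error(read_tree(withr::local_tempfile(lines = "{}", fileext = ".json")),
               "not an egfr_tree")
})
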