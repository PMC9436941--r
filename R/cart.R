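# Classification tree (CART/CRT style) with entropy impurity and
# information-gain splitting over mixed numeric/categorical covariates.
#
# Greedy recursive binary partitioning with pre-pruning only (max depth,
# minimum node sizes, minimum gain).  No surrogate splits and no
# cost-complexity pruning: at prediction time a row with a missing split
# value is routed to the larger child.

#' Tree hyperparameters
#'
#' Stopping and split-admissibility parameters for [fit_tree()].  The
#' defaults echo the conventions of classic recursive-partitioning software
#' and produce shallow, readable trees.
#'
#' @param max_depth Maximum tree depth (root = depth 0); >= 1.
#' @param min_samples_split Minimum rows in a node for it to be considered
#'   for splitting.
#' @param min_samples_leaf Minimum rows in each child of an admissible split.
#' @param min_gain Minimum information gain (bits) for a split to be kept.
#' @param impurity `"entropy"` (information gain, default) or `"gini"`.
#' @param max_exhaustive_levels Categorical variables with at most this many
#'   observed levels are split by exhaustive enumeration of binary
#'   partitions; above it, levels are ordered by majority-class proportion
#'   and split like an ordered variable.
#' @return A `tree_params` list.
#' @export
tree_params <- function(max_depth = 5L, min_samples_split = 20L,
                        min_samples_leaf = 7L, min_gain = 0,
                        impurity = c("entropy", "gini"),
                        max_exhaustive_levels = 12L) {
  impurity <- match.arg(impurity)
  stopifnot(max_depth >= 1, min_samples_leaf >= 1,
            min_samples_split >= 2, min_gain >= 0)
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 min_gain = min_gain, impurity = impurity,
                 max_exhaustive_levels = as.integer(max_exhaustive_levels)),
            class = "tree_params")
}

# 0 log 0 = 0 convention, elementwise on proportions
.xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Shannon entropy of a class-count vector
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} in bits, with \eqn{0 \log 0 = 0}.
#'
#' @param class_counts Named non-negative numeric vector of per-class counts.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(A = 2, B = 2))  # 1 bit
entropy <- function(class_counts) {
  if (length(class_counts) == 0 || sum(class_counts) <= 0) {
    stop("class_counts must have positive total", call. = FALSE)
  }
  if (any(class_counts < 0)) stop("negative class count", call. = FALSE)
  p <- class_counts / sum(class_counts)
  -sum(.xlog2x(p))
}

.gini <- function(class_counts) {
  p <- class_counts / sum(class_counts)
  1 - sum(p^2)
}

.impurity_fun <- function(impurity) {
  if (impurity == "entropy") entropy else .gini
}

#' Information gain of a binary split
#'
#' Parent impurity minus the child-count-weighted mean child impurity:
#' \eqn{H(parent) - [n_L H(left) + n_R H(right)] / n}.  Non-negative for any
#' admissible split.
#'
#' @param parent_counts,left_counts,right_counts Named class-count vectors;
#'   parent must equal left + right elementwise.
#' @param impurity `"entropy"` (bits) or `"gini"`.
#' @return The impurity decrease.
#' @export
information_gain <- function(parent_counts, left_counts, right_counts,
                             impurity = "entropy") {
  labs <- names(parent_counts)
  l <- left_counts[labs]; l[is.na(l)] <- 0
  r <- right_counts[labs]; r[is.na(r)] <- 0
  if (any(abs(parent_counts - (l + r)) > 1e-9)) {
    stop("left + right counts do not sum to parent counts", call. = FALSE)
  }
  if (sum(l) == 0 || sum(r) == 0) stop("both children must be nonempty", call. = FALSE)
  f <- .impurity_fun(impurity)
  n <- sum(parent_counts)
  f(parent_counts) - (sum(l) * f(l) + sum(r) * f(r)) / n
}

# --- split search -----------------------------------------------------------

# Vectorised impurity of each row of a count matrix (rows = candidate left or
# right children, columns = classes).
.row_impurity <- function(counts, impurity) {
  n <- rowSums(counts)
  p <- counts / n
  if (impurity == "entropy") -rowSums(.xlog2x(p)) else 1 - rowSums(p^2)
}

# Best threshold split of one numeric variable.  Returns NULL or
# list(threshold, gain).  `ymat` is the n x K class indicator matrix.
.best_numeric_split <- function(v, ymat, params, parent_impurity) {
  ord <- order(v)
  vs <- v[ord]
  n <- length(v)
  cum <- apply(ymat[ord, , drop = FALSE], 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  i <- seq_len(n - 1)
  ok <- vs[i] < vs[i + 1] &
    i >= params$min_samples_leaf & (n - i) >= params$min_samples_leaf
  if (!any(ok)) return(NULL)
  i <- i[ok]
  left <- cum[i, , drop = FALSE]
  right <- matrix(cum[n, ], nrow = length(i), ncol = ncol(cum), byrow = TRUE) - left
  child <- (i * .row_impurity(left, params$impurity) +
            (n - i) * .row_impurity(right, params$impurity)) / n
  gain <- parent_impurity - child
  best <- which.max(gain)  # earliest index on exact ties => smallest threshold
  list(threshold = (vs[i[best]] + vs[i[best] + 1]) / 2, gain = gain[best])
}

# Best subset split of one categorical variable.  Returns NULL or
# list(left_levels, gain).
.best_categorical_split <- function(v, ymat, params, parent_impurity) {
  v <- as.character(v)
  levs <- sort(unique(v))
  L <- length(levs)
  if (L < 2) return(NULL)
  n <- nrow(ymat)
  # per-level class counts (L x K)
  counts <- rowsum(ymat, v)[levs, , drop = FALSE]
  lev_n <- rowSums(counts)
  total <- colSums(counts)

  eval_subsets <- function(subsets) {
    best <- NULL
    for (s in subsets) {
      lc <- colSums(counts[s, , drop = FALSE])
      nl <- sum(lc)
      if (nl < params$min_samples_leaf || n - nl < params$min_samples_leaf) next
      rc <- total - lc
      f <- .impurity_fun(params$impurity)
      gain <- parent_impurity - (nl * f(lc) + (n - nl) * f(rc)) / n
      key <- paste(levs[s], collapse = "\x1f")
      if (is.null(best) || gain > best$gain + 1e-12 ||
          (abs(gain - best$gain) <= 1e-12 && key < best$key)) {
        best <- list(left_levels = levs[s], gain = gain, key = key)
      }
    }
    best
  }

  if (L <= params$max_exhaustive_levels) {
    # all binary partitions: subsets of levels[1..L-1] (complement-free)
    subsets <- list()
    for (m in seq_len(2^(L - 1) - 1)) {
      subsets[[m]] <- which(bitwAnd(m, 2^(seq_len(L - 1) - 1)) > 0)
    }
  } else {
    # order levels by the within-level proportion of the overall majority
    # class, then cut along that ordering (standard CART reduction)
    maj <- which.max(total)
    o <- order(counts[, maj] / lev_n, levs)
    subsets <- lapply(seq_len(L - 1), function(k) o[seq_len(k)])
  }
  b <- eval_subsets(subsets)
  if (is.null(b)) NULL else list(left_levels = b$left_levels, gain = b$gain)
}

#' Find the best admissible split of a node
#'
#' Enumerates candidate splits of every covariate -- midpoints between
#' consecutive distinct values for numeric variables, binary level partitions
#' for categorical variables -- and returns the one with maximal impurity
#' decrease, subject to both children containing at least
#' `min_samples_leaf` rows.  Ties are broken by variable name
#' (lexicographic), then by smallest threshold / lexicographically smallest
#' left-level set, so the search is deterministic.
#'
#' @param x Data frame of covariates (numeric, logical, character or factor).
#' @param y Class labels, one per row of `x`.
#' @param params A [tree_params()] object.
#' @return `NULL` if no admissible split attains `min_gain`, otherwise a list
#'   with `variable`, `kind` (`"numeric_threshold"` or
#'   `"categorical_subset"`), `threshold` or `left_levels`, and `gain`.
#' @export
best_split <- function(x, y, params = tree_params()) {
  if (ncol(x) == 0) stop("no covariates", call. = FALSE)
  n <- nrow(x)
  if (n < params$min_samples_split) return(NULL)
  y <- as.character(y)
  labs <- .label_levels(y)
  ymat <- outer(y, labs, "==") * 1L
  colnames(ymat) <- labs
  parent_impurity <- .impurity_fun(params$impurity)(colSums(ymat))
  if (parent_impurity <= 0) return(NULL)

  best <- NULL
  for (var in sort(names(x))) {
    v <- x[[var]]
    if (anyNA(v)) stop("missing values in covariate '", var,
                       "'; fit requires complete covariates", call. = FALSE)
    if (is.numeric(v) || is.logical(v)) {
      cand <- .best_numeric_split(as.numeric(v), ymat, params, parent_impurity)
      if (!is.null(cand)) {
        cand <- list(variable = var, kind = "numeric_threshold",
                     threshold = cand$threshold, gain = cand$gain)
      }
    } else {
      cand <- .best_categorical_split(v, ymat, params, parent_impurity)
      if (!is.null(cand)) {
        cand <- list(variable = var, kind = "categorical_subset",
                     left_levels = cand$left_levels, gain = cand$gain)
      }
    }
    # variables visited in name order, so strict improvement keeps the
    # lexicographically smallest variable on ties
    if (!is.null(cand) && (is.null(best) || cand$gain > best$gain + 1e-12)) {
      best <- cand
    }
  }
  # note: with min_gain = 0 a zero-gain split of an impure node is kept --
  # the children may become separable deeper down (XOR-style interactions)
  if (is.null(best) || best$gain < params$min_gain) return(NULL)
  best
}

# fixed label order: candidate-equation priority when applicable, else sorted
.label_levels <- function(y) {
  u <- unique(as.character(y))
  cand <- egfr_candidates()
  if (all(u %in% cand)) cand[cand %in% u] else sort(u)
}

.route_left <- function(split, v) {
  if (split$kind == "numeric_threshold") as.numeric(v) <= split$threshold
  else as.character(v) %in% split$left_levels
}

#' Fit a classification tree
#'
#' Greedy recursive binary partitioning: at each node the maximal
#' information-gain admissible split ([best_split()]) is applied until the
#' node is pure, too small, too deep, or no split attains `min_gain`.
#' Deterministic for identical input and parameters.
#'
#' @inheritParams best_split
#' @return An object of class `egfr_tree`: a recursive node structure with
#'   per-node class counts, split rules and depths, plus the fitting
#'   parameters and label set.
#' @seealso [predict_tree()], [variable_importance()], [write_tree()].
#' @export
fit_tree <- function(x, y, params = tree_params()) {
  if (nrow(x) == 0) stop("empty training table", call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  y <- as.character(y)
  labs <- .label_levels(y)
  id_counter <- 0L

  grow <- function(idx, depth) {
    id_counter <<- id_counter + 1L
    counts <- vapply(labs, function(l) sum(y[idx] == l), integer(1))
    node <- list(node_id = id_counter, depth = depth, n = length(idx),
                 class_counts = counts,
                 prediction = labs[which.max(counts)])
    if (depth < params$max_depth && length(idx) >= params$min_samples_split) {
      sp <- best_split(x[idx, , drop = FALSE], y[idx], params)
      if (!is.null(sp)) {
        goes_left <- .route_left(sp, x[idx, sp$variable, drop = TRUE])
        node$split <- sp
        node$left <- grow(idx[goes_left], depth + 1L)
        node$right <- grow(idx[!goes_left], depth + 1L)
      }
    }
    node
  }

  structure(list(root = grow(seq_along(y), 0L), params = params,
                 labels = labs),
            class = "egfr_tree")
}

#' Predict classes from a fitted tree
#'
#' Routes each row through the split rules to a leaf and returns the leaf's
#' majority class (ties broken by the fixed label order).  A row with a
#' missing value for a split variable is sent to the larger child; a
#' categorical level unseen at that split is routed like a right-side level.
#'
#' @param tree An `egfr_tree` from [fit_tree()].
#' @param newdata Data frame containing every covariate the tree splits on.
#' @return Character vector of predicted class labels.
#' @export
predict_tree <- function(tree, newdata) {
  used <- tree_split_variables(tree)
  absent <- setdiff(used, names(newdata))
  if (length(absent)) {
    stop("missing covariate required by the tree: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- character(nrow(newdata))
  descend <- function(node, idx) {
    if (is.null(node$split)) {
      out[idx] <<- node$prediction
      return(invisible())
    }
    v <- newdata[[node$split$variable]][idx]
    left <- .route_left(node$split, v)
    larger_left <- node$left$n >= node$right$n
    left[is.na(left)] <- larger_left
    if (any(left)) descend(node$left, idx[left])
    if (any(!left)) descend(node$right, idx[!left])
  }
  if (nrow(newdata) > 0) descend(tree$root, seq_len(nrow(newdata)))
  out
}

#' Variables a tree splits on
#'
#' @param tree An `egfr_tree`.
#' @return Character vector of covariate names (unique, in first-use order).
#' @export
tree_split_variables <- function(tree) {
  vars <- character(0)
  walk <- function(node) {
    if (!is.null(node$split)) {
      vars <<- c(vars, node$split$variable)
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  unique(vars)
}

#' Variable importance of a fitted tree
#'
#' For each covariate, sums `n_node * gain_node` over the internal nodes that
#' split on it, then rescales so the largest score is 100.
#'
#' @param tree An `egfr_tree`.
#' @return Data frame with columns `variable` and `importance`, sorted
#'   decreasing; zero rows for a single-leaf tree.
#' @export
variable_importance <- function(tree) {
  scores <- numeric(0)
  walk <- function(node) {
    if (!is.null(node$split)) {
      v <- node$split$variable
      scores[v] <<- (if (is.na(scores[v])) 0 else scores[v]) +
        node$n * node$split$gain
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  if (length(scores) == 0) {
    return(data.frame(variable = character(0), importance = numeric(0)))
  }
  scores <- 100 * scores / max(scores)
  scores <- sort(scores, decreasing = TRUE)
  data.frame(variable = names(scores), importance = unname(scores))
}

# --- serialization ----------------------------------------------------------

.flatten_tree <- function(node) {
  rec <- list(node_id = node$node_id, depth = node$depth, n = node$n,
              class_counts = as.list(node$class_counts),
              prediction = node$prediction)
  if (!is.null(node$split)) {
    sp <- node$split
    rec$split <- list(variable = sp$variable, kind = sp$kind, gain = sp$gain,
                      gain_hex = sprintf("%a", sp$gain))
    if (sp$kind == "numeric_threshold") {
      # decimal for readability, C99 hex float for bit-exact round-tripping
      rec$split$threshold <- sp$threshold
      rec$split$threshold_hex <- sprintf("%a", sp$threshold)
    } else {
      rec$split$left_levels <- as.list(sp$left_levels)
    }
    rec$left_id <- node$left$node_id
    rec$right_id <- node$right$node_id
    c(list(rec), .flatten_tree(node$left), .flatten_tree(node$right))
  } else {
    list(rec)
  }
}

#' Serialise / load a fitted tree as JSON
#'
#' The tree is written as a flat node list (id, depth, class counts,
#' prediction, split rule, child ids) plus the label order and fitting
#' parameters.  Loading reconstructs an identical `egfr_tree`: class counts
#' and split rules round-trip bit-exact.
#'
#' @param tree An `egfr_tree`.
#' @param path File path for the JSON document.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns the
#'   reconstructed `egfr_tree`.
#' @export
write_tree <- function(tree, path) {
  doc <- list(format = "egfr_tree/1", labels = as.list(tree$labels),
              params = unclass(tree$params),
              nodes = .flatten_tree(tree$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$format) || doc$format != "egfr_tree/1") {
    stop("not an egfr_tree JSON document: ", path, call. = FALSE)
  }
  nodes <- doc$nodes
  by_id <- list()
  for (nd in nodes) by_id[[as.character(nd$node_id)]] <- nd

  build <- function(id) {
    nd <- by_id[[as.character(id)]]
    counts <- vapply(nd$class_counts, function(z) as.integer(z), integer(1))
    node <- list(node_id = as.integer(nd$node_id),
                 depth = as.integer(nd$depth), n = as.integer(nd$n),
                 class_counts = counts, prediction = nd$prediction)
    if (!is.null(nd$split)) {
      sp <- list(variable = nd$split$variable, kind = nd$split$kind,
                 gain = if (!is.null(nd$split$gain_hex))
                   as.numeric(nd$split$gain_hex) else as.numeric(nd$split$gain))
      if (sp$kind == "numeric_threshold") {
        sp$threshold <- if (!is.null(nd$split$threshold_hex)) {
          as.numeric(nd$split$threshold_hex)
        } else as.numeric(nd$split$threshold)
      } else {
        sp$left_levels <- vapply(nd$split$left_levels, as.character,
                                 character(1))
      }
      node$split <- sp
      node$left <- build(nd$left_id)
      node$right <- build(nd$right_id)
    }
    node
  }

  prm <- doc$params
  params <- tree_params(max_depth = prm$max_depth,
                        min_samples_split = prm$min_samples_split,
                        min_samples_leaf = prm$min_samples_leaf,
                        min_gain = prm$min_gain, impurity = prm$impurity,
                        max_exhaustive_levels = prm$max_exhaustive_levels)
  structure(list(root = build(nodes[[1]]$node_id), params = params,
                 labels = vapply(doc$labels, as.character, character(1))),
            class = "egfr_tree")
}

#' @export
print.egfr_tree <- function(x, ...) {
  cat("Classification tree (", x$params$impurity, " impurity)\n", sep = "")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    counts <- paste(names(node$class_counts), node$class_counts,
                    sep = ":", collapse = " ")
    if (is.null(node$split)) {
      cat(pad, "leaf -> ", node$prediction, "  [", counts, "]\n", sep = "")
    } else {
      rule <- if (node$split$kind == "numeric_threshold") {
        paste0(node$split$variable, " <= ",
               format(node$split$threshold, digits = 4))
      } else {
        paste0(node$split$variable, " in {",
               paste(node$split$left_levels, collapse = ","), "}")
      }
      cat(pad, rule, "  (n=", node$n, ", gain=",
          format(node$split$gain, digits = 3), ")\n", sep = "")
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}
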