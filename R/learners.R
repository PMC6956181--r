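#' Train a cry classifier
#'
#' Four classifier families, implemented as documented simplified-faithful
#' variants of the classical algorithms:
#'
#' * `RT` — random tree: unpruned binary decision tree; at every node the
#'   best information-gain split is chosen among `K = ceiling(log2(p) + 1)`
#'   randomly sampled attributes (all attributes are reconsidered if none of
#'   the sampled ones yields gain), grown until leaves are pure.
#' * `IB1` — single nearest neighbour by Euclidean distance; ties broken by
#'   the first training instance found.
#' * `DT` — decision table: attributes are discretized into quantile bins and
#'   a lookup table is built over a subset of attributes chosen by greedy
#'   forward selection maximizing leave-one-out accuracy; rows not matched at
#'   prediction time fall back to the training majority class.
#' * `NNGE` — nearest-neighbour with generalized exemplars: instances are
#'   absorbed one at a time into axis-aligned hyperrectangles of their own
#'   class; a generalization that would swallow a point of another class is
#'   rejected and the instance is kept as a point exemplar.
#'
#' @param kind one of `"RT"`, `"DT"`, `"IB1"`, `"NNGE"`.
#' @param d a `feature_dataset` with at least 2 instances and both classes.
#' @param seed integer seed (controls RT attribute sampling).
#' @param ... kind-specific hyperparameters: `k_attrs` (RT), `n_bins`,
#'   `max_attrs` (DT).
#' @return A classifier object (class `cry_classifier` plus a kind-specific
#'   subclass) usable with [predict_cry()].
#' @export
train_classifier <- function(kind = c("RT", "DT", "IB1", "NNGE"), d,
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(d, "feature_dataset"))
  if (nrow(d$x) < 2) stop("need >= 2 instances", call. = FALSE)
  if (length(unique(d$class)) < 2)
    stop("single-class dataset: both classes must be present", call. = FALSE)
  fit <- switch(kind,
                RT = fit_random_tree(d, seed, ...),
                IB1 = fit_ib1(d, ...),
                DT = fit_decision_table(d, ...),
                NNGE = fit_nnge(d, ...))
  fit$kind <- kind
  fit$levels <- levels(d$class)
  fit$seed <- seed
  class(fit) <- c(paste0("cry_", tolower(kind)), "cry_classifier")
  fit
}

#' @export
print.cry_classifier <- function(x, ...) {
  cat(sprintf("<%s classifier, classes {%s}>\n", x$kind,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes and class probabilities
#'
#' @param model a classifier from [train_classifier()].
#' @param x numeric matrix of instances (rows) with the training attribute
#'   count.
#' @return List with `class` (factor) and `prob` (instances x classes matrix;
#'   rows sum to 1).
#' @export
predict_cry <- function(model, x) {
  stopifnot(inherits(model, "cry_classifier"))
  x <- as.matrix(x)
  prob <- predict_proba(model, x)
  colnames(prob) <- model$levels
  cls <- factor(model$levels[max.col(prob, ties.method = "first")],
                levels = model$levels)
  list(class = cls, prob = prob)
}

predict_proba <- function(model, x) UseMethod("predict_proba")

## ---- IB1 ------------------------------------------------------------------

fit_ib1 <- function(d, ...) {
  list(x = d$x, y = d$class)
}

# index of the Euclidean nearest training instance for every row of `x`
# (first-found tie-break); shared by IB1 and the test oracle comparison
nearest_index <- function(train_x, x) {
  train_sq <- rowSums(train_x^2)
  apply(x, 1, function(z) {
    # squared distances via the expansion |t - z|^2 = |t|^2 - 2 t.z + |z|^2
    d2 <- train_sq - 2 * drop(train_x %*% z)
    which.min(d2)
  })
}

#' @export
predict_proba.cry_ib1 <- function(model, x) {
  idx <- nearest_index(model$x, x)
  onehot(model$y[idx], model$levels)
}

onehot <- function(cls, levels) {
  p <- matrix(0, nrow = length(cls), ncol = length(levels))
  p[cbind(seq_along(cls), match(as.character(cls), levels))] <- 1
  p
}

## ---- Random tree -----------------------------------------------------------

entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# best threshold and gain for one numeric attribute at a node
best_split_attr <- function(v, y, n_levels) {
  o <- order(v)
  v <- v[o]; y <- y[o]
  n <- length(v)
  distinct <- which(diff(v) > 0)
  if (!length(distinct)) return(NULL)
  # cumulative class counts below each candidate cut
  cum <- apply(onehot(y, seq_len(n_levels)), 2, cumsum)
  total <- cum[n, ]
  h0 <- entropy(total)
  best <- NULL
  for (i in distinct) {
    left <- cum[i, ]; right <- total - left
    h <- (i / n) * entropy(left) + ((n - i) / n) * entropy(right)
    gain <- h0 - h
    if (is.null(best) || gain > best$gain)
      best <- list(gain = gain, threshold = (v[i] + v[i + 1]) / 2)
  }
  best
}

grow_tree <- function(x, y, n_levels, k_attrs) {
  counts <- tabulate(y, n_levels)
  if (sum(counts > 0) <= 1 || nrow(x) < 2)
    return(list(leaf = TRUE, counts = counts))
  try_attrs <- function(attrs) {
    best <- NULL
    for (j in attrs) {
      s <- best_split_attr(x[, j], y, n_levels)
      if (!is.null(s) && s$gain > 1e-12 &&
          (is.null(best) || s$gain > best$gain))
        best <- c(s, attr = j)
    }
    best
  }
  p <- ncol(x)
  sampled <- sample.int(p, min(k_attrs, p))
  best <- try_attrs(sampled)
  if (is.null(best)) best <- try_attrs(seq_len(p)) # fall back to all attrs
  if (is.null(best)) return(list(leaf = TRUE, counts = counts))
  left <- x[, best$attr] <= best$threshold
  list(leaf = FALSE, attr = best$attr, threshold = best$threshold,
       left = grow_tree(x[left, , drop = FALSE], y[left], n_levels, k_attrs),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], n_levels,
                         k_attrs))
}

fit_random_tree <- function(d, seed, k_attrs = NULL, ...) {
  p <- ncol(d$x)
  k_attrs <- k_attrs %||% ceiling(log2(p) + 1)
  y <- as.integer(d$class)
  tree <- with_seed(seed, grow_tree(d$x, y, nlevels(d$class), k_attrs))
  list(tree = tree, k_attrs = k_attrs)
}

tree_distribution <- function(node, z) {
  while (!node$leaf) {
    node <- if (z[node$attr] <= node$threshold) node$left else node$right
  }
  if (sum(node$counts) == 0) return(rep(1 / length(node$counts),
                                        length(node$counts)))
  node$counts / sum(node$counts)
}

#' @export
predict_proba.cry_rt <- function(model, x) {
  t(apply(x, 1, function(z) tree_distribution(model$tree, z)))
}

## ---- Decision table --------------------------------------------------------

# quantile-bin discretization; returns inner cut points per attribute
dt_cuts <- function(v, n_bins) {
  qs <- stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins, names = FALSE)
  unique(qs)
}

dt_bin <- function(v, cuts) {
  if (!length(cuts)) return(rep(1L, length(v)))
  findInterval(v, cuts) + 1L
}

dt_keys <- function(x, attrs, cuts) {
  if (!length(attrs)) return(rep("()", nrow(x)))
  bins <- vapply(seq_along(attrs),
                 function(i) dt_bin(x[, attrs[i]], cuts[[i]]),
                 integer(nrow(x)))
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = nrow(x))
  apply(bins, 1, paste, collapse = ".")
}

# leave-one-out accuracy of a table over `attrs` (each instance removed from
# its own cell before taking the majority; empty cells fall back to the
# global majority, also self-excluded)
dt_loo_accuracy <- function(x, y, attrs, cuts, n_levels) {
  keys <- dt_keys(x, attrs, cuts)
  global <- tabulate(y, n_levels)
  cell <- rowsum(onehot(y, seq_len(n_levels)), keys)
  correct <- 0L
  for (i in seq_along(y)) {
    counts <- cell[keys[i], ] ; counts[y[i]] <- counts[y[i]] - 1
    if (sum(counts) == 0) { counts <- global; counts[y[i]] <- counts[y[i]] - 1 }
    pred <- which.max(counts)
    if (pred == y[i]) correct <- correct + 1L
  }
  correct / length(y)
}

fit_decision_table <- function(d, n_bins = 4, max_attrs = 5, ...) {
  x <- d$x; y <- as.integer(d$class)
  n_levels <- nlevels(d$class)
  p <- ncol(x)
  all_cuts <- lapply(seq_len(p), function(j) dt_cuts(x[, j], n_bins))
  selected <- integer(0)
  sel_cuts <- list()
  best_acc <- dt_loo_accuracy(x, y, selected, sel_cuts, n_levels)
  repeat {
    if (length(selected) >= max_attrs) break
    cand_best <- NULL
    for (j in setdiff(seq_len(p), selected)) {
      acc <- dt_loo_accuracy(x, y, c(selected, j),
                             c(sel_cuts, all_cuts[j]), n_levels)
      if (is.null(cand_best) || acc > cand_best$acc)
        cand_best <- list(attr = j, acc = acc)
    }
    if (is.null(cand_best) || cand_best$acc <= best_acc) break
    selected <- c(selected, cand_best$attr)
    sel_cuts <- c(sel_cuts, all_cuts[cand_best$attr])
    best_acc <- cand_best$acc
  }
  if (!length(selected)) {
    # leave-one-out cannot rank attributes on very small data; keep the
    # single attribute with the best resubstitution accuracy so the table is
    # never an empty majority vote
    resub <- vapply(seq_len(p), function(j) {
      keys <- dt_keys(x, j, all_cuts[j])
      cell <- rowsum(onehot(y, seq_len(n_levels)), keys)
      mean(max.col(cell, ties.method = "first")[match(keys,
                                                      rownames(cell))] == y)
    }, numeric(1))
    if (max(resub) > mean(y == which.max(tabulate(y, n_levels)))) {
      selected <- which.max(resub)
      sel_cuts <- all_cuts[selected]
    }
  }
  keys <- dt_keys(x, selected, sel_cuts)
  cell <- rowsum(onehot(y, seq_len(n_levels)), keys)
  list(attrs = selected, cuts = sel_cuts, cell = cell,
       global = tabulate(y, n_levels), loo_accuracy = best_acc,
       n_bins = n_bins)
}

#' @export
predict_proba.cry_dt <- function(model, x) {
  keys <- dt_keys(x, model$attrs, model$cuts)
  t(vapply(keys, function(k) {
    counts <- if (k %in% rownames(model$cell)) model$cell[k, ] else
      model$global
    if (sum(counts) == 0) counts <- model$global
    counts / sum(counts)
  }, numeric(length(model$global))))
}

## ---- NNGE ------------------------------------------------------------------

# distance from point z to hyperrectangle [lo, hi], attribute-normalized
rect_distance <- function(z, lo, hi, scale) {
  d <- pmax(lo - z, z - hi, 0) / scale
  sqrt(sum(d^2))
}

fit_nnge <- function(d, ...) {
  x <- d$x; y <- as.integer(d$class)
  p <- ncol(x)
  scale <- apply(x, 2, function(v) max(diff(range(v)), .Machine$double.eps))
  lo <- list(); hi <- list(); cls <- integer(0)
  for (i in seq_len(nrow(x))) {
    z <- x[i, ]
    if (length(cls)) {
      dist <- vapply(seq_along(cls),
                     function(e) rect_distance(z, lo[[e]], hi[[e]], scale),
                     numeric(1))
      e <- which.min(dist)
      if (cls[e] == y[i]) {
        new_lo <- pmin(lo[[e]], z); new_hi <- pmax(hi[[e]], z)
        # reject a generalization that swallows an earlier other-class point
        seen <- seq_len(i - 1)
        conflict <- any(y[seen] != y[i] &
                          apply(x[seen, , drop = FALSE], 1, function(q)
                            all(q >= new_lo - 1e-12 & q <= new_hi + 1e-12)))
        if (!conflict) {
          lo[[e]] <- new_lo; hi[[e]] <- new_hi
          next
        }
      } else if (dist[e] == 0 && any(hi[[e]] > lo[[e]])) {
        # conflict: the point sits inside an other-class rectangle; shrink
        # the rectangle along the cheapest face so it no longer covers it
        width_lo <- (z - lo[[e]]) / scale   # cost of raising the lower face
        width_hi <- (hi[[e]] - z) / scale   # cost of lowering the upper face
        j_lo <- which.min(width_lo); j_hi <- which.min(width_hi)
        eps <- 1e-9 * scale
        if (width_lo[j_lo] <= width_hi[j_hi]) {
          lo[[e]][j_lo] <- z[j_lo] + eps[j_lo]
        } else {
          hi[[e]][j_hi] <- z[j_hi] - eps[j_hi]
        }
      }
    }
    lo[[length(lo) + 1]] <- z
    hi[[length(hi) + 1]] <- z
    cls <- c(cls, y[i])
  }
  list(lo = lo, hi = hi, cls = cls, scale = scale,
       n_exemplars = length(cls))
}

#' @export
predict_proba.cry_nnge <- function(model, x) {
  n_levels <- length(model$levels)
  t(apply(x, 1, function(z) {
    dist <- vapply(seq_along(model$cls),
                   function(e) rect_distance(z, model$lo[[e]], model$hi[[e]],
                                             model$scale),
                   numeric(1))
    onehot(model$cls[which.min(dist)], seq_len(n_levels))[1, ]
  }))
}
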