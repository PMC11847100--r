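# Chimp Optimization Algorithm (ChOA) and its binary wrapper variant for
# feature-subset selection.
#
# The four best solutions -- attacker, barrier, chaser, driver -- guide every
# other chimp: for leader i, D_i = |C_i * x_leader_i - m * x_chimp| and
# x_i = x_leader_i - A_i * D_i; the new position is the mean of the four
# leader-guided points. The coefficient conventions (f decaying linearly
# 2.5 -> 0, A = 2*f*r1 - f, C = 2*r2, m from a logistic chaotic map in [0,1])
# follow the original ChOA; the update equations only name A, C and m.

#' ChOA coefficient schedule for one iteration
#'
#' @param pop Population size.
#' @param d Dimension.
#' @param t Current iteration (1-based).
#' @param T_max Total iterations.
#' @param m_state Per-chimp chaotic-map state in `[0, 1]` (updated in place
#'   via the logistic map `m <- 4 m (1 - m)`).
#' @param f0 Initial value of the control scalar `f` (decays linearly to 0).
#' @return List with `f`, `A` and `C` (each a list of four `pop x d`
#'   matrices), `m` (length-pop chaotic values) and the updated `m_state`.
#' @export
choa_coefficients <- function(pop, d, t, T_max, m_state, f0 = 2.5) {
  f <- f0 * (1 - t / T_max)
  A <- lapply(1:4, function(i) matrix(2 * f * stats::runif(pop * d) - f, pop, d))
  C <- lapply(1:4, function(i) matrix(2 * stats::runif(pop * d), pop, d))
  m_state <- 4 * m_state * (1 - m_state)
  m_state <- pmin(pmax(m_state, 1e-12), 1 - 1e-12)
  list(f = f, A = A, C = C, m = m_state, m_state = m_state)
}

# initialize a ChOA state over [lb, ub]^d
choa_init <- function(fitness_fn, pop, d, lb, ub, T_max) {
  positions <- matrix(stats::runif(pop * d, lb, ub), pop, d)
  fitness <- apply(positions, 1, fitness_fn)
  state <- list(positions = positions, fitness = fitness,
                t = 0L, T_max = as.integer(T_max),
                lb = lb, ub = ub,
                m_state = stats::runif(pop))
  .elect_leaders(state)
}

.elect_leaders <- function(state) {
  ord <- order(state$fitness)[1:4]
  state$leaders <- list(positions = state$positions[ord, , drop = FALSE],
                        fitness = state$fitness[ord],
                        roles = c("attacker", "barrier", "chaser", "driver"))
  state
}

#' One ChOA iteration
#'
#' Moves every chimp by the four-leader update (driven by the supplied
#' coefficients), clamps to the search bounds, re-evaluates fitness,
#' re-elects the leaders, and increments the iteration counter.
#'
#' @param state A ChOA state (from `choa_init()` or a previous step), with at
#'   least four chimps and current leaders.
#' @param coeffs Coefficients from [choa_coefficients()].
#' @param fitness_fn Function mapping a position vector to a scalar fitness
#'   (minimized).
#' @param raw_distance If `TRUE`, uses the literal printed update without the
#'   absolute value in `D`; the default keeps `D` as a distance.
#' @return The advanced state.
#' @export
choa_step <- function(state, coeffs, fitness_fn, raw_distance = FALSE) {
  if (state$t >= state$T_max) stop("iteration budget exhausted", call. = FALSE)
  x <- state$positions
  pop <- nrow(x); d <- ncol(x)
  xnew <- matrix(0, pop, d)
  for (i in 1:4) {
    leader <- matrix(state$leaders$positions[i, ], pop, d, byrow = TRUE)
    D <- coeffs$C[[i]] * leader - coeffs$m * x
    if (!raw_distance) D <- abs(D)
    xnew <- xnew + (leader - coeffs$A[[i]] * D)
  }
  xnew <- xnew / 4
  bad <- !is.finite(xnew)
  if (any(bad)) {
    warning("non-finite positions clamped to bounds")
    xnew[bad] <- state$lb
  }
  xnew <- pmin(pmax(xnew, state$lb), state$ub)
  state$positions <- xnew
  state$fitness <- apply(xnew, 1, fitness_fn)
  state$t <- state$t + 1L
  state$m_state <- coeffs$m_state
  .elect_leaders(state)
}

#' Continuous ChOA optimizer
#'
#' Minimizes `fn` over `[lb, ub]^d` with a population of chimps; returns the
#' best solution ever seen and the per-iteration best-so-far trace.
#'
#' @param fn Objective function (vector -> scalar, minimized).
#' @param d Dimension.
#' @param lb,ub Scalar box bounds.
#' @param pop Population size (>= 5).
#' @param T_max Iterations.
#' @param seed Integer seed.
#' @param raw_distance See [choa_step()].
#' @return List with `best_x`, `best_fitness` and `trace` (length `T_max + 1`,
#'   non-increasing, starting at the initial population's best).
#' @export
choa_optimize <- function(fn, d, lb = -5, ub = 5, pop = 20L, T_max = 50L,
                          seed = 1L, raw_distance = FALSE) {
  stopifnot(pop >= 5L, d >= 1L)
  set.seed(seed)
  state <- choa_init(fn, pop, d, lb, ub, T_max)
  best_i <- which.min(state$fitness)
  best <- list(x = state$positions[best_i, ], f = state$fitness[best_i])
  trace <- numeric(T_max + 1L)
  trace[1] <- best$f
  t <- 0L
  while (t < T_max) {
    co <- choa_coefficients(pop, d, t + 1L, T_max, state$m_state)
    state <- choa_step(state, co, fn, raw_distance)
    t <- state$t
    if (min(state$fitness) < best$f) {
      best_i <- which.min(state$fitness)
      best <- list(x = state$positions[best_i, ], f = state$fitness[best_i])
    }
    trace[t + 1L] <- best$f
  }
  list(best_x = best$x, best_fitness = best$f, trace = trace)
}

#' Binarize a continuous position row
#'
#' `bit_j = 1` iff `rand_j < S(position_j)` with the logistic transfer
#' `S(x) = 1 / (1 + exp(-x))`. An all-zero result is repaired by setting the
#' bit with the largest transfer value, so the selected subset is never empty.
#'
#' @param position_row Numeric vector of positions.
#' @param rand_row Uniform draws of the same length.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(position_row, rand_row) {
  stopifnot(length(position_row) == length(rand_row))
  s <- 1 / (1 + exp(-position_row))
  bits <- as.integer(rand_row < s)
  if (!any(bits)) bits[which.max(s)] <- 1L
  bits
}

# deterministic stratified fold assignment
.stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  folds <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# 3-fold CV accuracy of a 1-nearest-neighbour classifier on masked columns
.knn_cv_accuracy <- function(x, y, folds) {
  correct <- 0L
  for (f in sort(unique(folds))) {
    te <- folds == f
    xtr <- x[!te, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    d2 <- outer(rowSums(xte^2), rowSums(xtr^2), `+`) - 2 * tcrossprod(xte, xtr)
    pred <- y[!te][max.col(-d2, ties.method = "first")]
    correct <- correct + sum(pred == y[te])
  }
  correct / length(y)
}

#' Wrapper fitness of a feature mask
#'
#' `fitness = alpha * (1 - cv_accuracy) + (1 - alpha) * |mask| / d`, lower is
#' better: a mask is good when a cheap classifier cross-validates well on the
#' masked columns and the mask is small. The inner classifier is 1-nearest-
#' neighbour with `k`-fold CV by default (`classifier = "nnn"` uses the
#' narrow neural-network preset instead, at a much higher cost).
#'
#' @param mask 0/1 vector over the feature columns (non-empty).
#' @param features A [feature_matrix] with labels (>= 2 classes).
#' @param alpha Accuracy weight in `[0, 1]` (default 0.99).
#' @param k Inner CV folds (default 3).
#' @param seed Seed fixing the inner fold assignment.
#' @param classifier `"knn"` or `"nnn"`.
#' @return Scalar fitness (minimized).
#' @export
evaluate_fitness <- function(mask, features, alpha = 0.99, k = 3L, seed = 1L,
                             classifier = c("knn", "nnn")) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(features, "feature_matrix"), alpha >= 0, alpha <= 1)
  if (!any(mask == 1)) stop("mask must select at least one feature", call. = FALSE)
  y <- features$labels
  if (is.null(y) || nlevels(droplevels(y)) < 2L)
    stop("fitness needs labels with at least two classes", call. = FALSE)
  x <- features$values[, mask == 1, drop = FALSE]
  folds <- .stratified_folds(y, k, seed)
  acc <- if (classifier == "knn") {
    .knn_cv_accuracy(x, y, folds)
  } else {
    preset <- classifier_preset("NNN")
    correct <- 0L
    for (f in sort(unique(folds))) {
      te <- folds == f
      fit <- mlp_fit(x[!te, , drop = FALSE], y[!te], hidden = preset$hidden,
                     max_epochs = 60L, seed = seed)
      pred <- mlp_predict(fit, x[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    correct / length(y)
  }
  alpha * (1 - acc) + (1 - alpha) * mean(mask)
}

#' Binary ChOA feature selection
#'
#' Runs the binary wrapper variant: chimp positions live in a continuous box,
#' are mapped to 0/1 masks through the logistic transfer with a fresh uniform
#' draw per bit per iteration, and are scored by [evaluate_fitness()]. The
#' best mask ever seen is returned (elitism), so the fitness trace is
#' non-increasing by construction. With `T_max = 0` the result is the best of
#' the random initial population. Deterministic given `seed`.
#'
#' @param features A labeled [feature_matrix] with `d >= 2` columns.
#' @param pop Population size (>= 5, default 20).
#' @param T_max Iterations (default 50).
#' @param seed Integer seed.
#' @param alpha Accuracy weight of the wrapper objective.
#' @param fitness_classifier Inner classifier, `"knn"` (default) or `"nnn"`.
#' @param raw_distance See [choa_step()].
#' @param bound Box half-width for the continuous positions.
#' @return A `selection_result`: `mask`, `selected_idx`, `selected_count`,
#'   `final_fitness`, `fitness_trace` (length `T_max + 1`).
#' @export
select_features <- function(features, pop = 20L, T_max = 50L, seed = 1L,
                            alpha = 0.99, fitness_classifier = c("knn", "nnn"),
                            raw_distance = FALSE, bound = 4) {
  fitness_classifier <- match.arg(fitness_classifier)
  stopifnot(inherits(features, "feature_matrix"))
  d <- ncol(features$values)
  if (d < 2L) stop("need at least 2 features", call. = FALSE)
  if (pop < 5L) stop("population must be >= 5", call. = FALSE)

  cache <- new.env(parent = emptyenv())
  fit_mask <- function(bits) {
    key <- paste(bits, collapse = "")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- evaluate_fitness(bits, features, alpha = alpha, seed = seed,
                            classifier = fitness_classifier)
    cache[[key]] <- val
    val
  }

  set.seed(seed)
  positions <- matrix(stats::runif(pop * d, -bound, bound), pop, d)
  masks <- t(apply(positions, 1, function(p) binarize(p, stats::runif(d))))
  fitness <- apply(masks, 1, fit_mask)
  state <- list(positions = positions, fitness = fitness, t = 0L,
                T_max = as.integer(T_max), lb = -bound, ub = bound,
                m_state = stats::runif(pop))
  state <- .elect_leaders(state)

  best_i <- which.min(fitness)
  best <- list(mask = masks[best_i, ], f = fitness[best_i])
  trace <- numeric(T_max + 1L)
  trace[1] <- best$f

  t <- 0L
  while (t < T_max) {
    co <- choa_coefficients(pop, d, t + 1L, T_max, state$m_state)
    x <- state$positions
    xnew <- matrix(0, pop, d)
    for (i in 1:4) {
      leader <- matrix(state$leaders$positions[i, ], pop, d, byrow = TRUE)
      D <- co$C[[i]] * leader - co$m * x
      if (!raw_distance) D <- abs(D)
      xnew <- xnew + (leader - co$A[[i]] * D)
    }
    xnew <- pmin(pmax(xnew / 4, -bound), bound)
    masks <- t(apply(xnew, 1, function(p) binarize(p, stats::runif(d))))
    fitness <- apply(masks, 1, fit_mask)
    state$positions <- xnew
    state$fitness <- fitness
    state$m_state <- co$m_state
    state$t <- t <- t + 1L
    state <- .elect_leaders(state)
    ti <- which.min(fitness)
    if (fitness[ti] < best$f) best <- list(mask = masks[ti, ], f = fitness[ti])
    trace[t + 1L] <- best$f
  }
  structure(list(mask = best$mask,
                 selected_idx = which(best$mask == 1L),
                 selected_count = sum(best$mask),
                 final_fitness = best$f,
                 fitness_trace = trace,
                 pop = pop, T_max = T_max, seed = seed, alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected, fitness %.4f (pop %d, %d iterations)\n",
              x$selected_count, x$final_fitness, x$pop, x$T_max))
  invisible(x)
}
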