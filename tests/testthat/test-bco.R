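# Chimp Optimization Algorithm and its binary feature-selection wrapper.

test_that("choa_step collapses to the leader mean when A = 0", {
  # scalar case: all four leaders at 4, A_i = 0 -> every chimp moves to 4
  state <- list(positions = matrix(c(-3, 0, 2, 5, 1), 5, 1),
                fitness = rep(1, 5), t = 0L, T_max = 10L, lb = -10, ub = 10,
                m_state = rep(0.5, 5))
  state$leaders <- list(positions = matrix(4, 4, 1), fitness = rep(0, 4))
  coeffs <- list(A = lapply(1:4, function(i) matrix(0, 5, 1)),
                 C = lapply(1:4, function(i) matrix(1, 5, 1)),
                 m = rep(0.5, 5), m_state = rep(0.5, 5))
  out <- choa_step(state, coeffs, function(x) sum(x^2))
  expect_equal(as.vector(out$positions), rep(4, 5))
  expect_equal(out$t, 1L)
})

test_that("one leader term reproduces direct substitution into the update", {
  # attacker = 5, x = 3, A1 = 0.5, C1 = 2, m = 1:
  # D = |2*5 - 1*3| = 7, x1 = 5 - 0.5*7 = 1.5
  x <- 3; leader <- 5; A1 <- 0.5; C1 <- 2; m <- 1
  D <- abs(C1 * leader - m * x)
  expect_equal(D, 7)
  expect_equal(leader - A1 * D, 1.5)
  # the same arithmetic inside choa_step (other three leaders neutralized
  # by A = 0 at the same leader position, contributing `leader` each)
  state <- list(positions = matrix(3, 5, 1), fitness = rep(1, 5),
                t = 0L, T_max = 10L, lb = -10, ub = 10, m_state = rep(1, 5))
  state$leaders <- list(positions = matrix(5, 4, 1), fitness = rep(0, 4))
  coeffs <- list(A = c(list(matrix(0.5, 5, 1)),
                       lapply(1:3, function(i) matrix(0, 5, 1))),
                 C = lapply(1:4, function(i) matrix(2, 5, 1)),
                 m = rep(1, 5), m_state = rep(1, 5))
  out <- choa_step(state, coeffs, function(x) sum(x^2))
  expect_equal(as.vector(out$positions), rep((1.5 + 5 + 5 + 5) / 4, 5))
})

test_that("choa_step agrees with the brute-force transcription on random configurations", {
  set.seed(99)
  for (rep in 1:100) {
    P <- sample(5:8, 1); d <- sample(1:4, 1)
    x <- matrix(runif(P * d, -5, 5), P, d)
    leaders <- matrix(runif(4 * d, -5, 5), 4, d)
    A <- lapply(1:4, function(i) matrix(runif(P * d, -2, 2), P, d))
    C <- lapply(1:4, function(i) matrix(runif(P * d, 0, 2), P, d))
    m <- runif(P)
    state <- list(positions = x, fitness = rep(1, P), t = 0L, T_max = 2L,
                  lb = -50, ub = 50, m_state = m)
    state$leaders <- list(positions = leaders, fitness = rep(0, 4))
    coeffs <- list(A = A, C = C, m = m, m_state = m)
    out <- choa_step(state, coeffs, function(v) sum(v^2))
    expect_equal(out$positions,
                 choa_update_bruteforce(x, leaders, A, C, m),
                 tolerance = 1e-14)
  }
})

test_that("leader ordering and elitism invariants hold through a run", {
  set.seed(5)
  sphere <- function(x) sum(x^2)
  state <- medleaf:::choa_init(sphere, pop = 8, d = 3, lb = -5, ub = 5, T_max = 20)
  for (t in 1:20) {
    co <- choa_coefficients(8, 3, t, 20, state$m_state)
    state <- choa_step(state, co, sphere)
    lf <- state$leaders$fitness
    expect_true(all(diff(lf) >= 0))                  # attacker <= ... <= driver
    expect_equal(lf, sort(state$fitness)[1:4])       # leaders best of the population
    expect_equal(lf[1], min(state$fitness))
  }
  opt <- choa_optimize(sphere, d = 5, lb = -5, ub = 5, pop = 6, T_max = 50, seed = 1)
  expect_true(all(diff(opt$trace) <= 0))             # best-so-far non-increasing
  expect_lt(opt$best_fitness, 1e-2 * opt$trace[1])   # converges on the sphere
})

test_that("population contracts onto a fixed leader when A = 0", {
  state <- list(positions = matrix(runif(12, -5, 5), 6, 2),
                fitness = rep(1, 6), t = 0L, T_max = 10L, lb = -10, ub = 10,
                m_state = rep(0.5, 6))
  target <- c(1.5, -2)
  state$leaders <- list(positions = matrix(target, 4, 2, byrow = TRUE),
                        fitness = rep(0, 4))
  zero <- lapply(1:4, function(i) matrix(0, 6, 2))
  coeffs <- list(A = zero, C = lapply(1:4, function(i) matrix(1, 6, 2)),
                 m = rep(0.5, 6), m_state = rep(0.5, 6))
  out <- choa_step(state, coeffs, function(x) sum((x - 1.5)^2))
  expect_equal(out$positions, matrix(target, 6, 2, byrow = TRUE))
})

test_that("binarize applies the logistic transfer and repairs empty masks", {
  # position 0 -> S = 0.5: bit set iff rand < 0.5
  expect_equal(binarize(c(0, 0), c(0.49, 0.51)), c(1L, 0L))
  # saturated positive position -> always selected
  expect_equal(binarize(10, 0.9999 - 1e-6), 1L)
  # all strongly negative -> repair sets exactly one bit (the largest S)
  b <- binarize(c(-10, -9, -11), c(0.5, 0.5, 0.5))
  expect_equal(sum(b), 1L)
  expect_equal(which(b == 1L), 2L)
})

test_that("evaluate_fitness combines accuracy and sparsity as documented", {
  # perfectly separable features: the 1-NN CV accuracy is 1
  set.seed(6)
  y <- rep(c("a", "b"), each = 15)
  x <- cbind(ifelse(y == "a", 0, 10) + rnorm(30, sd = .01),
             ifelse(y == "a", 10, 0) + rnorm(30, sd = .01),
             rnorm(30, sd = .01), rnorm(30, sd = .01))
  fm <- feature_matrix(x, labels = y, origin = "t")
  alpha <- 0.99
  expect_equal(evaluate_fitness(rep(1L, 4), fm, alpha = alpha),
               (1 - alpha) * 1)
  expect_equal(evaluate_fitness(c(1L, 1L, 0L, 0L), fm, alpha = alpha),
               (1 - alpha) / 2)
  expect_error(evaluate_fitness(rep(0L, 4), fm), "at least one")
  expect_error(evaluate_fitness(1L, feature_matrix(matrix(1:4), labels = rep("a", 4))),
               "two classes")
})

test_that("the planted informative subset scores better than the full mask", {
  fm <- generate_feature_table(planted_feature_spec(seed = 31), n_classes = 5)
  info <- attr(fm, "informative_idx")
  mask_info <- as.integer(seq_len(50) %in% info)
  f_info <- evaluate_fitness(mask_info, fm)
  f_full <- evaluate_fitness(rep(1L, 50), fm)
  expect_lt(f_info, f_full)
})

test_that("select_features is deterministic, elitist, and degenerates sanely", {
  fm <- generate_feature_table(planted_feature_spec(n_samples = 100,
                                                    n_features = 12,
                                                    informative_idx = 1:3,
                                                    seed = 17), n_classes = 4)
  r1 <- select_features(fm, pop = 6, T_max = 5, seed = 2)
  r2 <- select_features(fm, pop = 6, T_max = 5, seed = 2)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$fitness_trace, r2$fitness_trace)
  expect_true(all(diff(r1$fitness_trace) <= 0))
  expect_gte(r1$selected_count, 1L)

  # T_max = 0: best of the random initial population
  r0 <- select_features(fm, pop = 6, T_max = 0, seed = 2)
  expect_equal(length(r0$fitness_trace), 1L)
  expect_equal(r0$final_fitness, r0$fitness_trace[1])

  expect_error(select_features(fm, pop = 3, T_max = 2), ">= 5")
  one_col <- feature_matrix(matrix(rnorm(20), 20, 1), labels = rep(c("a", "b"), 10))
  expect_error(select_features(one_col, pop = 6, T_max = 2), "at least 2")
})
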