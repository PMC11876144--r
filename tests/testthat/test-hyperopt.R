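test_that("search spaces validate their parameters", {
  expect_error(param_real("a", 2, 1), "lower < upper")
  expect_error(param_real("a", -1, 1, scale = "log"), "positive")
  expect_error(param_categorical("k", character(0)), "non-empty")
  sp <- search_space(param_integer("n", 1, 5),
                     param_real("g", 1e-4, 1, scale = "log"))
  expect_s3_class(sp, "search_space")
  expect_named(sp, c("n", "g"))
})

test_that("random search recovers a discrete optimum and handles failures", {
  sp1 <- search_space(param_categorical("k", "only"))
  r <- random_search(function(p) 1, sp1, n_iter = 3, seed = 1)
  expect_identical(r$best_params$k, "only")

  # exhaustive oracle over p in 1..5: -(p - 3)^2 is maximised at p = 3
  sp2 <- search_space(param_integer("p", 1, 5))
  r2 <- random_search(function(par) -(par$p - 3)^2, sp2, n_iter = 50, seed = 2)
  expect_identical(r2$best_params$p, 3L)
  expect_identical(r2$best_objective, 0)
  expect_length(r2$history, 50)

  # objective failure is recorded as -Inf, search continues
  r3 <- random_search(function(par) if (par$p == 3) stop("boom") else -par$p,
                      sp2, n_iter = 30, seed = 3)
  expect_length(r3$history, 30)
  expect_identical(r3$best_params$p, 1L)
})

test_that("the shipped tuned configurations lie inside the default spaces", {
  inside <- function(space, params) {
    all(vapply(names(params), function(nm) {
      p <- space[[nm]]
      params[[nm]] >= p$lower && params[[nm]] <= p$upper
    }, logical(1)))
  }
  expect_true(inside(default_space("rf"),
                     rf_params()[c("n_estimators", "max_depth",
                                   "min_samples_split", "min_samples_leaf")]))
  expect_true(inside(default_space("svm"), svm_params()[c("C", "gamma")]))
  expect_true(inside(default_space("xgb"),
                     xgb_params()[c("max_depth", "learning_rate",
                                    "n_estimators", "subsample",
                                    "colsample_bytree")]))
})

test_that("particle swarm holds a fixed point and recovers the sphere optimum", {
  sp <- search_space(param_real("x", -5, 5), param_real("y", -5, 5))
  obj <- function(p) -(p$x^2 + p$y^2)

  # swarm started exactly at the optimum with zero velocity stays there
  init <- matrix(0, 4, 2)
  r0 <- pso_optimize(obj, sp, n_particles = 4, n_iter = 10, seed = 1,
                     init = init)
  expect_identical(r0$best_objective, 0)
  expect_true(all(vapply(r0$history,
                         function(h) h$objective == 0, logical(1))))

  r <- pso_optimize(obj, sp, n_particles = 20, n_iter = 50, seed = 1)
  expect_lt(abs(r$best_objective), 1e-2)
  # all visited positions are clipped to the bounds
  expect_true(all(vapply(r$history, function(h) {
    h$params$x >= -5 && h$params$x <= 5 && h$params$y >= -5 && h$params$y <= 5
  }, logical(1))))

  expect_error(
    pso_optimize(obj, search_space(param_categorical("k", c("a", "b"))),
                 n_particles = 4, n_iter = 2),
    "real/integer")
})

test_that("Bayesian optimisation recovers a 1-D optimum within budget", {
  sp <- search_space(param_real("x", 0, 10))
  r <- bayes_optimize(function(p) -(p$x - 7)^2, sp, n_init = 5, n_iter = 20,
                      seed = 1)
  expect_length(r$history, 25)
  expect_lt(abs(r$best_params$x - 7), 0.5)

  # constant objective: any evaluated point is a valid best
  rc <- bayes_optimize(function(p) 2.5, sp, n_init = 3, n_iter = 4, seed = 2)
  expect_identical(rc$best_objective, 2.5)
  expect_length(rc$history, 7)
})

test_that("optimizers are reproducible and their running best is monotone", {
  sp <- search_space(param_real("x", -5, 5), param_real("y", -5, 5))
  obj <- function(p) -(p$x - 1)^2 - (p$y + 2)^2
  # equal budgets of 40 evaluations each
  for (run in list(
    function(s) random_search(obj, sp, 40, seed = s),
    function(s) pso_optimize(obj, sp, 5, 7, seed = s),
    function(s) bayes_optimize(obj, sp, n_init = 10, n_iter = 30, seed = s))) {
    a <- run(42)
    b <- run(42)
    expect_identical(a$history, b$history)
    vals <- vapply(a$history, function(h) h$objective, numeric(1))
    expect_true(all(diff(cummax(vals)) >= 0))
    expect_identical(a$best_objective, max(vals))
    # each optimizer lands near the analytic optimum of the smooth bowl
    expect_lt(-a$best_objective, 1.5)
  }
})
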