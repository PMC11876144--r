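#' Define a hyperparameter search space
#'
#' A search space is an ordered collection of parameter definitions built
#' with [param_real()], [param_integer()] and [param_categorical()].
#' Real and integer parameters have finite bounds and an optional log scale
#' (sampling and swarm/surrogate geometry then operate on log-coordinates);
#' categorical parameters enumerate their choices.
#'
#' @param ... parameter definitions.
#' @return an object of class `search_space`.
#' @examples
#' space <- search_space(
#'   param_integer("n_estimators", 50, 400),
#'   param_real("learning_rate", 0.01, 0.3, scale = "log"))
#' @export
search_space <- function(...) {
  params <- list(...)
  for (p in params) {
    if (!inherits(p, "search_param")) stop_talsrx("arguments must be parameter definitions")
  }
  names(params) <- vapply(params, function(p) p$name, character(1))
  structure(params, class = "search_space")
}

new_param <- function(name, kind, lower = NULL, upper = NULL,
                      choices = NULL, scale = "linear") {
  stopifnot(is.character(name), length(name) == 1L)
  if (kind %in% c("real", "integer")) {
    if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
      stop_talsrx("parameter '%s': bounds must be finite with lower < upper", name)
    }
    if (scale == "log" && lower <= 0) {
      stop_talsrx("parameter '%s': log scale needs positive bounds", name)
    }
  }
  if (kind == "categorical" && length(choices) == 0L) {
    stop_talsrx("parameter '%s': choices must be non-empty", name)
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 choices = choices, scale = scale), class = "search_param")
}

#' @rdname search_space
#' @param name parameter name.
#' @param lower,upper finite bounds (`lower < upper`).
#' @param scale `"linear"` or `"log"`.
#' @export
param_real <- function(name, lower, upper, scale = "linear") {
  new_param(name, "real", lower, upper, scale = scale)
}

#' @rdname search_space
#' @export
param_integer <- function(name, lower, upper, scale = "linear") {
  new_param(name, "integer", lower, upper, scale = scale)
}

#' @rdname search_space
#' @param choices vector of allowed values.
#' @export
param_categorical <- function(name, choices) {
  new_param(name, "categorical", choices = choices)
}

# --- internal coordinate transforms (numeric parameters only) -------------

space_is_numeric <- function(space) {
  all(vapply(space, function(p) p$kind %in% c("real", "integer"), logical(1)))
}

# internal coordinates: log-transformed where scale = "log"
param_to_internal <- function(p, v) if (p$scale == "log") log(v) else v
param_bounds_internal <- function(p) {
  c(param_to_internal(p, p$lower), param_to_internal(p, p$upper))
}
# decode an internal coordinate vector into a named parameter list
decode_internal <- function(space, z) {
  out <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    v <- if (p$scale == "log") exp(z[i]) else z[i]
    v <- min(max(v, p$lower), p$upper)
    if (p$kind == "integer") v <- as.integer(round(v))
    out[[p$name]] <- v
  }
  out
}

sample_params <- function(space) {
  out <- list()
  for (p in space) {
    if (p$kind == "categorical") {
      out[[p$name]] <- p$choices[[sample.int(length(p$choices), 1L)]]
    } else {
      b <- param_bounds_internal(p)
      v <- stats::runif(1, b[1], b[2])
      if (p$scale == "log") v <- exp(v)
      if (p$kind == "integer") v <- as.integer(round(v))
      out[[p$name]] <- v
    }
  }
  out
}

safe_objective <- function(objective) {
  function(params) {
    val <- tryCatch(objective(params), error = function(e) -Inf)
    if (!is.numeric(val) || length(val) != 1L || is.na(val)) val <- -Inf
    val
  }
}

opt_result <- function(history) {
  obj <- vapply(history, function(h) h$objective, numeric(1))
  best <- which.max(obj) # first-found on ties
  structure(list(best_params = history[[best]]$params,
                 best_objective = obj[best],
                 history = history),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> %d evaluations, best objective %.6g\n",
              length(x$history), x$best_objective))
  cat("  best:", paste(names(x$best_params),
                       vapply(x$best_params, format, character(1)),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Random search over a parameter space
#'
#' Draws `n_iter` independent configurations uniformly over the space
#' (log-uniformly on log-scaled parameters) and returns the best. A failing
#' objective evaluation is recorded as `-Inf` and the search continues.
#'
#' @param objective function `params -> scalar`, maximised.
#' @param space a [search_space()].
#' @param n_iter evaluation budget (>= 1).
#' @param seed integer seed.
#' @return an `opt_result` with `best_params`, `best_objective` and the full
#'   evaluation `history`.
#' @export
random_search <- function(objective, space, n_iter, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (!is_count(n_iter)) stop_talsrx("n_iter must be a positive integer")
  f <- safe_objective(objective)
  set.seed(seed)
  history <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    params <- sample_params(space)
    history[[i]] <- list(params = params, objective = f(params))
  }
  opt_result(history)
}

#' Particle swarm optimisation over a numeric parameter space
#'
#' Canonical PSO: each particle's velocity is updated as
#' `v <- inertia * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)` with
#' per-dimension uniform random factors, positions are clipped to the bounds
#' and integer parameters are rounded at evaluation time. Defaults are the
#' standard constriction values.
#'
#' @inheritParams random_search
#' @param n_particles swarm size (>= 2).
#' @param n_iter number of swarm iterations.
#' @param inertia,c1,c2 velocity update constants.
#' @param init optional `n_particles x d` matrix of starting positions (in
#'   parameter units); velocities then start at zero.
#' @return an `opt_result`; history holds all evaluated positions.
#' @export
pso_optimize <- function(objective, space, n_particles = 20L, n_iter = 50L,
                         inertia = 0.72, c1 = 1.49, c2 = 1.49,
                         seed = 1L, init = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (!space_is_numeric(space)) {
    stop_talsrx("pso_optimize supports real/integer parameters only")
  }
  if (!is_count(n_particles) || n_particles < 2) {
    stop_talsrx("n_particles must be an integer >= 2")
  }
  if (!is_count(n_iter)) stop_talsrx("n_iter must be a positive integer")
  f <- safe_objective(objective)
  d <- length(space)
  lb <- vapply(space, function(p) param_bounds_internal(p)[1], numeric(1))
  ub <- vapply(space, function(p) param_bounds_internal(p)[2], numeric(1))
  set.seed(seed)
  if (is.null(init)) {
    X <- matrix(stats::runif(n_particles * d), n_particles, d)
    X <- sweep(sweep(X, 2, ub - lb, "*"), 2, lb, "+")
  } else {
    stopifnot(nrow(init) == n_particles, ncol(init) == d)
    X <- init
    for (j in seq_len(d)) X[, j] <- param_to_internal(space[[j]], init[, j])
  }
  V <- matrix(0, n_particles, d)
  history <- list()
  evaluate <- function(z) {
    params <- decode_internal(space, z)
    val <- f(params)
    history[[length(history) + 1L]] <<- list(params = params, objective = val)
    val
  }
  pbest <- X
  pbest_val <- apply(X, 1, evaluate)
  g <- which.max(pbest_val)
  gbest <- pbest[g, ]
  gbest_val <- pbest_val[g]
  for (it in seq_len(n_iter)) {
    r1 <- matrix(stats::runif(n_particles * d), n_particles, d)
    r2 <- matrix(stats::runif(n_particles * d), n_particles, d)
    V <- inertia * V +
      c1 * r1 * (pbest - X) +
      c2 * r2 * sweep(-X, 2, gbest, "+")
    X <- X + V
    X <- pmin(pmax(X, matrix(lb, n_particles, d, byrow = TRUE)),
              matrix(ub, n_particles, d, byrow = TRUE))
    vals <- apply(X, 1, evaluate)
    improved <- vals > pbest_val
    pbest[improved, ] <- X[improved, , drop = FALSE]
    pbest_val[improved] <- vals[improved]
    if (max(pbest_val) > gbest_val) {
      g <- which.max(pbest_val)
      gbest <- pbest[g, ]
      gbest_val <- pbest_val[g]
    }
  }
  opt_result(history)
}

# --- Gaussian-process surrogate for Bayesian optimisation -----------------
# Squared-exponential kernel on unit-cube coordinates; fixed length-scale,
# signal variance from the observed responses, small nugget for stability.
gp_fit <- function(X, y, lengthscale = 0.25) {
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  yc <- (y - y_mean) / y_sd
  K <- gp_kernel(X, X, lengthscale)
  diag(K) <- diag(K) + 1e-6
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, yc, transpose = TRUE))
  list(X = X, L = L, alpha = alpha, y_mean = y_mean, y_sd = y_sd,
       lengthscale = lengthscale)
}

gp_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * lengthscale^2))
}

gp_predict <- function(fit, Xnew) {
  Ks <- gp_kernel(Xnew, fit$X, fit$lengthscale)
  mu <- as.numeric(Ks %*% fit$alpha)
  v <- backsolve(fit$L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mu * fit$y_sd + fit$y_mean, sd = sqrt(s2) * fit$y_sd)
}

expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian optimisation with a Gaussian-process surrogate
#'
#' Evaluates `n_init` uniform random configurations, then iterates: fit a
#' Gaussian-process regression surrogate (squared-exponential kernel on the
#' unit cube of internal coordinates) to the evaluation history, propose the
#' candidate maximising expected improvement over a random candidate pool,
#' evaluate it. If the surrogate fit fails the round falls back to a random
#' proposal. Returns the argmax of the full history.
#'
#' @inheritParams random_search
#' @param n_init number of initial random evaluations (>= 2).
#' @param n_iter number of surrogate-guided evaluations.
#' @param n_candidates size of the random candidate pool scored per round.
#' @return an `opt_result`; history length is `n_init + n_iter`.
#' @export
bayes_optimize <- function(objective, space, n_init = 5L, n_iter = 20L,
                           n_candidates = 500L, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (!space_is_numeric(space)) {
    stop_talsrx("bayes_optimize supports real/integer parameters only")
  }
  if (!is_count(n_init) || n_init < 2) stop_talsrx("n_init must be >= 2")
  if (!is.numeric(n_iter) || n_iter < 0) stop_talsrx("n_iter must be >= 0")
  f <- safe_objective(objective)
  d <- length(space)
  lb <- vapply(space, function(p) param_bounds_internal(p)[1], numeric(1))
  ub <- vapply(space, function(p) param_bounds_internal(p)[2], numeric(1))
  to_unit <- function(Z) sweep(sweep(Z, 2, lb, "-"), 2, ub - lb, "/")
  set.seed(seed)
  Z <- matrix(stats::runif(n_init * d), n_init, d)
  Z <- sweep(sweep(Z, 2, ub - lb, "*"), 2, lb, "+")
  history <- list()
  vals <- numeric(0)
  for (i in seq_len(n_init)) {
    params <- decode_internal(space, Z[i, ])
    v <- f(params)
    history[[i]] <- list(params = params, objective = v)
    vals[i] <- v
  }
  for (it in seq_len(n_iter)) {
    cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
    cand <- sweep(sweep(cand, 2, ub - lb, "*"), 2, lb, "+")
    finite <- is.finite(vals)
    znext <- NULL
    if (sum(finite) >= 2) {
      znext <- tryCatch({
        fit <- gp_fit(to_unit(Z[finite, , drop = FALSE]), vals[finite])
        pr <- gp_predict(fit, to_unit(cand))
        ei <- expected_improvement(pr$mean, pr$sd, max(vals[finite]))
        cand[which.max(ei), ]
      }, error = function(e) NULL)
    }
    if (is.null(znext)) znext <- cand[1, ] # random fallback round
    params <- decode_internal(space, znext)
    v <- f(params)
    history[[length(history) + 1L]] <- list(params = params, objective = v)
    vals <- c(vals, v)
    Z <- rbind(Z, znext)
  }
  opt_result(history)
}
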