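#' Define a box-constrained search space
#'
#' A search space is a `D`-dimensional box with per-dimension lower and
#' upper bounds. Candidate honey sources are always kept inside it.
#'
#' @param lower,upper Numeric vectors of equal length giving the
#'   per-dimension bounds. `lower[j] <= upper[j]` must hold for all `j`.
#'
#' @return An object of class `search_space` with elements `dim`, `lower`
#'   and `upper`.
#' @examples
#' search_space(rep(-600, 5), rep(600, 5))
#' @export
search_space <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper)) {
    abort("`lower` and `upper` must be numeric vectors.")
  }
  if (length(lower) == 0L || length(lower) != length(upper)) {
    abort("`lower` and `upper` must be non-empty vectors of equal length.")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    abort("search space bounds must be finite.")
  }
  if (any(lower > upper)) {
    bad <- which(lower > upper)
    abort(sprintf(
      "degenerate search space: `lower` exceeds `upper` in dimension(s) %s.",
      paste(bad, collapse = ", ")
    ))
  }
  structure(
    list(dim = length(lower), lower = as.double(lower), upper = as.double(upper)),
    class = "search_space"
  )
}

#' Colony configuration for the ABC / IAABC optimiser
#'
#' Defaults follow the settings used for the spectra-classification study:
#' 35 bees, a retention limit of 100, at most 2000 cycles, inertia-weight
#' bounds \eqn{\omega_{max} = 1.05} and \eqn{\omega_{min} = 0.15}, and an
#' objective precision of 1e-6. The Levy mutation multiplies the
#' difference term of the improved search step (see [candidate_iaabc()]);
#' its defaults (`levy_beta = 1.5`, unit `levy_scale`) are package
#' choices and freely configurable.
#'
#' @param n_sources Number of honey sources (and employed bees) `N`.
#' @param max_cycles Maximum number of cycles (`MaxCycle`).
#' @param limit Retention limit: a source that fails to improve for more
#'   than `limit` trials is abandoned and re-initialised by a scout.
#' @param omega_min,omega_max Bounds of the adaptive inertia weight.
#'   `0 < omega_min <= omega_max` is required; setting the two equal pins
#'   the weight to a constant.
#' @param fitness_tol Stop when the best objective value drops to or below
#'   this precision.
#' @param levy_beta Stability exponent of the Levy mutation, in (1, 2].
#' @param levy_scale Scale of the Levy mutation term relative to the
#'   difference term; 0 disables the mutation, reducing the improved
#'   variant to the standard algorithm when the inertia weight is also
#'   pinned to 1.
#' @param seed Optional integer seed for reproducible runs.
#'
#' @return An object of class `colony_config`.
#' @examples
#' colony_config(n_sources = 35, max_cycles = 2000, limit = 100)
#' @export
colony_config <- function(n_sources = 35L, max_cycles = 2000L, limit = 100L,
                          omega_min = 0.15, omega_max = 1.05,
                          fitness_tol = 1e-6, levy_beta = 1.5,
                          levy_scale = 1, seed = NULL) {
  n_sources <- check_count(n_sources, "n_sources", min = 2L)
  max_cycles <- check_count(max_cycles, "max_cycles", min = 1L)
  limit <- check_count(limit, "limit", min = 1L)
  check_scalar_number(omega_min, "omega_min")
  check_scalar_number(omega_max, "omega_max")
  if (!(omega_min > 0 && omega_min <= omega_max)) {
    abort("inertia bounds must satisfy 0 < omega_min <= omega_max.")
  }
  check_scalar_number(fitness_tol, "fitness_tol")
  check_scalar_number(levy_beta, "levy_beta")
  if (levy_beta <= 1 || levy_beta > 2) {
    abort("`levy_beta` must lie in (1, 2].")
  }
  check_scalar_number(levy_scale, "levy_scale")
  if (levy_scale < 0) abort("`levy_scale` must be >= 0.")
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_sources = n_sources, max_cycles = max_cycles, limit = limit,
      omega_min = omega_min, omega_max = omega_max,
      fitness_tol = fitness_tol, levy_beta = levy_beta,
      levy_scale = levy_scale, seed = seed
    ),
    class = "colony_config"
  )
}

#' Fitness of an objective value
#'
#' Maps an objective (cost) value to the positive "nectar amount" used for
#' greedy and roulette-wheel selection: `1 / (1 + f)` for `f >= 0` and
#' `1 + |f|` otherwise. The map is positive everywhere and strictly
#' decreasing in `f`, so smaller objectives always mean fitter sources.
#'
#' @param objective_value Numeric vector of finite objective values.
#' @return Numeric vector of fitness values, all `> 0`.
#' @examples
#' fitness_of(c(0, 1, -2))
#' @export
fitness_of <- function(objective_value) {
  if (!is.numeric(objective_value) || length(objective_value) == 0L) {
    abort("`objective_value` must be a non-empty numeric vector.")
  }
  if (!all(is.finite(objective_value))) {
    abort("`objective_value` must be finite.")
  }
  ifelse(objective_value >= 0, 1 / (1 + objective_value), 1 + abs(objective_value))
}

#' Roulette-wheel selection probabilities
#'
#' Onlooker bees revisit a source with probability proportional to its
#' fitness.
#'
#' @param fitnesses Numeric vector of positive fitness values.
#' @return Numeric vector of probabilities summing to 1.
#' @examples
#' selection_probabilities(c(1, 3))
#' @export
selection_probabilities <- function(fitnesses) {
  if (!is.numeric(fitnesses) || length(fitnesses) == 0L) {
    abort("`fitnesses` must be a non-empty numeric vector.")
  }
  if (!all(is.finite(fitnesses)) || any(fitnesses <= 0)) {
    abort("all fitness values must be positive and finite.")
  }
  fitnesses / sum(fitnesses)
}

#' Adaptive inertia weight schedule
#'
#' The local-search step is scaled by an inertia weight that decays
#' linearly from `omega_max` at cycle 0 to `omega_min` at the final cycle,
#' shifting the colony from global exploration to local refinement.
#'
#' @param cycle Current cycle, between 0 and `config$max_cycles`.
#' @param config A [colony_config()].
#' @return The inertia weight for `cycle`.
#' @examples
#' inertia_weight(0, colony_config())
#' @export
inertia_weight <- function(cycle, config) {
  check_scalar_number(cycle, "cycle")
  if (cycle < 0 || cycle > config$max_cycles) {
    abort(sprintf("`cycle` must lie in [0, %d].", config$max_cycles))
  }
  config$omega_max - (config$omega_max - config$omega_min) * cycle / config$max_cycles
}

# Mantegna scale parameter sigma_u for a Levy-stable step of exponent beta
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw Levy-flight mutation steps
#'
#' Heavy-tailed random steps generated with Mantegna's algorithm:
#' `L = u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)` and `v ~ N(0, 1)`.
#' Occasional large jumps let the colony escape local optima.
#'
#' @param n Number of draws.
#' @param beta Stability exponent, in (1, 2].
#' @return Numeric vector of `n` Levy steps.
#' @examples
#' set.seed(1)
#' levy_step(5)
#' @export
levy_step <- function(n = 1L, beta = 1.5) {
  n <- check_count(n, "n", min = 1L)
  check_scalar_number(beta, "beta")
  if (beta <= 1 || beta > 2) abort("`beta` must lie in (1, 2].")
  u <- rnorm(n, sd = levy_sigma(beta))
  v <- rnorm(n)
  u / abs(v)^(1 / beta)
}

# shared neighbourhood-search kernel; `omega` scales the difference term and
# `levy` (already scaled by alpha) is added when non-NULL
candidate_kernel <- function(position, partner, space, j, r, omega, levy) {
  v <- position
  step <- omega * r * (position[j] - partner[j])
  if (!is.null(levy)) step <- step + levy
  v[j] <- clamp(position[j] + step, space$lower[j], space$upper[j])
  v
}

#' Basic ABC neighbourhood candidate
#'
#' Perturbs one randomly chosen dimension `j` of a honey source towards or
#' away from a randomly chosen partner source:
#' \eqn{\nu_{ij} = x_{ij} + r (x_{ij} - x_{kj})} with `r` uniform on
#' \eqn{[-1, 1]}. The candidate is clamped to the search-space bounds.
#'
#' @param source,other Positions (numeric vectors) of the reference source
#'   and of a different partner source.
#' @param space The [search_space()].
#' @param j Dimension to perturb; drawn uniformly when `NULL`.
#' @param r Step factor in `[-1, 1]`; drawn uniformly when `NULL`.
#' @return The candidate position vector.
#' @export
candidate_basic <- function(source, other, space, j = NULL, r = NULL) {
  if (identical(source, other)) {
    abort("`other` must be a different honey source than `source` (k != i).")
  }
  j <- j %||% sample.int(space$dim, 1L)
  r <- r %||% runif(1L, -1, 1)
  candidate_kernel(source, other, space, j, r, omega = 1, levy = NULL)
}

#' IAABC neighbourhood candidate with inertia weight and Levy mutation
#'
#' The improved update scales the difference term by the adaptive inertia
#' weight and adds a heavy-tailed Levy mutation step that multiplies the
#' same difference term:
#' \eqn{\nu_{ij} = x_{ij} + \omega r (x_{ij} - x_{kj}) + s (x_{ij} - x_{kj}) L_j(t)}
#' with `s = config$levy_scale`. Because the mutation amplitude tracks
#' the colony spread in dimension `j`, the heavy-tailed jumps are large
#' while the colony still explores and anneal automatically as it
#' converges, so the mutation never destroys late fine refinement. With
#' `omega = 1` and `levy_scale = 0` this reduces exactly to
#' [candidate_basic()].
#'
#' @inheritParams candidate_basic
#' @param omega Inertia weight for the current cycle.
#' @param config A [colony_config()] supplying `levy_beta` and `levy_scale`.
#' @param levy Optional pre-drawn Levy step (unscaled); drawn when `NULL`
#'   and `levy_scale > 0`.
#' @return The candidate position vector.
#' @export
candidate_iaabc <- function(source, other, space, omega,
                            config = colony_config(), j = NULL, r = NULL,
                            levy = NULL) {
  if (identical(source, other)) {
    abort("`other` must be a different honey source than `source` (k != i).")
  }
  j <- j %||% sample.int(space$dim, 1L)
  r <- r %||% runif(1L, -1, 1)
  scaled_levy <- NULL
  if (config$levy_scale > 0) {
    levy <- levy %||% levy_step(1L, config$levy_beta)
    scaled_levy <- config$levy_scale * (source[j] - other[j]) * levy
  }
  candidate_kernel(source, other, space, j, r, omega = omega, levy = scaled_levy)
}

#' Initialise the colony of honey sources
#'
#' Positions are drawn uniformly within the search space,
#' `x_j = lower_j + rand(0,1) (upper_j - lower_j)`, the objective and
#' fitness are evaluated, and the stagnation counter starts at 0.
#'
#' @param objective Objective function mapping a position vector to a
#'   finite scalar cost.
#' @param space A [search_space()].
#' @param config A [colony_config()]; `config$seed` (when set) makes the
#'   draw reproducible.
#' @return A tibble with one row per source and columns `source`,
#'   `position` (list-column), `objective`, `fitness` and `trials`.
#' @export
init_sources <- function(objective, space, config = colony_config()) {
  if (!is.function(objective)) abort("`objective` must be a function.")
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- init_positions(config$n_sources, space)
  obj <- apply(pos, 1L, objective)
  if (!all(is.finite(obj))) {
    abort("objective returned a non-finite value during initialisation.")
  }
  tibble::tibble(
    source = seq_len(config$n_sources),
    position = lapply(seq_len(config$n_sources), function(i) pos[i, ]),
    objective = as.double(obj),
    fitness = fitness_of(obj),
    trials = 0L
  )
}

# uniform initial positions, one row per source
init_positions <- function(n, space) {
  matrix(
    runif(n * space$dim, rep(space$lower, each = n), rep(space$upper, each = n)),
    nrow = n
  )
}

#' Run the ABC or IAABC optimiser
#'
#' Minimises `objective` over a box-constrained search space with an
#' artificial bee colony. Each cycle runs an employed phase (one
#' neighbourhood candidate per source, greedy selection), an onlooker
#' phase (`N` roulette-wheel revisits weighted by fitness), and a scout
#' phase (sources stagnant for more than `limit` trials are re-seeded
#' uniformly). In the `"iaabc"` variant the employed bees use the
#' improved update of [candidate_iaabc()] — the cycle-decaying inertia
#' weight on the difference term plus the Levy mutation — while the
#' onlooker revisits keep the canonical move; `"abc"` is the standard
#' algorithm throughout. Iteration stops when the best objective reaches
#' `fitness_tol` or after `max_cycles` cycles.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param space A [search_space()].
#' @param config A [colony_config()].
#' @param variant `"iaabc"` (default) or `"abc"`.
#'
#' @return An object of class `abc_result` with `best_position`,
#'   `best_objective`, `trace` (tibble of per-cycle best objective,
#'   starting at cycle 0), `cycles_run`, `variant` and `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- abc_optimize(sphere, search_space(c(-5, -5), c(5, 5)),
#'   colony_config(max_cycles = 50, seed = 1))
#' res$best_objective
#' @export
abc_optimize <- function(objective, space, config = colony_config(),
                         variant = c("iaabc", "abc")) {
  variant <- match.arg(variant)
  if (!is.function(objective)) abort("`objective` must be a function.")
  if (!inherits(space, "search_space")) abort("`space` must be a search_space.")
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_sources
  d <- space$dim
  use_levy <- variant == "iaabc" && config$levy_scale > 0

  eval_obj <- function(x, cycle) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      abort(sprintf("objective returned a non-finite value at cycle %d.", cycle))
    }
    as.double(f)
  }

  pos <- init_positions(n, space)
  obj <- vapply(seq_len(n), function(i) eval_obj(pos[i, ], 0L), double(1))
  fit <- fitness_of(obj)
  trials <- integer(n)

  best_i <- which.min(obj)
  best_obj <- obj[best_i]
  best_pos <- pos[best_i, ]
  trace <- numeric(config$max_cycles + 1L)
  trace[1L] <- best_obj
  cycles_run <- 0L

  # one candidate + greedy selection for source i; mutates state in parent.
  # `improved` switches on the inertia weight and Levy mutation (employed
  # phase of the improved variant); plain visits use the canonical update.
  visit <- function(i, omega, cycle, improved) {
    j <- sample.int(d, 1L)
    k <- sample.int(n - 1L, 1L)
    if (k >= i) k <- k + 1L
    r <- runif(1L, -1, 1)
    diff_j <- pos[i, j] - pos[k, j]
    step <- if (improved) omega * r * diff_j else r * diff_j
    if (improved && use_levy) {
      step <- step + config$levy_scale * diff_j * levy_step(1L, config$levy_beta)
    }
    v <- pos[i, ]
    v[j] <- clamp(pos[i, j] + step, space$lower[j], space$upper[j])
    f_v <- eval_obj(v, cycle)
    if (fitness_of(f_v) > fit[i]) { # ties keep the incumbent
      pos[i, ] <<- v
      obj[i] <<- f_v
      fit[i] <<- fitness_of(f_v)
      trials[i] <<- 0L
    } else {
      trials[i] <<- trials[i] + 1L
    }
  }

  improved <- variant == "iaabc"
  for (cycle in seq_len(config$max_cycles)) {
    omega <- if (improved) inertia_weight(cycle, config) else 1

    # employed bees search with the improved update; onlookers re-search
    # good sources with the canonical neighbourhood move
    for (i in seq_len(n)) visit(i, omega, cycle, improved)

    p <- selection_probabilities(fit)
    chosen <- sample.int(n, n, replace = TRUE, prob = p)
    for (i in chosen) visit(i, omega, cycle, improved = FALSE)

    worn <- which(trials > config$limit) # scouts re-seed uniformly
    for (i in worn) {
      pos[i, ] <- init_positions(1L, space)[1L, ]
      obj[i] <- eval_obj(pos[i, ], cycle)
      fit[i] <- fitness_of(obj[i])
      trials[i] <- 0L
    }

    cur_i <- which.min(obj)
    if (obj[cur_i] < best_obj) {
      best_obj <- obj[cur_i]
      best_pos <- pos[cur_i, ]
    }
    cycles_run <- cycle
    trace[cycle + 1L] <- best_obj
    if (best_obj <= config$fitness_tol) break
  }

  structure(
    list(
      best_position = best_pos,
      best_objective = best_obj,
      trace = tibble::tibble(
        cycle = 0:cycles_run,
        best_objective = trace[seq_len(cycles_run + 1L)]
      ),
      cycles_run = cycles_run,
      variant = variant,
      config = config
    ),
    class = "abc_result"
  )
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf(
    "<abc_result> variant = %s, cycles = %d, best objective = %.6g\n",
    x$variant, x$cycles_run, x$best_objective
  ))
  invisible(x)
}

#' @describeIn abc_optimize Per-cycle best-objective trace as a tibble.
#' @param x An `abc_result`.
#' @param ... Unused.
#' @export
tidy.abc_result <- function(x, ...) {
  dplyr::mutate(x$trace, variant = x$variant, .before = 1L)
}

#' @describeIn abc_optimize One-row summary of an optimisation run.
#' @export
glance.abc_result <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_sources = x$config$n_sources,
    cycles_run = x$cycles_run,
    best_objective = x$best_objective,
    converged = x$best_objective <= x$config$fitness_tol
  )
}

#' @describeIn abc_optimize Convergence-trace plot (log10 objective scale).
#' @param object An `abc_result`.
#' @export
autoplot.abc_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$cycle, .data$best_objective)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "cycle", y = "best objective",
      title = sprintf("%s convergence", toupper(object$variant))
    ) +
    ggplot2::theme_minimal()
}

#' Griewank benchmark function
#'
#' `f(x) = 1 + sum(x_i^2) / 4000 - prod(cos(x_i / sqrt(i)))`, with the
#' global minimum `f(0) = 0`, conventionally optimised on
#' `x_i` in `[-600, 600]`. Used to compare ABC and IAABC convergence.
#'
#' @param x Non-empty numeric vector.
#' @return The Griewank value at `x`.
#' @examples
#' griewank(rep(0, 5))
#' @export
griewank <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort("`x` must be a non-empty numeric vector.")
  }
  1 + sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x))))
}

#' Repeat an optimiser benchmark over independent seeded runs
#'
#' Runs [abc_optimize()] on a benchmark objective `runs` times with seeds
#' `seed, seed + 1, ..., seed + runs - 1` and returns all convergence
#' traces stacked in one tibble, ready for comparison plots or medians.
#'
#' @param variant `"iaabc"` or `"abc"`.
#' @param objective Objective function (default [griewank()]).
#' @param dim Problem dimension.
#' @param bounds Length-2 vector of common per-dimension bounds.
#' @param runs Number of independent runs.
#' @param seed Base seed for the first run.
#' @param config A [colony_config()]; its `seed` is overridden per run.
#' @return A tibble with columns `variant`, `run`, `seed`, `cycle`,
#'   `best_objective`.
#' @export
run_benchmark <- function(variant = c("iaabc", "abc"), objective = griewank,
                          dim = 5L, bounds = c(-600, 600), runs = 30L,
                          seed = 1L, config = colony_config()) {
  variant <- match.arg(variant)
  runs <- check_count(runs, "runs", min = 1L)
  space <- search_space(rep(bounds[1L], dim), rep(bounds[2L], dim))
  purrr::map_dfr(seq_len(runs), function(r) {
    cfg <- config
    cfg$seed <- seed + r - 1L
    res <- abc_optimize(objective, space, cfg, variant = variant)
    dplyr::mutate(res$trace, variant = variant, run = r, seed = cfg$seed,
                  .before = 1L)
  })
}
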