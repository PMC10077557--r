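test_that("search spaces and colony configs validate their invariants", {
  sp <- search_space(rep(-600, 5), rep(600, 5))
  expect_equal(sp$dim, 5)
  expect_error(search_space(c(0, 1), c(1, 0)), "degenerate")
  expect_error(search_space(numeric(), numeric()), "non-empty")
  expect_error(colony_config(n_sources = 1), ">=")
  expect_error(colony_config(omega_min = 0.5, omega_max = 0.2), "omega")
  expect_error(colony_config(levy_beta = 2.5), "1, 2")
  # a constant inertia weight (equal bounds) is allowed
  expect_equal(colony_config(omega_min = 1, omega_max = 1)$omega_max, 1)
})

test_that("initial honey sources cover the space and respect the seed", {
  sp <- search_space(rep(-600, 5), rep(600, 5))
  cfg <- colony_config(n_sources = 35, seed = 11)
  col <- init_sources(griewank, sp, cfg)
  expect_equal(nrow(col), 35)
  expect_true(all(lengths(col$position) == 5))
  pos <- do.call(rbind, col$position)
  expect_true(all(pos >= -600 & pos <= 600))
  expect_true(all(col$trials == 0L))
  expect_equal(col$fitness, fitness_of(col$objective))

  col2 <- init_sources(griewank, sp, cfg)
  expect_identical(col$position, col2$position)

  # zero-width space collapses every source onto the single point
  pt <- search_space(c(1, 2), c(1, 2))
  colp <- init_sources(function(x) sum(x^2), pt, colony_config(n_sources = 5))
  expect_true(all(vapply(colp$position, identical, logical(1), c(1, 2))))
})

test_that("fitness and selection probabilities follow the canonical forms", {
  expect_equal(fitness_of(0), 1)
  expect_equal(fitness_of(1), 0.5)
  expect_equal(fitness_of(-2), 3)
  expect_error(fitness_of(NaN), "finite")
  expect_error(fitness_of(Inf), "finite")
  # strictly decreasing in the objective for non-negative objectives
  f <- fitness_of(seq(0, 10, by = 0.5))
  expect_true(all(diff(f) < 0))
  expect_true(all(fitness_of(rnorm(100)) > 0))

  expect_equal(selection_probabilities(rep(2, 8)), rep(1 / 8, 8))
  expect_equal(selection_probabilities(5), 1)
  expect_equal(selection_probabilities(c(1, 3)), c(0.25, 0.75))
  withr::with_seed(2, {
    fit <- runif(50, 0.1, 1)
    p <- selection_probabilities(fit)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(order(p), order(fit)) # order-preserving in fitness
  })
  expect_error(selection_probabilities(numeric()), "non-empty")
})

test_that("the inertia weight decays linearly between its bounds", {
  cfg <- colony_config(omega_min = 0.15, omega_max = 1.05, max_cycles = 2000)
  expect_equal(inertia_weight(0, cfg), 1.05)
  expect_equal(inertia_weight(2000, cfg), 0.15)
  expect_equal(inertia_weight(1000, cfg), 0.60)
  w <- vapply(seq(0, 2000, by = 50), inertia_weight, double(1), config = cfg)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0.15 & w <= 1.05))
  expect_error(inertia_weight(2001, cfg), "\\[0, 2000\\]")
  expect_error(inertia_weight(-1, cfg), "\\[0, 2000\\]")
})

test_that("Levy steps use Mantegna's scale and are heavy-tailed", {
  # closed-form sigma_u at beta = 1.5, evaluated independently
  beta <- 1.5
  sigma_oracle <- (gamma(1 + beta) * sin(pi * beta / 2) /
    (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  expect_equal(sigma_oracle, 0.6966, tolerance = 1e-4)
  expect_equal(uvabc:::levy_sigma(beta), sigma_oracle)

  withr::with_seed(4, {
    l1 <- levy_step(10)
  })
  withr::with_seed(4, {
    l2 <- levy_step(10)
  })
  expect_identical(l1, l2)

  withr::with_seed(6, {
    levy <- levy_step(1e5, beta = 1.5)
    gauss <- rnorm(1e5, sd = sd(levy[abs(levy) < 5]))
    expect_gt(mean(abs(levy) > 5), 0)
    expect_gt(mean(abs(levy) > 5), mean(abs(gauss) > 5))
  })
  expect_error(levy_step(1, beta = 1), "1, 2")
  expect_error(levy_step(1, beta = 2.1), "1, 2")
})

test_that("neighbourhood candidates follow the update algebra and clamp", {
  sp <- search_space(c(-10, -10, -10), c(10, 10, 10))
  x <- c(1, 2, 3)
  k <- c(4, 0, -1)

  # r = 0 leaves the source unchanged
  expect_equal(candidate_basic(x, k, sp, j = 2, r = 0), x)
  # equal coordinates in j leave the source unchanged for any r
  k2 <- c(9, 2, 9)
  expect_equal(candidate_basic(x, k2, sp, j = 2, r = 0.7), x)
  # only dimension j moves
  v <- candidate_basic(x, k, sp, j = 1, r = 0.5)
  expect_equal(v[2:3], x[2:3])
  expect_equal(v[1], 1 + 0.5 * (1 - 4))
  # out-of-bounds candidates are clamped to the violated bound
  xb <- c(9.5, 0, 0)
  kb <- c(-9.5, 0, 0)
  vb <- candidate_basic(xb, kb, sp, j = 1, r = 1)
  expect_equal(vb[1], 10)
  expect_error(candidate_basic(x, x, sp), "different")

  cfg <- colony_config()
  # omega = 0 and no mutation: candidate equals the source
  cfg0 <- colony_config(levy_scale = 0)
  expect_equal(candidate_iaabc(x, k, sp, omega = 0, config = cfg0, j = 1, r = 0.9), x)
  # without mutation the improved update is the basic one scaled by omega
  v1 <- candidate_iaabc(x, k, sp, omega = 0.5, config = cfg0, j = 1, r = 1)
  expect_equal(v1[1], 1 + 0.5 * 1 * (1 - 4))
  v2 <- candidate_iaabc(x, k, sp, omega = 1, config = cfg0, j = 1, r = 1)
  expect_equal(v2[1], 2 * 1 - 4)
  # a pinned Levy draw adds the difference-scaled mutation step
  v3 <- candidate_iaabc(x, k, sp, omega = 1, config = cfg, j = 1, r = 1,
                        levy = 0.25)
  expect_equal(v3[1], 1 + (1 - 4) + cfg$levy_scale * (1 - 4) * 0.25)
  expect_error(candidate_iaabc(x, x, sp, omega = 1), "different")
})

test_that("the Griewank function matches its closed form", {
  expect_identical(griewank(rep(0, 5)), 0)
  expect_identical(griewank(rep(0, 20)), 0)
  expect_equal(griewank(c(pi, 0)), 2 + pi^2 / 4000)
  withr::with_seed(13, {
    for (rep in 1:10) {
      x <- runif(1000 * 5, -600, 600)
      m <- matrix(x, ncol = 5)
      vals <- apply(m, 1, griewank)
      expect_true(all(vals >= 0))
    }
  })
  expect_error(griewank(numeric()), "non-empty")
})

test_that("the optimiser converges on convex objectives and keeps its contracts", {
  sp <- search_space(c(-5, -5), c(5, 5))
  target <- c(1.5, -2)
  res <- abc_optimize(function(x) sum((x - target)^2), sp,
                      colony_config(max_cycles = 2000, seed = 3))
  expect_lte(res$best_objective, 1e-6)
  expect_true(all(diff(res$trace$best_objective) <= 0))
  expect_equal(res$best_objective,
               res$trace$best_objective[nrow(res$trace)])
  expect_true(all(res$best_position >= -5 & res$best_position <= 5))

  # 1-D quadratic: the minimiser itself is recovered (the precision goal
  # is tightened so the early stop does not cap the position accuracy)
  sp1 <- search_space(-4, 4)
  res1 <- abc_optimize(function(x) (x - 0.73)^2, sp1,
                       colony_config(max_cycles = 2000, seed = 5,
                                     fitness_tol = 1e-10))
  expect_lt(abs(res1$best_position - 0.73), 1e-4)

  # early stop on reaching the precision goal
  expect_lt(res1$cycles_run, 2000)

  # seeded runs are reproducible
  cfg <- colony_config(max_cycles = 100, seed = 17)
  r1 <- abc_optimize(griewank, search_space(rep(-600, 3), rep(600, 3)), cfg)
  r2 <- abc_optimize(griewank, search_space(rep(-600, 3), rep(600, 3)), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)

  # non-finite objectives are reported with cycle context
  expect_error(
    abc_optimize(function(x) NA_real_, sp, colony_config(max_cycles = 5)),
    "cycle"
  )
})

test_that("optimiser summaries expose the trace and run facts", {
  res <- abc_optimize(function(x) sum(x^2), search_space(c(-2, -2), c(2, 2)),
                      colony_config(max_cycles = 40, seed = 1), variant = "abc")
  td <- tidy(res)
  expect_equal(nrow(td), res$cycles_run + 1)
  expect_equal(td$variant[1], "abc")
  gl <- glance(res)
  expect_equal(gl$best_objective, res$best_objective)
  expect_equal(gl$n_sources, 35)
})

test_that("benchmark runs stack seeded traces for both variants", {
  cfg <- colony_config(max_cycles = 30)
  tr <- run_benchmark("abc", dim = 2, runs = 3, seed = 5, config = cfg)
  expect_equal(sort(unique(tr$run)), 1:3)
  expect_equal(sort(unique(tr$seed)), 5:7)
  expect_true(all(tr$variant == "abc"))
  finals <- tapply(tr$best_objective, tr$run, function(v) v[length(v)])
  expect_true(all(is.finite(finals)))
})
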