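unit_bounds <- function(dims = c("p1", "p2")) {
  tibble::tibble(parameter = dims, lower = 0, upper = 1)
}

test_that("a single particle does not move", {
  cfg <- swarm_config(unit_bounds("p1"), n_particles = 1)
  part <- tibble::tibble(p1 = 0.4, fitness = -1)
  expect_equal(swarm_step(part, cfg), part)
})

test_that("two equal-fitness particles approach symmetrically", {
  cfg <- swarm_config(unit_bounds("p1"), learning_rate = 0.1)
  part <- tibble::tibble(p1 = c(0.2, 0.8), fitness = c(-1, -1))
  moved <- swarm_step(part, cfg)
  # each steps eta of the way toward the other
  expect_equal(moved$p1, c(0.2 + 0.1 * 0.6, 0.8 - 0.1 * 0.6),
               tolerance = 1e-12)
  expect_equal(mean(moved$p1), 0.5, tolerance = 1e-12)
})

test_that("the movement rule matches a hand-computed attraction sum", {
  pos <- c(0, 0.5, 1)
  fit <- c(-2, -0.5, -1)
  eta <- 0.1; beta <- 10; floor_d <- 1e-6
  cfg <- swarm_config(unit_bounds("p1"), learning_rate = eta,
                      selection_strength = beta)
  moved <- swarm_step(tibble::tibble(p1 = pos, fitness = fit), cfg)

  # independent evaluation of the documented update rule
  w <- exp(beta * (fit - max(fit)) / (max(fit) - min(fit)))
  expected <- sapply(1:3, function(i) {
    d <- abs(pos[-i] - pos[i])
    a <- w[-i] / pmax(d, floor_d)
    target <- sum(pos[-i] * a) / sum(a)
    min(max(pos[i] + eta * (target - pos[i]), 0), 1)
  })
  expect_equal(moved$p1, expected, tolerance = 1e-12)
})

test_that("positions stay inside bounds, including degenerate ones", {
  bounds <- tibble::tibble(parameter = c("p1", "p2"),
                           lower = c(0, 0.3), upper = c(1, 0.3))
  cfg <- swarm_config(bounds, n_particles = 6, seed = 2, max_iterations = 15)
  res <- run_swarm(function(x) -sum((x - c(0.5, 0.3))^2), cfg)
  expect_true(all(res$trace$p1 >= 0 & res$trace$p1 <= 1))
  expect_true(all(res$trace$p2 == 0.3)) # pinned coordinate
})

test_that("the swarm converges on a concave objective", {
  target <- c(0.3, 0.7)
  obj <- function(x) -sum((x - target)^2)
  hits <- sum(sapply(1:25, function(s) {
    res <- run_swarm(obj, swarm_config(unit_bounds(), n_particles = 12,
                                       learning_rate = 0.1,
                                       max_iterations = 60, seed = s))
    sqrt(sum((res$best_position - target)^2)) < 0.05
  }))
  expect_gte(hits, 22) # ~90% of seeds
})

test_that("best-ever fitness is non-decreasing and runs are reproducible", {
  obj <- function(x) -sum((x - 0.4)^2)
  cfg <- swarm_config(unit_bounds("p1"), n_particles = 8, seed = 5,
                      max_iterations = 30)
  res <- run_swarm(obj, cfg)
  best_by_iter <- res$trace |>
    dplyr::group_by(iteration) |>
    dplyr::summarise(best = max(fitness), .groups = "drop")
  expect_true(all(diff(cummax(best_by_iter$best)) >= 0))
  expect_identical(res$trace, run_swarm(obj, cfg)$trace)
})

test_that("a constant objective leaves the best fitness flat", {
  cfg <- swarm_config(unit_bounds(), n_particles = 6, seed = 1,
                      max_iterations = 20)
  res <- run_swarm(function(x) 7, cfg)
  expect_equal(res$best_fitness, 7)
  expect_true(all(res$trace$fitness == 7))
})

test_that("objective failures keep the previous fitness and are logged", {
  calls <- new.env(); calls$n <- 0
  obj <- function(x) {
    calls$n <- calls$n + 1
    if (calls$n %% 7 == 0) stop("simulated instrument failure")
    -sum((x - 0.5)^2)
  }
  cfg <- swarm_config(unit_bounds("p1"), n_particles = 4, seed = 3,
                      max_iterations = 10)
  res <- run_swarm(obj, cfg)
  expect_true(any(res$trace$eval_failed))
  expect_true(is.finite(res$best_fitness))
})

test_that("the gradient-pair step reproduces the worked example", {
  obj <- function(x) -sum(x^2)
  st <- gradient_pair_state(eta = 0.5)
  out <- gradient_pair_step(1, 2, obj, st)
  expect_equal(out$candidate, 0.5)
  expect_true(out$accepted)
  expect_setequal(c(out$point_hi, out$point_lo), c(0.5, 1))
  expect_equal(out$point_hi, 0.5) # candidate is the new best

  # points are re-ordered if given worst-first
  out2 <- gradient_pair_step(2, 1, obj, st)
  expect_equal(out2$candidate, 0.5)
})

test_that("a rejected candidate shrinks the rate and flips direction", {
  # objective peaked between the pair: stepping away from lo overshoots
  obj <- function(x) -(x - 0.9)^2
  st <- gradient_pair_state(eta = 1, shrink = 0.5)
  out <- gradient_pair_step(1, 0.5, obj, st) # candidate 1.5, worse than both
  expect_false(out$accepted)
  expect_equal(out$state$eta, 0.5)
  expect_equal(out$state$sign, -1)
  expect_equal(out$point_hi, 1)
  expect_equal(out$point_lo, 0.5)
  # degenerate pair: candidate equals the point
  out3 <- gradient_pair_step(0.3, 0.3, function(x) -x^2,
                             gradient_pair_state())
  expect_equal(out3$candidate, 0.3)
})

test_that("learning rates of 1 or more oscillate instead of converging", {
  obj <- function(x) -x^2
  hi <- 1; lo <- 2
  st <- list(eta = 1, sign = 1, shrink = 1) # fixed, never shrinks
  widths <- numeric(12)
  f_hi <- obj(hi); f_lo <- obj(lo)
  for (k in 1:12) {
    out <- gradient_pair_step(hi, lo, obj, st, f_hi = f_hi, f_lo = f_lo)
    hi <- out$point_hi; lo <- out$point_lo
    f_hi <- out$f_hi; f_lo <- out$f_lo
    st <- out$state
    widths[k] <- abs(hi - lo)
  }
  # the pair never contracts: the step mirrors the interval each time
  expect_false(all(diff(widths) < 0))
  expect_gt(min(widths), 0.5)
})
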