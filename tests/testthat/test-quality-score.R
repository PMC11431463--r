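# closed forms the scoring components must reproduce
height_oracle <- function(x_bar, mu, sigma) {
  -(x_bar - mu)^2 / (2 * sigma^2) * log10(exp(1))
}
cov_oracle <- function(cv, lambda) -lambda * cv * log10(exp(1))

test_that("height penalty equals its closed form on a grid", {
  grid <- seq(-2000, 12000, length.out = 100)
  expect_equal(height_score(grid, 1000, 500),
               height_oracle(grid, 1000, 500), tolerance = 1e-12)
  expect_identical(height_score(1000, 1000, 500), 0)
  expect_equal(height_score(500, 1000, 500), -0.5 * log10(exp(1)),
               tolerance = 1e-12)
  # symmetric about the ideal
  expect_equal(height_score(500, 1000, 500), height_score(1500, 1000, 500))
})

test_that("COV penalty equals its closed form on a grid", {
  cvs <- seq(0, 5, length.out = 100)
  for (lam in c(0.5, 1, 2)) {
    expect_equal(cov_score(cvs, lam), cov_oracle(cvs, lam),
                 tolerance = 1e-12)
  }
  expect_identical(cov_score(0, 2), 0)
  expect_equal(cov_score(1, 1), -log10(exp(1)), tolerance = 1e-12)
})

test_that("peak COV is the population sd over the powered mean", {
  h <- c(100, 200, 300)
  sd_pop <- sqrt(sum((h - mean(h))^2) / length(h)) # brute-force oracle
  expect_equal(peak_cov(h), sd_pop / mean(h), tolerance = 1e-12)
  expect_equal(peak_cov(h, 0.8), sd_pop / mean(h)^0.8, tolerance = 1e-12)
  expect_equal(peak_cov(rep(123, 10)), 0)
  # zeros for missing alleles inflate the statistic
  expect_gt(peak_cov(c(h, 0, 0)), peak_cov(h))
  expect_error(peak_cov(c(0, 0, 0)), class = "smartpcr_domain_error")
})

test_that("COV from reported moments reproduces the published summaries", {
  expect_equal(round(cov_from_moments(687, 631), 2), 0.92)
  expect_equal(round(cov_from_moments(436, 421), 2), 0.97)
  expect_equal(cov_from_moments(1000, 0), 0)
  expect_error(cov_from_moments(0, 10), class = "smartpcr_domain_error")
})

test_that("the ideal profile scores exactly zero", {
  ref <- example_reference_genotype()
  mu <- 5000
  ideal <- str_profile("ideal",
                       dplyr::mutate(tibble::as_tibble(ref),
                                     height_rfu = mu), ref)
  sb <- score_profile(ideal, t_minutes = 50,
                      params = score_params(mu_a = mu, k3 = 0))
  expect_identical(sb$total, 0)
  expect_identical(sb$height_component, 0)
  expect_identical(sb$cov_component, 0)
  expect_identical(sb$artefact_component, 0)
})

test_that("the total is the weighted sum of closed-form components", {
  ref <- example_reference_genotype()
  prof <- str_profile("s", dplyr::mutate(tibble::as_tibble(ref),
                                         height_rfu = 500), ref)
  params <- score_params(mu_a = 1000, sigma_a = 500, lambda_cov = 2,
                         k0 = 1, k1 = 1, k2 = -1, k3 = -0.05)
  sb <- score_profile(prof, t_minutes = 50, params = params)
  expected <- height_oracle(500, 1000, 500) + cov_oracle(0, 2) +
    (-1) * 0 + (-0.05) * 50
  expect_equal(sb$total, expected, tolerance = 1e-12)
  expect_equal(sb$total, -0.5 * log10(exp(1)) - 2.5, tolerance = 1e-10)

  # one artefact peak shifts the total by k2
  with_art <- prof
  with_art$peaks <- dplyr::bind_rows(
    with_art$peaks,
    tibble::tibble(locus = "QC", allele = "x", size_bp = 93,
                   height_rfu = 2000, dye = "G", artefact = TRUE)
  )
  sb_art <- score_profile(with_art, t_minutes = 50, params = params)
  expect_equal(sb_art$total, sb$total - 1, tolerance = 1e-12)

  # summed-RFU artefact mode scales with total artefact height
  params_rfu <- score_params(mu_a = 1000, sigma_a = 500, lambda_cov = 2,
                             k2 = -0.001, k3 = -0.05,
                             artefact_mode = "summed_rfu")
  sb_rfu <- score_profile(with_art, t_minutes = 50, params = params_rfu)
  expect_equal(sb_rfu$artefact_component, -0.001 * 2000, tolerance = 1e-12)
})

test_that("offsets reduce to the single-constant form when k0 = k1 = 1", {
  ref <- example_reference_genotype()
  prof <- str_profile("s", dplyr::mutate(tibble::as_tibble(ref),
                                         height_rfu = 800), ref)
  mu <- 1000; sigma <- 400; lam <- 2; k2 <- -1; k3 <- -0.02; t <- 45
  sb <- score_profile(prof, t_minutes = t,
                      params = score_params(mu, sigma, lam,
                                            k2 = k2, k3 = k3))
  C <- log10(dnorm(mu, mu, sigma)) + log10(lam)
  raw <- log10(dnorm(800, mu, sigma)) + log10(lam * exp(-lam * sb$cv)) +
    k2 * 0 + k3 * t
  expect_equal(sb$total, raw - C, tolerance = 1e-10)
  expect_equal(sb$offset_constant, C, tolerance = 1e-12)
})

test_that("the score is maximal at the ideal and monotone in cv, na, t", {
  params <- score_params(mu_a = 1000, sigma_a = 300, lambda_cov = 2,
                         k2 = -0.5, k3 = -0.1)
  # height: unique max at mu_a
  xs <- seq(200, 1800, by = 50)
  hs <- height_score(xs, 1000, 300)
  expect_equal(xs[which.max(hs)], 1000)
  expect_true(all(hs[xs != 1000] < 0))
  # strictly decreasing in cv
  expect_true(all(diff(cov_score(seq(0, 3, 0.1), 2)) < 0))
  # strictly decreasing in na and t through the weights
  expect_true(all(diff(params$k2 * 0:5) < 0))
  expect_true(all(diff(params$k3 * seq(0, 60, 10)) < 0))
})

test_that("power-0.8 COV decorrelates balance from mean height", {
  std <- load_program_fixture("globalfiler_standard")
  ref <- example_reference_genotype()
  templates <- exp(seq(log(5), log(500), length.out = 80))
  stats <- purrr::map_dfr(seq_along(templates), function(i) {
    p <- sim_params(template_pg = templates[i])
    prof <- call_alleles(simulate_profile(p, std, ref, seed = 500 + i))
    tibble::tibble(
      mean_height = profile_summary(prof)$x_bar_observed,
      cv1 = profile_summary(prof, cov_power = 1)$cv,
      cv8 = profile_summary(prof, cov_power = 0.8)$cv
    )
  })
  r1 <- cor(stats$mean_height, stats$cv1, method = "spearman")
  r8 <- cor(stats$mean_height, stats$cv8, method = "spearman")
  expect_lt(r1, -0.5) # plain COV strongly anti-correlated with height
  expect_lt(abs(r8), abs(r1)) # the power adjustment shrinks the trend
})

test_that("tidy and glance expose the breakdown", {
  ref <- example_reference_genotype()
  prof <- str_profile("s", dplyr::mutate(tibble::as_tibble(ref),
                                         height_rfu = 900), ref)
  sb <- score_profile(prof, t_minutes = 10)
  td <- tidy(sb)
  expect_setequal(td$component, c("height", "cov", "artefact", "duration"))
  expect_equal(sum(td$penalty), sb$total, tolerance = 1e-12)
  expect_named(glance(sb),
               c("sample", "x_bar_observed", "cv", "n_artefacts",
                 "t_minutes", "total"))
})
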