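test_that("inverse logit is correct and numerically stable", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(inv_logit(log(999)), 0.999)
  expect_equal(inv_logit(-50), 1.928749848e-22, tolerance = 1e-9)
  expect_gt(inv_logit(-745), 0)           # no underflow to exact zero
  expect_equal(inv_logit(745), 1)
  expect_equal(inv_logit(c(-1, 0, 1)), c(plogis(-1), 0.5, plogis(1)))
})

test_that("the linear predictor evaluates the model equation", {
  u <- one_unit("chlorpyrifos", "rural", 20L)
  p0 <- zero_params()
  expect_equal(linear_predictor(p0, u), 0)

  full <- build_design(design_spec(1, 1, 1))
  pops <- unique(full$population_id); clones <- unique(full$clone_id)
  p1 <- zero_params(beta = c(1, rep(0, 7)), pops = pops, clones = clones)
  expect_equal(linear_predictor(p1, full), rep(1, 8))

  # hand evaluation: beta_cpf = -7.86, b_clone = 2, cpf code +0.5
  p2 <- zero_params(beta = c(0, -7.86, rep(0, 6)))
  p2$b_clone[["r1.1"]] <- 2
  expect_equal(linear_predictor(p2, u), 0.5 * (-7.86) + 0.5 * 2)
  expect_equal(linear_predictor(p2, u), -2.93)

  # indicator coding multiplies random effects by 0/1 instead
  expect_equal(linear_predictor(p2, u, re_coding = "indicator"),
               0.5 * (-7.86) + 1 * 2)
})

test_that("log-likelihood matches binomial closed forms", {
  p0 <- zero_params()
  u <- one_unit(n_surviving = 0L)
  expect_equal(log_likelihood(p0, u), 5 * log(0.5), tolerance = 1e-12)

  u2 <- one_unit(n_surviving = 2L)
  expect_equal(log_likelihood(p0, u2), log(10 * 0.5^5), tolerance = 1e-12)

  # certain survival in the saturating limit contributes ~0
  psat <- zero_params(beta = c(40, rep(0, 7)))
  u5 <- one_unit(n_surviving = 5L)
  expect_equal(log_likelihood(psat, u5), 0, tolerance = 1e-10)

  # permutation invariance
  d <- small_dataset(seed = 5)
  g <- toxglmm:::group_indices(d)
  set.seed(1)
  pr <- model_params(rnorm(8), setNames(rnorm(4), g$pop_levels),
                     setNames(rnorm(8), g$clone_levels), 1.1, 0.9, 8)
  perm <- sample(nrow(d))
  expect_equal(log_likelihood(pr, d), log_likelihood(pr, d[perm, ]),
               tolerance = 1e-12)
})

test_that("coding symmetry: flipping the pesticide code and its effects leaves eta unchanged", {
  d <- small_dataset(seed = 6)
  g <- toxglmm:::group_indices(d)
  set.seed(2)
  pr <- model_params(rnorm(8), setNames(rnorm(4), g$pop_levels),
                     setNames(rnorm(8), g$clone_levels), 1.3, 0.8, 12)
  # swap the pesticide labels (flips every cpf code) ...
  d_flip <- d
  d_flip$pesticide <- ifelse(d$pesticide == "control", "chlorpyrifos", "control")
  # ... and flip the sign of every cpf-bearing coefficient and random effect
  pr_flip <- pr
  flip <- c("beta_cpf", "beta_cpf_urb", "beta_cpf_temp", "beta_cpf_urb_temp")
  pr_flip$beta[flip] <- -pr$beta[flip]
  pr_flip$b_pop <- -pr$b_pop
  pr_flip$b_clone <- -pr$b_clone
  expect_equal(linear_predictor(pr, d), linear_predictor(pr_flip, d_flip),
               tolerance = 1e-10)
})

test_that("log-prior matches independent density oracles", {
  # StudentT(3, 0, 5) log-density at 0 via the closed-form normalizer
  oracle_t0 <- log(gamma(2) / (gamma(1.5) * sqrt(3 * pi) * 5))
  u <- one_unit(n_surviving = 3L)
  base <- zero_params()
  lp0 <- log_prior(base)
  one_beta <- base
  one_beta$beta[["beta_cpf"]] <- 0  # still zero: lp0 already has 8 t(0) terms
  # isolate the single-coordinate density by differencing a shifted point
  shifted <- base
  shifted$beta[["beta_cpf"]] <- 3
  d_density <- log_prior(shifted) - lp0
  expect_equal(d_density,
               dt(3 / 5, 3, log = TRUE) - dt(0, 3, log = TRUE),
               tolerance = 1e-12)
  expect_equal(dt(0, 3, log = TRUE) - log(5), oracle_t0, tolerance = 1e-12)

  # Gamma(2, rate 0.1) has its mode at nu = 10
  nus <- seq(0.5, 60, by = 0.1)
  dens <- dgamma(nus, shape = 2, rate = 0.1, log = TRUE)
  expect_equal(nus[which.max(dens)], 10, tolerance = 0.11)

  # clone-effect term approaches the Normal log-density as nu -> infinity
  big_nu <- zero_params(nu = 1e7)
  big_nu$b_clone[["r1.1"]] <- 1.7
  norm_ref <- zero_params(nu = 1e7)
  t_term <- log_prior(big_nu) - log_prior(norm_ref)
  n_term <- dnorm(1.7, 0, 1, log = TRUE) - dnorm(0, 0, 1, log = TRUE)
  expect_equal(t_term, n_term, tolerance = 1e-5)

  # out-of-support parameters are rejected upstream
  expect_error(model_params(base$beta, base$b_pop, base$b_clone, -1, 1, 5),
               class = "toxglmm_params_error")
})

test_that("the StudentT(3,0,5) prior density is proper", {
  total <- integrate(function(x) dt(x / 5, 3) / 5, -1e4, 1e4,
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-4)
})

test_that("log-posterior decomposes and the reparameterization round-trips", {
  d <- small_dataset(seed = 8)
  g <- toxglmm:::group_indices(d)
  pr <- prior_spec()
  set.seed(3)
  for (i in 1:5) {
    p <- model_params(rnorm(8), setNames(rnorm(4), g$pop_levels),
                      setNames(rnorm(8), g$clone_levels),
                      runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 2, 30))
    expect_equal(log_posterior(p, d, pr),
                 log_likelihood(p, d) + log_prior(p, pr), tolerance = 1e-12)
  }
  # round-trip identity on 100 random points
  set.seed(4)
  for (i in 1:100) {
    p <- model_params(rnorm(8), setNames(rnorm(4), g$pop_levels),
                      setNames(rnorm(8), g$clone_levels),
                      runif(1, 0.2, 3), runif(1, 0.2, 3), runif(1, 0.5, 50))
    q <- par_untransform(par_transform(p), g$pop_levels, g$clone_levels)
    expect_equal(unlist(q[1:6]), unlist(p[1:6]), tolerance = 1e-10)
  }
  expect_error(par_untransform(rep(0, 5), g$pop_levels, g$clone_levels),
               class = "toxglmm_params_error")
})

test_that("the unconstrained target differs from likelihood+prior by the Jacobian only", {
  d <- small_dataset(seed = 8)
  g <- toxglmm:::group_indices(d)
  pr <- prior_spec()
  set.seed(5)
  diffs <- vapply(1:5, function(i) {
    p <- model_params(rnorm(8), setNames(rnorm(4), g$pop_levels),
                      setNames(rnorm(8), g$clone_levels),
                      runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 2, 30))
    jac <- (length(g$pop_levels) + 1) * log(p$sigma_pop) +
      (length(g$clone_levels) + 1) * log(p$sigma_clone) + log(p$nu)
    toxglmm:::unconstrained_lp(unname(par_transform(p)), d, pr)$lp -
      log_posterior(p, d, pr) - jac
  }, numeric(1))
  expect_equal(diffs, rep(0, 5), tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  d <- small_dataset(seed = 10)
  prep <- toxglmm:::prepare_model_data(d)
  D <- 8 + prep$npop + prep$nclone + 3
  pr <- unclass(prior_spec())
  lp_at <- function(th) {
    toxglmm:::cpp_lp_grad(th, prep$y, prep$N, prep$X, prep$pop0, prep$npop,
                          prep$clone0, prep$nclone, prep$cre, pr)$lp
  }
  set.seed(6)
  for (rep in 1:20) {
    th <- runif(D, -1.5, 1.5)
    g <- toxglmm:::cpp_lp_grad(th, prep$y, prep$N, prep$X, prep$pop0,
                               prep$npop, prep$clone0, prep$nclone, prep$cre,
                               pr)$grad
    fd <- vapply(seq_len(D), function(j) {
      h <- 1e-6 * max(1, abs(th[j]))
      tp <- th; tp[j] <- th[j] + h
      tm <- th; tm[j] <- th[j] - h
      (lp_at(tp) - lp_at(tm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-5)
  }
})
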