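test_that("truth presets encode the intended generative settings", {
  pl <- truth_preset("paper_like")
  expect_equal(pl$beta[["beta_cpf"]], -7.86)
  expect_equal(pl$sigma_pop, 1.25)
  expect_equal(pl$sigma_clone, 1.12)
  expect_equal(pl$nu, 14.76)
  # derived intercept: control-arm marginal survival ~ 0.999 and the implied
  # exposed-arm survival ~ 0.27
  ctrl <- inv_logit(pl$beta[["beta_0"]] - 0.5 * pl$beta[["beta_cpf"]])
  expo <- inv_logit(pl$beta[["beta_0"]] + 0.5 * pl$beta[["beta_cpf"]])
  expect_equal(ctrl, 0.999, tolerance = 1e-6)
  # medians do not compose exactly across the link, so the implied exposed-arm
  # survival only approximates the reported marginal median
  expect_equal(expo, 0.2707, tolerance = 0.05)

  nl <- truth_preset("null")
  expect_equal(unname(nl$beta), c(2, rep(0, 7)))

  si <- truth_preset("strong_interaction")
  expect_equal(si$beta[["beta_cpf_urb"]], 2 * pl$beta[["beta_cpf_urb"]])

  expect_error(truth_preset("no_such_preset"), class = "toxglmm_truth_error")
  expect_error(simulation_truth(pl$beta, 1, 1, nu = -1),
               class = "toxglmm_truth_error")
  expect_error(simulation_truth(pl$beta, -0.1, 1, nu = 5),
               class = "toxglmm_truth_error")
})

test_that("random-effect draws have the stated distributions", {
  # one clone row per draw; group structure is all the generator needs
  n <- 1e5
  units <- data.frame(population_id = "r1",
                      clone_id = paste0("r1.", seq_len(n)))
  tr <- simulation_truth(truth_preset("null")$beta, sigma_pop = 0,
                         sigma_clone = 1, nu = 1e6)
  re <- draw_random_effects(tr, units, seed = 1)
  expect_equal(re$b_pop[["r1"]], 0)          # degenerate scale boundary
  expect_equal(sd(re$b_clone), 1, tolerance = 0.01)  # t -> Normal limit

  tr3 <- simulation_truth(truth_preset("null")$beta, sigma_pop = 0.5,
                          sigma_clone = 1, nu = 3)
  re3 <- draw_random_effects(tr3, units, seed = 2)
  expect_equal(sd(re3$b_clone), sqrt(3), tolerance = 0.02)  # var = nu/(nu-2)

  expect_identical(draw_random_effects(tr3, units, seed = 7),
                   draw_random_effects(tr3, units, seed = 7))
})

test_that("outcome simulation follows the binomial-logit model", {
  units <- build_design(design_spec(1, 1, 1))
  sat <- simulation_truth(c(beta_0 = 20, beta_cpf = 0, beta_urb = 0,
                            beta_temp = 0, beta_cpf_urb = 0, beta_cpf_temp = 0,
                            beta_urb_temp = 0, beta_cpf_urb_temp = 0),
                          sigma_pop = 0, sigma_clone = 0, nu = 10)
  d <- simulate_outcomes(units, sat, seed = 1)
  expect_true(all(d$n_surviving == d$n_start))  # saturating logit

  # symmetric null: grand mean of y/N ~ 0.5 over 1e4 units
  many <- build_design(design_spec(1, 1, 1250))  # 1e4 units
  nul <- simulation_truth(c(beta_0 = 0, beta_cpf = 0, beta_urb = 0,
                            beta_temp = 0, beta_cpf_urb = 0, beta_cpf_temp = 0,
                            beta_urb_temp = 0, beta_cpf_urb_temp = 0),
                          sigma_pop = 0, sigma_clone = 0, nu = 10)
  d <- simulate_outcomes(many, nul, seed = 2)
  expect_equal(mean(d$n_surviving / d$n_start), 0.5, tolerance = 0.01)

  expect_error(simulate_outcomes(d, nul, seed = 1),
               class = "toxglmm_simulation_error")  # outcomes already present
})

test_that("per-cell survival converges to the inverse-logit of the cell logit", {
  tr <- simulation_truth(c(beta_0 = 0.4, beta_cpf = -2, beta_urb = 0.6,
                           beta_temp = -0.4, beta_cpf_urb = 1, beta_cpf_temp = 0.5,
                           beta_urb_temp = -0.3, beta_cpf_urb_temp = 0.25),
                         sigma_pop = 0, sigma_clone = 0, nu = 10)
  cells <- build_design(design_spec(1, 1, 10000))
  d <- simulate_outcomes(cells, tr, seed = 4)
  eta <- drop(design_matrix(d) %*% tr$beta)
  cell <- interaction(d$pesticide, d$urbanization, d$temperature)
  emp <- tapply(d$n_surviving / d$n_start, cell, mean)
  thr <- tapply(inv_logit(eta), cell, mean)
  expect_equal(unname(emp[names(thr)]), unname(thr), tolerance = 0.02)
})

test_that("paper-like exposure kills: chlorpyrifos arm below control arm", {
  spec <- design_spec(excluded_clones = "u2.5")
  worse <- vapply(1:200, function(s) {
    d <- simulate_dataset(spec, "paper_like", seed = s)
    mean(d$n_surviving[d$pesticide == "chlorpyrifos"] /
           d$n_start[d$pesticide == "chlorpyrifos"]) <
      mean(d$n_surviving[d$pesticide == "control"] /
             d$n_start[d$pesticide == "control"])
  }, logical(1))
  expect_gte(mean(worse), 0.99)
})

test_that("seeding is bit-reproducible and substream-stable", {
  spec <- design_spec(2, 2, 2)
  d1 <- simulate_dataset(spec, "paper_like", seed = 11, n_oversized = 2)
  d2 <- simulate_dataset(spec, "paper_like", seed = 11, n_oversized = 2)
  expect_identical(d1, d2)
  expect_equal(sum(d1$n_start == 6), 2)

  # adding replicates must not perturb the random-effect substreams
  d3 <- simulate_dataset(design_spec(2, 2, 3), "paper_like", seed = 11,
                         n_oversized = 2)
  expect_identical(attr(d1, "random_effects"), attr(d3, "random_effects"))
})
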