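test_that("design expansion reproduces the factorial cardinalities", {
  expect_equal(nrow(build_design(design_spec())), 400)
  expect_equal(nrow(build_design(design_spec(excluded_clones = "u2.5"))), 392)
  expect_equal(nrow(build_design(design_spec(1, 1, 1))), 8)

  # unit count = 2 classes * P * C * 2 * 2 * R - (2*2*R per excluded clone)
  cases <- list(list(P = 3, C = 2, R = 1, ex = character()),
                list(P = 2, C = 4, R = 3, ex = c("r1.2", "u2.4")),
                list(P = 5, C = 5, R = 2, ex = c("u2.5", "r3.1", "u5.5")))
  for (cs in cases) {
    n <- nrow(build_design(design_spec(cs$P, cs$C, cs$R,
                                       excluded_clones = cs$ex)))
    expect_equal(n, 2 * cs$P * cs$C * 4 * cs$R - 4 * cs$R * length(cs$ex))
  }
})

test_that("design ordering is deterministic and excluded clones are absent", {
  spec <- design_spec(excluded_clones = "u2.5",
                      oversized_units = c(3, 10, 100, 392))
  u1 <- build_design(spec)
  u2 <- build_design(spec)
  expect_identical(u1, u2)
  expect_false("u2.5" %in% u1$clone_id)
  expect_equal(sum(u1$n_start == 6), 4)
  expect_equal(which(u1$n_start == 6), c(3, 10, 100, 392))
  expect_true(all(u1$n_start[-c(3, 10, 100, 392)] == 5))
  # sorted by population, clone, pesticide (control first), temperature, replicate
  first8 <- u1[u1$clone_id == u1$clone_id[1], ]
  expect_equal(first8$pesticide, rep(c("control", "chlorpyrifos"), each = 4))
  expect_equal(first8$temperature, rep(rep(c(20L, 24L), each = 2), 2))
  expect_equal(first8$replicate, rep(1:2, 4))
})

test_that("invalid design specs raise labelled errors", {
  expect_error(build_design(design_spec(excluded_clones = "x9.9")),
               class = "toxglmm_design_error")
  expect_error(build_design(design_spec(1, 1, 1, oversized_units = 99)),
               class = "toxglmm_design_error")
})

test_that("covariate coding matches the signed half-unit convention", {
  u <- rbind(one_unit("chlorpyrifos", "urban", 24L),
             one_unit("control", "rural", 20L),
             one_unit("control", "urban", 20L))
  codes <- encode_units(u)
  expect_equal(unlist(codes[1, ]),
               c(cpf = 0.5, urb = 0.5, temp = 0.5, cpf_urb = 0.25,
                 cpf_temp = 0.25, urb_temp = 0.25, cpf_urb_temp = 0.125))
  expect_equal(unlist(codes[2, c("cpf", "urb", "temp", "cpf_urb_temp")]),
               c(cpf = -0.5, urb = -0.5, temp = -0.5, cpf_urb_temp = -0.125))
  expect_equal(codes$cpf_urb[3], -0.25)
  # pure function: identical input, identical output
  expect_identical(codes, encode_units(u))
  # centering: every code column sums to zero over a balanced design
  full <- encode_units(build_design(design_spec()))
  expect_equal(unname(colSums(full)), rep(0, 7))
})

test_that("unit tables round-trip through CSV with validation", {
  d <- simulate_dataset(design_spec(excluded_clones = "u2.5"), "paper_like",
                        seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_units(d, path)
  back <- read_units(path)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  expect_equal(back, d)
})

test_that("validation rejects malformed rows and names them", {
  u <- rbind(one_unit(n_surviving = 3L), one_unit(n_surviving = 7L, replicate = 2L))
  err <- tryCatch(validate_units(u), error = identity)
  expect_s3_class(err, "toxglmm_validation_error")
  expect_match(conditionMessage(err), "row 2")

  # same clone under two populations
  u <- rbind(one_unit(), one_unit(population_id = "r2", replicate = 2L))
  expect_error(validate_units(u), class = "toxglmm_validation_error")

  # missing column
  expect_error(validate_units(one_unit()[, -2]),
               class = "toxglmm_validation_error")

  # non-integer counts
  u <- one_unit()
  u$n_surviving <- 2.5
  expect_error(validate_units(u), class = "toxglmm_validation_error")

  # n_start outside the allowed bound unless the bound is raised
  u <- one_unit(n_start = 9L, n_surviving = 1L)
  expect_error(validate_units(u), class = "toxglmm_validation_error")
  expect_silent(validate_units(u, max_n_start = 10))
})

test_that("the column-mapping shim ingests foreign CSV dialects", {
  d <- small_dataset(seed = 3)
  foreign <- data.frame(Pond = d$population_id, Genotype = d$clone_id,
                        Urb = d$urbanization, Temp = d$temperature,
                        Treat = d$pesticide, Rep = d$replicate,
                        Nstart = d$n_start, Alive = d$n_surviving)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(foreign, path, row.names = FALSE)
  mapping <- c(population_id = "Pond", clone_id = "Genotype",
               urbanization = "Urb", temperature = "Temp",
               pesticide = "Treat", replicate = "Rep",
               n_start = "Nstart", n_surviving = "Alive")
  back <- read_units(path, mapping = mapping)
  expect_equal(back$n_surviving, d$n_surviving)
  expect_equal(back$clone_id, d$clone_id)

  # mapping supplied as a JSON config file
  mpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.list(mapping), mpath, auto_unbox = TRUE)
  back2 <- read_units(path, mapping = mpath)
  expect_equal(back2$n_surviving, d$n_surviving)

  expect_error(read_units(path, mapping = c(n_start = "NoSuchColumn")),
               class = "toxglmm_io_error")
})
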