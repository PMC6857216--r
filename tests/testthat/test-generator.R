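test_that("sampled actors follow the configured marginals", {
  cfg <- generator_config(seed = 1)
  set.seed(424242)
  draws <- replicate(4000, sample_actor(cfg, "x", role = "alter"),
                     simplify = FALSE)
  eth <- vapply(draws, function(d) d$ethnicity, character(1))
  # binomial SE at p = .805, n = 4000 is ~0.006; 2% is a generous band
  expect_equal(mean(eth == "Hausa"), 0.805, tolerance = 0.025)
  age <- vapply(draws, function(d) d$age_group, character(1))
  expect_equal(mean(age == ">=30"), 0.627, tolerance = 0.025)
})

test_that("ego role forces adopter status; singles have NA marriage type", {
  cfg <- generator_config(seed = 2)
  set.seed(7)
  egos <- replicate(50, sample_actor(cfg, "e", role = "ego"),
                    simplify = FALSE)
  expect_true(all(vapply(egos, function(d) d$cbdic_use, character(1)) ==
                  "yes"))
  expect_true(all(vapply(egos, function(d) d$marital_status,
                         character(1)) == "married"))
  # alter-relative attributes are NA on egos
  expect_true(all(is.na(vapply(egos, function(d) d$relationship,
                               character(1)))))

  marg <- default_marginals()
  marg$marital_status <- c(single = 1, married = 0)
  cfg2 <- generator_config(seed = 3, attribute_marginals = marg)
  set.seed(7)
  a <- sample_actor(cfg2, "x", role = "alter")
  expect_equal(a$marital_status, "single")
  expect_true(is.na(a$marriage_type))

  # degenerate marginal pins the level
  marg$ethnicity <- c(Hausa = 1, Others = 0)
  cfg3 <- generator_config(seed = 4, attribute_marginals = marg)
  set.seed(7)
  expect_true(all(replicate(20, sample_actor(cfg3, "x")$ethnicity) ==
                  "Hausa"))

  bad <- default_marginals()
  bad$ethnicity <- c(Hausa = 0.9, Others = 0.9)
  expect_error(generator_config(attribute_marginals = bad),
               "summing to 1")
})

test_that("tie probability endpoints give complete and empty networks", {
  full <- generate_network(generator_config(seed = 1, base_tie_prob = 1),
                           "SNA-A")
  expect_equal(net_density(full), 1)
  empty <- generate_network(
    generator_config(seed = 1, base_tie_prob = 0,
                     homophily_weights = c(ethnicity = 0)),
    "SNA-A")
  expect_equal(directed_tie_count(empty), 0L)
})

test_that("realized density tracks p0 when homophily is off", {
  cfg <- generator_config(seed = 10, base_tie_prob = 0.75,
                          homophily_weights = c(ethnicity = 0))
  dens <- vapply(1:150, function(i) {
    net_density(generate_network(cfg, paste0("R", i)))
  }, numeric(1))
  # mean of 150 x 55 Bernoulli(0.75) draws: SE ~ 0.0048
  expect_lt(abs(mean(dens) - 0.75), 3 * sqrt(0.75 * 0.25 / (150 * 55)))
})

test_that("generation is deterministic and label-stable", {
  cfg <- generator_config(seed = 77, k_egos = 3)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$networks, s2$networks)

  # adding networks never perturbs earlier ones
  s3 <- generate_study(generator_config(seed = 77, k_egos = 5))
  for (lbl in names(s1$networks)) {
    expect_identical(s3$networks[[lbl]], s1$networks[[lbl]])
  }

  # a different seed changes the draw
  s4 <- generate_study(generator_config(seed = 78, k_egos = 3))
  expect_false(identical(s4$networks, s1$networks))
})

test_that("generate_study honours shape parameters", {
  study <- generate_study(generator_config(seed = 1))
  expect_length(study$networks, 20)
  expect_equal(sum(vapply(study$networks, n_actors, integer(1))), 220)
  expect_equal(unname(vapply(study$networks, function(nw) nw$site,
                             character(1))),
               rep(c("A", "B"), each = 10))
  expect_equal(names(study$networks)[1:3],
               c("SNA-A", "SNA-B", "SNA-C"))

  expect_length(generate_study(generator_config(seed = 1,
                                                k_egos = 0))$networks, 0)
})

test_that("generated collections pass model validation end to end", {
  study <- generate_study(generator_config(seed = 31, k_egos = 5))
  for (nw in study$networks) {
    expect_s3_class(nw, "ego_network")
    expect_equal(n_actors(nw), 11L)
    expect_equal(sum(nw$actors$role == "ego"), 1L)
    expect_true(all(nw$ties$from != nw$ties$to))
  }
})

test_that("a YAML config round-trips into a generator_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "k_egos: 3", "base_tie_prob: 0.4",
               "homophily_weights:", "  ethnicity: 2.0",
               "attribute_marginals:", "  ethnicity:",
               "    Hausa: 0.5", "    Others: 0.5"), path)
  cfg <- read_generator_config(path)
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$k_egos, 3L)
  expect_equal(cfg$base_tie_prob, 0.4)
  expect_equal(unname(cfg$homophily_weights["ethnicity"]), 2)
  expect_equal(unname(cfg$attribute_marginals$ethnicity["Hausa"]), 0.5)
  # untouched marginals keep their defaults
  expect_equal(cfg$attribute_marginals$cbdic_use,
               default_marginals()$cbdic_use)
})
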