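test_that("the default study design has 41 sequences from 7 animals", {
  sc <- study_config()
  expect_equal(sc$n_animals, 7)
  expect_equal(sum(sc$sequences_per_animal), 41)
  st <- gen_study(seed = 1, keep_traces = FALSE)
  seqs <- dplyr::distinct(st$table, animal, sequence)
  expect_equal(nrow(seqs), 41)
})

test_that("nesting is conserved between design and long table", {
  st <- gen_study(tiny_study(), seed = 2, keep_traces = FALSE)
  per_animal <- dplyr::count(dplyr::distinct(st$table, animal, sequence), animal)
  expect_equal(per_animal$n, c(2, 2, 2))
  # every sequence belongs to exactly one animal
  x <- dplyr::distinct(st$table, animal, sequence)
  expect_equal(anyDuplicated(x$sequence), 0)
  expect_false(any(is.na(st$table$map)) || any(is.na(st$table$tav)))
})

test_that("with all SDs zero every sequence lies on the same TAV~MAP curve", {
  sc <- tiny_study(animal_sd = 0, sequence_sd = 0, residual_sd = 0,
                   level_jitter = FALSE)
  st <- gen_study(sc, scenario_config("vco", map_noise_cv = 0, noise_sd = 0),
                  seed = 3, keep_traces = FALSE)
  expect_equal(st$table$tav, 8.3 + 0.333 * st$table$map, tolerance = 1e-12)
})

test_that("sequence durations average 50 s within the 30-69 s range", {
  st <- gen_study(seed = 4, keep_traces = FALSE)
  d <- st$effects$durations
  expect_equal(mean(d), 50, tolerance = 1e-9)
  expect_true(all(d > 25 & d < 80))
})

test_that("study generation is deterministic per seed and across modes", {
  a <- gen_study(tiny_study(), seed = 9, keep_traces = FALSE)
  b <- gen_study(tiny_study(), seed = 9, keep_traces = FALSE)
  expect_identical(a$table, b$table)
  # table-only mode matches the fully rendered run bit for bit
  cc <- gen_study(tiny_study(), seed = 9, keep_traces = TRUE)
  expect_identical(a$table, cc$table)
})

test_that("drawn random effects have the configured spread", {
  sc <- study_config(n_animals = 40, sequences_per_animal = rep(2, 40),
                     level_jitter = FALSE)
  st <- gen_study(sc, scenario_config("vco", duration_s = 40), seed = 5,
                  keep_traces = FALSE)
  expect_equal(sd(st$effects$animal$intercept), 9.381, tolerance = 0.25)
  expect_equal(sd(st$effects$sequence$seq_intercept), 2.449, tolerance = 0.25)
  # residual spread on the table after removing the deterministic part
  resid <- st$table$tav - (8.3 + 0.333 * st$table$map)
  eff <- dplyr::left_join(
    dplyr::left_join(st$table, st$effects$sequence, by = c("animal", "sequence")),
    st$effects$animal, by = "animal")
  resid <- resid - eff$intercept - eff$seq_intercept
  expect_equal(sd(resid), 2.449, tolerance = 0.15)
})

test_that("mismatched sequence counts are rejected", {
  expect_error(study_config(n_animals = 3, sequences_per_animal = c(2, 2)),
               class = "pwdop_config_error")
  expect_error(study_config(animal_sd = -1), class = "pwdop_config_error")
})
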