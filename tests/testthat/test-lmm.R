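# small simulated study table without the trace machinery
sim_table <- function(seed, n_animals = 7, n_seq = 6, n_obs = 60,
                      sd_a = 9.381, sd_s = 2.449, sd_e = 2.449,
                      beta = c(8.3, 0.333, 0)) {
  withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_animals)) {
      a <- rnorm(1, 0, sd_a)
      for (j in seq_len(n_seq)) {
        b <- rnorm(1, 0, sd_s)
        map <- seq(86, 23, length.out = n_obs)
        tav <- beta[1] + beta[2] * map + beta[3] * map^2 + a + b +
          rnorm(n_obs, 0, sd_e)
        out[[length(out) + 1]] <- tibble::tibble(
          animal = paste0("a", i), sequence = paste0("a", i, "_s", j),
          map = map, tav = tav)
      }
    }
    dplyr::bind_rows(out)
  })
}

test_that("noise-free data with no random effects recovers the coefficients", {
  d <- sim_table(1, n_animals = 3, n_seq = 2, n_obs = 30,
                 sd_a = 0, sd_s = 0, sd_e = 1e-8,
                 beta = c(5, 0.4, -0.001))
  fit <- suppressMessages(suppressWarnings(fit_lmm(d)))
  expect_equal(unname(fit$beta), c(5, 0.4, -0.001), tolerance = 1e-4)
  expect_lt(sum(fit$components$variance), 1e-6)
})

test_that("slope estimate covers the truth across seeded replicates", {
  hits <- 0
  for (s in 1:10) {
    d <- sim_table(s, n_animals = 5, n_seq = 3, n_obs = 40)
    fit <- fit_lmm(d, degree = 1)
    se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))[2]
    ci <- fit$beta["beta1"] + c(-2, 2) * se
    hits <- hits + (ci[1] <= 0.333 && 0.333 <= ci[2])
  }
  expect_gte(hits, 9)
})

test_that("fit preconditions are enforced", {
  d <- sim_table(2, n_animals = 2, n_seq = 2, n_obs = 20)
  expect_error(fit_lmm(d), class = "pwdop_data_error")
  d1 <- sim_table(3, n_animals = 4, n_seq = 1, n_obs = 20)
  expect_error(fit_lmm(d1), class = "pwdop_data_error")
  d2 <- sim_table(4, n_animals = 3, n_seq = 2, n_obs = 20)
  d2$tav[1] <- NA
  expect_error(fit_lmm(d2), class = "pwdop_data_error")
})

test_that("ICC ratios follow the variance decomposition identities", {
  icc <- compute_icc(fake_fit(88, 6, 6))
  expect_equal(icc$icc, c(0.88, 0.94))
  expect_equal(compute_icc(fake_fit(0, 0, 10))$icc, c(0, 0))
  expect_equal(compute_icc(fake_fit(50, 25, 25))$icc, c(0.50, 0.75))
  expect_true(all(is.nan(compute_icc(fake_fit(0, 0, 0))$icc)))
  # scale invariance
  for (k in c(0.1, 3, 1e4)) {
    expect_equal(compute_icc(fake_fit(88 * k, 6 * k, 6 * k))$icc,
                 c(0.88, 0.94), tolerance = 1e-12)
  }
  # within-animal ICC always dominates the animal-level ICC
  set.seed(6)
  for (i in 1:10) {
    v <- runif(3, 0, 10)
    icc <- compute_icc(fake_fit(v[1], v[2], v[3]))$icc
    expect_gte(icc[2], icc[1])
  }
})

test_that("ICC recovery is unbiased enough on the reference design", {
  iccs <- vapply(1:6, function(s) {
    fit <- fit_lmm(sim_table(s))
    compute_icc(fit)$icc
  }, numeric(2))
  expect_gt(mean(iccs[1, ]), 0.75)
  expect_lt(mean(iccs[1, ]), 0.95)
  expect_gt(mean(iccs[2, ]), 0.88)
})

test_that("bootstrap intervals contain the point estimate", {
  d <- sim_table(7, n_animals = 5, n_seq = 3, n_obs = 30)
  fit <- fit_lmm(d)
  ci <- suppressWarnings(icc_ci(fit, n_boot = 40, seed = 1))
  expect_true(all(ci$conf_low <= ci$icc + 1e-9))
  expect_true(all(ci$conf_high >= ci$icc - 1e-9))
  pt <- icc_ci(fit, n_boot = 0)
  expect_true(all(is.na(pt$conf_low)))
  expect_equal(pt$icc, compute_icc(fit)$icc)
})

test_that("fits are invariant to relabeling but not to re-nesting", {
  d <- sim_table(8, n_animals = 4, n_seq = 3, n_obs = 25)
  fit <- fit_lmm(d)
  # permute sequence labels within one animal
  d2 <- d
  d2$sequence[d2$sequence == "a1_s1"] <- "tmp"
  d2$sequence[d2$sequence == "a1_s2"] <- "a1_s1"
  d2$sequence[d2$sequence == "tmp"] <- "a1_s2"
  fit2 <- fit_lmm(d2)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit$components$variance, fit2$components$variance,
               tolerance = 1e-6)
  # move a whole sequence to a different animal: animal variance changes
  d3 <- d
  d3$animal[d3$sequence == "a1_s1"] <- "a2"
  fit3 <- fit_lmm(d3)
  expect_gt(abs(fit3$components$variance[1] - fit$components$variance[1]),
            1e-4)
})

test_that("per-animal predictions collapse when random effects vanish", {
  d <- sim_table(9, n_animals = 3, n_seq = 2, n_obs = 30,
                 sd_a = 0, sd_s = 0, sd_e = 0.01)
  fit <- suppressMessages(suppressWarnings(fit_lmm(d)))
  pred <- predict_per_animal(fit, n_points = 11)
  spread <- pred |> dplyr::group_by(map) |>
    dplyr::summarise(d = max(tav_pred) - min(tav_pred))
  expect_lt(max(spread$d), 0.2)
  expect_error(predict_per_animal(fit, map_range = c(0, 300)),
               class = "pwdop_data_error")
})

test_that("random-slopes fits stay usable and ICC falls back to intercepts", {
  d <- sim_table(10, n_animals = 5, n_seq = 3, n_obs = 30)
  fit <- suppressMessages(suppressWarnings(
    fit_lmm(d, random_slopes = TRUE)))
  icc <- compute_icc(fit)
  expect_true(all(icc$icc >= 0 & icc$icc <= 1))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(glance(fit)$random_slopes)
})
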