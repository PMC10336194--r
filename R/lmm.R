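#' Fit the hierarchical TAV ~ MAP linear mixed model
#'
#' Fits `TAV = beta0 + beta1*MAP + beta2*MAP^2 + a_animal +
#' b_sequence(animal) [+ per-animal random MAP slopes] + e` on a long-format
#' study table, with sequences nested within animals as random intercepts.
#' MAP is centred at its grand mean before polynomial expansion (for
#' conditioning) and the fixed coefficients are reported back on the raw MAP
#' scale. REML is the default estimator: with a handful of animals, maximum
#' likelihood underestimates the animal-level variance (and hence the ICC),
#' while REML removes the fixed-effect degrees of freedom from the variance
#' estimates.
#'
#' @param table Data frame with columns `animal`, `sequence`, `map`, `tav`
#'   (a `study_dataset$table` works as is).
#' @param degree Polynomial degree of MAP in the fixed part (1 or 2).
#'   Default 2.
#' @param random_slopes Also give each animal random slopes on the centred
#'   MAP polynomial? Default FALSE.
#' @param method `"REML"` (default) or `"ML"`.
#' @return An object of class `lmm_fit` wrapping the `lme4` fit plus tidy
#'   variance components, raw-scale fixed effects and the input data.
#' @export
fit_lmm <- function(table, degree = 2, random_slopes = FALSE,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(all(c("animal", "sequence", "map", "tav") %in% names(table)))
  if (!all(is.finite(table$map)) || !all(is.finite(table$tav)))
    stop_data("`map` and `tav` must be finite")
  if (dplyr::n_distinct(table$animal) < 3)
    stop_data("need at least 3 animals")
  seq_counts <- table |> dplyr::distinct(.data$animal, .data$sequence) |>
    dplyr::count(.data$animal)
  if (any(seq_counts$n < 2))
    stop_data("need at least 2 sequences per animal")
  if (!degree %in% 1:2) stop_config("`degree` must be 1 or 2")

  d <- table
  map_center <- mean(d$map)
  d$map_c <- d$map - map_center
  d$map_c2 <- d$map_c^2
  fixed <- if (degree == 2) "tav ~ map_c + map_c2" else "tav ~ map_c"
  re <- "(1 | animal) + (1 | animal:sequence)"
  if (random_slopes) {
    re <- paste(re, if (degree == 2) "+ (0 + map_c + map_c2 | animal)"
                else "+ (0 + map_c | animal)")
  }
  form <- stats::as.formula(paste(fixed, "+", re))
  fit <- lme4::lmer(form, data = d, REML = method == "REML",
                    control = lme4::lmerControl(calc.derivs = TRUE))
  conv <- is.null(fit@optinfo$conv$lme4$messages)
  grad <- tryCatch(max(abs(fit@optinfo$derivs$gradient)), error = function(e) NA)
  # hard failure only when the optimizer itself reports one; lme4's gradient
  # warnings are recorded in `converged` but left to the caller
  if (isTRUE(fit@optinfo$conv$opt != 0))
    stop_convergence(sprintf("mixed-model optimizer failed (|grad| = %.3g)",
                             grad))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- tibble(
    component = c("animal", "sequence", "residual"),
    variance = c(
      vc$vcov[vc$grp == "animal" & vc$var1 == "(Intercept)"][1],
      vc$vcov[vc$grp == "animal:sequence"][1],
      vc$vcov[vc$grp == "Residual"][1]))
  # back-transform the centred polynomial to raw-MAP coefficients
  b <- lme4::fixef(fit)
  b2 <- if (degree == 2) b[["map_c2"]] else 0
  b1 <- b[["map_c"]] - 2 * b2 * map_center
  b0 <- b[["(Intercept)"]] - b[["map_c"]] * map_center + b2 * map_center^2
  structure(
    list(model = fit, beta = c(beta0 = unname(b0), beta1 = unname(b1),
                               beta2 = unname(b2)),
         components = comp, method = method, degree = degree,
         random_slopes = random_slopes, map_center = map_center,
         converged = conv, loglik = as.numeric(stats::logLik(fit)),
         data = d),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s, degree %d%s; beta = (%.3f, %.4f, %.2e); var(a/s/e) = (%.2f, %.2f, %.2f)\n",
    x$method, x$degree, if (x$random_slopes) " + random slopes" else "",
    x$beta[1], x$beta[2], x$beta[3],
    x$components$variance[1], x$components$variance[2], x$components$variance[3]))
  invisible(x)
}

#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$beta), estimate = unname(x$beta),
           type = "fixed"),
    tibble(term = paste0("var_", x$components$component),
           estimate = x$components$variance, type = "variance"))
}

#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(method = x$method, degree = x$degree,
         random_slopes = x$random_slopes, logLik = x$loglik,
         converged = x$converged, nobs = nrow(x$data))
}

#' Intraclass correlation coefficients from the variance decomposition
#'
#' `icc_animal = s2_a / (s2_a + s2_s + s2_e)` and
#' `icc_within = (s2_a + s2_s) / (s2_a + s2_s + s2_e)`: the correlation
#' between observations from the same animal (different sequences) and from
#' the same sequence, respectively. Under random slopes the intercept
#' decomposition is not constant in MAP, so the ICC is always computed from a
#' companion intercepts-only REML fit (refit internally when needed); the
#' slopes model remains available for prediction.
#'
#' @param fit An `lmm_fit`.
#' @return An `icc_result` tibble: `level` (`animal`, `within_animal`),
#'   `icc`. All-zero variance components give `NaN` (undefined sentinel).
#' @examples
#' # components 88 : 6 : 6 give ICCs 0.88 and 0.94
#' @export
compute_icc <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  comp <- icc_basis_fit(fit)$components
  v <- comp$variance
  tot <- sum(v)
  icc <- if (tot == 0) c(NaN, NaN) else c(v[1] / tot, (v[1] + v[2]) / tot)
  out <- tibble(level = c("animal", "within_animal"), icc = icc)
  class(out) <- c("icc_result", class(out))
  out
}

# the intercepts-only REML fit the ICC decomposition is defined on
icc_basis_fit <- function(fit) {
  if (!fit$random_slopes && fit$method == "REML") return(fit)
  fit_lmm(fit$data, degree = fit$degree, random_slopes = FALSE,
          method = "REML")
}

#' Parametric-bootstrap confidence intervals for the ICCs
#'
#' Simulates `n_boot` response vectors from the fitted intercepts-only
#' model, refits each, and returns percentile intervals for both ICCs.
#'
#' @param fit An `lmm_fit`.
#' @param n_boot Number of bootstrap replicates. Default 200. With
#'   `n_boot = 0` the point estimates are returned without intervals.
#' @param level Confidence level. Default 0.95.
#' @param seed Optional integer seed.
#' @return An `icc_result` tibble with columns `level`, `icc`, `conf_low`,
#'   `conf_high`, plus attributes `n_boot` and `failed` (refit failures; a
#'   warning condition is attached when more than 20% fail).
#' @export
icc_ci <- function(fit, n_boot = 200, level = 0.95, seed = NULL) {
  base <- icc_basis_fit(fit)
  pt <- compute_icc(base)
  if (n_boot == 0) {
    pt$conf_low <- NA_real_
    pt$conf_high <- NA_real_
    return(pt)
  }
  sims <- with_seed_opt(seed, stats::simulate(base$model, nsim = n_boot))
  boots <- matrix(NA_real_, n_boot, 2)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    fb <- tryCatch(lme4::refit(base$model, newresp = sims[[b]]),
                   error = function(e) NULL, warning = function(w) {
                     suppressWarnings(lme4::refit(base$model,
                                                  newresp = sims[[b]]))
                   })
    if (is.null(fb)) { failed <- failed + 1L; next }
    vc <- as.data.frame(lme4::VarCorr(fb))
    va <- vc$vcov[vc$grp == "animal"][1]
    vs <- vc$vcov[vc$grp == "animal:sequence"][1]
    ve <- vc$vcov[vc$grp == "Residual"][1]
    tot <- va + vs + ve
    if (tot > 0) boots[b, ] <- c(va / tot, (va + vs) / tot)
  }
  if (failed > 0.2 * n_boot)
    warn(sprintf("bootstrap refit failure rate %.0f%% exceeds 20%%",
                 100 * failed / n_boot))
  a <- (1 - level) / 2
  qs <- apply(boots, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  pt$conf_low <- qs[1, ]
  pt$conf_high <- qs[2, ]
  attr(pt, "n_boot") <- n_boot
  attr(pt, "failed") <- failed
  pt
}

#' Per-animal fitted TAV-vs-MAP curves
#'
#' Evaluates the fixed part plus each animal's random effects (sequence
#' effects excluded) over that animal's observed MAP range, for Fig-style
#' per-animal prediction plots. Requests outside an animal's observed range
#' (beyond a 10% margin) are refused rather than extrapolated.
#'
#' @param fit An `lmm_fit`.
#' @param n_points Grid points per animal. Default 50.
#' @param map_range Optional explicit MAP range (applied to every animal,
#'   checked against the observed range).
#' @return A tibble: `animal`, `map`, `tav_pred`.
#' @export
predict_per_animal <- function(fit, n_points = 50, map_range = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  d <- fit$data
  ranges <- d |> group_by(.data$animal) |>
    summarise(lo = min(.data$map), hi = max(.data$map), .groups = "drop")
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- ranges$lo[i]; hi <- ranges$hi[i]
    margin <- 0.1 * (hi - lo)
    if (!is.null(map_range)) {
      if (map_range[1] < lo - margin || map_range[2] > hi + margin)
        stop_data(sprintf(
          "requested MAP range extrapolates beyond animal %s's data",
          ranges$animal[i]))
      lo <- map_range[1]; hi <- map_range[2]
    }
    grid <- tibble(
      animal = ranges$animal[i],
      map = seq(lo, hi, length.out = n_points))
    grid$map_c <- grid$map - fit$map_center
    grid$map_c2 <- grid$map_c^2
    re_form <- if (fit$random_slopes) {
      if (fit$degree == 2) ~(1 | animal) + (0 + map_c + map_c2 | animal)
      else ~(1 | animal) + (0 + map_c | animal)
    } else ~(1 | animal)
    grid$tav_pred <- predict(fit$model, newdata = grid, re.form = re_form)
    grid[, c("animal", "map", "tav_pred")]
  })
  bind_rows(out)
}
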