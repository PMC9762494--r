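#' Hyperelastic material parameter sets
#'
#' Coefficients of a named incompressible hyperelastic model family, MPa:
#' * `yeoh3`: `C10`, `C20`, `C30` — strain energy in powers of `I1 - 3`.
#' * `mooney_rivlin`: `C10`, `C01`.
#' * `ogden1`: `mu1` (MPa), `alpha1` (dimensionless) — first-order Ogden.
#' * `neo_hookean`: `C10`.
#'
#' @param model_name model family id.
#' @param coefficients named list/vector of coefficients.
#' @return A list of class `hyperelastic_params`.
#' @export
hyperelastic_params <- function(model_name, coefficients) {
  need <- switch(model_name,
    yeoh3 = c("C10", "C20", "C30"),
    mooney_rivlin = c("C10", "C01"),
    ogden1 = c("mu1", "alpha1"),
    neo_hookean = "C10",
    stop(sprintf("unknown hyperelastic model '%s'", model_name), call. = FALSE)
  )
  coefficients <- as.list(coefficients)
  if (!all(need %in% names(coefficients))) {
    stop(sprintf("model '%s' needs coefficients: %s", model_name,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  structure(list(model_name = model_name,
                 coefficients = coefficients[need]),
            class = "hyperelastic_params")
}

n_coefficients <- function(model_name) {
  switch(model_name, yeoh3 = 3L, mooney_rivlin = 2L, ogden1 = 2L, neo_hookean = 1L,
         stop("unknown model", call. = FALSE))
}

#' Uniaxial nominal stress of an incompressible hyperelastic model
#'
#' First Piola-Kirchhoff (nominal) stress under incompressible uniaxial
#' extension at stretch `lambda` (`I1 = lambda^2 + 2 / lambda`):
#' * yeoh3: `2 (l - l^-2) [C10 + 2 C20 (I1 - 3) + 3 C30 (I1 - 3)^2]`
#' * mooney_rivlin: `2 (l - l^-2) (C10 + C01 / l)`
#' * neo_hookean: `2 (l - l^-2) C10`
#' * ogden1: `(2 mu1 / alpha1) (l^(alpha1 - 1) - l^(-alpha1/2 - 1))`
#'
#' All models give zero stress at `lambda = 1`; the small-strain Young's
#' modulus is `6 C10` (yeoh3, neo-Hookean), `6 (C10 + C01)`
#' (Mooney-Rivlin) and `3 mu1` (Ogden).
#'
#' @param params a [hyperelastic_params()].
#' @param lambda stretch (> 0), vectorized.
#' @return Nominal stress, MPa.
#' @export
uniaxial_stress <- function(params, lambda) {
  if (!inherits(params, "hyperelastic_params")) {
    stop("`params` must be a hyperelastic_params object", call. = FALSE)
  }
  stopifnot(all(lambda > 0))
  cf <- params$coefficients
  base <- 2 * (lambda - lambda^-2)
  I1 <- lambda^2 + 2 / lambda
  switch(params$model_name,
    yeoh3 = base * (cf$C10 + 2 * cf$C20 * (I1 - 3) + 3 * cf$C30 * (I1 - 3)^2),
    mooney_rivlin = base * (cf$C10 + cf$C01 / lambda),
    neo_hookean = base * cf$C10,
    ogden1 = (2 * cf$mu1 / cf$alpha1) *
      (lambda^(cf$alpha1 - 1) - lambda^(-cf$alpha1 / 2 - 1))
  )
}

#' Scale a macroscopic load to a representative volume element
#'
#' Equal-stress scaling: `F_rve = F_macro * A_rve / A_macro`, so that the
#' RVE experiences the same nominal stress as the macroscopic sample.
#'
#' @param F_macro macroscopic load, N.
#' @param A_macro macroscopic cross-section, m^2.
#' @param A_rve RVE cross-section, m^2.
#' @return RVE load, N.
#' @export
scale_load_to_rve <- function(F_macro, A_macro, A_rve) {
  stopifnot(A_macro > 0, A_rve > 0)
  F_macro * A_rve / A_macro
}

as_curve_tibble <- function(curve) {
  stopifnot(is.data.frame(curve))
  if (!"stretch" %in% names(curve)) {
    if ("strain" %in% names(curve)) curve$stretch <- 1 + curve$strain
    else stop("curve needs a `stretch` or `strain` column", call. = FALSE)
  }
  if (!"strain" %in% names(curve)) curve$strain <- curve$stretch - 1
  if (!"stress_MPa" %in% names(curve)) stop("curve needs a `stress_MPa` column", call. = FALSE)
  if (is.unsorted(curve$stretch, strictly = FALSE)) {
    stop("stretch must be non-decreasing", call. = FALSE)
  }
  curve
}

#' Fit a hyperelastic model to a uniaxial curve
#'
#' Least-squares fit of the model's uniaxial closed form to
#' `(stretch, nominal stress)` data. Yeoh, Mooney-Rivlin and neo-Hookean
#' stresses are linear in their coefficients and are fitted by ordinary
#' least squares; the first-order Ogden model is fitted by
#' Levenberg-Marquardt with small-strain-slope starting values.
#'
#' @param curve a data frame with `stretch` (or `strain`) and `stress_MPa`.
#' @param model_name model family id (see [hyperelastic_params()]).
#' @return An object of class `hyperelastic_fit`: `params`
#'   ([hyperelastic_params()]), `fit_mse` (MPa^2), `stable` (tangent
#'   modulus positive over the fitted range), `n`, `model_name`,
#'   `fitted` (tibble with `stretch`, `stress_MPa`, `fitted`).
#' @export
fit_hyperelastic <- function(curve, model_name = "yeoh3") {
  curve <- as_curve_tibble(curve)
  lam <- curve$stretch
  sig <- curve$stress_MPa
  p <- n_coefficients(model_name)
  if (length(lam) < 2 * p) {
    stop("need at least twice as many points as coefficients", call. = FALSE)
  }
  base <- 2 * (lam - lam^-2)
  I1 <- lam^2 + 2 / lam
  cf <- switch(model_name,
    yeoh3 = {
      X <- cbind(C10 = base, C20 = 2 * base * (I1 - 3), C30 = 3 * base * (I1 - 3)^2)
      as.list(stats::lm.fit(X, sig)$coefficients)
    },
    mooney_rivlin = {
      X <- cbind(C10 = base, C01 = base / lam)
      as.list(stats::lm.fit(X, sig)$coefficients)
    },
    neo_hookean = {
      X <- cbind(C10 = base)
      as.list(stats::lm.fit(X, sig)$coefficients)
    },
    ogden1 = {
      # start from the small-strain slope (E ~ 3 mu) and alpha = 2 (neo-Hookean)
      pos <- which(curve$strain > 0)
      E0 <- if (length(pos)) sig[pos[1]] / curve$strain[pos[1]] else 1
      fit <- minpack.lm::nlsLM(
        sig ~ (2 * mu1 / alpha1) * (lam^(alpha1 - 1) - lam^(-alpha1 / 2 - 1)),
        start = list(mu1 = max(E0 / 3, 1e-6), alpha1 = 2),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      as.list(stats::coef(fit))
    },
    stop(sprintf("unknown hyperelastic model '%s'", model_name), call. = FALSE)
  )
  params <- hyperelastic_params(model_name, cf)
  pred <- uniaxial_stress(params, lam)
  mse <- mean((pred - sig)^2)
  # stability: tangent modulus positive across the fitted stretch range
  lg <- seq(min(lam), max(lam), length.out = 200)
  lg <- pmax(lg, 1 + 1e-6)
  dl <- 1e-6
  tangent <- (uniaxial_stress(params, lg + dl) - uniaxial_stress(params, lg - dl)) / (2 * dl)
  stable <- all(tangent > 0)
  structure(list(
    params = params, fit_mse = mse, stable = stable,
    n = length(lam), model_name = model_name,
    fitted = tibble::tibble(stretch = lam, stress_MPa = sig, fitted = pred)
  ), class = "hyperelastic_fit")
}

#' @export
print.hyperelastic_fit <- function(x, ...) {
  cf <- unlist(x$params$coefficients)
  cat(sprintf("<hyperelastic_fit> %s: %s\n", x$model_name,
              paste(sprintf("%s = %.5g", names(cf), cf), collapse = ", ")))
  cat(sprintf("  MSE %.4e MPa^2 on %d points; %s\n", x$fit_mse, x$n,
              if (x$stable) "stable" else "UNSTABLE (non-monotone tangent)"))
  invisible(x)
}

#' Fit several hyperelastic models and rank them
#'
#' All candidates are fitted; stable fits are ranked by mean squared error,
#' unstable fits after them. Among stable fits whose MSE is within
#' `tie_tol` (relative, plus a negligible absolute floor) of the minimum,
#' the model with the fewest coefficients is selected, so a needlessly
#' rich model never wins on a numerically irrelevant MSE margin.
#'
#' @param curve uniaxial data (see [fit_hyperelastic()]).
#' @param candidates character vector of model ids (>= 2, or 1 for a
#'   trivial selection).
#' @param tie_tol relative MSE tie tolerance (default 0.1).
#' @return A list of class `model_selection`: `ranking` (tibble with
#'   `model`, `n_params`, `mse`, `stable`, `selected`), `best`
#'   (the selected [fit_hyperelastic()] object).
#' @export
select_best_model <- function(curve,
                              candidates = c("yeoh3", "mooney_rivlin",
                                             "ogden1", "neo_hookean"),
                              tie_tol = 0.1) {
  stopifnot(length(candidates) >= 1)
  fits <- list()
  for (m in candidates) {
    fits[[m]] <- tryCatch(fit_hyperelastic(curve, m), error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all hyperelastic fits failed", call. = FALSE)
  fits <- fits[ok]
  tab <- tibble::tibble(
    model = names(fits),
    n_params = vapply(names(fits), n_coefficients, integer(1)),
    mse = vapply(fits, function(f) f$fit_mse, numeric(1)),
    stable = vapply(fits, function(f) f$stable, logical(1))
  )
  tab <- dplyr::arrange(tab, dplyr::desc(.data$stable), .data$mse, .data$n_params)
  stable_tab <- tab[tab$stable, , drop = FALSE]
  pool <- if (nrow(stable_tab)) stable_tab else tab
  scale2 <- max(stats::quantile(abs(as_curve_tibble(curve)$stress_MPa), 0.9)^2, 1e-300)
  best_mse <- min(pool$mse)
  tied <- pool$mse <= best_mse * (1 + tie_tol) + 1e-12 * scale2
  sel <- pool$model[tied][which.min(pool$n_params[tied])]
  tab$selected <- tab$model == sel
  structure(list(ranking = tab, best = fits[[sel]]), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>\n")
  print(x$ranking)
  invisible(x)
}

#' Post-toe linear modulus and toe strain of a J-shaped curve
#'
#' Soft collagenous tissues show a J-shaped tensile response: a compliant
#' toe region (fibril un-crimping) followed by a linear segment. The linear
#' window is identified as the widest sliding window covering at least
#' `min_frac` of the points whose linear-fit RMSE stays within
#' `noise_mult` times the curve's noise floor (robustly estimated from
#' second differences, which are blind to any linear trend). A plain
#' R-squared threshold cannot separate the toe — a straight line through an
#' entire J-curve easily exceeds R^2 = 0.99 — whereas the residual
#' criterion rejects windows that swallow the curved toe as soon as the
#' systematic deviation exceeds the noise.
#'
#' The slope of the chosen window (stress vs engineering strain) is the
#' linear modulus and the strain at the window start estimates the toe
#' strain. If no window of the minimum width passes, the smallest-RMSE
#' window is returned with a warning.
#'
#' @param curve uniaxial data (>= 10 points).
#' @param min_frac minimum window width as a fraction of the points.
#' @param noise_mult RMSE acceptance multiple of the estimated noise floor.
#' @return A list of class `linear_region`: `modulus_MPa`, `toe_strain`,
#'   `r2`, `rmse`, `window` (index range), `converged`.
#' @export
linear_region_modulus <- function(curve, min_frac = 0.3, noise_mult = 1.5) {
  curve <- as_curve_tibble(curve)
  x <- curve$strain
  y <- curve$stress_MPa
  n <- length(x)
  if (n < 10) stop("need at least 10 points", call. = FALSE)
  wmin <- max(5L, ceiling(min_frac * n))
  # robust noise floor: Var(second difference) = 6 sigma^2 for iid noise;
  # the median absolute deviation ignores the toe's smooth curvature
  sigma_hat <- stats::mad(diff(y, differences = 2)) / sqrt(6)
  thr <- max(noise_mult * sigma_hat, 1e-8 * max(abs(y), 1))
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  win_stats <- function(len) {
    i <- seq_len(n - len + 1L)          # window [i, i + len - 1]
    j <- i + len - 1L
    S <- function(cs) cs[j] - c(0, cs)[i]   # sum over [i, j]
    sx <- S(cx); sy <- S(cy); sxx <- S(cxx); syy <- S(cyy); sxy <- S(cxy)
    Sxx <- sxx - sx^2 / len
    Syy <- syy - sy^2 / len
    Sxy <- sxy - sx * sy / len
    sse <- pmax(Syy - Sxy^2 / pmax(Sxx, .Machine$double.xmin), 0)
    r2 <- ifelse(Syy <= .Machine$double.eps * pmax(syy, 1),
                 1, 1 - sse / Syy)
    list(i = i, rmse = sqrt(sse / len), r2 = r2, slope = Sxy / Sxx)
  }
  best <- NULL
  for (len in seq(n, wmin)) {
    ws <- win_stats(len)
    top <- which.min(ws$rmse)
    if (is.null(best) || ws$rmse[top] < best$rmse) {
      best <- list(i = ws$i[top], len = len, rmse = ws$rmse[top],
                   r2 = ws$r2[top], slope = ws$slope[top])
    }
    if (ws$rmse[top] <= thr) {
      i0 <- ws$i[top]
      return(structure(list(
        modulus_MPa = ws$slope[top], toe_strain = x[i0], r2 = ws$r2[top],
        rmse = ws$rmse[top], window = c(i0, i0 + len - 1L), converged = TRUE
      ), class = "linear_region"))
    }
  }
  warning(sprintf("no window of >= %d points reached the residual criterion; returning the best window",
                  wmin), call. = FALSE)
  structure(list(
    modulus_MPa = best$slope, toe_strain = x[best$i], r2 = best$r2,
    rmse = best$rmse, window = c(best$i, best$i + best$len - 1L),
    converged = FALSE
  ), class = "linear_region")
}

#' @export
print.linear_region <- function(x, ...) {
  cat(sprintf(
    "<linear_region> modulus %.4g MPa, toe strain %.4f (R^2 %.5f, points %d-%d%s)\n",
    x$modulus_MPa, x$toe_strain, x$r2, x$window[1], x$window[2],
    if (x$converged) "" else ", NOT converged"
  ))
  invisible(x)
}
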