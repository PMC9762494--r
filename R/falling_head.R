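#' Fluid properties
#'
#' Water at test conditions by default: density 1000 kg m^-3, dynamic
#' viscosity 1e-3 Pa s, gravity 9.8 m s^-2.
#'
#' @param density kg m^-3.
#' @param viscosity dynamic viscosity, Pa s.
#' @param gravity m s^-2.
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1e-3, gravity = 9.8) {
  stopifnot(density > 0, viscosity > 0, gravity > 0)
  structure(list(density = density, viscosity = viscosity, gravity = gravity),
            class = "fluid_properties")
}

#' Falling-head permeameter records
#'
#' A tibble of falling-head tests, one row per trial: standpipe
#' cross-section `a_m2`, sample cross-section `A_m2`, sample height `H_m`,
#' initial/final heads `L1_m`/`L2_m` and elapsed time `t_s` (equivalently
#' `t1 - t0`).
#'
#' @param a_m2,A_m2,H_m,L1_m,L2_m,t_s numeric vectors, recycled to a common
#'   length.
#' @param sample optional sample label.
#' @return A tibble of class `falling_head_test`.
#' @export
falling_head_test <- function(a_m2, A_m2, H_m, L1_m, L2_m, t_s, sample = NA_character_) {
  out <- tibble::tibble(
    sample = sample, a_m2 = a_m2, A_m2 = A_m2, H_m = H_m,
    L1_m = L1_m, L2_m = L2_m, t_s = t_s
  )
  bad <- with(out, a_m2 <= 0 | A_m2 <= 0 | H_m <= 0 | L2_m <= 0 | L1_m < L2_m | t_s < 0)
  if (any(bad)) stop("non-physical falling-head record (need positive geometry, L1 >= L2, t >= 0)",
                     call. = FALSE)
  class(out) <- c("falling_head_test", class(out))
  out
}

#' Hydraulic conductivity from a falling-head record
#'
#' Applies the falling-head working equation
#' `K = a * H / (A * t) * log(L1 / L2)` (m/s) to each row.
#'
#' @param test a [falling_head_test()] tibble (or any data frame with the
#'   same columns).
#' @return The input with a `K_m_per_s` column appended.
#' @examples
#' falling_head_test(3.58e-3, 1.42e-5, 1.00e-2, 0.45, 0.425, 950) |>
#'   falling_head_conductivity()
#' @export
falling_head_conductivity <- function(test) {
  need <- c("a_m2", "A_m2", "H_m", "L1_m", "L2_m", "t_s")
  stopifnot(all(need %in% names(test)))
  if (any(test$t_s <= 0 & test$L1_m > test$L2_m)) {
    stop("elapsed time must be positive when the head drops", call. = FALSE)
  }
  dplyr::mutate(
    test,
    K_m_per_s = ifelse(.data$L1_m == .data$L2_m, 0,
                       .data$a_m2 * .data$H_m / (.data$A_m2 * .data$t_s) *
                         log(.data$L1_m / .data$L2_m))
  )
}

#' Convert hydraulic conductivity to intrinsic permeability
#'
#' `k = K * mu / (rho * g)` (m^2).
#'
#' @param K hydraulic conductivity, m/s (vector), or a data frame with a
#'   `K_m_per_s` column (a `k_m2` column is then appended).
#' @param fluid a [fluid_properties()].
#' @return Numeric vector of permeabilities, or the augmented data frame.
#' @export
conductivity_to_permeability <- function(K, fluid = fluid_properties()) {
  if (is.data.frame(K)) {
    stopifnot("K_m_per_s" %in% names(K))
    return(dplyr::mutate(K, k_m2 = .data$K_m_per_s * fluid$viscosity /
                           (fluid$density * fluid$gravity)))
  }
  stopifnot(all(K >= 0))
  K * fluid$viscosity / (fluid$density * fluid$gravity)
}

#' Mean and population SD of a set of permeabilities
#'
#' Population (divide-by-n) standard deviation, matching how replicate
#' image-based permeabilities are usually summarized.
#'
#' @param values numeric vector of permeabilities (>= 2 values).
#' @return A one-row tibble with `n`, `mean`, `sd_pop`.
#' @export
aggregate_permeability <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  tibble::tibble(
    n = length(values), mean = m,
    sd_pop = sqrt(mean((values - m)^2))
  )
}
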