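# Closed-form volume models. The larva body is modelled as a cylinder whose
# projected area and length are measured from the image; yolk sac and eye as
# prolate spheroids from their measured width and length; the egg as a
# sphere of the mean of the measured major and minor axes.

#' Total larva volume (cylinder model)
#'
#' A cylinder of length `L_L` seen side-on projects a rectangle of area
#' `A_L = L_L * d`, so `d = A_L / L_L` and
#' `V_L = pi/4 * d^2 * L_L = A_L^2 / L_L * pi / 4`.
#'
#' @param A_L projected body area in mm^2.
#' @param L_L standard length in mm.
#' @return total volume `V_L` in mm^3.
#' @export
larva_total_volume <- function(A_L, L_L) {
  if (any(!is.finite(A_L)) || any(!is.finite(L_L)) ||
      any(A_L <= 0) || any(L_L <= 0))
    stop("`A_L` and `L_L` must be positive", call. = FALSE)
  A_L^2 / L_L * pi / 4
}

#' Prolate-spheroid volume (yolk sac, eye)
#'
#' `V = 4/3 * pi * (W/2)^2 * (L/2)` for measured width `W` (the two equal
#' minor semi-axes) and length `L` (major axis). If `W > L` the arguments
#' are swapped with a warning.
#'
#' @param W width (minor axis) in mm.
#' @param L length (major axis) in mm.
#' @return volume in mm^3.
#' @export
prolate_spheroid_volume <- function(W, L) {
  if (any(!is.finite(W)) || any(!is.finite(L)) || any(W <= 0) || any(L <= 0))
    stop("`W` and `L` must be positive", call. = FALSE)
  if (any(W > L)) {
    warning("width exceeds length; swapping to keep minor <= major", call. = FALSE)
    tmp <- pmin(W, L); L <- pmax(W, L); W <- tmp
  }
  4 / 3 * pi * (W / 2)^2 * (L / 2)
}

#' Structural volume
#'
#' `V_S = V_L - V_Y`: the body volume excluding the yolk sac. A negative
#' result (yolk model exceeding the body model, a segmentation fault) is
#' retained but flagged suspect, preserving auditability.
#'
#' @param V_L total larva volume in mm^3.
#' @param V_Y yolk-sac volume in mm^3.
#' @return list with `value` (mm^3) and `suspect` (logical).
#' @export
structural_volume <- function(V_L, V_Y) {
  stopifnot(V_L >= 0, V_Y >= 0)
  v <- V_L - V_Y
  list(value = v, suspect = v < 0)
}

#' Mean egg diameter and radius
#'
#' The egg outline is near-circular; its measured major and minor axes are
#' averaged into a mean diameter `D_E = (L_E + W_E) / 2` and radius
#' `R_E = D_E / 2`. A `W_E / L_E` ratio below `eccentricity_warn` triggers a
#' warning (the sphere model degrades for eccentric outlines).
#'
#' @param L_E_egg,W_E_egg egg major and minor axes in mm.
#' @param eccentricity_warn warn when `W/L` falls below this (default 0.95).
#' @return list with `diameter_mm`, `radius_mm`.
#' @export
egg_diameter <- function(L_E_egg, W_E_egg, eccentricity_warn = 0.95) {
  stopifnot(L_E_egg > 0, W_E_egg > 0)
  if (W_E_egg / L_E_egg < eccentricity_warn)
    warning(sprintf("egg outline eccentric (W/L = %.3f): sphere model suspect",
                    W_E_egg / L_E_egg), call. = FALSE)
  d <- (L_E_egg + W_E_egg) / 2
  list(diameter_mm = d, radius_mm = d / 2)
}

#' Spherical egg volume
#'
#' `V_E = 4/3 * pi * R_E^3` with `R_E = D_E / 2`.
#'
#' @param D_E mean egg diameter in mm.
#' @return volume in mm^3.
#' @export
egg_volume <- function(D_E) {
  if (any(!is.finite(D_E)) || any(D_E <= 0))
    stop("`D_E` must be positive", call. = FALSE)
  # written as (R^2 * R) so the sphere is bit-identical to the prolate
  # spheroid evaluated at equal axes
  4 / 3 * pi * (D_E / 2)^2 * (D_E / 2)
}
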