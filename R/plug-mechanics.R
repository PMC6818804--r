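# The two fundamental mechanical steps: trailing-film deposition during
# transit, and plug splitting at a bifurcation. Pure functions, CGS units.

#' Fluid properties of the instilled mixture
#'
#' @param viscosity dynamic viscosity in poise (1 P = 100 cP; clinical
#'   surfactants are around 0.3 P = 30 cP).
#' @param density in g/cm^3.
#' @param surface_tension in dyn/cm.
#' @return list of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity, density, surface_tension) {
  if (viscosity <= 0 || density <= 0 || surface_tension <= 0)
    stop("all fluid properties must be > 0")
  structure(list(viscosity = viscosity, density = density,
                 surface_tension = surface_tension),
            class = "fluid_properties")
}

#' Dimensionless numbers of a plug in an airway
#'
#' Reynolds `Re = rho*U*a/mu`, capillary `Ca = mu*U/sigma`, Bond
#' `Bo = rho*g*a^2/sigma` and the dimensionless plug volume
#' `Vtilde = V1/(pi*a^3)`, with `a` the airway radius and `U` the plug
#' velocity.
#'
#' @param props a [fluid_properties()].
#' @param a airway radius, cm.
#' @param U plug velocity, cm/s.
#' @param V1 plug volume entering the bifurcation, mL.
#' @param g gravitational acceleration, cm/s^2 (default 981).
#' @return list of class `dimensionless_state` with `Re`, `Ca`, `Bo`,
#'   `Vtilde`, `g`, `a`, `U`.
#' @export
dimensionless_state <- function(props, a, U, V1 = 0, g = 981) {
  if (a < 0 || U < 0) stop("radius and velocity must be >= 0")
  structure(list(Re = props$density * U * a / props$viscosity,
                 Ca = props$viscosity * U / props$surface_tension,
                 Bo = props$density * g * a^2 / props$surface_tension,
                 Vtilde = if (a > 0) V1 / (pi * a^3) else 0,
                 g = g, a = a, U = U),
            class = "dimensionless_state")
}

#' Trailing-film thickness ratio
#'
#' Ratio `H = h/a` of the trailing film left on the wall by a moving plug to
#' the airway radius, as a function of the capillary number:
#' `H = 0.36 * (1 - exp(-2 * Ca^0.523))`. Monotone increasing, `H(0) = 0`,
#' saturating at 0.36 for fast plugs.
#'
#' @param Ca capillary number(s), >= 0. Vectorised.
#' @return `h/a` in `[0, 0.36)`.
#' @export
film_thickness_ratio <- function(Ca) {
  if (any(Ca < 0)) stop("Ca must be >= 0")
  0.36 * (1 - exp(-2 * Ca^0.523))
}

#' Volume lost by a plug transiting one airway
#'
#' A plug crossing an airway deposits an annular film of thickness
#' `h = H * a` on the dry portion of the wall; the film volume per unit
#' length is `q = pi * h * (2a - h)`. Pre-coated wall (up to
#' `coated_length`) costs nothing: the plug rides the precursor film
#' losslessly. If the plug volume is insufficient to coat the remaining dry
#' length it dies mid-airway and is deposited entirely.
#'
#' @param plug_volume entering plug volume, mL (>= 0).
#' @param diameter,length airway dimensions, cm.
#' @param H film thickness ratio `h/a`, from [film_thickness_ratio()].
#' @param coated_length already-coated proximal length, cm (in `[0, length]`).
#' @return list with `volume_deposited` (mL), `wetted_length` (total coated
#'   length after transit, cm) and `exit_volume` (mL; 0 if the plug dies).
#'   Volume is conserved exactly:
#'   `plug_volume == volume_deposited + exit_volume`.
#' @export
transit_loss <- function(plug_volume, diameter, length, H,
                         coated_length = 0) {
  if (plug_volume < 0) stop("plug_volume must be >= 0")
  if (coated_length < 0 || coated_length > length + 1e-12)
    stop("coated_length outside [0, length]")
  a <- diameter / 2
  h <- H * a
  q <- pi * h * (2 * a - h)          # annular film volume per unit length
  dry <- max(length - coated_length, 0)
  need <- q * dry
  if (q > 0 && plug_volume <= need) {
    list(volume_deposited = plug_volume,
         wetted_length = coated_length + plug_volume / q,
         exit_volume = 0)
  } else {
    dep <- if (q > 0) need else 0
    list(volume_deposited = dep,
         wetted_length = if (q > 0) length else coated_length,
         exit_volume = plug_volume - dep)
  }
}

#' Coefficients of the plug-splitting quadratic
#'
#' The splitting factor `alpha` (fraction of the plug entering the upper
#' daughter) solves `A*alpha^2 + B*alpha + C = 0` with
#' \deqn{A = Re Ca (1/\lambda_2^4 - 1/\lambda_3^4) +
#'       16 \tilde V_1 Ca (1/\lambda_2^6 - 1/\lambda_3^6)}
#' \deqn{B = 2 \tilde V_1 Bo (f_2/\lambda_2^2 + f_3/\lambda_3^2) +
#'       2 Re Ca/\lambda_3^4 + 32 \tilde V_1 Ca/\lambda_3^6}
#' \deqn{C = -Re Ca/\lambda_3^4 - 16 \tilde V_1 Ca/\lambda_3^6 -
#'       2 \tilde V_1 Bo f_3/\lambda_3^2 + 4 (1/\lambda_3 - 1/\lambda_2)}
#' where `f_i = sin(theta_i) sin(phi) - cos(theta_i) sin(gamma)` with the
#' signed half-branching angles `theta_2 = +|theta_2|` (upper daughter) and
#' `theta_3 = -|theta_3|` (lower daughter).
#'
#' @param state a [dimensionless_state()] at the parent airway scale.
#' @param orient a [orient_bifurcation()] result (or any list carrying
#'   `gamma`, `phi`, `theta2`, `theta3`, `lambda2`, `lambda3`).
#' @return list of class `split_coefficients` with `A`, `B`, `C`, `f2`, `f3`.
#' @export
split_coefficients <- function(state, orient) {
  l2 <- orient$lambda2; l3 <- orient$lambda3
  if (!(l2 > 0) || !(l3 > 0)) stop("diameter ratios must be > 0")
  co <- .split_coeffs(state$Re, state$Ca, state$Bo, state$Vtilde,
                      orient$theta2, orient$theta3,
                      orient$phi, orient$gamma, l2, l3)
  structure(co, class = "split_coefficients")
}

.split_coeffs <- function(Re, Ca, Bo, Vt, th2, th3, phi, gamma, l2, l3) {
  f2 <- sin(th2) * sin(phi) - cos(th2) * sin(gamma)
  f3 <- sin(-th3) * sin(phi) - cos(th3) * sin(gamma)
  A <- Re * Ca * (l2^-4 - l3^-4) + 16 * Vt * Ca * (l2^-6 - l3^-6)
  B <- 2 * Vt * Bo * (f2 / l2^2 + f3 / l3^2) +
    2 * Re * Ca / l3^4 + 32 * Vt * Ca / l3^6
  C <- -Re * Ca / l3^4 - 16 * Vt * Ca / l3^6 -
    2 * Vt * Bo * f3 / l3^2 + 4 * (1 / l3 - 1 / l2)
  list(A = A, B = B, C = C, f2 = f2, f3 = f3)
}

# Solve the quadratic for alpha with the physical-root policy:
# roots in [0,1] preferred; two qualifying -> the one nearer 0.5 (continuity
# with the zero-gravity limit); none -> clamp the nearest real root; complex
# -> clamp the vertex; A=B=0, C!=0 -> degenerate, decide by gravity bias.
.split_alpha <- function(Re, Ca, Bo, Vt, th2, th3, phi, gamma, l2, l3) {
  co <- .split_coeffs(Re, Ca, Bo, Vt, th2, th3, phi, gamma, l2, l3)
  A <- co$A; B <- co$B; C <- co$C
  scale <- max(abs(A), abs(B), abs(C), 1e-300)
  eps <- 1e-14 * scale
  if (abs(A) <= eps) {
    if (abs(B) <= eps) {
      if (abs(C) <= eps) return(0.5)
      # no root at all: send the plug with the gravity bias
      message("degenerate splitting balance (A = B = 0, C != 0): ",
              "plug follows the gravity bias")
      return(if (sin(phi) >= 0) 0 else 1)
    }
    return(min(1, max(0, -C / B)))
  }
  disc <- B * B - 4 * A * C
  if (disc < 0) return(min(1, max(0, -B / (2 * A))))
  sq <- sqrt(disc)
  qq <- -(B + sign(B + (B == 0)) * sq) / 2
  roots <- c(qq / A, if (qq != 0) C / qq else -B / A - qq / A)
  tol <- 1e-12
  ok <- roots >= -tol & roots <= 1 + tol
  if (any(ok)) {
    cand <- roots[ok]
    alpha <- cand[which.min(abs(cand - 0.5))]
  } else {
    dist <- pmax(roots - 1, -roots, 0)
    alpha <- roots[which.min(dist)]
  }
  min(1, max(0, alpha))
}

#' Split a plug at a bifurcation
#'
#' Solves the splitting quadratic (see [split_coefficients()]) for the
#' splitting factor `alpha`, the fraction of the incoming volume entering
#' the upper daughter; `V2 = alpha * V1`, `V3 = (1 - alpha) * V1`, and the
#' splitting ratio `Rs = alpha/(1-alpha)` (may be `Inf`). Root policy: both
#' roots are computed; roots inside `[0, 1]` are preferred; when two
#' qualify the one continuous with the zero-gravity limit (nearer 0.5) is
#' taken; when none does, the nearest real root is clamped into `[0, 1]`.
#'
#' For a symmetric bifurcation (`lambda2 == lambda3`, equal and opposite
#' branching angles) the result reduces to the closed form
#' `alpha = (1 - X sin(theta) sin(phi) / (1 - X cos(theta) sin(gamma))) / 2`
#' with `X = 2 Bo Vtilde lambda^4 / ((Re lambda^2 + 16 Vtilde) Ca)`.
#'
#' @param V1 incoming plug volume, mL (> 0).
#' @param state a [dimensionless_state()] at the parent scale (its `Vtilde`
#'   must correspond to `V1`).
#' @param orient bifurcation orientation, see [orient_bifurcation()].
#' @return list of class `split_result` with `alpha`, `Rs`, `V2`, `V3`.
#'   `V2 + V3 == V1` exactly.
#' @export
split_plug <- function(V1, state, orient) {
  if (!(V1 > 0)) stop("V1 must be > 0")
  alpha <- .split_alpha(state$Re, state$Ca, state$Bo, state$Vtilde,
                        orient$theta2, orient$theta3,
                        orient$phi, orient$gamma,
                        orient$lambda2, orient$lambda3)
  V2 <- alpha * V1
  structure(list(alpha = alpha,
                 Rs = if (alpha < 1) alpha / (1 - alpha) else Inf,
                 V2 = V2, V3 = V1 - V2),
            class = "split_result")
}
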