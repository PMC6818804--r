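# Drives plugs through the tree for single- and multiple-aliquot protocols.

#' Instillation protocol
#'
#' @param dose_volume_per_kg total instilled dose volume, mL per kg body
#'   weight.
#' @param body_weight kg.
#' @param flow_rate_per_kg ventilation-driven tracheal flow, mL/s per kg.
#' @param postures either a single [posture()] (whole dose in one posture) or
#'   a list of `list(posture, fraction)` phases; fractions must sum to 1.
#'   See [posture_sequence_LR()] for the divided L+R protocol.
#' @param n_aliquots number of equal aliquots (breaths) per posture phase.
#' @param min_plug_volume plugs smaller than this (mL) are deposited in
#'   place and stop propagating (recursion epsilon, default 1e-6 mL).
#' @return list of class `protocol`.
#' @export
protocol <- function(dose_volume_per_kg, body_weight, flow_rate_per_kg,
                     postures = posture("LLD"), n_aliquots = 1L,
                     min_plug_volume = 1e-6) {
  if (dose_volume_per_kg <= 0 || body_weight <= 0 || flow_rate_per_kg <= 0)
    stop("dose, body weight and flow rate must be > 0")
  if (n_aliquots < 1L) stop("n_aliquots must be >= 1")
  if (inherits(postures, "posture"))
    postures <- list(list(posture = postures, fraction = 1))
  fr <- vapply(postures, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-10) stop("posture dose fractions must sum to 1")
  if (any(fr <= 0)) stop("posture dose fractions must be > 0")
  structure(list(dose_volume_per_kg = dose_volume_per_kg,
                 body_weight = body_weight,
                 flow_rate_per_kg = flow_rate_per_kg,
                 postures = postures,
                 n_aliquots = as.integer(n_aliquots),
                 min_plug_volume = min_plug_volume),
            class = "protocol")
}

#' Divided right-then-left lateral decubitus posture sequence
#'
#' The classical divided protocol: half of the dose in right lateral
#' decubitus, the other half in left lateral decubitus.
#'
#' @param tilt_deg reverse-Trendelenburg tilt applied to both phases.
#' @export
posture_sequence_LR <- function(tilt_deg = 0) {
  list(list(posture = posture("RLD", tilt_deg = tilt_deg), fraction = 0.5),
       list(posture = posture("LLD", tilt_deg = tilt_deg), fraction = 0.5))
}

#' Air velocity in each airway
#'
#' The tracheal flow is partitioned at every bifurcation proportionally to
#' the number of terminal airways subtended by each daughter (uniform
#' ventilation), so the flow in an airway is
#' `Q * n_terminals(subtree) / M`; the mean velocity is `Q_airway/(pi a^2)`.
#'
#' @param tree an `airway_tree`.
#' @param tracheal_flow mL/s.
#' @param airway_id optional single id; if `NULL` a vector over all airways
#'   (named by id) is returned.
#' @return velocity in cm/s.
#' @export
airway_velocity <- function(tree, tracheal_flow, airway_id = NULL) {
  nt <- .subtended_terminals(tree)
  af <- tree$airways
  Q <- tracheal_flow * nt / length(tree$terminal_ids)
  U <- Q / (pi * (af$diameter / 2)^2)
  names(U) <- af$id
  if (is.null(airway_id)) U else unname(U[as.character(airway_id)])
}

# number of terminal airways subtended by (and including) each airway
.subtended_terminals <- function(tree) {
  af <- tree$airways
  ch <- tree$children
  nt <- ifelse(is.na(ch[, 1L]), 1L, 0L)
  ord <- order(af$generation, decreasing = TRUE)
  prow <- match(af$parent_id, af$id)
  for (i in ord) {
    if (!is.na(prow[i])) nt[prow[i]] <- nt[prow[i]] + nt[i]
  }
  nt
}

#' Simulate an instillation
#'
#' Runs the full delivery: for each posture phase and each aliquot, a plug
#' of the aliquot volume is seeded at the trachea and propagated distally.
#' In each airway the plug deposits a trailing film over the still-dry
#' portion of the wall ([transit_loss()], with the film thickness from the
#' airway-local capillary number); at each bifurcation the surviving volume
#' splits between the daughters ([split_plug()], oriented under the active
#' posture). A plug reaching the distal end of a terminal airway delivers
#' its remaining volume to that terminal; a plug smaller than
#' `min_plug_volume` is deposited onto the wall of its current airway.
#' Wall-coating state persists across aliquots and posture phases, so later
#' plugs ride precursor films losslessly.
#'
#' @param tree an embedded `airway_tree`. Its coating state is taken as the
#'   initial state (fresh trees are dry) and is not modified in place.
#' @param protocol a [protocol()].
#' @param fluid a [fluid_properties()].
#' @param film_fun film-thickness law, `H(Ca)`; default
#'   [film_thickness_ratio()]. Exposed for regime studies (e.g. the
#'   lossless limit `function(Ca) 0`).
#' @param g gravitational acceleration, cm/s^2; 0 switches gravity off.
#' @param keep_history keep the per-terminal cumulative volumes after every
#'   breath (matrix `M x breaths`), needed for breath-resolved indices.
#' @return list of class `delivery_result`:
#'   `terminal_volumes` (named mL per terminal), `coating_volumes` (named mL
#'   deposited per airway during this run), `coated_length` (cm per airway),
#'   `V_D`, `V_CC` (= sum of coating, incl. plugs extinguished mid-airway),
#'   `delivered`, `eta` (%), `HI`, `snapshots` (one row per breath with
#'   cumulative eta and HI) and optionally `terminal_history`.
#'   `V_D = delivered + V_CC` to machine precision.
#' @export
instill <- function(tree, protocol, fluid,
                    film_fun = film_thickness_ratio, g = 981,
                    keep_history = TRUE) {
  if (!.is_embedded(tree)) stop("tree is not embedded; call embed_tree()")
  if (n_airways(tree) < 1L) stop("empty tree")
  af <- tree$airways
  ch <- tree$children
  n <- nrow(af)
  terminal <- is.na(ch[, 1L])
  term_rows <- which(terminal)
  rt <- .row_of(tree, tree$root_id)

  V_D <- protocol$dose_volume_per_kg * protocol$body_weight
  Q <- protocol$flow_rate_per_kg * protocol$body_weight
  U <- unname(airway_velocity(tree, Q))
  a <- af$diameter / 2
  mu <- fluid$viscosity; rho <- fluid$density; sig <- fluid$surface_tension
  Ca <- mu * U / sig
  H <- film_fun(Ca)
  h <- H * a
  q <- pi * h * (2 * a - h)
  Re <- rho * U * a / mu
  Bo <- rho * g * a^2 / sig
  Lv <- af$length
  minv <- protocol$min_plug_volume

  coated <- af$coated_length
  coatvol <- numeric(n)          # deposited during this run
  termvol <- numeric(n)

  n_breaths <- length(protocol$postures) * protocol$n_aliquots
  snapshots <- data.frame(breath = seq_len(n_breaths),
                          phase = NA_integer_, posture = NA_character_,
                          instilled = NA_real_, delivered = NA_real_,
                          V_CC = NA_real_, eta = NA_real_, HI = NA_real_)
  history <- if (keep_history)
    matrix(0, length(term_rows), n_breaths) else NULL

  # preallocated plug stack
  cap <- 2048L
  st_row <- integer(cap); st_vol <- numeric(cap)

  breath <- 0L
  instilled <- 0
  for (ph in seq_along(protocol$postures)) {
    phase <- protocol$postures[[ph]]
    oa <- .orient_all(tree, phase$posture)
    v_aliq <- V_D * phase$fraction / protocol$n_aliquots
    for (al in seq_len(protocol$n_aliquots)) {
      breath <- breath + 1L
      instilled <- instilled + v_aliq
      top <- 1L
      st_row[1L] <- rt; st_vol[1L] <- v_aliq
      while (top > 0L) {
        i <- st_row[top]; v <- st_vol[top]; top <- top - 1L
        if (v <= 0) next
        if (v < minv) { coatvol[i] <- coatvol[i] + v; next }
        dry <- Lv[i] - coated[i]
        need <- q[i] * dry
        if (q[i] > 0 && v <= need) {      # plug dies mid-airway
          coatvol[i] <- coatvol[i] + v
          coated[i] <- coated[i] + v / q[i]
          next
        }
        if (q[i] > 0 && dry > 0) {
          coatvol[i] <- coatvol[i] + need
          coated[i] <- Lv[i]
          v <- v - need
        }
        if (terminal[i]) { termvol[i] <- termvol[i] + v; next }
        if (v < minv) { coatvol[i] <- coatvol[i] + v; next }
        alpha <- .split_alpha(Re[i], Ca[i], Bo[i], v / (pi * a[i]^3),
                              oa$theta2[i], oa$theta3[i],
                              oa$phi[i], oa$gamma[i],
                              oa$lambda2[i], oa$lambda3[i])
        if (top + 2L > length(st_row)) {
          st_row <- c(st_row, integer(length(st_row)))
          st_vol <- c(st_vol, numeric(length(st_vol)))
        }
        v2 <- alpha * v
        top <- top + 1L
        st_row[top] <- oa$upper_row[i]; st_vol[top] <- v2
        top <- top + 1L
        st_row[top] <- oa$lower_row[i]; st_vol[top] <- v - v2
      }
      delivered <- sum(termvol)
      vcc <- sum(coatvol)
      tv <- termvol[term_rows]
      snapshots$phase[breath] <- ph
      snapshots$posture[breath] <- phase$posture$name
      snapshots$instilled[breath] <- instilled
      snapshots$delivered[breath] <- delivered
      snapshots$V_CC[breath] <- vcc
      snapshots$eta[breath] <- efficiency(tv, V_D)
      snapshots$HI[breath] <- if (sum(tv) > 0)
        homogeneity_index(tv) else 0
      if (keep_history) history[, breath] <- tv
    }
  }

  tv <- termvol[term_rows]
  names(tv) <- af$id[term_rows]
  cv <- coatvol
  names(cv) <- af$id
  cl <- coated
  names(cl) <- af$id
  structure(list(terminal_volumes = tv,
                 coating_volumes = cv,
                 coated_length = cl,
                 V_D = V_D,
                 V_CC = sum(coatvol),
                 delivered = sum(tv),
                 eta = efficiency(tv, V_D),
                 HI = if (sum(tv) > 0) homogeneity_index(tv) else 0,
                 snapshots = snapshots,
                 terminal_history = history,
                 protocol = protocol,
                 fluid = fluid),
            class = "delivery_result")
}

#' @export
print.delivery_result <- function(x, ...) {
  cat("delivery_result\n")
  cat("  instilled dose V_D: ", signif(x$V_D, 4), " mL\n", sep = "")
  cat("  delivered to acini: ", signif(x$delivered, 4), " mL\n", sep = "")
  cat("  coating cost V_CC:  ", signif(x$V_CC, 4), " mL (",
      signif(100 * x$V_CC / x$V_D, 3), "% of dose)\n", sep = "")
  cat("  efficiency eta:     ", signif(x$eta, 3), " %\n", sep = "")
  cat("  homogeneity HI:     ", signif(x$HI, 3), "\n", sep = "")
  cat("  breaths:            ", nrow(x$snapshots), "\n", sep = "")
  invisible(x)
}

#' Splitting-factor sweep over the dimensionless plug volume
#'
#' Recomputes, point by point with [split_plug()], the splitting factor of a
#' vertical-plane asymmetric bifurcation (horizontal parent, branching
#' angles `theta` each side, daughter/parent diameter ratios
#' `lambda_large` / `lambda_small`) over a grid of dimensionless volumes and
#' flow conditions, in both vertical configurations: larger daughter down
#' and larger daughter up.
#'
#' @param vtilde vector of dimensionless plug volumes `V1/(pi a^3)`.
#' @param conditions data.frame with columns `Ca`, `Re`, `Bo` (one row per
#'   flow condition).
#' @param lambda_large,lambda_small daughter/parent diameter ratios.
#' @param theta half-branching angle, radians.
#' @return long data.frame: `config` (`"larger_down"` / `"larger_up"`),
#'   `Ca`, `Re`, `Bo`, `vtilde`, `alpha` (fraction to the upper daughter),
#'   `frac_larger`, `frac_smaller`.
#' @export
sweep_alpha_vs_volume <- function(vtilde, conditions,
                                  lambda_large = 0.83, lambda_small = 0.72,
                                  theta = pi / 4) {
  configs <- list(
    larger_down = list(lambda2 = lambda_small, lambda3 = lambda_large),
    larger_up   = list(lambda2 = lambda_large, lambda3 = lambda_small))
  out <- list()
  for (cf in names(configs)) {
    lam <- configs[[cf]]
    orient <- list(gamma = 0, phi = pi / 2, theta2 = theta, theta3 = theta,
                   lambda2 = lam$lambda2, lambda3 = lam$lambda3)
    for (r in seq_len(nrow(conditions))) {
      cond <- conditions[r, ]
      alpha <- vapply(vtilde, function(vt) {
        st <- list(Re = cond$Re, Ca = cond$Ca, Bo = cond$Bo, Vtilde = vt)
        split_plug(1, st, orient)$alpha
      }, numeric(1))
      frac_up <- alpha
      out[[length(out) + 1L]] <- data.frame(
        config = cf, Ca = cond$Ca, Re = cond$Re, Bo = cond$Bo,
        vtilde = vtilde, alpha = alpha,
        frac_larger = if (cf == "larger_down") 1 - frac_up else frac_up,
        frac_smaller = if (cf == "larger_down") frac_up else 1 - frac_up)
    }
  }
  do.call(rbind, out)
}

#' Coating-cost sweep over dose volume and flow rate
#'
#' Runs [instill()] on a fresh copy of the tree for every (dose, flow)
#' combination and tabulates the coating cost.
#'
#' @param tree an embedded `airway_tree`.
#' @param doses_per_kg vector of dose volumes, mL/kg.
#' @param flows_per_kg vector of flow rates, mL/s/kg.
#' @param fluid a [fluid_properties()].
#' @param postures posture or posture sequence (default divided L+R).
#' @param n_aliquots aliquots per posture phase.
#' @param body_weight kg; defaults to the tree's.
#' @return data.frame with one row per grid point: `dose_per_kg`,
#'   `flow_per_kg`, `V_D`, `V_CC`, `VCC_frac` (= V_CC/V_D), `eta`, `HI`.
#' @export
sweep_coating_cost <- function(tree, doses_per_kg, flows_per_kg, fluid,
                               postures = posture_sequence_LR(),
                               n_aliquots = 1L,
                               body_weight = tree$body_weight) {
  grid <- expand.grid(dose_per_kg = doses_per_kg,
                      flow_per_kg = flows_per_kg)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    pr <- protocol(grid$dose_per_kg[k], body_weight, grid$flow_per_kg[k],
                   postures = postures, n_aliquots = n_aliquots)
    res <- instill(tree, pr, fluid, keep_history = FALSE)
    data.frame(dose_per_kg = grid$dose_per_kg[k],
               flow_per_kg = grid$flow_per_kg[k],
               V_D = res$V_D, V_CC = res$V_CC,
               VCC_frac = res$V_CC / res$V_D,
               eta = res$eta, HI = res$HI)
  })
  do.call(rbind, rows)
}
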