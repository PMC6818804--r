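# 3D embedding of the tree and gravity-relative bifurcation angles.

# Rodrigues rotation of vector v about unit axis k by angle ang
.rotate_about <- function(v, k, ang) {
  v * cos(ang) + .cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) {
  nv <- sqrt(sum(v * v))
  if (nv == 0) stop("cannot normalise a zero vector")
  v / nv
}

#' Compute the 3D embedding of an airway tree
#'
#' Assigns to every airway a unit direction in the body frame and the normal
#' of the bifurcation plane at its proximal end, then propagates endpoint
#' coordinates from the root. The root (trachea) points along the caudal
#' axis, `c(0, 0, -1)`; its reference plane normal is the anterior axis.
#' For each child, the bifurcation plane is the parent's plane rotated by the
#' child's rotation angle `psi` about the parent axis, and the child
#' direction is the parent direction tipped by the signed branching angle
#' `theta` within that plane.
#'
#' @param tree an `airway_tree` (angles `theta`, `psi` present on every
#'   non-root airway).
#' @return The tree with `dir_*`, `nrm_*` and endpoint coordinates filled in.
#' @export
embed_tree <- function(tree) {
  af <- tree$airways
  if (anyNA(af$theta[-.row_of(tree, tree$root_id)]) ||
      anyNA(af$psi[-.row_of(tree, tree$root_id)]))
    stop("missing branching or rotation angle on a non-root airway")
  n <- nrow(af)
  dirs <- matrix(NA_real_, n, 3L)
  nrms <- matrix(NA_real_, n, 3L)
  p0 <- matrix(NA_real_, n, 3L)

  rt <- .row_of(tree, tree$root_id)
  dirs[rt, ] <- c(0, 0, -1)
  nrms[rt, ] <- c(1, 0, 0)
  p0[rt, ] <- c(0, 0, 0)

  ord <- order(af$generation)  # parents always precede children
  prow <- match(af$parent_id, af$id)
  for (i in ord) {
    if (i == rt) next
    p <- prow[i]
    dp <- dirs[p, ]
    np <- .rotate_about(nrms[p, ], dp, af$psi[i])
    np <- .unit(np - dp * sum(np * dp))   # keep exactly orthogonal to axis
    tv <- .cross3(np, dp)
    dirs[i, ] <- .unit(cos(af$theta[i]) * dp + sin(af$theta[i]) * tv)
    nrms[i, ] <- np
    p0[i, ] <- p0[p, ] + af$length[p] * dp
  }
  p1 <- p0 + af$length * dirs

  af$dir_x <- dirs[, 1L]; af$dir_y <- dirs[, 2L]; af$dir_z <- dirs[, 3L]
  af$nrm_x <- nrms[, 1L]; af$nrm_y <- nrms[, 2L]; af$nrm_z <- nrms[, 3L]
  af$x0 <- p0[, 1L]; af$y0 <- p0[, 2L]; af$z0 <- p0[, 3L]
  af$x1 <- p1[, 1L]; af$y1 <- p1[, 2L]; af$z1 <- p1[, 3L]
  tree$airways <- af
  tree
}

#' Body posture as a gravity direction
#'
#' Expresses the direction of gravity in the body frame (x anterior, y toward
#' the animal's left, z caudal to cranial; the trachea points along -z).
#' `"LLD"` (left lateral decubitus, lying on the left side, trachea
#' horizontal) puts gravity along +y; `"RLD"` along -y; `"VERTICAL"`
#' (head-up) along -z. A reverse-Trendelenburg tilt raises the head and is
#' applied as a rotation of the gravity vector toward the caudal axis.
#'
#' @param name `"LLD"`, `"RLD"`, `"VERTICAL"` or `"CUSTOM"`.
#' @param gravity length-3 gravity direction in the body frame (required for
#'   `"CUSTOM"`; normalised internally).
#' @param tilt_deg reverse-Trendelenburg tilt in degrees (default 0).
#' @return list of class `posture` with `name` and unit `gravity_body`.
#' @export
posture <- function(name = c("LLD", "RLD", "VERTICAL", "CUSTOM"),
                    gravity = NULL, tilt_deg = 0) {
  name <- match.arg(name)
  g <- switch(name,
              LLD = c(0, 1, 0),
              RLD = c(0, -1, 0),
              VERTICAL = c(0, 0, -1),
              CUSTOM = {
                if (is.null(gravity)) stop("CUSTOM posture needs a gravity vector")
                .unit(gravity)
              })
  if (tilt_deg != 0) {
    t <- tilt_deg * pi / 180
    caudal <- c(0, 0, -1)
    ax <- .cross3(g, caudal)   # rotate g toward the caudal axis
    na <- sqrt(sum(ax * ax))
    if (na > 1e-12) g <- .rotate_about(g, ax / na, t)
  }
  structure(list(name = name, gravity_body = .unit(g)), class = "posture")
}

# Vectorised gravity-relative orientation of every bifurcation.
# Returns a data.frame indexed like tree$airways, NA rows for terminals:
# gamma, phi (rad), theta2, theta3 (magnitudes, rad), lambda2, lambda3,
# upper_row, lower_row. Daughter "2" is the upper one (higher distal end);
# ties go to the smaller id.
.orient_all <- function(tree, posture) {
  if (!.is_embedded(tree)) stop("tree is not embedded; call embed_tree()")
  af <- tree$airways
  g <- posture$gravity_body
  ch <- tree$children
  n <- nrow(af)
  out <- data.frame(gamma = rep(NA_real_, n), phi = NA_real_,
                    theta2 = NA_real_, theta3 = NA_real_,
                    lambda2 = NA_real_, lambda3 = NA_real_,
                    upper_row = NA_integer_, lower_row = NA_integer_)
  int <- which(!is.na(ch[, 1L]))
  if (length(int) == 0L) return(out)
  c1 <- ch[int, 1L]; c2 <- ch[int, 2L]
  elev <- -(af$x1 * g[1L] + af$y1 * g[2L] + af$z1 * g[3L])
  e1 <- elev[c1]; e2 <- elev[c2]
  # upper daughter: larger distal elevation; exact tie -> smaller id
  up <- ifelse(e1 > e2, c1,
        ifelse(e2 > e1, c2, ifelse(af$id[c1] < af$id[c2], c1, c2)))
  lo <- ifelse(up == c1, c2, c1)

  dxp <- af$dir_x[int]; dyp <- af$dir_y[int]; dzp <- af$dir_z[int]
  singam <- pmin(1, pmax(-1, g[1L] * dxp + g[2L] * dyp + g[3L] * dzp))
  # transverse axis toward the upper daughter: t = s * (n_up x d_parent)
  nx <- af$nrm_x[up]; ny <- af$nrm_y[up]; nz <- af$nrm_z[up]
  tx <- ny * dzp - nz * dyp
  ty <- nz * dxp - nx * dzp
  tz <- nx * dyp - ny * dxp
  s <- ifelse(af$theta[up] >= 0, 1, -1)
  sinphi <- pmin(1, pmax(-1, -s * (g[1L] * tx + g[2L] * ty + g[3L] * tz)))

  out$gamma[int] <- asin(singam)
  out$phi[int] <- asin(sinphi)
  out$theta2[int] <- abs(af$theta[up])
  out$theta3[int] <- abs(af$theta[lo])
  out$lambda2[int] <- af$diameter[up] / af$diameter[int]
  out$lambda3[int] <- af$diameter[lo] / af$diameter[int]
  out$upper_row[int] <- up
  out$lower_row[int] <- lo
  out
}

#' Gravity-relative orientation of one bifurcation
#'
#' Computes the pitch angle `gamma` (angle of the parent axis to the
#' horizontal plane, positive when the parent points downhill), the roll
#' angle `phi` (angle to the horizontal of the in-plane transverse axis,
#' positive when daughter "2" lies uphill), relabels the daughters so that
#' daughter "2" is the upper one (higher distal endpoint; ties broken toward
#' the smaller id), and reports the half-branching angles and
#' daughter-to-parent diameter ratios.
#'
#' @param tree an embedded `airway_tree`.
#' @param airway_id id of the parent airway of the bifurcation (must have
#'   two children).
#' @param posture a [posture()].
#' @return list of class `bifurcation_orientation` with `gamma`, `phi`,
#'   `theta2`, `theta3` (radians; magnitudes), `lambda2`, `lambda3`,
#'   `upper_id`, `lower_id`.
#' @export
orient_bifurcation <- function(tree, airway_id, posture) {
  r <- .row_of(tree, airway_id)
  if (is.na(tree$children[r, 1L]))
    stop("airway ", airway_id, " is terminal: no bifurcation to orient")
  oa <- .orient_all(tree, posture)
  structure(list(gamma = oa$gamma[r], phi = oa$phi[r],
                 theta2 = oa$theta2[r], theta3 = oa$theta3[r],
                 lambda2 = oa$lambda2[r], lambda3 = oa$lambda3[r],
                 upper_id = tree$airways$id[oa$upper_row[r]],
                 lower_id = tree$airways$id[oa$lower_row[r]]),
            class = "bifurcation_orientation")
}
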