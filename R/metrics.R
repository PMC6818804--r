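# Delivery-performance indices: efficiency, homogeneity, molecular dose,
# and the image-based quadrant homogeneity index.

#' Delivery efficiency
#'
#' Percentage of the instilled dose volume that reached the ends of the
#' terminal airways: `eta = 100 * sum(V_i) / V_D`.
#'
#' @param terminal_volumes vector of per-terminal delivered volumes, mL.
#' @param V_D instilled dose volume, mL (> 0).
#' @return efficiency in percent.
#' @export
efficiency <- function(terminal_volumes, V_D) {
  if (!(V_D > 0)) stop("V_D must be > 0")
  100 * sum(terminal_volumes) / V_D
}

#' Homogeneity index of the terminal distribution
#'
#' Reciprocal standard deviation of the normalised terminal volumes
#' `V_N,i = V_i / mean(V)`:
#' `HI = (M * sum(V^2) / sum(V)^2 - 1)^(-1/2)`.
#' A perfectly uniform distribution has zero variance and returns `Inf`;
#' the minimum, attained when the whole delivered volume reaches a single
#' terminal, is `1/sqrt(M - 1)`. Scale-invariant.
#'
#' @param terminal_volumes vector of per-terminal volumes, mL; at least two
#'   terminals, not all zero.
#' @return the homogeneity index (possibly `Inf`).
#' @export
homogeneity_index <- function(terminal_volumes) {
  v <- terminal_volumes
  M <- length(v)
  if (M < 2L) stop("homogeneity index needs at least 2 terminals")
  s <- sum(v)
  if (s <= 0) stop("homogeneity index undefined for an all-zero distribution")
  denom <- M * sum(v^2) / s^2 - 1
  if (denom < 1e-12) Inf else denom^(-0.5)
}

#' Molecular dose
#'
#' Phospholipid mass per kg delivered by a dose volume:
#' `concentration (mg/mL) * dose volume per kg (mL/kg)`.
#'
#' @param concentration mg/mL.
#' @param dose_volume_per_kg mL/kg.
#' @return mg/kg.
#' @export
molecular_dose <- function(concentration, dose_volume_per_kg) {
  if (concentration < 0 || dose_volume_per_kg < 0)
    stop("inputs must be >= 0")
  concentration * dose_volume_per_kg
}

#' Render the terminal distribution as a grayscale sphere projection
#'
#' Mimics end-inspiration lung images: a sphere of acinar size is drawn
#' around each terminal branch, its grey level proportional to the
#' delivered volume (white = nothing, black = at least `full_coat_volume`);
#' overlapping spheres add their grey levels, clipped at black. Orthographic
#' projection; the raster extent is the bounding box of the projected tree.
#'
#' @param tree an embedded `airway_tree`.
#' @param terminal_volumes per-terminal volumes in mL, ordered and named as
#'   `tree$terminal_ids` (e.g. `result$terminal_volumes`).
#' @param view `"front"` (project along the anterior axis onto the y-z
#'   plane), `"side"` (along y) or `"top"` (along z).
#' @param sphere_radius sphere radius in cm; default 2% of the projected
#'   bounding-box diagonal (an acinar scale derived from the tree extent).
#' @param full_coat_volume volume (mL) at which a sphere is fully black.
#' @param image_size raster edge in pixels.
#' @param pad extra margin (cm) added around the bounding box; the default 0
#'   keeps the raster extent equal to the projected tree's bounding box,
#'   which is what [sqhi()] quadrants are defined on.
#' @return `image_size x image_size` matrix of darkness values in `[0, 1]`
#'   (0 = white), class `plug_raster`, with attributes `extent`
#'   (`c(hmin, hmax, vmin, vmax)`, cm) and `sphere_radius`. Row 1 is the
#'   top of the image.
#' @export
render_terminal_spheres <- function(tree, terminal_volumes,
                                    view = c("front", "side", "top"),
                                    sphere_radius = NULL,
                                    full_coat_volume = 1e-3,
                                    image_size = 256L, pad = 0) {
  if (!.is_embedded(tree)) stop("tree is not embedded; call embed_tree()")
  if (n_airways(tree) < 1L) stop("empty tree")
  view <- match.arg(view)
  af <- tree$airways
  axes <- switch(view,
                 front = c("y", "z"),
                 side = c("x", "z"),
                 top = c("y", "x"))
  hc <- c(af[[paste0(axes[1L], "0")]], af[[paste0(axes[1L], "1")]])
  vc <- c(af[[paste0(axes[2L], "0")]], af[[paste0(axes[2L], "1")]])
  hr <- range(hc); vr <- range(vc)
  if (diff(hr) == 0) hr <- hr + c(-0.5, 0.5)
  if (diff(vr) == 0) vr <- vr + c(-0.5, 0.5)
  hr <- hr + c(-pad, pad)
  vr <- vr + c(-pad, pad)
  if (is.null(sphere_radius))
    sphere_radius <- 0.02 * sqrt(diff(hr)^2 + diff(vr)^2)

  m <- as.integer(image_size)
  img <- matrix(0, m, m)
  # pixel-centre coordinates; row 1 = top (max v)
  hx <- hr[1L] + (seq_len(m) - 0.5) * diff(hr) / m
  vx <- vr[2L] - (seq_len(m) - 0.5) * diff(vr) / m
  dh <- diff(hr) / m; dv <- diff(vr) / m

  trow <- .row_of(tree, tree$terminal_ids)
  th <- af[[paste0(axes[1L], "1")]][trow]
  tv <- af[[paste0(axes[2L], "1")]][trow]
  grey <- pmin(terminal_volumes / full_coat_volume, 1)
  r2 <- sphere_radius^2
  for (k in seq_along(trow)) {
    if (grey[k] <= 0) next
    cols <- which(abs(hx - th[k]) <= sphere_radius)
    rows <- which(abs(vx - tv[k]) <= sphere_radius)
    if (length(cols) == 0L || length(rows) == 0L) next
    dd <- outer((vx[rows] - tv[k])^2, (hx[cols] - th[k])^2, "+")
    img[rows, cols] <- img[rows, cols] + grey[k] * (dd <= r2)
  }
  img <- pmin(img, 1)
  structure(img, extent = c(hr, vr), sphere_radius = sphere_radius,
            class = c("plug_raster", "matrix", "array"))
}

#' Quadrant homogeneity index of a rendered image
#'
#' Thresholds the grayscale raster to black/white, splits the image (the
#' bounding box of the projected tree) into four equal rectangles, measures
#' in each the fraction of area reached by liquid (`AR`), and reports the
#' smallest `AR` divided by the largest. 1 means homogeneous at quadrant
#' scale; 0 means at least one quadrant untouched while another is reached
#' (or nothing reached anywhere).
#'
#' @param raster a grayscale darkness matrix in `[0, 1]` (e.g. from
#'   [render_terminal_spheres()]).
#' @param threshold grey fraction above which a pixel counts as reached
#'   (default 0.9).
#' @return list with `AR` (named fractions: `upper_left`, `upper_right`,
#'   `lower_left`, `lower_right`) and `QHI` in `[0, 1]`.
#' @export
sqhi <- function(raster, threshold = 0.9) {
  bw <- unclass(raster) >= threshold
  nr <- nrow(bw); nc <- ncol(bw)
  top <- seq_len(nr %/% 2L); bot <- (nr %/% 2L + 1L):nr
  lef <- seq_len(nc %/% 2L); rig <- (nc %/% 2L + 1L):nc
  AR <- c(upper_left = mean(bw[top, lef]),
          upper_right = mean(bw[top, rig]),
          lower_left = mean(bw[bot, lef]),
          lower_right = mean(bw[bot, rig]))
  QHI <- if (max(AR) == 0) 0 else min(AR) / max(AR)
  list(AR = AR, QHI = QHI)
}

#' Write a raster as a plain-text PGM image
#'
#' Portable graymap (P2, ASCII): 0 = black, maxval = white. Darkness values
#' are inverted so that a fully coated sphere prints black.
#'
#' @param raster darkness matrix in `[0, 1]`.
#' @param path output file.
#' @param maxval maximum grey value (default 255).
#' @export
write_pgm <- function(raster, path, maxval = 255L) {
  g <- round((1 - unclass(raster)) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), as.character(maxval)), con)
  write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
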