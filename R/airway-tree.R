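#' plugflow: liquid plug transport through branching airway trees
#'
#' Simulates instillation of a liquid surfactant mixture into a conducting
#' airway tree. The model alternates two steps: deposition of a trailing film
#' on the airway wall while a plug transits an airway (a capillary-number
#' law), and splitting of the plug at each bifurcation (a quadratic balance
#' of inertial, viscous, capillary and gravitational terms). On top of the
#' two mechanical steps the package provides tree generators emulating rat
#' lung morphometry, single- and multiple-aliquot instillation protocols
#' with posture sequences, and delivery-performance indices.
#'
#' @section Units:
#' CGS throughout: lengths in cm, volumes in mL (= cm^3), viscosity in poise
#' (1 P = 100 cP), surface tension in dyn/cm, density in g/cm^3,
#' g = 981 cm/s^2.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif
#' @importFrom utils read.delim write.table
NULL

# ---------------------------------------------------------------------------
# airway_tree: a rooted binary-branching tree of rigid tubes with a 3D
# embedding in the body frame.
#
# Body frame convention: x anterior (ventral), y toward the animal's left,
# z caudal -> cranial. The trachea initially points along -z.
# ---------------------------------------------------------------------------

#' Construct an airway tree from a morphometry-style table
#'
#' Low-level constructor. Most users will call [read_morphometry()],
#' [build_symmetric_tree()], [generate_monopodial_tree()] or [toy_tree()].
#'
#' @param airways data.frame with columns `id` (unique integers),
#'   `parent_id` (integer; `NA` or `-1` for the root), `diameter` and
#'   `length` (cm), `theta` (signed branching angle to the parent axis,
#'   radians) and `psi` (rotation of this bifurcation plane relative to the
#'   parent's, radians; siblings conventionally share `psi`).
#' @param body_weight body weight in kg associated with the tree.
#' @param provenance one of `"morphometry_table"`, `"symmetric_builder"`,
#'   `"monopodial_generator"` or a free-form label.
#' @param embed compute the 3D embedding (default `TRUE`).
#'
#' @return An object of class `airway_tree`: a list with elements `airways`
#'   (one row per airway, including the embedded direction, bifurcation-plane
#'   normal and proximal/distal coordinates), `children` (N x 2 matrix of row
#'   indices, `NA` for terminals), `root_id`, `terminal_ids`, `body_weight`
#'   and `provenance`. Coating state (`coated_length`, `coating_volume`) is
#'   initialised to zero.
#' @export
airway_tree <- function(airways, body_weight = NA_real_,
                        provenance = "morphometry_table", embed = TRUE) {
  req <- c("id", "parent_id", "diameter", "length", "theta", "psi")
  miss <- setdiff(req, names(airways))
  if (length(miss) > 0L)
    stop("airway table is missing column(s): ", paste(miss, collapse = ", "))
  af <- airways[req]
  af$id <- as.integer(af$id)
  af$parent_id <- as.integer(af$parent_id)
  af$parent_id[!is.na(af$parent_id) & af$parent_id == -1L] <- NA_integer_
  n <- nrow(af)
  if (n < 1L) stop("airway table is empty")
  if (anyDuplicated(af$id))
    stop("duplicate airway id in row ",
         which(duplicated(af$id))[1L])

  bad <- which(!(af$diameter > 0) | !(af$length > 0))
  if (length(bad) > 0L)
    stop("non-positive diameter or length in row ", bad[1L],
         " (id ", af$id[bad[1L]], ")")

  self_loop <- which(!is.na(af$parent_id) & af$parent_id == af$id)
  if (length(self_loop) > 0L)
    stop("cycle: airway is its own parent in row ", self_loop[1L],
         " (id ", af$id[self_loop[1L]], ")")

  root_rows <- which(is.na(af$parent_id))
  if (length(root_rows) == 0L) stop("no root row (parent_id NA or -1)")
  if (length(root_rows) > 1L)
    stop("multiple roots: rows ", paste(root_rows, collapse = ", "))

  prow <- match(af$parent_id, af$id)
  orphan <- which(!is.na(af$parent_id) & is.na(prow))
  if (length(orphan) > 0L)
    stop("unknown parent_id ", af$parent_id[orphan[1L]], " in row ",
         orphan[1L])

  # children and arity
  kids <- split(seq_len(n), factor(prow, levels = seq_len(n)))
  nkid <- lengths(kids)
  bad_arity <- which(!(nkid %in% c(0L, 2L)))
  if (length(bad_arity) > 0L)
    stop("non-binary internal node: airway id ", af$id[bad_arity[1L]],
         " (row ", bad_arity[1L], ") has ", nkid[bad_arity[1L]],
         " child(ren)")
  children <- matrix(NA_integer_, n, 2L)
  for (i in which(nkid == 2L)) children[i, ] <- sort(kids[[i]])

  # generations via BFS; detects cycles / disconnected components
  gen <- rep(NA_integer_, n)
  gen[root_rows] <- 0L
  frontier <- root_rows
  while (length(frontier) > 0L) {
    nxt <- which(prow %in% frontier & is.na(gen))
    gen[nxt] <- gen[prow[nxt]] + 1L
    frontier <- nxt
  }
  if (anyNA(gen)) {
    r <- which(is.na(gen))[1L]
    stop("cycle or disconnected component involving row ", r,
         " (id ", af$id[r], ")")
  }
  af$generation <- gen
  af$dir_x <- af$dir_y <- af$dir_z <- NA_real_
  af$nrm_x <- af$nrm_y <- af$nrm_z <- NA_real_
  af$x0 <- af$y0 <- af$z0 <- NA_real_
  af$x1 <- af$y1 <- af$z1 <- NA_real_
  af$coated_length <- 0
  af$coating_volume <- 0
  rownames(af) <- NULL

  tree <- structure(
    list(airways = af,
         children = children,
         root_id = af$id[root_rows],
         terminal_ids = af$id[is.na(children[, 1L])],
         body_weight = body_weight,
         provenance = provenance),
    class = "airway_tree")
  if (embed) tree <- embed_tree(tree) else tree
}

#' Number of terminal airways
#' @param tree an `airway_tree`.
#' @return Integer count of terminal (childless) airways, the M of the delivery indices.
#' @export
n_terminals <- function(tree) length(tree$terminal_ids)

#' Number of airways in the tree
#' @param tree an `airway_tree`.
#' @export
n_airways <- function(tree) nrow(tree$airways)

#' Total airway wall surface area
#'
#' Lateral (cylindrical) wall area summed over all airways, `sum(pi * D * L)`
#' in cm^2. Used to match symmetric and asymmetric trees at equal coating
#' capacity.
#'
#' @param tree an `airway_tree`.
#' @export
tree_wall_area <- function(tree) {
  with(tree$airways, sum(pi * diameter * length))
}

#' @export
print.airway_tree <- function(x, ...) {
  af <- x$airways
  cat("airway_tree (", x$provenance, ")\n", sep = "")
  cat("  airways:          ", nrow(af), "\n", sep = "")
  cat("  terminal branches:", length(x$terminal_ids), "\n")
  cat("  max generation:   ", max(af$generation), "\n")
  cat("  tracheal diameter:", signif(af$diameter[af$id == x$root_id], 3),
      "cm\n")
  cat("  wall surface area:", signif(tree_wall_area(x), 4), "cm^2\n")
  if (!is.na(x$body_weight))
    cat("  body weight:      ", x$body_weight, "kg\n")
  invisible(x)
}

# row index of an airway id
.row_of <- function(tree, id) {
  r <- match(id, tree$airways$id)
  if (anyNA(r)) stop("unknown airway id: ", paste(id[is.na(r)], collapse = ", "))
  r
}

.is_embedded <- function(tree) !anyNA(tree$airways$dir_x)

#' Airway node coordinates
#'
#' One row per airway with its proximal and distal endpoint coordinates in
#' the body frame, for external visualisation.
#'
#' @param tree an embedded `airway_tree`.
#' @return data.frame with `id`, `generation`, `terminal`, `x0..z0` (proximal)
#'   and `x1..z1` (distal), in cm.
#' @export
airway_coordinates <- function(tree) {
  if (!.is_embedded(tree)) stop("tree is not embedded; call embed_tree()")
  af <- tree$airways
  data.frame(id = af$id, generation = af$generation,
             terminal = is.na(tree$children[, 1L]),
             x0 = af$x0, y0 = af$y0, z0 = af$z0,
             x1 = af$x1, y1 = af$y1, z1 = af$z1)
}
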