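# Tree builders: regular symmetric trees, the stochastic monopodial
# generator, and the per-generation-average symmetric counterpart.

#' Build a regular (Weibel-style) symmetric airway tree
#'
#' A full binary tree in which all airways of the same generation share the
#' same diameter and length, every bifurcation has branching angle
#' `2 * branching_angle` split symmetrically, and successive bifurcation
#' planes rotate by alternating +90/-90 degrees per generation.
#'
#' @param n_generations number of bifurcating generations (>= 1); the tree
#'   has `2^n_generations` terminal airways.
#' @param trachea_diameter,trachea_length tracheal dimensions in cm.
#' @param diameter_ratio,length_ratio per-generation scale factors; scalars
#'   (constant ratio) or vectors of length `n_generations`.
#' @param branching_angle half-branching angle in radians (default `pi/4`,
#'   i.e. a 90-degree opening).
#' @param body_weight body weight in kg carried by the tree.
#' @return An embedded `airway_tree` with provenance `"symmetric_builder"`.
#' @export
build_symmetric_tree <- function(n_generations,
                                 trachea_diameter = 0.34,
                                 trachea_length = 2.5,
                                 diameter_ratio = 0.78,
                                 length_ratio = 0.85,
                                 branching_angle = pi / 4,
                                 body_weight = 0.330) {
  if (n_generations < 1L) stop("n_generations must be >= 1")
  if (trachea_diameter <= 0 || trachea_length <= 0)
    stop("non-positive tracheal dimensions")
  dr <- rep_len(diameter_ratio, n_generations)
  lr <- rep_len(length_ratio, n_generations)
  if (any(dr <= 0) || any(lr <= 0)) stop("non-positive scale ratio")
  D <- trachea_diameter * cumprod(c(1, dr))
  L <- trachea_length * cumprod(c(1, lr))
  .symmetric_from_dims(D, L, branching_angle, body_weight,
                       provenance = "symmetric_builder")
}

# full binary tree from per-generation absolute dimensions D[g+1], L[g+1]
.symmetric_from_dims <- function(D, L, branching_angle, body_weight,
                                 provenance) {
  ngen <- length(D) - 1L
  n <- 2L^(ngen + 1L) - 1L
  id <- seq_len(n) - 1L                      # heap order, 0-based ids
  gen <- as.integer(floor(log2(id + 1) + 1e-9))
  parent <- ifelse(id == 0L, NA_integer_, (id - 1L) %/% 2L)
  first_child <- (id %% 2L) == 1L            # left child of its parent
  theta <- ifelse(is.na(parent), 0,
                  ifelse(first_child, branching_angle, -branching_angle))
  # bifurcation planes alternate +90/-90 by generation; generation-1
  # airways keep the root reference plane
  psi <- ifelse(is.na(parent) | gen == 1L, 0,
                ifelse(gen %% 2L == 0L, pi / 2, -pi / 2))
  af <- data.frame(id = id, parent_id = parent,
                   diameter = D[gen + 1L], length = L[gen + 1L],
                   theta = theta, psi = psi)
  airway_tree(af, body_weight = body_weight, provenance = provenance)
}

#' Generate a stochastic monopodial airway tree
#'
#' Emulates the strongly asymmetric (monopodial) branching of the rat lung:
#' at every bifurcation a major daughter continues with a large
#' daughter-to-parent diameter ratio and a small branching angle, while a
#' minor lateral daughter branches off with a small diameter ratio and a
#' large branching angle. Growth stops when the airway diameter falls to the
#' cutoff; with the defaults the tree starts from a 0.34 cm trachea and its
#' terminal count lands in a band around 1457 terminal branches.
#'
#' Diameter ratios are drawn from truncated normals around `lambda_major` /
#' `lambda_minor`, branching angles (degrees) from truncated normals with
#' the configured means and sds, and the rotation angle between successive
#' bifurcation planes uniformly from `psi_range_deg` with a random sign.
#' Airway length is `length_to_diameter` times the diameter with lognormal
#' scatter.
#'
#' @param seed integer seed; the same seed reproduces the identical tree.
#' @param trachea_diameter,trachea_length tracheal dimensions (cm).
#' @param lambda_major,lambda_minor mean daughter/parent diameter ratios.
#' @param lambda_sd sd of the diameter-ratio scatter.
#' @param theta_major_deg,theta_major_sd_deg,theta_minor_deg,theta_minor_sd_deg
#'   branching-angle statistics in degrees (major / minor daughter).
#' @param psi_range_deg range of the rotation angle between successive
#'   bifurcation planes, degrees.
#' @param length_to_diameter mean length-to-diameter ratio of an airway.
#' @param length_sd lognormal sd of the length scatter.
#' @param diameter_cutoff growth cutoff in cm: an airway bifurcates only
#'   while its diameter exceeds the cutoff. Must be > 0.
#' @param max_airways hard cap guarding against runaway configurations.
#' @param body_weight body weight in kg.
#' @return An embedded `airway_tree`, provenance `"monopodial_generator"`.
#' @export
generate_monopodial_tree <- function(seed,
                                     trachea_diameter = 0.34,
                                     trachea_length = 2.5,
                                     lambda_major = 0.92,
                                     lambda_minor = 0.50,
                                     lambda_sd = 0.12,
                                     theta_major_deg = 19.3,
                                     theta_major_sd_deg = 14.6,
                                     theta_minor_deg = 60.5,
                                     theta_minor_sd_deg = 19.4,
                                     psi_range_deg = c(24, 53),
                                     length_to_diameter = 3.0,
                                     length_sd = 0.40,
                                     diameter_cutoff = 0.019,
                                     max_airways = 50000L,
                                     body_weight = 0.330) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (!(diameter_cutoff > 0))
    stop("diameter_cutoff must be > 0: growth would be unbounded")
  if (trachea_diameter <= 0 || trachea_length <= 0)
    stop("non-positive tracheal dimensions")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  rtnorm <- function(n, mean, sd, lo, hi) {
    x <- rnorm(n, mean, sd)
    pmin(hi, pmax(lo, x))
  }

  cap <- as.integer(max_airways)
  id <- integer(cap); parent <- integer(cap)
  D <- numeric(cap); L <- numeric(cap)
  theta <- numeric(cap); psi <- numeric(cap)
  id[1L] <- 0L; parent[1L] <- NA_integer_
  D[1L] <- trachea_diameter; L[1L] <- trachea_length
  theta[1L] <- 0; psi[1L] <- 0
  n <- 1L
  head <- 1L
  while (head <= n) {
    if (D[head] > diameter_cutoff) {
      if (n + 2L > cap)
        stop("tree exceeded max_airways = ", cap,
             "; configuration grows too far")
      lm <- rtnorm(1L, lambda_major, lambda_sd, 0.50, 0.95)
      ln <- rtnorm(1L, lambda_minor, lambda_sd, 0.40, 0.90)
      t_maj <- rtnorm(1L, theta_major_deg, theta_major_sd_deg, 1, 85) * pi / 180
      t_min <- rtnorm(1L, theta_minor_deg, theta_minor_sd_deg, 5, 88) * pi / 180
      p <- sample(c(-1, 1), 1L) *
        runif(1L, psi_range_deg[1L], psi_range_deg[2L]) * pi / 180
      side <- sample(c(-1, 1), 1L)   # which side the minor daughter leaves on
      for (k in 1:2) {
        n <- n + 1L
        id[n] <- n - 1L
        parent[n] <- id[head]
        if (k == 1L) {               # major daughter
          D[n] <- D[head] * lm
          theta[n] <- -side * t_maj
        } else {                     # minor daughter
          D[n] <- D[head] * ln
          theta[n] <- side * t_min
        }
        L[n] <- length_to_diameter * D[n] * exp(rnorm(1L, 0, length_sd))
        psi[n] <- p
      }
    }
    head <- head + 1L
  }
  af <- data.frame(id = id[1:n], parent_id = parent[1:n],
                   diameter = D[1:n], length = L[1:n],
                   theta = theta[1:n], psi = psi[1:n])
  airway_tree(af, body_weight = body_weight,
              provenance = "monopodial_generator")
}

#' Symmetric counterpart of an asymmetric tree at equal wall area
#'
#' Builds a regular symmetric tree whose generation-g airways take the mean
#' diameter and length of generation g of `tree`, with 90-degree openings
#' and alternating bifurcation planes, then (optionally) rescales all
#' lengths by a single factor so that the total wall surface area
#' `sum(pi*D*L)` matches the asymmetric tree. Used to isolate the effect of
#' branching asymmetry from that of coating capacity.
#'
#' @param tree an `airway_tree`.
#' @param n_generations depth of the symmetric tree; defaults to
#'   `floor(log2(n_terminals(tree)))` so the two trees have comparable
#'   terminal counts.
#' @param match_area rescale lengths to equal total wall area (default TRUE).
#' @return An embedded `airway_tree`, provenance `"symmetric_builder"`.
#' @export
matched_symmetric_tree <- function(tree, n_generations = NULL,
                                   match_area = TRUE) {
  af <- tree$airways
  if (is.null(n_generations))
    n_generations <- max(1L, floor(log2(n_terminals(tree))))
  gmax <- max(af$generation)
  if (n_generations > gmax)
    stop("tree has only ", gmax, " generations")
  Dg <- tapply(af$diameter, af$generation, mean)[as.character(0:n_generations)]
  Lg <- tapply(af$length, af$generation, mean)[as.character(0:n_generations)]
  sym <- .symmetric_from_dims(as.numeric(Dg), as.numeric(Lg),
                              branching_angle = pi / 4,
                              body_weight = tree$body_weight,
                              provenance = "symmetric_builder")
  if (match_area) {
    s <- tree_wall_area(tree) / tree_wall_area(sym)
    sym$airways$length <- sym$airways$length * s
    sym <- embed_tree(sym)
  }
  sym
}
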