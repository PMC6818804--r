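# Canned study conditions and toy trees making every stage testable offline.

#' Canned instillation condition presets
#'
#' Fully populated fluid/protocol conditions from published rat instillation
#' studies, with the dimensionless numbers those studies printed so tests
#' can recompute and compare them:
#' \describe{
#'   \item{`cassidy_sim`}{simulation arm of the multiple-aliquot rat imaging
#'     comparison: diluted surfactant (12.2 cP, 54 dyn/cm, 1.22 g/mL),
#'     26.8 mL/s/kg, 0.330 kg, 0.34 cm trachea, vertical posture,
#'     1 mL/kg total in 10 aliquots. Printed: Ca 0.22, Bo 0.64, Re 165,
#'     tracheal velocity 97 cm/s.}
#'   \item{`cassidy_exp`}{experimental arm of the same study: 16 mL/s/kg,
#'     0.500 kg, 0.324 cm trachea. Printed: Ca 0.22, Bo 0.58, Re 160,
#'     velocity 97 cm/s.}
#'   \item{`nieman_exp`}{dye-tagged dose-escalation experiments: clinical
#'     surfactant (30 cP, 30 dyn/cm, 1 g/mL), 6 mL/s/kg (tidal volume
#'     6 mL/kg, 20 breaths/min, I:E 1:2), ~0.450 kg rats, divided L+R
#'     posture, doses 1.125, 2.5 and 5.8 mL/kg.}
#'   \item{`normal_breathing`}{reference tracheal conditions of a normally
#'     breathing 0.330 kg rat: 30 mL/s/kg with clinical surfactant.
#'     Printed: Re ~61, Ca ~1, Bo ~1 in the trachea.}
#' }
#'
#' @param name preset name.
#' @return list of class `condition_preset` with `name`, `fluid`
#'   (a [fluid_properties()]), `flow_rate_per_kg`, `body_weight`,
#'   `dose_volume_per_kg` (possibly a vector of studied doses),
#'   `n_aliquots`, `postures`, `trachea_diameter`, `expected` (printed
#'   dimensionless values, where available) and `context` (ventilation
#'   settings the flow rate derives from).
#' @export
condition_preset <- function(name = c("cassidy_sim", "cassidy_exp",
                                      "nieman_exp", "normal_breathing")) {
  name <- match.arg(name)
  p <- switch(name,
    cassidy_sim = list(
      fluid = fluid_properties(0.122, 1.22, 54),
      flow_rate_per_kg = 26.8, body_weight = 0.330,
      dose_volume_per_kg = 1, n_aliquots = 10L,
      postures = posture("VERTICAL"),
      trachea_diameter = 0.34,
      expected = list(Ca = 0.22, Bo = 0.64, Re = 165, U = 97),
      context = list(tidal_volume_per_kg = 8)),
    cassidy_exp = list(
      fluid = fluid_properties(0.122, 1.22, 54),
      flow_rate_per_kg = 16, body_weight = 0.500,
      dose_volume_per_kg = 1, n_aliquots = 10L,
      postures = posture("VERTICAL"),
      trachea_diameter = 0.324,
      expected = list(Ca = 0.22, Bo = 0.58, Re = 160, U = 97),
      context = list(tidal_volume_per_kg = 8)),
    nieman_exp = list(
      fluid = fluid_properties(0.30, 1, 30),
      flow_rate_per_kg = 6, body_weight = 0.450,
      dose_volume_per_kg = c(1.125, 2.5, 5.8), n_aliquots = 1L,
      postures = posture_sequence_LR(),
      trachea_diameter = 0.34,
      expected = NULL,
      context = list(tidal_volume_per_kg = 6, frequency_per_min = 20,
                     IE_ratio = c(1, 2))),
    normal_breathing = list(
      fluid = fluid_properties(0.30, 1, 30),
      flow_rate_per_kg = 30, body_weight = 0.330,
      dose_volume_per_kg = 1, n_aliquots = 1L,
      postures = posture("LLD"),
      trachea_diameter = 0.34,
      expected = list(Re = 61, Bo = 0.95, Ca = 1.1),
      context = NULL))
  structure(c(list(name = name), p), class = "condition_preset")
}

#' Canned toy airway trees
#'
#' Small deterministic trees for worked examples and tests:
#' \describe{
#'   \item{`single_bifurcation`}{trachea plus two identical daughters
#'     (half-angle 45 degrees), M = 2.}
#'   \item{`fig5_bifurcation`}{one asymmetric bifurcation with
#'     daughter/parent diameter ratios 0.83 (major) and 0.72 (minor) and
#'     both branching angles 45 degrees; the bifurcation plane contains the
#'     left-right axis, so a `posture("CUSTOM", gravity = c(0, -1, 0))`
#'     makes it a vertical-plane bifurcation with the major daughter down.}
#'   \item{`three_generation_symmetric`}{regular symmetric tree with three
#'     bifurcating generations, M = 8.}
#' }
#'
#' @param name tree name.
#' @return An embedded `airway_tree`.
#' @export
toy_tree <- function(name = c("single_bifurcation", "fig5_bifurcation",
                              "three_generation_symmetric")) {
  name <- match.arg(name)
  switch(name,
    single_bifurcation = {
      af <- data.frame(id = 0:2, parent_id = c(NA, 0L, 0L),
                       diameter = c(0.34, 0.272, 0.272),
                       length = c(2.5, 1.0, 1.0),
                       theta = c(0, pi / 4, -pi / 4),
                       psi = c(0, 0, 0))
      airway_tree(af, body_weight = 0.330, provenance = "toy")
    },
    fig5_bifurcation = {
      # theta > 0 tips toward +y; with gravity -y the major daughter
      # (theta = -45 deg) is the lower one
      af <- data.frame(id = 0:2, parent_id = c(NA, 0L, 0L),
                       diameter = c(0.34, 0.34 * 0.83, 0.34 * 0.72),
                       length = c(2.5, 0.9, 0.8),
                       theta = c(0, -pi / 4, pi / 4),
                       psi = c(0, 0, 0))
      airway_tree(af, body_weight = 0.330, provenance = "toy")
    },
    three_generation_symmetric =
      build_symmetric_tree(3, trachea_diameter = 0.34, trachea_length = 2.5,
                           diameter_ratio = 0.78, length_ratio = 0.85))
}
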