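# Readers and writers: morphometry tables (tab-delimited text, one row per
# airway) and a JSON export of the full tree state.

#' Read an airway tree from a morphometry table
#'
#' Dialect: tab-delimited text with a header row and columns `id`,
#' `parent_id`, `diameter_cm`, `length_cm`, `branching_angle_deg` (signed
#' angle to the parent axis) and `rotation_angle_deg` (rotation between
#' successive bifurcation planes; siblings conventionally share the value).
#' Ids are 0-based integers; the root row has `parent_id` -1 (or empty).
#' Diameters are circular diameters in cm.
#'
#' @param path file to read.
#' @param body_weight body weight in kg to attach to the tree.
#' @return An embedded `airway_tree` with provenance `"morphometry_table"`.
#' @export
read_morphometry <- function(path, body_weight = NA_real_) {
  tb <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  req <- c("id", "parent_id", "diameter_cm", "length_cm",
           "branching_angle_deg", "rotation_angle_deg")
  miss <- setdiff(req, names(tb))
  if (length(miss) > 0L)
    stop("morphometry table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  af <- data.frame(id = tb$id, parent_id = tb$parent_id,
                   diameter = tb$diameter_cm, length = tb$length_cm,
                   theta = tb$branching_angle_deg * pi / 180,
                   psi = tb$rotation_angle_deg * pi / 180)
  airway_tree(af, body_weight = body_weight,
              provenance = "morphometry_table")
}

#' Write an airway tree as a morphometry table
#'
#' Inverse of [read_morphometry()]; writes the tab-delimited dialect
#' documented there (angles in degrees, lengths in cm, root `parent_id` -1).
#'
#' @param tree an `airway_tree`.
#' @param path file to write.
#' @export
write_morphometry <- function(tree, path) {
  af <- tree$airways
  tb <- data.frame(id = af$id,
                   parent_id = ifelse(is.na(af$parent_id), -1L, af$parent_id),
                   diameter_cm = af$diameter, length_cm = af$length,
                   branching_angle_deg = af$theta * 180 / pi,
                   rotation_angle_deg = af$psi * 180 / pi)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import the full airway tree state as JSON
#'
#' Serialises the complete tree (dimensions, angles, embedding, coating
#' state, body weight, provenance) so that a tree round-trips exactly.
#'
#' @param tree an `airway_tree`.
#' @param path file to write / read.
#' @return `read_tree_json` returns the reconstructed `airway_tree`.
#' @export
write_tree_json <- function(tree, path) {
  payload <- list(format = "plugflow_tree", version = 1L,
                  body_weight = tree$body_weight,
                  provenance = tree$provenance,
                  root_id = tree$root_id,
                  airways = tree$airways)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "plugflow_tree"))
    stop(path, " is not a plugflow tree JSON file")
  af <- payload$airways
  tree <- airway_tree(af[c("id", "parent_id", "diameter", "length",
                           "theta", "psi")],
                      body_weight = payload$body_weight,
                      provenance = payload$provenance, embed = TRUE)
  # restore coating state
  r <- match(tree$airways$id, af$id)
  tree$airways$coated_length <- af$coated_length[r]
  tree$airways$coating_volume <- af$coating_volume[r]
  tree
}
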