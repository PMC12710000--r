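# RSML (Root System Markup Language) interchange.
#
# Reads the common RSML layout: rsml > metadata + scene > plant > root
# (recursively nested laterals), geometry/polyline/point with x/y/z
# attributes, and per-node diameters as a "diameter" sample function.
# Root-level diameter properties/attributes are honoured as a fallback.
# Coordinates are scaled to cm using the metadata unit and resolution fields.

UNIT_TO_CM <- c(m = 100, dm = 10, cm = 1, mm = 0.1, um = 1e-4,
                micron = 1e-4, inch = 2.54, pixel = 1)

#' Read a root system from an RSML file
#'
#' @param path Path to an RSML (XML) file.
#' @param default_diameter Diameter (cm) assigned to nodes when the file
#'   carries none; tracings made without diameter information remain
#'   scoreable.
#' @param flip_z Negate the z axis on read. The package convention is
#'   right-handed with z increasing downward into the soil column; files
#'   written with z up can be flipped here.
#' @return A validated [root_system()], with all coordinates in cm.
#' @details Root branching order is inferred from nesting depth (a root
#'   nested inside another is one order deeper); an explicit `order`
#'   property that disagrees with the nesting depth is overridden with a
#'   warning. The metadata `unit` and `resolution` fields are applied
#'   multiplicatively to all coordinates and diameters.
#' @export
read_rsml <- function(path, default_diameter = 0.1, flip_z = FALSE) {
  if (!file.exists(path)) stop_parse("RSML file does not exist: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_parse("malformed XML in %s: %s", path, conditionMessage(e)))
  if (xml2::xml_name(doc) != "rsml")
    stop_parse("%s: top-level element is <%s>, expected <rsml>",
               path, xml2::xml_name(doc))

  unit <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/unit"))
  resolution <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/resolution"))
  scale <- 1
  if (!is.na(unit) && nzchar(unit)) {
    u <- tolower(trimws(unit))
    if (!u %in% names(UNIT_TO_CM)) {
      warning(sprintf("unknown RSML unit '%s'; assuming cm", unit))
    } else scale <- UNIT_TO_CM[[u]]
  }
  if (!is.na(resolution) && nzchar(resolution)) {
    res <- suppressWarnings(as.numeric(resolution))
    if (is.finite(res) && res > 0) scale <- scale * res
  }

  label <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/label"))
  if (is.na(label)) label <- ""

  roots <- list()
  walk <- function(node, depth, parent_id) {
    id <- xml2::xml_attr(node, "ID") %||% NA_character_
    if (is.na(id)) id <- xml2::xml_attr(node, "id")
    if (is.na(id)) id <- sprintf("root_%d", length(roots) + 1L)
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    if (length(pts) < 2L)
      stop_validation("root '%s' in %s has fewer than 2 points", id, path)
    xyz <- cbind(as.numeric(xml2::xml_attr(pts, "x")),
                 as.numeric(xml2::xml_attr(pts, "y")),
                 as.numeric(xml2::xml_attr(pts, "z")))
    if (anyNA(xyz))
      stop_parse("root '%s' in %s: non-numeric point coordinates", id, path)
    xyz <- xyz * scale
    if (flip_z) xyz[, 3L] <- -xyz[, 3L]

    # per-node diameter function, else root-level property/attribute, else default
    dia_samples <- xml2::xml_find_all(
      node, "./functions/function[@name='diameter']/sample")
    if (length(dia_samples) == nrow(xyz)) {
      dia <- as.numeric(xml2::xml_attr(dia_samples, "value"))
      if (anyNA(dia)) dia <- as.numeric(xml2::xml_text(dia_samples))
      dia <- dia * scale
    } else {
      d1 <- xml2::xml_attr(
        xml2::xml_find_first(node, "./properties/property[@name='diameter']"),
        "value")
      if (is.na(d1)) d1 <- xml2::xml_attr(node, "diameter")
      dia <- if (!is.na(d1)) as.numeric(d1) * scale else default_diameter
    }

    depth_order <- depth
    prop_order <- xml2::xml_attr(
      xml2::xml_find_first(node, "./properties/property[@name='order']"),
      "value")
    if (!is.na(prop_order) &&
        suppressWarnings(as.integer(prop_order)) != depth_order)
      warning(sprintf(
        "root '%s': order property %s conflicts with nesting depth %d; using depth",
        id, prop_order, depth_order))

    att <- xml2::xml_attr(
      xml2::xml_find_first(node, "./properties/property[@name='attachment']"),
      "value")
    att <- if (!is.na(att)) as.numeric(att) * scale else NULL

    roots[[length(roots) + 1L]] <<- root(
      root_id = id, nodes = xyz, diameters = dia,
      order = depth_order, parent_root_id = parent_id,
      parent_attachment = att)

    for (child in xml2::xml_find_all(node, "./root"))
      walk(child, depth + 1L, id)
  }

  for (top in xml2::xml_find_all(doc, "./scene/plant/root"))
    walk(top, 0L, NULL)

  root_system(roots = roots, label = label, unit = "cm")
}

#' Write a root system to an RSML file
#'
#' Emits per-node coordinates and a per-node "diameter" sample function,
#' nests lateral roots under their parent root element, and writes a
#' metadata block with the unit (cm), resolution 1 and a software tag.
#'
#' @param rsa A valid [root_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(rsa, path) {
  validate_root_system(rsa)
  doc <- xml2::xml_new_root("rsml", version = "1.0")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "cm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "rsaeval")
  xml2::xml_add_child(meta, "last-modified", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (nzchar(rsa$label)) xml2::xml_add_child(meta, "label", rsa$label)
  scene <- xml2::xml_add_child(doc, "scene")

  ids <- root_ids(rsa)
  parents <- vapply(rsa$roots, function(r) r$parent_root_id %||% NA_character_,
                    character(1))
  fmt <- function(x) formatC(x, format = "g", digits = 12)

  add_root <- function(parent_node, r) {
    rn <- xml2::xml_add_child(parent_node, "root", ID = r$root_id)
    props <- xml2::xml_add_child(rn, "properties")
    xml2::xml_add_child(props, "property", name = "order",
                        value = as.character(r$order))
    if (!is.null(r$parent_attachment))
      xml2::xml_add_child(props, "property", name = "attachment",
                          value = fmt(r$parent_attachment))
    geom <- xml2::xml_add_child(rn, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (i in seq_len(nrow(r$nodes)))
      xml2::xml_add_child(poly, "point",
                          x = fmt(r$nodes[i, 1L]),
                          y = fmt(r$nodes[i, 2L]),
                          z = fmt(r$nodes[i, 3L]))
    fns <- xml2::xml_add_child(rn, "functions")
    fn <- xml2::xml_add_child(fns, "function", name = "diameter",
                              domain = "polyline")
    for (d in r$diameters)
      xml2::xml_add_child(fn, "sample", value = fmt(d))
    for (child in rsa$roots[which(!is.na(parents) & parents == r$root_id)])
      add_root(rn, child)
    rn
  }

  tops <- rsa$roots[is.na(parents)]
  if (length(tops)) {
    plant <- xml2::xml_add_child(scene, "plant", id = "1")
    for (r in tops) add_root(plant, r)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
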