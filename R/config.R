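#' Read a probe geometry configuration (YAML or JSON)
#'
#' The config carries `type: rect` or `type: tbeam`, the dimension fields
#' in um, and optionally a `material: {name, E_GPa}` block. For `rect`:
#' `width_b`, `thickness_h`. For `tbeam`: `planar_width`,
#' `planar_thickness`, `fin_depth`, `fin_top_width`, `fin_tip_width`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `section` (a `cross_section`) and
#'   `material` (a [material()] or NULL).
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop("geometry config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$type)) stop("geometry config needs `type: rect` or `type: tbeam`")
  need <- function(keys) {
    miss <- setdiff(keys, names(cfg))
    if (length(miss))
      stop("geometry config (type ", cfg$type, ") missing field(s): ",
           paste(miss, collapse = ", "))
  }
  section <- switch(cfg$type,
    rect = {
      need(c("width_b", "thickness_h"))
      rect_section(cfg$width_b, cfg$thickness_h)
    },
    tbeam = {
      need(c("planar_width", "planar_thickness", "fin_depth",
             "fin_top_width", "fin_tip_width"))
      tbeam_section(cfg$planar_width, cfg$planar_thickness, cfg$fin_depth,
                    cfg$fin_top_width, cfg$fin_tip_width)
    },
    stop("unknown geometry type '", cfg$type, "' (rect or tbeam)"))
  mat <- if (!is.null(cfg$material))
    material(cfg$material$name, cfg$material$E_GPa) else NULL
  list(section = section, material = mat)
}

#' Export a contour as a CSV vertex list
#'
#' Writes the polygon's vertices (columns `x`, `y`, um, y positive
#' downward) for plotting or inspection; the closing edge back to the
#' first vertex is implicit.
#'
#' @param poly A [section_polygon()] or a `cross_section`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(poly, path) {
  if (inherits(poly, "cross_section")) poly <- make_contour(poly)
  utils::write.csv(as.data.frame(poly), path, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic-network configuration (YAML or JSON)
#'
#' Keys mirror [synth_network_config()]: `box_um` (length-3),
#' `length_density`, `length_dist`, `diameter_dist`, `seed`. Missing keys
#' fall back to the generator defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [synth_network_config()].
#' @export
read_synth_network_config <- function(path) {
  if (!file.exists(path)) stop("network config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- synth_network_config()
  args <- list(
    box_um = if (!is.null(cfg$box_um)) unlist(cfg$box_um) else defaults$box_um,
    length_density = cfg$length_density %||% defaults$length_density,
    length_dist = cfg$length_dist %||% defaults$length_dist,
    diameter_dist = cfg$diameter_dist %||% defaults$diameter_dist,
    seed = cfg$seed %||% defaults$seed)
  do.call(synth_network_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
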