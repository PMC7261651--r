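#' Rectangular probe cross-section
#'
#' A solid rectangle of width `width_b` (lateral, the probe's planar width)
#' and thickness `thickness_h` (depth, measured from the top surface down).
#' All dimensions are in micrometres; the package keeps micrometres
#' internally everywhere, converting only at I/O boundaries.
#'
#' @param width_b Lateral width b, um. Must be > 0.
#' @param thickness_h Thickness (height) h, um. Must be > 0.
#' @return An object of class `c("rect_section", "cross_section")`.
#' @examples
#' rect_section(65, 34)
#' @export
rect_section <- function(width_b, thickness_h) {
  stopifnot(is.numeric(width_b), length(width_b) == 1L,
            is.numeric(thickness_h), length(thickness_h) == 1L)
  if (!is.finite(width_b) || width_b <= 0)
    stop("`width_b` must be a positive finite number (um), got ", width_b)
  if (!is.finite(thickness_h) || thickness_h <= 0)
    stop("`thickness_h` must be a positive finite number (um), got ", thickness_h)
  structure(
    list(width_b = as.numeric(width_b), thickness_h = as.numeric(thickness_h)),
    class = c("rect_section", "cross_section")
  )
}

#' T-shaped probe cross-section (planar top + trapezoidal vertical fin)
#'
#' The section is a planar rectangle (`planar_width` x `planar_thickness`)
#' with a trapezoidal fin attached centred beneath it. The fin is
#' `fin_depth` deep; it is `fin_top_width` wide where it joins the planar
#' part and tapers to `fin_tip_width` at its free tip. This is the raised
#' second-moment, low-added-area geometry used for stiff diamond shuttles.
#'
#' @param planar_width Width of the planar (top) portion, um.
#' @param planar_thickness Thickness of the planar portion, um.
#' @param fin_depth Depth of the vertical fin below the planar portion, um.
#' @param fin_top_width Fin width at the junction with the planar part, um.
#' @param fin_tip_width Fin width at the free tip, um (may be 0 for a
#'   triangular fin).
#' @return An object of class `c("tbeam_section", "cross_section")`.
#' @examples
#' # the diamond-shuttle study geometry
#' tbeam_section(65, 11, 27.5, 16, 2)
#' @export
tbeam_section <- function(planar_width, planar_thickness, fin_depth,
                          fin_top_width, fin_tip_width) {
  vals <- c(planar_width = planar_width, planar_thickness = planar_thickness,
            fin_depth = fin_depth, fin_top_width = fin_top_width,
            fin_tip_width = fin_tip_width)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  pos <- vals[c("planar_width", "planar_thickness", "fin_depth", "fin_top_width")]
  if (any(pos <= 0))
    stop("planar_width, planar_thickness, fin_depth and fin_top_width must all be > 0")
  if (fin_tip_width < 0)
    stop("`fin_tip_width` must be >= 0, got ", fin_tip_width)
  if (fin_top_width > planar_width)
    stop("`fin_top_width` (", fin_top_width, ") cannot exceed `planar_width` (",
         planar_width, ")")
  if (fin_tip_width > fin_top_width)
    stop("`fin_tip_width` (", fin_tip_width, ") cannot exceed `fin_top_width` (",
         fin_top_width, ")")
  structure(
    list(planar_width = as.numeric(planar_width),
         planar_thickness = as.numeric(planar_thickness),
         fin_depth = as.numeric(fin_depth),
         fin_top_width = as.numeric(fin_top_width),
         fin_tip_width = as.numeric(fin_tip_width)),
    class = c("tbeam_section", "cross_section")
  )
}

#' @export
print.rect_section <- function(x, ...) {
  cat(sprintf("Rectangular cross-section: %g um wide x %g um thick (area %g um^2)\n",
              x$width_b, x$thickness_h, section_area(x)))
  invisible(x)
}

#' @export
print.tbeam_section <- function(x, ...) {
  cat(sprintf(
    "T-beam cross-section: planar %g x %g um; fin %g um deep, %g -> %g um wide (area %g um^2)\n",
    x$planar_width, x$planar_thickness, x$fin_depth,
    x$fin_top_width, x$fin_tip_width, section_area(x)))
  invisible(x)
}

#' Shuttle material
#'
#' @param name Material name, e.g. `"UNCD"` or `"silicon"`.
#' @param youngs_modulus_E Young's modulus, GPa. Must be > 0.
#' @return An object of class `"material"`.
#' @examples
#' material("UNCD", 800)
#' material_silicon()
#' @export
material <- function(name, youngs_modulus_E) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(youngs_modulus_E) || length(youngs_modulus_E) != 1L ||
      !is.finite(youngs_modulus_E) || youngs_modulus_E <= 0)
    stop("`youngs_modulus_E` must be a positive finite number (GPa)")
  structure(list(name = name, youngs_modulus_E = as.numeric(youngs_modulus_E)),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("Material: %s, E = %g GPa\n", x$name, x$youngs_modulus_E))
  invisible(x)
}

#' @rdname material
#' @details `material_uncd()` uses 800 GPa, the modulus that best fits the
#'   ultrananocrystalline diamond shuttle's measured buckling loads.
#'   `material_silicon()` defaults to 169 GPa, the common <110> value for
#'   single-crystal silicon; it is configurable because silicon anisotropy
#'   spans roughly 130-188 GPa.
#' @export
material_uncd <- function() material("UNCD", 800)

#' @rdname material
#' @param E_GPa Young's modulus override for silicon, GPa.
#' @export
material_silicon <- function(E_GPa = 169) material("silicon", E_GPa)

#' Cross-sectional area
#'
#' Exact closed-form area of a parametric cross-section, um^2.
#'
#' @param section A `rect_section` or `tbeam_section`.
#' @return Area in um^2.
#' @examples
#' section_area(rect_section(65, 34))      # 2210
#' section_area(tbeam_section(65, 11, 27.5, 16, 2))  # 962.5
#' @export
section_area <- function(section) UseMethod("section_area")

#' @export
section_area.rect_section <- function(section) {
  section$width_b * section$thickness_h
}

#' @export
section_area.tbeam_section <- function(section) {
  planar <- section$planar_width * section$planar_thickness
  fin <- section$fin_depth * (section$fin_top_width + section$fin_tip_width) / 2
  planar + fin
}

#' Centroid depth of a cross-section
#'
#' Depth of the area centroid measured from the top surface (y positive
#' downward), um. For a rectangle this is h/2; for a T-beam it is the
#' area-weighted composite centroid of the planar rectangle and the
#' trapezoidal fin.
#'
#' @inheritParams section_area
#' @return Centroid depth, um.
#' @export
section_centroid_depth <- function(section) UseMethod("section_centroid_depth")

#' @export
section_centroid_depth.rect_section <- function(section) {
  section$thickness_h / 2
}

#' @export
section_centroid_depth.tbeam_section <- function(section) {
  a1 <- section$planar_width * section$planar_thickness
  y1 <- section$planar_thickness / 2
  a2 <- section$fin_depth * (section$fin_top_width + section$fin_tip_width) / 2
  # trapezoid centroid measured from its wide (top) side a toward tip b:
  # h * (a + 2 b) / (3 (a + b))
  a <- section$fin_top_width
  b <- section$fin_tip_width
  y2 <- section$planar_thickness +
    section$fin_depth * (a + 2 * b) / (3 * (a + b))
  (a1 * y1 + a2 * y2) / (a1 + a2)
}

#' Second moment of area about the centroidal horizontal axis
#'
#' Second moment of area I (um^4) about the horizontal axis through the
#' composite centroid — the axis relevant for bending/buckling in the depth
#' direction. For a rectangle I = b h^3 / 12. For a T-beam, standard
#' composite-beam theory: own-axis moments of the planar rectangle and the
#' trapezoidal fin plus parallel-axis terms about the shared centroid.
#'
#' @inheritParams section_area
#' @return I in um^4.
#' @examples
#' second_moment(rect_section(65, 34))  # b h^3 / 12 = 212896.7
#' second_moment(tbeam_section(65, 11, 27.5, 16, 2))
#' @export
second_moment <- function(section) UseMethod("second_moment")

#' @export
second_moment.rect_section <- function(section) {
  section$width_b * section$thickness_h^3 / 12
}

#' @export
second_moment.tbeam_section <- function(section) {
  a <- section$fin_top_width
  b <- section$fin_tip_width
  h <- section$fin_depth
  a1 <- section$planar_width * section$planar_thickness
  y1 <- section$planar_thickness / 2
  i1 <- section$planar_width * section$planar_thickness^3 / 12
  a2 <- h * (a + b) / 2
  y2 <- section$planar_thickness + h * (a + 2 * b) / (3 * (a + b))
  # trapezoid about its own centroidal axis parallel to the parallel sides
  i2 <- h^3 * (a^2 + 4 * a * b + b^2) / (36 * (a + b))
  ybar <- (a1 * y1 + a2 * y2) / (a1 + a2)
  i1 + a1 * (y1 - ybar)^2 + i2 + a2 * (y2 - ybar)^2
}

#' Equivalent rectangular thickness at matched bending stiffness
#'
#' Solves for the thickness h of a rectangular section of width `width_b`
#' and modulus `material$youngs_modulus_E` whose bending stiffness E*I
#' equals `target_EI`:  h = (12 * target_EI / (E * b))^(1/3). This is how a
#' T-beam shuttle in a stiff material is compared to the planar silicon
#' shuttle with equivalent buckling strength.
#'
#' @param target_EI Target bending stiffness, GPa * um^4.
#' @param width_b Rectangle width, um.
#' @param material A [material()] supplying E in GPa.
#' @return Thickness h in um.
#' @examples
#' tb <- tbeam_section(65, 11, 27.5, 16, 2)
#' EI <- 800 * second_moment(tb)
#' equivalent_rect_thickness(EI, 65, material_silicon())
#' @export
equivalent_rect_thickness <- function(target_EI, width_b, material) {
  stopifnot(inherits(material, "material"))
  if (!is.numeric(target_EI) || target_EI <= 0) stop("`target_EI` must be > 0")
  if (!is.numeric(width_b) || width_b <= 0) stop("`width_b` must be > 0")
  (12 * target_EI / (material$youngs_modulus_E * width_b))^(1 / 3)
}

#' Percent reduction in cross-sectional area
#'
#' `100 * (1 - area(a) / area(b))`: how much smaller section `a` is than
#' reference section `b`. Positive when `a` is the smaller section.
#'
#' @param a Section of interest (`cross_section`).
#' @param b Reference section (`cross_section`); must have positive area.
#' @return Percent reduction (may be negative if `a` is larger).
#' @examples
#' area_reduction_percent(tbeam_section(65, 11, 27.5, 16, 2), rect_section(65, 34))
#' @export
area_reduction_percent <- function(a, b) {
  stopifnot(inherits(a, "cross_section"), inherits(b, "cross_section"))
  area_b <- section_area(b)
  if (area_b <= 0) stop("reference section `b` has non-positive area")
  100 * (1 - section_area(a) / area_b)
}
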