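#' Boundary-condition effective-length factor
#'
#' Euler buckling of a slender column depends on how its ends are held,
#' through the effective-length factor K. For shuttle insertion the base is
#' clamped (fixed) and the tip condition depends on how well it pins into
#' the tissue surface: `fixed-pinned` (K = 0.699) when the tip stays
#' embedded, `fixed-guided` (K = 1) when the tip is held but the tissue
#' itself moves, and `fixed-free` (K = 2) when the tip slips — the
#' worst case on curved or tough membranes.
#'
#' @param condition_name One of `"fixed-pinned"`, `"fixed-guided"`,
#'   `"fixed-free"`.
#' @return The dimensionless K factor.
#' @examples
#' k_factor("fixed-pinned")  # 0.699
#' k_factor("fixed-free")    # 2
#' @export
k_factor <- function(condition_name) {
  ks <- c("fixed-pinned" = 0.699, "fixed-guided" = 1, "fixed-free" = 2)
  stopifnot(is.character(condition_name), length(condition_name) == 1L)
  if (!condition_name %in% names(ks))
    stop("unknown boundary condition '", condition_name, "'; known: ",
         paste(names(ks), collapse = ", "))
  unname(ks[[condition_name]])
}

#' Boundary condition object
#'
#' Either a named standard condition (see [k_factor()]) or a custom
#' positive K.
#'
#' @param name Condition name; `"custom"` when only `K` is given.
#' @param K Effective-length factor override; required for custom names.
#' @return An object of class `"boundary_condition"`.
#' @export
boundary_condition <- function(name = c("fixed-pinned", "fixed-guided",
                                        "fixed-free", "custom"),
                               K = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(K)) stop("a custom boundary condition needs an explicit `K`")
  } else if (is.null(K)) {
    K <- k_factor(name)
  }
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("`K` must be a positive finite number")
  structure(list(name = name, K = as.numeric(K)), class = "boundary_condition")
}

#' @export
print.boundary_condition <- function(x, ...) {
  cat(sprintf("Boundary condition: %s (K = %g)\n", x$name, x$K))
  invisible(x)
}

.resolve_bc <- function(boundary) {
  if (inherits(boundary, "boundary_condition")) return(boundary)
  if (is.character(boundary)) return(boundary_condition(boundary))
  if (is.numeric(boundary)) return(boundary_condition("custom", K = boundary))
  stop("`boundary` must be a boundary_condition, a condition name, or a numeric K")
}

#' Shuttle beam: the unit of buckling analysis
#'
#' @param section A `cross_section` (see [rect_section()], [tbeam_section()]).
#' @param material A [material()] (E in GPa).
#' @param length_L Column length, mm. Must be > 0.
#' @param boundary A [boundary_condition()], a condition name, or a numeric
#'   K. There is no silent default: boundary sensitivity is the central
#'   design lesson for these devices.
#' @return An object of class `"shuttle_beam"`.
#' @examples
#' shuttle_beam(rect_section(65, 15), material_silicon(), 1.5, "fixed-pinned")
#' @export
shuttle_beam <- function(section, material, length_L, boundary) {
  stopifnot(inherits(section, "cross_section"), inherits(material, "material"))
  if (!is.numeric(length_L) || length(length_L) != 1L || length_L <= 0)
    stop("`length_L` must be a positive length in mm")
  structure(list(section = section, material = material,
                 length_L = as.numeric(length_L),
                 boundary = .resolve_bc(boundary)),
            class = "shuttle_beam")
}

#' @export
print.shuttle_beam <- function(x, ...) {
  cat(sprintf("Shuttle beam: L = %g mm, %s, %s (K = %g)\n",
              x$length_L, x$material$name, x$boundary$name, x$boundary$K))
  print(x$section)
  cat(sprintf("  I = %.6g um^4, P_cr = %.4g mN\n",
              second_moment(x$section), buckling_load(x)))
  invisible(x)
}

#' Euler critical buckling load
#'
#' P_cr = pi^2 E I / (K L)^2, returned in millinewtons. Units: E in GPa,
#' I in um^4, L in mm combine as
#' GPa * um^4 / mm^2 = 1e9 N/m^2 * 1e-24 m^4 / 1e-6 m^2 = 1e-9 N = 1e-6 mN,
#' hence the 1e-6 factor below.
#'
#' @param beam A [shuttle_beam()]; alternatively pass `section`,
#'   `material`, `length_L`, `boundary` to build one on the fly.
#' @param ... Passed to [shuttle_beam()] when `beam` is a section.
#' @return Critical load P_cr, mN.
#' @examples
#' buckling_load(shuttle_beam(rect_section(65, 15), material_silicon(),
#'                            1.5, "fixed-pinned"))  # ~27.7 mN
#' @export
buckling_load <- function(beam, ...) {
  if (inherits(beam, "cross_section")) beam <- shuttle_beam(beam, ...)
  stopifnot(inherits(beam, "shuttle_beam"))
  E <- beam$material$youngs_modulus_E
  I <- second_moment(beam$section)
  K <- beam$boundary$K
  L <- beam$length_L
  pi^2 * E * I / (K * L)^2 * 1e-6
}

#' Design-space sweep over section thickness
#'
#' Evaluates a family of sections over a grid of thicknesses, reporting
#' area, second moment and critical buckling load per thickness. The
#' family is a function mapping thickness (um) to a `cross_section`, e.g.
#' `function(h) rect_section(65, h)`.
#'
#' @param section_family Function: thickness um -> `cross_section`.
#' @param thickness_um Numeric vector of thicknesses, um; must be
#'   non-empty and strictly increasing.
#' @param material A [material()].
#' @param length_L Beam length, mm.
#' @param boundary Boundary condition (see [shuttle_beam()]).
#' @return A data.frame with columns `thickness_um`, `area_um2`, `I_um4`,
#'   `P_cr_mN`, one row per thickness.
#' @examples
#' design_space_sweep(function(h) rect_section(65, h), seq(5, 52, by = 1),
#'                    material_uncd(), 1.5, "fixed-pinned")
#' @export
design_space_sweep <- function(section_family, thickness_um, material,
                               length_L, boundary) {
  stopifnot(is.function(section_family))
  if (!length(thickness_um)) stop("`thickness_um` must be a non-empty grid")
  if (is.unsorted(thickness_um, strictly = TRUE))
    stop("`thickness_um` must be strictly increasing")
  bc <- .resolve_bc(boundary)
  rows <- lapply(thickness_um, function(h) {
    sec <- section_family(h)
    data.frame(thickness_um = h,
               area_um2 = section_area(sec),
               I_um4 = second_moment(sec),
               P_cr_mN = buckling_load(shuttle_beam(sec, material, length_L, bc)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Worst-case boundary-condition safety factor
#'
#' Convenience derived from the Euler scaling P_cr proportional to 1/K^2: a
#' load requirement established under a design boundary condition must be
#' multiplied by (K_worst / K_design)^2 to remain safe if the tip slips to
#' the worst-case condition. For fixed-pinned design vs fixed-free worst
#' case this is (2 / 0.699)^2, i.e. about 8.2 — the "design it ~8x
#' stiffer" rule for peripheral-nerve targets.
#'
#' @param required_load_mN Load requirement under the design condition, mN.
#' @param design Design boundary condition (name, K, or object).
#' @param worst Worst-case boundary condition. Default `"fixed-free"`.
#' @return Scaled load requirement, mN.
#' @export
worst_case_load <- function(required_load_mN, design = "fixed-pinned",
                            worst = "fixed-free") {
  kd <- .resolve_bc(design)$K
  kw <- .resolve_bc(worst)$K
  required_load_mN * (kw / kd)^2
}
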