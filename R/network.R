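#' 3-D microvascular network
#'
#' A set of straight vessel segments, each with two 3-D endpoints and a
#' diameter, um. Curved vessels are represented piecewise-straight; each
#' straight piece is an independent unit in the damage counting.
#'
#' The object carries two boxes: `bbox`, the tight axis-aligned box of all
#' endpoints, and `domain`, the nominal volume the network describes (for
#' synthetic networks, the generation box; segments whose midpoints lie
#' inside may protrude past it). Length density is defined against
#' `domain`.
#'
#' @param segments data.frame with columns `id`, `x0`, `y0`, `z0`, `x1`,
#'   `y1`, `z1`, `diameter` (um).
#' @param domain Optional 2x3 matrix (rows = min/max, cols = x/y/z), um.
#'   Defaults to the endpoint bounding box.
#' @param source List describing provenance, e.g. `list(kind = "file",
#'   path = ...)` or `list(kind = "synthetic", seed = ..., config = ...)`.
#' @return An object of class `"vascular_network"`. Zero-length segments
#'   are kept but flagged in the logical column `zero_length` (with a
#'   warning), never silently dropped.
#' @export
vascular_network <- function(segments, domain = NULL,
                             source = list(kind = "unknown")) {
  req <- c("id", "x0", "y0", "z0", "x1", "y1", "z1", "diameter")
  if (!all(req %in% names(segments)))
    stop("`segments` must have columns: ", paste(req, collapse = ", "))
  segments <- as.data.frame(segments)[, req]
  if (nrow(segments)) {
    if (anyDuplicated(segments$id)) stop("segment ids must be unique")
    if (any(!is.finite(as.matrix(segments[, req[-1L]]))))
      stop("segment coordinates and diameters must be finite")
    if (any(segments$diameter <= 0)) stop("all diameters must be > 0")
  }
  len <- .segment_lengths(segments)
  segments$zero_length <- len == 0
  if (any(segments$zero_length))
    warning(sum(segments$zero_length), " zero-length segment(s) flagged ",
            "(kept, not dropped)")
  ends <- rbind(as.matrix(segments[, c("x0", "y0", "z0")]),
                as.matrix(segments[, c("x1", "y1", "z1")]))
  bbox <- if (nrow(ends)) apply(ends, 2L, range) else
    matrix(0, 2, 3)
  dimnames(bbox) <- list(c("min", "max"), c("x", "y", "z"))
  if (is.null(domain)) domain <- bbox
  structure(list(segments = segments, bbox = bbox, domain = domain,
                 source = source),
            class = "vascular_network")
}

.segment_lengths <- function(seg) {
  sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
}

#' @export
print.vascular_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "Vascular network (%s): %d segments, total length %.4g um, density %.3g um/um^3\n",
    x$source$kind, s$n_segments, s$total_length_um, s$length_density))
  invisible(x)
}

#' Declarative column map for the published node/segment network format
#'
#' The public rat-brain microvascular dataset is distributed as plain text
#' with a segment block (records carrying a segment id, a vessel-type
#' code, from-node, to-node and diameter) followed by a node block (node
#' id and x, y, z coordinates); each block is preceded by a line whose
#' first numeric token is its record count. Because column layouts drift
#' between mirrors, the reader is driven by this declarative map rather
#' than hard-wired positions.
#'
#' @param header_lines Lines to skip before the segment-count line.
#' @param segment_cols Named integer vector giving 1-based token positions
#'   of `id`, `type`, `from`, `to`, `diameter` in a segment record.
#' @param node_cols Named integer vector giving token positions of `id`,
#'   `x`, `y`, `z` in a node record.
#' @return An object of class `"network_dialect"`.
#' @export
network_dialect <- function(header_lines = 0L,
                            segment_cols = c(id = 1L, type = 2L, from = 3L,
                                             to = 4L, diameter = 5L),
                            node_cols = c(id = 1L, x = 2L, y = 3L, z = 4L)) {
  stopifnot(all(c("id", "type", "from", "to", "diameter") %in% names(segment_cols)),
            all(c("id", "x", "y", "z") %in% names(node_cols)))
  structure(list(header_lines = as.integer(header_lines),
                 segment_cols = segment_cols, node_cols = node_cols),
            class = "network_dialect")
}

#' Read a 3-D vascular network from plain text
#'
#' Two dialects are supported: the canonical per-segment CSV written by
#' [write_network()] (columns `id,x0,y0,z0,x1,y1,z1,diameter`) and the
#' published node/segment topology format described by
#' [network_dialect()], in which segment endpoints are resolved from the
#' node coordinate table. Malformed input fails with an error naming the
#' first offending line.
#'
#' @param path Path to a readable text file.
#' @param dialect `"csv"`, or a [network_dialect()] (the default map
#'   matches the published layout).
#' @return A [vascular_network()].
#' @export
read_network <- function(path, dialect = network_dialect()) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (identical(dialect, "csv")) {
    seg <- utils::read.csv(path)
    req <- c("id", "x0", "y0", "z0", "x1", "y1", "z1", "diameter")
    if (!all(req %in% names(seg)))
      stop("CSV network file must have columns: ", paste(req, collapse = ", "))
    return(vascular_network(seg, source = list(kind = "file", path = path,
                                               dialect = "csv")))
  }
  stopifnot(inherits(dialect, "network_dialect"))
  lines <- readLines(path, warn = FALSE)
  lines_kept <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(lines_kept)) stop("empty network file: ", path)
  pos <- dialect$header_lines
  if (pos >= length(lines_kept)) stop("network file ends inside the header: ", path)

  take_count <- function(what) {
    pos <<- pos + 1L
    if (pos > length(lines_kept))
      stop("network file ends before the ", what, " count line")
    lineno <- lines_kept[pos]
    n <- suppressWarnings(as.integer(strsplit(trimws(lines[lineno]), "\\s+")[[1L]][1L]))
    if (is.na(n) || n < 0)
      stop("line ", lineno, ": expected a ", what, " count, got '",
           lines[lineno], "'")
    n
  }
  take_block <- function(n, cols, what) {
    out <- matrix(NA_real_, n, length(cols))
    for (i in seq_len(n)) {
      pos <<- pos + 1L
      if (pos > length(lines_kept))
        stop("network file ends inside the ", what, " block (record ", i,
             " of ", n, ")")
      lineno <- lines_kept[pos]
      tok <- strsplit(trimws(lines[lineno]), "[\\s,]+", perl = TRUE)[[1L]]
      if (length(tok) < max(cols))
        stop("line ", lineno, ": ", what, " record has ", length(tok),
             " fields, need at least ", max(cols))
      vals <- suppressWarnings(as.numeric(tok[cols]))
      if (any(is.na(vals)))
        stop("line ", lineno, ": non-numeric value in ", what, " record")
      out[i, ] <- vals
    }
    colnames(out) <- names(cols)
    as.data.frame(out)
  }

  n_seg <- take_count("segment")
  segrec <- take_block(n_seg, dialect$segment_cols, "segment")
  n_node <- take_count("node")
  noderec <- take_block(n_node, dialect$node_cols, "node")

  idx <- match(segrec$from, noderec$id)
  idx2 <- match(segrec$to, noderec$id)
  bad <- which(is.na(idx) | is.na(idx2))
  if (length(bad))
    stop("segment record ", bad[1L], " references unknown node(s) ",
         segrec$from[bad[1L]], " / ", segrec$to[bad[1L]])
  seg <- data.frame(id = segrec$id,
                    x0 = noderec$x[idx], y0 = noderec$y[idx],
                    z0 = noderec$z[idx],
                    x1 = noderec$x[idx2], y1 = noderec$y[idx2],
                    z1 = noderec$z[idx2],
                    diameter = segrec$diameter)
  message("read_network: parsed ", n_seg, " segment and ", n_node,
          " node records from ", basename(path))
  vascular_network(seg, source = list(kind = "file", path = path,
                                      dialect = "nodeseg",
                                      vessel_type = segrec$type))
}

#' Write a network in the canonical per-segment CSV form
#'
#' Columns `id,x0,y0,z0,x1,y1,z1,diameter`; coordinates round-trip
#' losslessly to well below 1e-6 um (15 significant digits).
#'
#' @param net A [vascular_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "vascular_network"))
  seg <- net$segments[, c("id", "x0", "y0", "z0", "x1", "y1", "z1", "diameter")]
  for (col in names(seg)[-1L]) seg[[col]] <- formatC(seg[[col]], digits = 15,
                                                     format = "g")
  utils::write.csv(seg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Orthographic projection of a network to the insertion plane
#'
#' Probe insertion is modelled as vertical and straight, so the 3-D
#' network is collapsed along the insertion axis: the axis coordinate is
#' dropped and the remaining two are kept, diameters unchanged. Segments
#' parallel to the insertion axis project to zero length; they are kept
#' and flagged.
#'
#' @param net A [vascular_network()].
#' @param insertion_axis Which axis the probe travels along: `"z"`
#'   (default), `"x"` or `"y"`.
#' @return A data.frame of class `"projected_segments"` with columns `id`,
#'   `x0`, `y0`, `x1`, `y1`, `diameter`, `zero_length`, plus attributes
#'   `insertion_axis` and `bbox` (2x2 of the projected plane).
#' @export
project_to_plane <- function(net, insertion_axis = c("z", "x", "y")) {
  stopifnot(inherits(net, "vascular_network"))
  insertion_axis <- match.arg(insertion_axis)
  keep <- setdiff(c("x", "y", "z"), insertion_axis)
  seg <- net$segments
  out <- data.frame(id = seg$id,
                    x0 = seg[[paste0(keep[1L], "0")]],
                    y0 = seg[[paste0(keep[2L], "0")]],
                    x1 = seg[[paste0(keep[1L], "1")]],
                    y1 = seg[[paste0(keep[2L], "1")]],
                    diameter = seg$diameter)
  out$zero_length <- (out$x0 == out$x1) & (out$y0 == out$y1)
  bbox <- net$domain[, keep, drop = FALSE]
  colnames(bbox) <- c("x", "y")
  structure(out, insertion_axis = insertion_axis, bbox = bbox,
            class = c("projected_segments", "data.frame"))
}

#' Descriptive statistics of a network
#'
#' @param net A [vascular_network()].
#' @return A list: `n_segments`, `total_length_um`, `length_density`
#'   (um of vessel per um^3 of the network domain), `diameter_quantiles`
#'   (0/25/50/75/100%), `domain_volume_um3`. An empty network returns
#'   zeros with a warning.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "vascular_network"))
  seg <- net$segments
  vol <- prod(net$domain[2L, ] - net$domain[1L, ])
  if (!nrow(seg)) {
    warning("empty network: statistics are all zero")
    return(list(n_segments = 0L, total_length_um = 0,
                length_density = 0,
                diameter_quantiles = stats::setNames(rep(0, 5),
                  c("0%", "25%", "50%", "75%", "100%")),
                domain_volume_um3 = vol))
  }
  len <- .segment_lengths(seg)
  list(n_segments = nrow(seg),
       total_length_um = sum(len),
       length_density = if (vol > 0) sum(len) / vol else NA_real_,
       diameter_quantiles = stats::quantile(seg$diameter),
       domain_volume_um3 = vol)
}

#' Configuration for the synthetic vascular-network generator
#'
#' The generator emulates the statistical structure the damage model
#' assumes: straight vessel segments whose midpoints form a homogeneous
#' Poisson process in a box, isotropic 3-D orientations, and i.i.d.
#' segment lengths and diameters. Defaults describe cortical
#' microvasculature-like numbers: lognormal lengths with median 60 um,
#' lognormal diameters with median 6 um, and a length density of 1e-4 um
#' of vessel per um^3 in a 400-um cube.
#'
#' @param box_um Length-3 vector of box extents, um.
#' @param length_density Target um of vessel centreline per um^3; > 0.
#' @param length_dist,diameter_dist Distribution spec: `list(name, ...)`
#'   with `name` one of `"lognormal"` (`meanlog`, `sdlog`), `"uniform"`
#'   (`min`, `max`), `"fixed"` (`value`).
#' @param seed Integer seed; the generated network is a pure function of
#'   this configuration.
#' @return An object of class `"synth_network_config"`.
#' @export
synth_network_config <- function(box_um = c(400, 400, 400),
                                 length_density = 1e-4,
                                 length_dist = list(name = "lognormal",
                                                    meanlog = log(60),
                                                    sdlog = 0.5),
                                 diameter_dist = list(name = "lognormal",
                                                      meanlog = log(6),
                                                      sdlog = 0.4),
                                 seed = 1L) {
  stopifnot(length(box_um) == 3L, all(box_um > 0))
  if (!is.numeric(length_density) || length_density <= 0)
    stop("`length_density` must be > 0 (um of vessel per um^3)")
  for (d in list(length_dist, diameter_dist)) .check_dist(d)
  structure(list(box_um = as.numeric(box_um),
                 length_density = length_density,
                 length_dist = length_dist, diameter_dist = diameter_dist,
                 seed = as.integer(seed)),
            class = "synth_network_config")
}

.check_dist <- function(d) {
  if (!is.list(d) || is.null(d$name))
    stop("distribution spec must be list(name = ..., ...)")
  switch(d$name,
    lognormal = if (is.null(d$meanlog) || is.null(d$sdlog) || d$sdlog < 0)
      stop("lognormal spec needs meanlog and sdlog >= 0"),
    uniform = if (is.null(d$min) || is.null(d$max) || d$min <= 0 ||
                  d$max < d$min)
      stop("uniform spec needs 0 < min <= max"),
    fixed = if (is.null(d$value) || d$value <= 0)
      stop("fixed spec needs value > 0"),
    stop("unknown distribution '", d$name, "'"))
  invisible(d)
}

.dist_mean <- function(d) {
  switch(d$name,
         lognormal = exp(d$meanlog + d$sdlog^2 / 2),
         uniform = (d$min + d$max) / 2,
         fixed = d$value)
}

.dist_draw <- function(d, n) {
  switch(d$name,
         lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
         uniform = stats::runif(n, d$min, d$max),
         fixed = rep(d$value, n))
}

#' Generate a synthetic vascular network
#'
#' Segment count is Poisson with mean `length_density * volume /
#' mean_segment_length`, so expected total centreline length matches the
#' density target. Midpoints are uniform in the box; orientations are
#' isotropic on the sphere (uniform cos of polar angle, uniform azimuth);
#' lengths and diameters are i.i.d. draws from the configured
#' distributions. Segments may protrude past the box; the generation box
#' is stored as the network `domain`. Fully reproducible from
#' `cfg$seed`; the caller's RNG state is left untouched.
#'
#' @param cfg A [synth_network_config()].
#' @return A [vascular_network()] with `source$kind == "synthetic"`.
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_network_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  vol <- prod(cfg$box_um)
  n <- stats::rpois(1L, cfg$length_density * vol / .dist_mean(cfg$length_dist))
  if (n == 0L) {
    seg <- data.frame(id = integer(), x0 = numeric(), y0 = numeric(),
                      z0 = numeric(), x1 = numeric(), y1 = numeric(),
                      z1 = numeric(), diameter = numeric())
  } else {
    mid <- cbind(stats::runif(n, 0, cfg$box_um[1L]),
                 stats::runif(n, 0, cfg$box_um[2L]),
                 stats::runif(n, 0, cfg$box_um[3L]))
    cz <- stats::runif(n, -1, 1)            # isotropic: cos(polar) uniform
    phi <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - cz^2))
    u <- cbind(r * cos(phi), r * sin(phi), cz)
    len <- .dist_draw(cfg$length_dist, n)
    half <- u * (len / 2)
    seg <- data.frame(id = seq_len(n),
                      x0 = mid[, 1L] - half[, 1L], y0 = mid[, 2L] - half[, 2L],
                      z0 = mid[, 3L] - half[, 3L],
                      x1 = mid[, 1L] + half[, 1L], y1 = mid[, 2L] + half[, 2L],
                      z1 = mid[, 3L] + half[, 3L],
                      diameter = .dist_draw(cfg$diameter_dist, n))
  }
  domain <- rbind(min = c(0, 0, 0), max = cfg$box_um)
  colnames(domain) <- c("x", "y", "z")
  vascular_network(seg, domain = domain,
                   source = list(kind = "synthetic", seed = cfg$seed,
                                 config = cfg))
}
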