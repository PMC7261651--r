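test_that("node/segment dialect parses and resolves endpoints", {
  p <- write_nodeseg_fixture(tempfile(fileext = ".txt"))
  expect_message(net <- read_network(p), "3 segment and 4 node")
  expect_equal(nrow(net$segments), 3L)
  expect_equal(net$segments$diameter, c(6, 5, 8))
  # endpoints resolved from the node coordinate table
  expect_equal(unlist(net$segments[2, c("x0", "y0", "z0", "x1", "y1", "z1")],
                      use.names = FALSE),
               c(100, 0, 0, 100, 50, 0))
  unlink(p)
})

test_that("the bundled synthetic fixture parses with the default dialect", {
  p <- system.file("extdata", "synthetic_microvascular_nodeseg.txt",
                   package = "shuttlemech")
  suppressMessages(net <- read_network(p))
  expect_equal(nrow(net$segments), 28L)
  expect_true(all(net$segments$diameter > 0))
  expect_s3_class(project_to_plane(net), "projected_segments")
})

test_that("malformed input errors name the first offending line", {
  p <- tempfile()
  writeLines(c("2 segments", "1 4 1 2 6.0", "2 4 2 oops 5.0",
               "2 nodes", "1 0 0 0", "2 1 1 1"), p)
  expect_error(read_network(p), "line 3.*non-numeric")
  writeLines(c("1 segments", "1 4 1 2"), p)
  expect_error(read_network(p), "line 2.*4 fields")
  writeLines(character(), p)
  expect_error(read_network(p), "empty network file")
  expect_error(read_network(tempfile()), "not found")
  # dangling node reference
  writeLines(c("1 segments", "1 4 1 99 6.0", "1 nodes", "1 0 0 0"), p)
  expect_error(read_network(p), "unknown node")
  unlink(p)
})

test_that("canonical CSV writer/reader round-trips losslessly", {
  net <- generate_synthetic(synth_network_config(seed = 11))
  p <- tempfile(fileext = ".csv")
  write_network(net, p)
  back <- read_network(p, dialect = "csv")
  cols <- c("x0", "y0", "z0", "x1", "y1", "z1", "diameter")
  expect_equal(back$segments$id, net$segments$id)
  for (cl in cols)
    expect_equal(back$segments[[cl]], net$segments[[cl]], tolerance = 1e-12)
  expect_true(max(abs(as.matrix(back$segments[cols]) -
                      as.matrix(net$segments[cols]))) < 1e-6)
  unlink(p)
})

test_that("zero-length segments are flagged, not dropped", {
  seg <- data.frame(id = 1:2, x0 = c(0, 5), y0 = 0, z0 = 0,
                    x1 = c(0, 15), y1 = 0, z1 = 0, diameter = 4)
  expect_warning(net <- vascular_network(seg), "zero-length")
  expect_equal(nrow(net$segments), 2L)
  expect_equal(net$segments$zero_length, c(TRUE, FALSE))
  expect_error(vascular_network(transform(seg, diameter = c(4, 0))),
               "diameters")
  expect_error(vascular_network(transform(seg, id = c(1, 1))), "unique")
})

test_that("projection drops the insertion axis and never lengthens", {
  # parallel to the insertion axis -> zero-length, flagged
  seg <- data.frame(id = 1:2,
                    x0 = c(10, 0), y0 = c(10, 0), z0 = c(0, 0),
                    x1 = c(10, 30), y1 = c(10, 40), z1 = c(50, 0),
                    diameter = 6)
  net <- vascular_network(seg)
  pr <- project_to_plane(net, "z")
  expect_true(pr$zero_length[1])
  expect_false(pr$zero_length[2])
  # perpendicular to the axis: 2-D length equals 3-D length
  expect_equal(sqrt((pr$x1[2] - pr$x0[2])^2 + (pr$y1[2] - pr$y0[2])^2), 50)
  expect_equal(pr$diameter, seg$diameter)

  # property: projected length <= 3-D length over 1e4 random segments
  set.seed(5)
  n <- 1e4
  cz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - cz^2); len <- runif(n, 1, 100)
  segs <- data.frame(id = 1:n, x0 = 0, y0 = 0, z0 = 0,
                     x1 = len * r * cos(phi), y1 = len * r * sin(phi),
                     z1 = len * cz, diameter = 5)
  for (ax in c("x", "y", "z")) {
    pr <- project_to_plane(vascular_network(segs), ax)
    l2 <- sqrt((pr$x1 - pr$x0)^2 + (pr$y1 - pr$y0)^2)
    expect_true(all(l2 <= len + 1e-9))
  }
  # idempotent on planar data: z-constant network keeps its full lengths
  planar <- transform(segs, z1 = 0)
  prp <- project_to_plane(vascular_network(planar), "z")
  expect_equal(sqrt((prp$x1 - prp$x0)^2 + (prp$y1 - prp$y0)^2),
               sqrt(planar$x1^2 + planar$y1^2))
})

test_that("network statistics: arithmetic and rigid-translation invariance", {
  seg <- data.frame(id = 1L, x0 = 0, y0 = 50, z0 = 50,
                    x1 = 100, y1 = 50, z1 = 50, diameter = 6)
  dom <- rbind(min = c(0, 0, 0), max = c(100, 100, 100))
  colnames(dom) <- c("x", "y", "z")
  s <- network_stats(vascular_network(seg, domain = dom))
  expect_equal(s$length_density, 1e-4)
  expect_equal(s$total_length_um, 100)
  # rigid translation of coordinates and domain leaves statistics unchanged
  seg2 <- transform(seg, x0 = x0 + 20, x1 = x1 + 20, y0 = y0 - 5, y1 = y1 - 5)
  dom2 <- dom; dom2[, "x"] <- dom2[, "x"] + 20; dom2[, "y"] <- dom2[, "y"] - 5
  s2 <- network_stats(vascular_network(seg2, domain = dom2))
  expect_equal(s2$total_length_um, s$total_length_um)
  expect_equal(s2$length_density, s$length_density)
  expect_equal(s2$diameter_quantiles, s$diameter_quantiles)
  # empty network: zeros with warning
  empty <- vascular_network(seg[0, ])
  expect_warning(s0 <- network_stats(empty), "empty")
  expect_equal(s0$n_segments, 0L)
})

test_that("synthetic generator is a pure function of its seed", {
  cfg <- synth_network_config(seed = 99)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$segments, b$segments)
  expect_false(identical(
    a$segments,
    generate_synthetic(synth_network_config(seed = 100))$segments))
  # caller RNG state untouched
  set.seed(7); before <- runif(5)
  set.seed(7); invisible(generate_synthetic(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("synthetic networks hit the configured length density", {
  # law-of-large-numbers check over 50 independent seeds
  cfg0 <- synth_network_config()
  dens <- vapply(1:50, function(s) {
    net <- generate_synthetic(synth_network_config(seed = s))
    network_stats(net)$length_density
  }, numeric(1))
  se <- sd(dens) / sqrt(length(dens))
  # mean total length = density x volume within 3 standard errors ...
  expect_lt(abs(mean(dens) - cfg0$length_density), 3 * se)
  # ... which also lands the mean density within 5% of the target
  expect_lt(abs(mean(dens) / cfg0$length_density - 1), 0.05)
  # vanishing density gives an empty network
  tiny <- generate_synthetic(synth_network_config(length_density = 1e-12,
                                                  seed = 3))
  expect_equal(nrow(tiny$segments), 0L)
  expect_error(synth_network_config(length_density = 0), "length_density")
})

test_that("synthetic midpoints are spatially uniform (chi-square, alpha 0.01)", {
  cfg <- synth_network_config(length_density = 2e-3, seed = 2024)
  net <- generate_synthetic(cfg)
  seg <- net$segments
  mid <- cbind((seg$x0 + seg$x1) / 2, (seg$y0 + seg$y1) / 2,
               (seg$z0 + seg$z1) / 2)
  brk <- seq(0, 400, length.out = 5)
  bin <- function(v) pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE),
                               1L), 4L)
  cell <- bin(mid[, 1]) + 4L * (bin(mid[, 2]) - 1L) + 16L * (bin(mid[, 3]) - 1L)
  counts <- tabulate(cell, nbins = 64L)
  expect_equal(sum(counts), nrow(seg))
  pval <- chisq.test(counts)$p.value
  expect_gt(pval, 0.01)
})

test_that("synthetic-network YAML config reader honours overrides and defaults", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("box_um: [200, 200, 300]", "length_density: 2.0e-4",
               "seed: 5"), p)
  cfg <- read_synth_network_config(p)
  expect_equal(cfg$box_um, c(200, 200, 300))
  expect_equal(cfg$length_density, 2e-4)
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$length_dist$name, "lognormal")  # default retained
  unlink(p)
})
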