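# Shared fixtures: random valid sections, a hand-checkable toy network, and
# a writer for the node/segment text dialect.

random_rect <- function() rect_section(runif(1, 1, 120), runif(1, 1, 60))

random_tbeam <- function() {
  pw <- runif(1, 10, 120)
  wtop <- runif(1, 1, pw)
  tbeam_section(pw, runif(1, 2, 30), runif(1, 2, 60),
                wtop, runif(1, 0, wtop))
}

random_section <- function() {
  if (runif(1) < 0.5) random_rect() else random_tbeam()
}

# six segments around the axis-aligned rectangle [0,10] x [0,4] with
# hand-derived verdicts; the rectangle footprint is rect_section(10, 4)
# placed with centroid at (5, 2) and theta = 0
toy_segments <- function() {
  data.frame(
    id = 1:6,
    x0 = c(2, -5,  5,   1,  9,  9.0),
    y0 = c(-1, 2, -2,   1,  2, -0.5),
    x1 = c(2, -1,  5,   3, 15, 11.0),
    y1 = c(5,  2, -0.1, 3,  2,  1.5),
    diameter = c(1, 1, 1, 0.5, 1, 2),
    zero_length = FALSE)
}
toy_expected_centerline <- c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
toy_expected_fullwidth  <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)

toy_placement <- function() list(x = 5, y = 2, theta = 0)

# small random planar networks for oracle-equivalence checks
random_small_network2d <- function(n = 40, extent = 200) {
  x0 <- runif(n, 0, extent); y0 <- runif(n, 0, extent)
  ang <- runif(n, 0, 2 * pi); len <- runif(n, 5, 80)
  data.frame(id = seq_len(n),
             x0 = x0, y0 = y0,
             x1 = x0 + len * cos(ang), y1 = y0 + len * sin(ang),
             diameter = runif(n, 2, 12),
             zero_length = FALSE)
}

write_nodeseg_fixture <- function(path) {
  writeLines(c(
    "# synthetic microvascular network, node/segment dialect",
    "3 segments",
    "1 4 1 2 6.0",
    "2 4 2 3 5.0",
    "3 5 3 4 8.0",
    "4 nodes",
    "1 0 0 0",
    "2 100 0 0",
    "3 100 50 0",
    "4 100 50 80"), path)
  path
}
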