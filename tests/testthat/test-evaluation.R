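test_that("longitudinal axis averages sense-corrected segment vectors", {
  # single segment rising along z
  cen <- make_centres(c("L", "L"), rbind(c(0, 0, -15), c(0, 0, 15)))
  topo <- topology("A", 1, 2, "in-out")
  expect_equal(longitudinal_axis(cen, topo), c(0, 0, 1))

  # antiparallel pair with annotated senses both contribute +z-wards
  cen2 <- make_centres(c("L", "L", "A", "A"),
                       rbind(c(0, 0, -15), c(0, 0, 15),
                             c(5, 0, 15), c(5, 0, -15)),
                       res_seq = c(1, 2, 3, 4))
  topo2 <- topology(c("A", "A"), c(1, 3), c(2, 4), c("in-out", "out-in"))
  expect_equal(longitudinal_axis(cen2, topo2), c(0, 0, 1))

  # unit vectors (0,0,1) and (1,0,0) average to (1,0,1)/sqrt(2)
  cen3 <- make_centres(c("L", "L", "A", "A"),
                       rbind(c(0, 0, 0), c(0, 0, 1),
                             c(0, 0, 0), c(1, 0, 0)),
                       res_seq = c(1, 2, 3, 4))
  topo3 <- topology(c("A", "A"), c(1, 3), c(2, 4))
  expect_equal(longitudinal_axis(cen3, topo3), c(1, 0, 1) / sqrt(2),
               tolerance = 1e-12)

  # antiparallel pair without sense correction would cancel
  topo_bad <- topology(c("A", "A"), c(1, 3), c(2, 4), c("in-out", "in-out"))
  expect_error(longitudinal_axis(cen2, topo_bad), "degenerate")
})

test_that("tilt angles fold into [0, 90] degrees", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 1) / sqrt(2)), 45, tolerance = 1e-9)
  expect_equal(tilt_angle(c(0, 0, -1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
})

test_that("mean segment tilt averages per-segment magnitudes", {
  mk <- function(theta) c(sin(theta * pi / 180), 0, cos(theta * pi / 180))
  cen <- make_centres(rep("L", 4),
                      rbind(c(0, 0, 0), mk(30) * 20,
                            c(10, 0, 0), c(10, 0, 0) + mk(50) * 20),
                      res_seq = 1:4)
  topo <- topology(c("A", "A"), c(1, 3), c(2, 4))
  expect_equal(mean_segment_tilt(cen, topo), 40, tolerance = 1e-9)
  # single-segment structure equals that segment's tilt
  expect_equal(mean_segment_tilt(cen, topo[1, ]), 30, tolerance = 1e-9)
  # all segments parallel to z
  cen0 <- make_centres(rep("L", 2), rbind(c(0, 0, -10), c(0, 0, 10)))
  expect_equal(mean_segment_tilt(cen0, topology("A", 1, 2)), 0)
})

test_that("z-shift is the mean boundary-residue depth", {
  cen <- make_centres(rep("L", 2), rbind(c(0, 0, -15), c(0, 0, 15)))
  expect_equal(z_shift(cen, topology("A", 1, 2)), 0)
  cen2 <- make_centres(rep("L", 2), rbind(c(0, 0, -10), c(0, 0, 20)))
  expect_equal(z_shift(cen2, topology("A", 1, 2)), 5)
  # a missing boundary residue is skipped with a warning
  expect_warning(z <- z_shift(cen2, topology("A", 1, 9)), "missing")
  expect_equal(z, -10)   # only residue 1 remains usable
})

test_that("naive orientation aligns the axis and centres the span", {
  set.seed(40)
  b <- build_ideal_helix(rep("L", 37), tilt = 25, z_offset = 6)
  t <- naive_orient(b$structure, b$topology)
  oriented <- transform_structure(b$structure, t)
  expect_lt(tilt_angle(longitudinal_axis(oriented, b$topology)), 1e-6)
  expect_lt(abs(z_shift(oriented, b$topology)), 1e-6)
  # idempotent: a second call returns the identity
  t2 <- naive_orient(oriented, b$topology)
  expect_equal(t2$rot_x %% 360, 0, tolerance = 1e-6)
  expect_equal(t2$rot_y %% 360, 0, tolerance = 1e-6)
  expect_equal(t2$dz, 0, tolerance = 1e-6)

  # an axis-aligned structure with z-shift 5 needs only dz = -5
  cen <- make_centres(rep("L", 2), rbind(c(0, 0, 0), c(0, 0, 10)))
  s <- structure_from_centres(cen)
  t3 <- naive_orient(s, topology("A", 1, 2))
  expect_equal(unlist(t3), c(rot_x = 0, rot_y = 0, dz = -5), tolerance = 1e-9)
})

test_that("orientation comparison reports tilt and z deltas against the error margin", {
  set.seed(41)
  b <- build_bundle(n_helices = 2, n_res = 37, id = "cmp")
  s <- b$structure
  topo <- b$topology
  same <- compare_orientations(s, s, topo, ref_error = c(3, 1))
  expect_equal(same$tilt_delta, 0)
  expect_equal(same$z_delta, 0)
  expect_true(same$within_error)

  rot5 <- transform_structure(s, transform_pose(5, 0, 0))
  c5 <- compare_orientations(rot5, s, topo, ref_error = c(3, 1))
  expect_equal(c5$tilt_delta, 5, tolerance = 0.3)
  expect_false(c5$within_error)

  sh <- transform_structure(s, transform_pose(0, 0, 0.5))
  cs <- compare_orientations(sh, s, topo, ref_error = c(3, 1))
  expect_equal(cs$z_delta, 0.5, tolerance = 1e-9)
  expect_true(cs$within_error)

  other <- build_bundle(n_helices = 2, n_res = 19, id = "other")$structure
  expect_error(compare_orientations(other, s, topo), "mismatch")
})

test_that("lipid vector tilt averages terminal-carbon vectors per leaflet", {
  lipid <- function(res_seq, base, tip) {
    data.frame(serial = c(1L, 2L), name = c("C1", "C9"), alt_loc = " ",
               res_name = "PLM", chain = "Z", res_seq = res_seq, i_code = " ",
               x = c(base[1], tip[1]), y = c(base[2], tip[2]),
               z = c(base[3], tip[3]), element = "C", het = TRUE,
               stringsAsFactors = FALSE)
  }
  pol <- structure_from_centres(make_centres("L", c(0, 0, 0)))$atoms
  # one lower-leaflet lipid along z, one upper-leaflet tilted 45 degrees
  atoms <- rbind(pol,
                 lipid(501, c(0, 0, -18), c(0, 0, -4)),
                 lipid(502, c(5, 0, 18), c(5, 10, 8)))
  s <- structure(list(id = "lip", atoms = atoms), class = "mem_structure")
  expect_equal(lipid_vector_tilt(s, "lower"), 0, tolerance = 1e-9)
  expect_equal(lipid_vector_tilt(s, "upper"), 45, tolerance = 1e-9)

  # two-lipid average in one leaflet: mean of unit vectors, then tilt
  atoms2 <- rbind(pol,
                  lipid(501, c(0, 0, -18), c(0, 0, -8)),
                  lipid(502, c(5, 0, -18), c(5, 10, -8)))
  s2 <- structure(list(id = "lip2", atoms = atoms2), class = "mem_structure")
  v <- c(0, 0, 1) + c(0, 1, 1) / sqrt(2)
  expect_equal(lipid_vector_tilt(s2, "lower"), tilt_angle(v / sqrt(sum(v^2))),
               tolerance = 1e-9)
  expect_error(lipid_vector_tilt(structure_from_centres(make_centres("L", c(0, 0, 0))),
                                 "lower"), "no lipid")
})

test_that("topology files parse, validate, and round-trip", {
  txt <- c("# chain start end sense",
           "A\t5\t29\tin-out",
           "A 40 64 OUT->IN",
           "B 10 30")
  topo <- read_topology(txt)
  expect_equal(topo$sense, c("in-out", "out-in", "in-out"))
  expect_equal(topo$start, c(5L, 40L, 10L))

  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f), add = TRUE)
  write_topology(topo, f)
  expect_equal(read_topology(f), topo)

  expect_error(topology("A", c(1, 5), c(10, 20)), "overlap")
  expect_error(topology("A", 10, 5), "start < end|not TRUE")
  expect_error(read_topology("# only a comment"), "empty")
})
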