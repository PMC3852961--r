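test_that("pose transforms follow the right-handed R_y R_x + dz convention", {
  pts <- rbind(c(0, 1, 0), c(1, 0, 0), c(2, -3, 5))
  expect_equal(apply_transform(pts, transform_pose(0, 0, 0)), pts)
  expect_equal(apply_transform(c(0, 1, 0), transform_pose(90, 0, 0)),
               matrix(c(0, 0, 1), 1), tolerance = 1e-9)
  expect_equal(apply_transform(c(0, 0, 1), transform_pose(0, 90, 0)),
               matrix(c(1, 0, 0), 1), tolerance = 1e-9)
  shifted <- apply_transform(pts, transform_pose(0, 0, 7))
  expect_equal(shifted[, 3], pts[, 3] + 7)
  expect_equal(shifted[, 1:2], pts[, 1:2])
  # angles reduce to [0, 360)
  expect_equal(transform_pose(-30, 370, 0)$rot_x, 330)
  expect_equal(transform_pose(-30, 370, 0)$rot_y, 10)
})

test_that("random poses are reproducible, bounded, and uniform in angle", {
  expect_equal(random_pose(seed = 11), random_pose(seed = 11))
  set.seed(1)
  draws <- replicate(1e4, unlist(random_pose(dz_bounds = c(-20, 20))))
  expect_true(all(draws["rot_x", ] >= 0 & draws["rot_x", ] < 360))
  expect_true(all(abs(draws["dz", ]) <= 20))
  # law of large numbers: mean angle 180 +/- 5 (se ~ 1.04)
  expect_lt(abs(mean(draws["rot_x", ]) - 180), 5)
  expect_lt(abs(mean(draws["rot_y", ]) - 180), 5)
})

test_that("grid search is exhaustive, deterministic, and breaks ties lexicographically", {
  flat <- potential_from_counts(matrix(5, 20, 32))   # all energies zero
  cen <- make_centres(c("L", "A"), rbind(c(0, 0, 1), c(0, 0, -1)))
  cfg <- search_config("grid", grid_rot_step = 45, grid_dz_step = 5,
                       dz_bounds = c(-10, 10))
  g <- grid_search(flat, cen, cfg)
  expect_equal(unlist(g$best), c(rot_x = 0, rot_y = 0, dz = -10))
  expect_equal(g$energy, 0)
  expect_equal(g$n_energy_calls, 8L * 8L * 5L)

  # a nested coarser grid never beats the finer one
  p <- toy_band_potential()
  h <- perfect_helix()
  cen <- scoring_centres(h$structure, quiet = TRUE)
  fine <- grid_search(p, cen, search_config("grid", grid_rot_step = 5,
                                            grid_dz_step = 1,
                                            dz_bounds = c(-20, 20)))
  coarse <- grid_search(p, cen, search_config("grid", grid_rot_step = 10,
                                              grid_dz_step = 2,
                                              dz_bounds = c(-20, 20)))
  expect_gte(coarse$energy, fine$energy)
  # determinism
  expect_equal(fine$energy,
               grid_search(p, cen, search_config("grid", grid_rot_step = 5,
                                                 grid_dz_step = 1,
                                                 dz_bounds = c(-20, 20)))$energy)
})

test_that("the pattern-search core solves analytic problems", {
  quad <- function(v) (v[1] - 10)^2 + (v[2] - 20)^2 + (v[3] - 3)^2
  r <- memorient:::.hooke_jeeves(quad, c(0, 0, 0), c(16, 16, 8), 0.5,
                                 c(0.1, 0.1, 0.05))
  expect_equal(r$par, c(10, 20, 3), tolerance = 1e-6)
  # a start at the optimum is a fixed point
  r0 <- memorient:::.hooke_jeeves(quad, c(10, 20, 3), c(16, 16, 8), 0.5,
                                  c(0.1, 0.1, 0.05))
  expect_equal(r0$par, c(10, 20, 3))
  expect_equal(r0$value, 0)
  # banana valley
  ros <- function(v) 100 * (v[2] - v[1]^2)^2 + (1 - v[1])^2 + v[3]^2
  r2 <- memorient:::.hooke_jeeves(ros, c(-1.2, 1, 1), c(1, 1, 1), 0.5,
                                  rep(1e-4, 3))
  expect_lt(r2$value, 1e-6)
})

test_that("direct search never worsens its start and is deterministic", {
  p <- shared_potential()
  set.seed(30)
  b <- build_bundle(n_helices = 2, n_res = 37, id = "ds")
  cen <- scoring_centres(b$structure, quiet = TRUE)
  start <- transform_pose(40, 10, 3)
  e_start <- structure_energy(p, cen, start)
  d <- direct_search(p, cen, search_config("direct"), start = start)
  expect_lte(d$energy, e_start)
  expect_equal(d$energy, structure_energy(p, cen, d$best), tolerance = 1e-9)
  d2 <- direct_search(p, cen, search_config("direct"))
  expect_equal(d2$energy,
               direct_search(p, cen, search_config("direct"))$energy)
})

test_that("genetic search is seed-reproducible and reports a consistent energy", {
  p <- shared_potential()
  set.seed(31)
  b <- build_bundle(n_helices = 2, n_res = 37, id = "ga")
  cen <- scoring_centres(b$structure, quiet = TRUE)
  cfg <- search_config("ga", pop_size = 300, generations = 25, n_runs = 2,
                       seed = 5)
  r1 <- genetic_search(p, cen, cfg)
  r2 <- genetic_search(p, cen, cfg)
  expect_equal(r1$best, r2$best)
  expect_equal(r1$energy, r2$energy)
  expect_equal(r1$energy, structure_energy(p, cen, r1$best), tolerance = 1e-9)
  expect_length(r1$runs, 2L)
  expect_equal(r1$energy, min(vapply(r1$runs, `[[`, numeric(1), "energy")))
  # a different seed explores differently but stays a valid energy
  r3 <- genetic_search(p, cen, search_config("ga", pop_size = 300,
                                             generations = 25, n_runs = 2,
                                             seed = 6))
  expect_equal(r3$energy, structure_energy(p, cen, r3$best), tolerance = 1e-9)
})

test_that("max_energy_calls caps the genetic search budget", {
  p <- shared_potential()
  set.seed(32)
  b <- build_bundle(n_helices = 1, n_res = 37, id = "cap")
  cen <- scoring_centres(b$structure, quiet = TRUE)
  cfg <- search_config("ga", pop_size = 200, generations = 50, n_runs = 1,
                       seed = 1, max_energy_calls = 600)
  r <- genetic_search(p, cen, cfg)
  expect_lte(r$n_energy_calls, 600 + 200)   # stops after the crossing generation
})

test_that("orient scrambles, dispatches, and returns a consistently transformed structure", {
  p <- shared_potential()
  set.seed(33)
  b <- build_bundle(n_helices = 2, n_res = 37, tilt = 10, id = "or")
  cfg <- search_config("ga", pop_size = 400, generations = 30, n_runs = 2,
                       seed = 9)
  res <- orient(b$structure, p, cfg)
  expect_s3_class(res$result, "mem_orientation")
  expect_s3_class(res$structure, "mem_structure")
  expect_s3_class(res$scramble, "mem_transform")
  # the reported energy is the energy of the returned oriented structure
  cen_out <- scoring_centres(res$structure, quiet = TRUE)
  expect_equal(structure_energy(p, cen_out), res$result$energy,
               tolerance = 1e-9)

  # exhaustive is the grid code path at fine steps
  tiny <- search_config("exhaustive", grid_rot_step = 30, grid_dz_step = 5,
                        dz_bounds = c(-2, 2), seed = 2)
  tiny_grid <- search_config("grid", grid_rot_step = 0.5, grid_dz_step = 0.25,
                             dz_bounds = c(-2, 2), seed = 2)
  cen <- scoring_centres(b$structure, quiet = TRUE)
  expect_equal(orient(b$structure, p, tiny, scramble = FALSE)$result$energy,
               grid_search(p, cen, tiny_grid)$energy)
})

test_that("starting-pose independence: pre-rotated input reaches the same energy", {
  p <- shared_potential()
  set.seed(34)
  b <- build_bundle(n_helices = 4, n_res = 37, id = "si")
  pre <- transform_structure(b$structure, transform_pose(142, 261, 18))
  cfg <- search_config("ga", pop_size = 1500, generations = 50, n_runs = 5,
                       seed = 3)
  e1 <- orient(b$structure, p, cfg)$result$energy
  e2 <- orient(pre, p, cfg)$result$energy
  expect_lt(abs(e1 - e2), 0.08 * abs(e1))
})
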