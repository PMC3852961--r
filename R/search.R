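## search: minimise structure_energy over the 3-parameter pose space.
##
## Three strategies: a genetic algorithm (population 10000, the production
## default; 500 in refinement mode), Hooke-Jeeves direct pattern search,
## and an exhaustive grid search at 1 degree / 0.5 A steps. The GA is run
## n_runs times independently (default 5) and the lowest-energy pose over
## all runs is reported.

#' Search configuration
#'
#' @param method One of "ga", "direct", "grid", "exhaustive".
#' @param pop_size GA population size (production default 10000; use 500
#'   for refinement-mode scoring).
#' @param n_runs Independent GA restarts; the best pose over runs wins.
#' @param generations GA generations per run.
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-gene Gaussian mutation probability.
#' @param mutation_sigma Mutation standard deviations (deg, deg, A).
#' @param elite_fraction Fraction of the population copied unchanged.
#' @param tournament_size GA selection tournament size.
#' @param hj_initial_steps Hooke-Jeeves initial steps (deg, deg, A).
#' @param hj_resize_factor Step shrink factor on a failed sweep, in (0,1).
#' @param hj_min_steps Termination steps (deg, deg, A).
#' @param grid_rot_step Grid rotation step, degrees.
#' @param grid_dz_step Grid translation step, A.
#' @param dz_bounds Translation bounds, A.
#' @param seed Integer seed for all stochastic methods.
#' @param max_energy_calls Optional cap on energy evaluations (GA stops
#'   adding generations once exceeded).
#' @return List of class `mem_search_config`.
#' @export
search_config <- function(method = c("ga", "direct", "grid", "exhaustive"),
                          pop_size = 10000, n_runs = 5, generations = 100,
                          crossover_rate = 0.9, mutation_rate = 0.1,
                          mutation_sigma = c(10, 10, 2),
                          elite_fraction = 0.01, tournament_size = 2,
                          hj_initial_steps = c(16, 16, 8),
                          hj_resize_factor = 0.5,
                          hj_min_steps = c(0.1, 0.1, 0.05),
                          grid_rot_step = 1, grid_dz_step = 0.5,
                          dz_bounds = c(-50, 50), seed = 1,
                          max_energy_calls = NULL) {
  method <- match.arg(method)
  stopifnot(pop_size >= 2, all(hj_initial_steps > 0),
            hj_resize_factor > 0, hj_resize_factor < 1,
            grid_rot_step > 0, grid_dz_step > 0,
            dz_bounds[1] < dz_bounds[2])
  structure(list(method = method, pop_size = pop_size, n_runs = n_runs,
                 generations = generations, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, mutation_sigma = mutation_sigma,
                 elite_fraction = elite_fraction,
                 tournament_size = tournament_size,
                 hj_initial_steps = hj_initial_steps,
                 hj_resize_factor = hj_resize_factor,
                 hj_min_steps = hj_min_steps,
                 grid_rot_step = grid_rot_step, grid_dz_step = grid_dz_step,
                 dz_bounds = dz_bounds, seed = seed,
                 max_energy_calls = max_energy_calls),
            class = "mem_search_config")
}

.orientation_result <- function(best, energy, method, runs, n_calls) {
  structure(list(best = best, energy = energy, method = method,
                 runs = runs, n_energy_calls = n_calls),
            class = "mem_orientation")
}

#' @export
print.mem_orientation <- function(x, ...) {
  cat(sprintf("<mem_orientation %s: E=%.4f at (%.2f deg, %.2f deg, %.2f A), %d energy calls>\n",
              x$method, x$energy, x$best$rot_x, x$best$rot_y, x$best$dz,
              x$n_energy_calls))
  invisible(x)
}

#' Exhaustive grid search over poses
#'
#' Evaluates every pose on the (rot_x, rot_y, dz) grid at the configured
#' steps and returns the minimum. Deterministic; ties are broken by the
#' first pose encountered in lexicographic (rot_x, rot_y, dz) order.
#'
#' @param p A `mem_potential`.
#' @param centres A `mem_centres` data.frame.
#' @param cfg A `mem_search_config`.
#' @return A `mem_orientation`.
#' @export
grid_search <- function(p, centres, cfg = search_config("grid")) {
  cm <- .centres_matrix(centres)
  rxs <- seq(0, 360 - cfg$grid_rot_step, by = cfg$grid_rot_step)
  rys <- rxs
  dzs <- seq(cfg$dz_bounds[1], cfg$dz_bounds[2], by = cfg$grid_dz_step)
  inner <- expand.grid(dz = dzs, rot_y = rys)   # dz varies fastest
  best_e <- Inf
  best <- transform_pose(0, 0, dzs[1])
  n_calls <- 0L
  for (rx in rxs) {                             # rot_x outermost: lexicographic
    e <- .pose_energies(p, cm, rep.int(rx, nrow(inner)), inner$rot_y, inner$dz)
    n_calls <- n_calls + length(e)
    i <- which.min(e)
    if (e[i] < best_e) {
      best_e <- e[i]
      best <- transform_pose(rx, inner$rot_y[i], inner$dz[i])
    }
  }
  .orientation_result(best, best_e, "grid",
                      list(list(transform = best, energy = best_e)), n_calls)
}

#' Hooke-Jeeves direct pattern search
#'
#' Classic derivative-free pattern search: exploratory moves vary one
#' parameter at a time by the current step; a successful exploration
#' triggers a pattern move; when no single-coordinate move improves the
#' energy, all steps shrink by the resize factor. Terminates when every
#' step is below its minimum. The returned energy never exceeds the
#' starting pose's energy.
#'
#' @param p A `mem_potential`.
#' @param centres A `mem_centres` data.frame.
#' @param cfg A `mem_search_config`.
#' @param start Optional starting `mem_transform`; when given, a single
#'   pattern search is run from it. By default the search is seeded
#'   deterministically from a coarse probe grid (15 degrees / 2.5 A) and
#'   iterated pattern searches (restarting with full steps until no
#'   further improvement) are run from the best `n_runs` probe poses,
#'   keeping the best result: the energy landscape has wide zero-energy
#'   plateaus (any pose placing the protein entirely outside the slab)
#'   and multiple local basins, on which a pattern search started blind
#'   stalls immediately.
#' @return A `mem_orientation`.
#' @export
direct_search <- function(p, centres, cfg = search_config("direct"),
                          start = NULL) {
  cm <- .centres_matrix(centres)
  n_calls <- 0L
  ener <- function(v) {
    n_calls <<- n_calls + 1L
    .pose_energies(p, cm, v[1], v[2], v[3])
  }
  clamp <- function(v) {
    v[3] <- min(max(v[3], cfg$dz_bounds[1]), cfg$dz_bounds[2])
    v
  }
  # iterate the pattern search, resetting the step schedule at the last
  # optimum, until a full schedule yields no further improvement
  iterated_hj <- function(v0) {
    best <- .hooke_jeeves(ener, v0, cfg$hj_initial_steps,
                          cfg$hj_resize_factor, cfg$hj_min_steps, clamp)
    repeat {
      nxt <- .hooke_jeeves(ener, best$par, cfg$hj_initial_steps,
                           cfg$hj_resize_factor, cfg$hj_min_steps, clamp)
      if (nxt$value < best$value - 1e-12) best <- nxt else break
    }
    best
  }

  if (!is.null(start)) {
    starts <- list(c(start$rot_x, start$rot_y, start$dz))
  } else {
    probe <- expand.grid(dz = seq(cfg$dz_bounds[1], cfg$dz_bounds[2], by = 2.5),
                         rot_y = seq(0, 345, by = 15),
                         rot_x = seq(0, 345, by = 15))
    pe <- .pose_energies(p, cm, probe$rot_x, probe$rot_y, probe$dz)
    n_calls <- n_calls + length(pe)
    top <- order(pe)[seq_len(max(1L, cfg$n_runs))]
    starts <- lapply(top, function(i) c(probe$rot_x[i], probe$rot_y[i],
                                        probe$dz[i]))
  }
  runs <- lapply(starts, iterated_hj)
  vals <- vapply(runs, `[[`, numeric(1), "value")
  hj <- runs[[which.min(vals)]]
  best <- transform_pose(hj$par[1], hj$par[2], hj$par[3])
  .orientation_result(
    best, hj$value, "direct",
    lapply(runs, function(r) {
      list(transform = transform_pose(r$par[1], r$par[2], r$par[3]),
           energy = r$value)
    }), n_calls)
}

# classic Hooke-Jeeves pattern search on an arbitrary objective;
# exploratory +/- step per coordinate, pattern extrapolation on success,
# multiplicative step shrink on failure, stop when all steps < min_steps
.hooke_jeeves <- function(f, par, steps, resize, min_steps,
                          clamp = identity) {
  explore <- function(base, e_base, step) {
    v <- base
    e <- e_base
    for (k in seq_along(v)) {
      for (sgn in c(1, -1)) {
        cand <- clamp(replace(v, k, v[k] + sgn * step[k]))
        ec <- f(cand)
        if (ec < e) {
          v <- cand
          e <- ec
          break
        }
      }
    }
    list(v = v, e = e)
  }
  base <- clamp(par)
  e_base <- f(base)
  step <- steps
  while (any(step >= min_steps)) {
    ex <- explore(base, e_base, step)
    if (ex$e < e_base) {
      # pattern move: extrapolate along the improving direction
      repeat {
        pat <- clamp(2 * ex$v - base)
        base <- ex$v
        e_base <- ex$e
        ex2 <- explore(pat, f(pat), step)
        if (ex2$e < e_base) ex <- ex2 else break
      }
    } else {
      step <- step * resize
    }
  }
  list(par = base, value = e_base)
}

# one GA run; RNG state is the caller's responsibility
.ga_run <- function(p, cm, cfg) {
  n <- cfg$pop_size
  pop <- cbind(runif(n, 0, 360), runif(n, 0, 360),
               runif(n, cfg$dz_bounds[1], cfg$dz_bounds[2]))
  fit <- .pose_energies(p, cm, pop[, 1], pop[, 2], pop[, 3])
  n_calls <- n
  n_elite <- max(1L, floor(cfg$elite_fraction * n))
  for (g in seq_len(cfg$generations)) {
    if (!is.null(cfg$max_energy_calls) && n_calls >= cfg$max_energy_calls) break
    ord <- order(fit)
    elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
    # tournament selection of two parent sets
    n_off <- n - n_elite
    pick <- function() {
      cand <- matrix(sample.int(n, cfg$tournament_size * n_off, replace = TRUE),
                     n_off)
      idx <- cand[cbind(seq_len(n_off), max.col(-matrix(fit[cand], n_off)))]
      idx
    }
    pa <- pop[pick(), , drop = FALSE]
    pb <- pop[pick(), , drop = FALSE]
    # uniform crossover of the 3 genes
    cross <- runif(n_off) < cfg$crossover_rate
    mask <- matrix(runif(3 * n_off) < 0.5, n_off) & cross
    off <- ifelse(mask, pb, pa)
    # Gaussian mutation
    mut <- matrix(runif(3 * n_off) < cfg$mutation_rate, n_off)
    noise <- matrix(rnorm(3 * n_off), n_off) *
      rep(cfg$mutation_sigma, each = n_off)
    off <- off + ifelse(mut, noise, 0)
    off[, 1:2] <- off[, 1:2] %% 360
    off[, 3] <- pmin(pmax(off[, 3], cfg$dz_bounds[1]), cfg$dz_bounds[2])
    e_off <- .pose_energies(p, cm, off[, 1], off[, 2], off[, 3])
    n_calls <- n_calls + nrow(off)
    pop <- rbind(elite, off)
    fit <- c(fit[ord[seq_len(n_elite)]], e_off)
  }
  i <- which.min(fit)
  list(transform = transform_pose(pop[i, 1], pop[i, 2], pop[i, 3]),
       energy = fit[i], n_calls = n_calls)
}

#' Genetic-algorithm pose search
#'
#' Runs `cfg$n_runs` independent GA optimisations (tournament selection,
#' uniform crossover, Gaussian mutation, elitism) and reports the
#' lowest-energy pose found across runs. Fully reproducible given
#' `cfg$seed`.
#'
#' @param p A `mem_potential`.
#' @param centres A `mem_centres` data.frame.
#' @param cfg A `mem_search_config`.
#' @return A `mem_orientation` whose `runs` element holds the per-run
#'   (transform, energy) pairs.
#' @export
genetic_search <- function(p, centres, cfg = search_config("ga")) {
  cm <- .centres_matrix(centres)
  set.seed(cfg$seed)
  runs <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) runs[[r]] <- .ga_run(p, cm, cfg)
  energies <- vapply(runs, `[[`, numeric(1), "energy")
  i <- which.min(energies)
  .orientation_result(runs[[i]]$transform, energies[i], "ga",
                      lapply(runs, function(r) r[c("transform", "energy")]),
                      sum(vapply(runs, `[[`, numeric(1), "n_calls")))
}

#' Orient a structure in the membrane
#'
#' The structure is first scrambled by a random pose (so nothing about its
#' input orientation leaks into the search), then the selected method
#' minimises the membrane pseudo-energy. "exhaustive" is the grid method
#' at fine steps (0.5 degree / 0.25 A).
#'
#' @param s A `mem_structure`.
#' @param p A `mem_potential`.
#' @param cfg A `mem_search_config`.
#' @param scramble Apply the initial random pose (default TRUE).
#' @return List with `result` (a `mem_orientation`, pose relative to the
#'   scrambled structure), `structure` (the oriented `mem_structure`), and
#'   `scramble` (the initial random pose applied).
#' @export
orient <- function(s, p, cfg = search_config("ga"), scramble = TRUE) {
  t0 <- if (scramble) {
    random_pose(cfg$dz_bounds, seed = cfg$seed)
  } else {
    transform_pose(0, 0, 0)
  }
  s0 <- transform_structure(s, t0)
  centres <- scoring_centres(s0, quiet = TRUE)
  res <- switch(cfg$method,
    ga = genetic_search(p, centres, cfg),
    direct = direct_search(p, centres, cfg),
    grid = grid_search(p, centres, cfg),
    exhaustive = {
      fine <- cfg
      fine$grid_rot_step <- min(cfg$grid_rot_step, 0.5)
      fine$grid_dz_step <- min(cfg$grid_dz_step, 0.25)
      grid_search(p, centres, fine)
    })
  list(result = res, structure = transform_structure(s0, res$best),
       scramble = t0)
}
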