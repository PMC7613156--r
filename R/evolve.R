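#' Genetic-algorithm configuration
#'
#' @param pop_size even population size (>= 4).
#' @param generations number of generations.
#' @param sigma mutation SD on the log scale.
#' @param fitness_evals engagements (or solo flights) averaged per fitness
#'   estimate when the fitness is stochastic.
#' @param seed master seed.
#' @return list of class `stoopsim_ga_config`.
#' @export
ga_config <- function(pop_size = 20, generations = 40, sigma = 0.3,
                      fitness_evals = 200, seed = 1) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, sigma >= 0, generations >= 1)
  structure(
    list(
      pop_size = pop_size, generations = generations, sigma = sigma,
      fitness_evals = fitness_evals, seed = seed
    ),
    class = "stoopsim_ga_config"
  )
}

#' Log-scale Gaussian mutation
#'
#' Haploid inheritance with Gaussian mutation on the log scale of each
#' evolving parameter: every component is multiplied by `exp(mu)` with
#' `mu ~ N(0, sigma^2)` independently, so positivity is preserved.
#'
#' @param g positive parameter vector.
#' @param sigma mutation SD on the log scale.
#' @param mu optional fixed mutation vector (test hook); when supplied it
#'   replaces the random draws.
#' @return mutated parameter vector (all components > 0).
#' @export
#' @examples
#' mutate_params(c(1, 2), sigma = 0) # identity
#' mutate_params(c(1, 2), mu = log(2)) # doubles every component
mutate_params <- function(g, sigma = 0.3, mu = NULL) {
  if (any(g <= 0)) stop("all parameter components must be positive")
  if (is.null(mu)) mu <- rnorm(length(g), 0, sigma)
  g * exp(rep_len(mu, length(g)))
}

#' One generation of selection and reproduction
#'
#' The fittest half of the population reproduces two copies of itself,
#' one exact and one mutated; ties are broken by first occurrence, the
#' population size is preserved and the best individual always survives
#' unmutated.
#'
#' @param population list of positive parameter vectors.
#' @param fitnesses numeric vector, one fitness per individual (higher is
#'   fitter).
#' @param sigma mutation SD on the log scale.
#' @return list of parameter vectors of the same length.
#' @export
next_generation <- function(population, fitnesses, sigma = 0.3) {
  n <- length(population)
  stopifnot(length(fitnesses) == n, n %% 2 == 0)
  ord <- order(-fitnesses) # stable: first occurrence wins ties
  parents <- population[ord[seq_len(n / 2)]]
  offspring <- c(parents, lapply(parents, mutate_params, sigma = sigma))
  offspring[seq_len(n)]
}

#' Optimise a positive parameter vector by the genetic algorithm
#'
#' @param fitness function mapping a parameter vector to a (possibly
#'   stochastic) scalar fitness; called as `fitness(g, generation)`.
#' @param init initial parameter vector, or a list of vectors (one per
#'   individual).
#' @param cfg a [ga_config()].
#' @return list with `best` (parameter vector), `best_fitness`, and
#'   `trace` (data.frame of per-generation best fitness and parameters).
#' @export
#' @examples
#' f <- function(g, gen) -(log(g) - log(5))^2
#' res <- ga_optimize(f, init = 1, cfg = ga_config(pop_size = 12,
#'   generations = 25, sigma = 0.4, seed = 7))
#' res$best # ~5
ga_optimize <- function(fitness, init, cfg = ga_config()) {
  set.seed(cfg$seed)
  pop <- if (is.list(init)) {
    stopifnot(length(init) == cfg$pop_size)
    init
  } else {
    # spread the initial population around the given point
    lapply(seq_len(cfg$pop_size), function(i) {
      mutate_params(init, sigma = cfg$sigma)
    })
  }
  np <- length(pop[[1]])
  trace <- vector("list", cfg$generations)
  for (gen in seq_len(cfg$generations)) {
    fit <- vapply(pop, fitness, numeric(1), gen)
    best_i <- which.max(fit)
    trace[[gen]] <- data.frame(
      generation = gen, best_fitness = fit[best_i],
      t(setNames(pop[[best_i]], paste0("g", seq_len(np))))
    )
    if (gen < cfg$generations) {
      pop <- next_generation(pop, fit, cfg$sigma)
    }
  }
  tr <- do.call(rbind, trace)
  final_fit <- vapply(pop, fitness, numeric(1), cfg$generations)
  bi <- which.max(final_fit)
  list(best = pop[[bi]], best_fitness = final_fit[bi], trace = tr)
}

#' Evolve the prey's evasion parameters and the falcon's navigation gain
#'
#' Two-stage optimisation following the study design: first the erratic
#' evasion parameters (c1, c2, c3, c4) are evolved with the prey's mean
#' sustained centripetal acceleration (flying alone) as the fitness, which
#' is independent of the predator; then the falcon's navigation constant
#' `N` is evolved against the evolved prey with catch success as the
#' fitness.
#'
#' @param falcon falcon morphology (used in stage two).
#' @param prey prey morphology.
#' @param cfg_erratic,cfg_N [ga_config()]s for the two stages.
#' @param engagement engagement configuration for stage two (geometry at
#'   which `N` is tuned).
#' @param duration solo-flight duration per fitness evaluation, s.
#' @param aero model constants.
#' @param stages which stages to run (`"erratic"`, `"N"` or both).
#' @param erratic_init initial evasion parameters.
#' @return list with `erratic` (an [erratic_params()]), `N`, and the GA
#'   traces.
#' @export
optimize_guidance <- function(falcon, prey,
                              cfg_erratic = ga_config(pop_size = 12,
                                generations = 15, sigma = 0.3,
                                fitness_evals = 8, seed = 1),
                              cfg_N = ga_config(pop_size = 8,
                                generations = 10, sigma = 0.2,
                                fitness_evals = 60, seed = 2),
                              engagement = engagement_config(dz = 200,
                                dx = 100),
                              duration = 15, aero = aero_params(),
                              stages = c("erratic", "N"),
                              erratic_init = erratic_params()) {
  out <- list()
  ep <- erratic_init
  if ("erratic" %in% stages) {
    ps <- agent_spec(prey, aero)
    v0p <- if (inherits(prey, "stoopsim_morphology")) {
      max_range_speed(prey, aero)
    } else {
      prey$speed
    }
    fit_e <- function(g, gen) {
      cc <- list(
        dz = 0, dx = 0, dt = engagement$dt, r_intercept = 0.2,
        r_nearmiss = 5, blind_halfangle = pi / 4, head_start = 0,
        timeout = duration, v0_falcon = 1, v0_prey = v0p,
        N = 3, delay = 0, sigma_v = 0, guidance_dt = 0.05,
        # the evasion family is jinking by construction: switching
        # intervals are bounded sub-second so the optimum cannot
        # degenerate into a smooth spiral
        c1 = min(g[2], 0.4) + min(g[1], 0.8), c2 = min(g[2], 0.4),
        c3 = min(g[3], 1), c4 = g[4]
      )
      m <- .cpp_prey_solo_accel(ps, aero, cc, cfg_erratic$fitness_evals,
        duration, cfg_erratic$seed * 1e4 + gen)
      # sustainability: evasion must be quasi-level (net descent under
      # ~1 m/s); in an unbounded airspace an altitude-burning dive would
      # otherwise dominate the fitness, a strategy no real chase sustains
      mean(m[, 1]) - 10 * max(0, -mean(m[, 2]) - 1)
    }
    # genotype: (c1 - c2, c2, c3, c4); all positive on the log scale
    g0 <- c(max(ep$c1 - ep$c2, 0.05), max(ep$c2, 0.01), ep$c3,
      max(ep$c4, 0.01))
    res_e <- ga_optimize(fit_e, g0, cfg_erratic)
    g <- res_e$best
    ep <- erratic_params(c1 = min(g[2], 0.4) + min(g[1], 0.8),
      c2 = min(g[2], 0.4), c3 = min(g[3], 1), c4 = g[4])
    out$erratic_trace <- res_e$trace
  }
  out$erratic <- ep
  N <- 3
  if ("N" %in% stages) {
    fit_N <- function(g, gen) {
      cfg <- engagement
      cfg$ppn <- ppn_config(N = g[1], delay = engagement$ppn$delay,
        sigma_v = engagement$ppn$sigma_v)
      cfg$erratic <- ep
      oc <- run_engagements(falcon, prey, cfg, n = cfg_N$fitness_evals,
        seed = cfg_N$seed * 1e5 + gen * 1e3, aero = aero)
      mean(oc$category == "intercept")
    }
    res_N <- ga_optimize(fit_N, 3, cfg_N)
    N <- res_N$best[1]
    out$N_trace <- res_N$trace
  }
  out$N <- N
  out
}
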