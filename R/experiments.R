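#' The three attack strategies (start geometries)
#'
#' High altitude: 1500 m above the prey at 50 m horizontal distance;
#' moderate: 200 m above at 100 m; low: 50 m above at 200 m.
#'
#' @return named list of `c(dz, dx)` pairs.
#' @export
attack_strategies <- function() {
  list(
    high = c(dz = 1500, dx = 50),
    moderate = c(dz = 200, dx = 100),
    low = c(dz = 50, dx = 200)
  )
}

falcon_species <- function() {
  c(male = "Peregrine falcon (male)", female = "Peregrine falcon (female)")
}

#' Experiment 1: catch success by sex, attack strategy and prey species
#'
#' Monte Carlo catch success of male and female falcons against the six
#' prey species, attacking from each of the three start geometries, with
#' per-species evolved guidance parameters.
#'
#' @param n_per_condition engagements per condition (the full-scale study
#'   uses 1e5; desk-scale runs use 1e3-1e4 via `scale`).
#' @param scale multiplier applied to `n_per_condition`.
#' @param seed master seed; every engagement stream derives from it and
#'   the condition/engagement index.
#' @param sexes,strategies,prey subsets of conditions to run.
#' @param guidance function(species) returning `list(erratic =, N =)`;
#'   defaults to the evolved values shipped with the package.
#' @param dt integration step, s.
#' @param timeout chase timeout, s.
#' @param aero model constants.
#' @return data.frame with one row per condition: catch success with
#'   Wilson 95% CI, near-miss/timeout shares, mean prey sustained load
#'   factor, and mean falcon/prey metrics at intercept.
#' @export
run_experiment1 <- function(n_per_condition = 1e5, scale = 0.01, seed = 1,
                            sexes = c("male", "female"),
                            strategies = names(attack_strategies()),
                            prey = prey_species(),
                            guidance = default_guidance,
                            dt = 0.005, timeout = 60,
                            aero = aero_params()) {
  n <- max(1L, as.integer(round(n_per_condition * scale)))
  morphs <- load_morphology_table()
  strat <- attack_strategies()
  rows <- list()
  cond <- 0L
  for (sex in sexes) {
    fal <- morphs[[falcon_species()[[sex]]]]
    for (sp in prey) {
      gd <- guidance(sp)
      er <- do.call(erratic_params, gd$erratic[c("c1", "c2", "c3", "c4")])
      for (st in strategies) {
        cond <- cond + 1L
        g <- strat[[st]]
        cfg <- engagement_config(
          dz = g[["dz"]], dx = g[["dx"]], dt = dt, timeout = timeout,
          ppn = ppn_config(N = gd$N), erratic = er
        )
        oc <- run_engagements(fal, morphs[[sp]], cfg,
          n = n,
          seed = seed, start_index = cond * 1e7, aero = aero
        )
        cs <- catch_success(oc)
        ic <- oc[oc$category == "intercept", , drop = FALSE]
        rows[[cond]] <- data.frame(
          sex = sex, prey = sp, strategy = st, n = cs$n, k = cs$k,
          success = cs$estimate, lower = cs$lower, upper = cs$upper,
          near_miss = mean(oc$category == "near_miss"),
          timeout = mean(oc$category == "timeout"),
          prey_mean_lf = mean(oc$prey_mean_lf),
          falcon_speed_icpt = if (nrow(ic)) mean(ic$falcon_speed) else NA_real_,
          falcon_lf_icpt = if (nrow(ic)) mean(ic$falcon_lf) else NA_real_,
          prey_speed_icpt = if (nrow(ic)) mean(ic$prey_speed) else NA_real_,
          prey_lf_icpt = if (nrow(ic)) mean(ic$prey_lf) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Experiment 2: which prey flight-performance dimensions matter
#'
#' A male peregrine attacks capped prey whose flight speed, maximum load
#' factor and maximum roll acceleration are sampled uniformly and
#' independently (breaking their physical correlation), for a horizontal
#' (low-altitude) and a stooping (high-altitude) geometry.
#'
#' @param n_samples sampled (speed, load factor, roll acceleration)
#'   triples per geometry (full scale 1e6).
#' @param scale multiplier on `n_samples`.
#' @param seed master seed.
#' @param speed_range,loadfactor_range,rollacc_range sampling ranges
#'   (m/s, -, rad/s^2).
#' @param geometries subset of `c("horizontal", "stoop")`.
#' @param erratic evasion parameters of the capped prey.
#' @param N falcon navigation constant.
#' @param dt integration step, s.
#' @param timeout chase timeout, s.
#' @param aero model constants.
#' @return data.frame with one row per sampled engagement: the sampled
#'   caps, geometry and outcome (`caught` logical).
#' @export
run_experiment2 <- function(n_samples = 1e6, scale = 0.01, seed = 2,
                            speed_range = c(0, 100),
                            loadfactor_range = c(0, 15),
                            rollacc_range = c(0, 8000),
                            geometries = c("horizontal", "stoop"),
                            erratic = erratic_params(), N = 3,
                            dt = 0.005, timeout = 30,
                            aero = aero_params()) {
  n <- max(1L, as.integer(round(n_samples * scale)))
  fal <- get_morphology("Peregrine falcon (male)")
  geom <- list(horizontal = c(dz = 50, dx = 200), stoop = c(dz = 1500, dx = 50))
  set.seed(seed)
  rows <- list()
  for (gname in geometries) {
    g <- geom[[gname]]
    sp <- runif(n, max(speed_range[1], 1), speed_range[2])
    lf <- runif(n, loadfactor_range[1], loadfactor_range[2])
    ra <- runif(n, rollacc_range[1], rollacc_range[2])
    caught <- logical(n)
    mlf <- numeric(n)
    for (i in seq_len(n)) {
      prey <- capped_agent(speed = sp[i], n_max = lf[i], rollacc_max = ra[i])
      cfg <- engagement_config(
        dz = g[["dz"]], dx = g[["dx"]], dt = dt,
        timeout = timeout, ppn = ppn_config(N = N), erratic = erratic
      )
      oc <- run_engagements(fal, prey, cfg,
        n = 1, seed = seed,
        start_index = (match(gname, geometries) - 1) * 1e7 + i, aero = aero
      )
      caught[i] <- oc$category == "intercept"
      mlf[i] <- oc$prey_mean_lf
    }
    rows[[gname]] <- data.frame(
      geometry = gname, speed = sp, load_factor = lf, roll_accel = ra,
      caught = caught, prey_mean_lf = mlf, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Experiment 3: which raptor flight-performance dimensions matter
#'
#' A generic capped raptor (fixed speed, maximum load factor and maximum
#' roll acceleration, sampled uniformly) attacks a full-physics blue tit
#' or mallard flying erratically.
#'
#' @inheritParams run_experiment2
#' @param targets prey species (smallest and largest by default).
#' @param guidance function(species) returning the evasion parameters.
#' @return data.frame with one row per sampled engagement.
#' @export
run_experiment3 <- function(n_samples = 1e6, scale = 0.01, seed = 3,
                            speed_range = c(0, 100),
                            loadfactor_range = c(0, 15),
                            rollacc_range = c(0, 8000),
                            targets = c("Eurasian blue tit", "Mallard"),
                            guidance = default_guidance,
                            dt = 0.005, timeout = 30,
                            aero = aero_params()) {
  n <- max(1L, as.integer(round(n_samples * scale)))
  morphs <- load_morphology_table()
  set.seed(seed)
  rows <- list()
  for (tg in targets) {
    gd <- guidance(tg)
    er <- do.call(erratic_params, gd$erratic[c("c1", "c2", "c3", "c4")])
    sp <- runif(n, max(speed_range[1], 1), speed_range[2])
    lf <- runif(n, loadfactor_range[1], loadfactor_range[2])
    ra <- runif(n, rollacc_range[1], rollacc_range[2])
    caught <- logical(n)
    for (i in seq_len(n)) {
      raptor <- capped_agent(speed = sp[i], n_max = lf[i], rollacc_max = ra[i])
      cfg <- engagement_config(
        dz = 200, dx = 100, dt = dt, timeout = timeout,
        ppn = ppn_config(N = gd$N), erratic = er
      )
      oc <- run_engagements(raptor, morphs[[tg]], cfg,
        n = 1, seed = seed,
        start_index = (match(tg, targets) - 1) * 1e7 + i, aero = aero
      )
      caught[i] <- oc$category == "intercept"
    }
    rows[[tg]] <- data.frame(
      target = tg, speed = sp, load_factor = lf, roll_accel = ra,
      caught = caught, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
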