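#' Wilson score interval for catch success
#'
#' @param k number of intercepts.
#' @param n number of engagements (> 0).
#' @param conf confidence level.
#' @return list with `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' catch_success_ci(0, 100) # upper ~0.037
catch_success_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, centre - half),
    upper = min(1, centre + half))
}

#' Penalized additive logistic response surface
#'
#' Fits the catch probability as an additive logistic model with penalized
#' smooths of prey (or predator) speed `S`, maximum load factor `L` and
#' maximum roll acceleration `R`, plus a low-rank tensor interaction
#' smooth, with smoothing selected by generalized cross-validation.
#'
#' @param records data.frame with columns `speed`, `load_factor`,
#'   `roll_accel` and a logical/0-1 `caught`.
#' @param k_main basis dimension of the univariate smooths.
#' @param k_int marginal basis dimension of the tensor interaction.
#' @param interaction include the trivariate interaction smooth.
#' @return object of class `stoopsim_surface`: the fitted `mgcv::gam`
#'   plus a `predict_prob(newdata)` function returning probabilities in
#'   (0, 1).
#' @export
fit_success_surface <- function(records, k_main = 10, k_int = 4,
                                interaction = TRUE) {
  stopifnot(all(c("speed", "load_factor", "roll_accel", "caught")
  %in% names(records)))
  if (nrow(records) < 100) stop("too few records to fit a surface")
  d <- data.frame(
    S = records$speed, L = records$load_factor, R = records$roll_accel,
    C = as.integer(records$caught)
  )
  keep <- vapply(
    c("S", "L", "R"),
    function(v) stats::sd(d[[v]]) > 1e-10, logical(1)
  )
  if (!all(keep)) {
    warning(
      "dropping constant covariate(s): ",
      paste(c("S", "L", "R")[!keep], collapse = ", ")
    )
  }
  terms <- paste0("s(", c("S", "L", "R")[keep], ", k = ", k_main, ")")
  if (interaction && sum(keep) == 3) {
    terms <- c(terms, paste0("ti(L, R, S, k = ", k_int, ")"))
  }
  form <- stats::as.formula(paste("C ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = stats::binomial(), data = d, method = "GCV.Cp")
  out <- list(
    fit = fit,
    predict_prob = function(newdata) {
      nd <- data.frame(
        S = newdata$speed, L = newdata$load_factor,
        R = newdata$roll_accel
      )
      as.numeric(predict(fit, newdata = nd, type = "response"))
    }
  )
  class(out) <- "stoopsim_surface"
  out
}

#' Partial effect of one covariate of a fitted success surface
#'
#' Varies one covariate over its range while holding the others at their
#' medians (or at caller-chosen reference values).
#'
#' @param surface a `stoopsim_surface`.
#' @param records the records the surface was fitted to.
#' @param var one of `"speed"`, `"load_factor"`, `"roll_accel"`.
#' @param n grid size.
#' @param at named list fixing reference values for the held covariates
#'   (defaults to their medians).
#' @return data.frame with the grid and the predicted catch probability.
#' @export
partial_effect <- function(surface, records, var, n = 50, at = list()) {
  stopifnot(var %in% c("speed", "load_factor", "roll_accel"))
  grid <- seq(min(records[[var]]), max(records[[var]]), length.out = n)
  nd <- data.frame(
    speed = stats::median(records$speed),
    load_factor = stats::median(records$load_factor),
    roll_accel = stats::median(records$roll_accel)
  )[rep(1, n), ]
  for (nm in names(at)) nd[[nm]] <- at[[nm]]
  nd[[var]] <- grid
  data.frame(value = grid, prob = surface$predict_prob(nd))
}

#' Mean sustained load factor of the prey over a chase
#'
#' Time-average of the prey's lift-to-weight ratio from attack initiation
#' to termination; in straight level flight this is exactly 1.  Species
#' that sustain a high value are the hardest to catch.
#'
#' @param load_factors per-step prey load factors, or an outcomes
#'   data.frame from [run_engagements()] (whose `prey_mean_lf` column
#'   already holds the per-engagement mean).
#' @return scalar mean.
#' @export
mean_sustained_load_factor <- function(load_factors) {
  if (is.data.frame(load_factors)) {
    lf <- load_factors$prey_mean_lf
  } else {
    lf <- load_factors
  }
  if (!length(lf)) stop("no telemetry supplied")
  mean(lf)
}

#' Mean flight performance metrics at the moment of intercept
#'
#' @param outcomes data.frame from [run_engagements()], or a list of such
#'   data.frames (one per condition).
#' @param who `"falcon"` or `"prey"`: whose metrics to average.
#' @return one-row data.frame (or row-bound rows) with the number of
#'   intercepts and mean speed, load factor, roll acceleration and turn
#'   radius at the intercept instant; conditions without intercepts are
#'   omitted with a note.
#' @export
intercept_summary <- function(outcomes, who = c("falcon", "prey")) {
  who <- match.arg(who)
  if (is.data.frame(outcomes)) outcomes <- list(outcomes)
  rows <- lapply(seq_along(outcomes), function(i) {
    oc <- outcomes[[i]]
    ic <- oc[oc$category == "intercept", , drop = FALSE]
    if (!nrow(ic)) {
      message("condition ", i, ": no intercepts; row omitted")
      return(NULL)
    }
    pre <- paste0(who, "_")
    data.frame(
      condition = if (!is.null(names(outcomes))) names(outcomes)[i] else i,
      n_intercepts = nrow(ic),
      speed = mean(ic[[paste0(pre, "speed")]]),
      load_factor = mean(ic[[paste0(pre, "lf")]]),
      roll_accel = mean(ic[[paste0(pre, "rollacc")]]),
      turn_radius = mean(ic[[paste0(pre, "radius")]][
        is.finite(ic[[paste0(pre, "radius")]])
      ]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Howland's escape-by-turning condition in acceleration form
#'
#' A fleeing prey can escape by turning more tightly than its pursuer if
#' and only if its normalized speed exceeds its normalized turn radius;
#' since centripetal acceleration equals speed squared over radius, the
#' condition is equivalent to `a > 1` where `a` is the prey's centripetal
#' acceleration normalized by the predator's.
#'
#' @param prey_a prey centripetal acceleration, m/s^2.
#' @param pred_a predator centripetal acceleration, m/s^2 (> 0).
#' @param prey_v,pred_v,prey_r,pred_r optional speeds and radii; when
#'   given, the normalized `v` and `r` ratios are reported too.
#' @return list with `a` (= prey_a / pred_a), optional `v` and `r`, and
#'   `escape_possible` (strict inequality `a > 1`).
#' @export
#' @examples
#' howland_ratio(10, 5)$escape_possible # TRUE
#' howland_ratio(5, 5)$escape_possible # FALSE (boundary)
howland_ratio <- function(prey_a, pred_a, prey_v = NULL, pred_v = NULL,
                          prey_r = NULL, pred_r = NULL) {
  stopifnot(pred_a > 0)
  out <- list(a = prey_a / pred_a)
  if (!is.null(prey_v) && !is.null(pred_v)) out$v <- prey_v / pred_v
  if (!is.null(prey_r) && !is.null(pred_r)) out$r <- prey_r / pred_r
  out$escape_possible <- out$a > 1
  out
}
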