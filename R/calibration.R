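#' Weighted relative-error objective specification
#'
#' Holds the observed carbon-density series and the weights applied to
#' the final survey year. `w_a` (default 25) weights the aboveground
#' woody error and `w_l` (default 5) the leaf error in year `n`, so the
#' latest field survey dominates the fit.
#'
#' @param observed a `carbon_density_series` with positive AC and LC.
#' @param w_a,w_l final-year weights (>= 1).
#' @return an `objective_spec` object.
#' @export
objective_spec <- function(observed, w_a = 25, w_l = 5) {
  stopifnot(w_a >= 1, w_l >= 1)
  if (any(observed$AC <= 0) || any(observed$LC <= 0))
    stop("observed AC and LC must be positive at every age (relative errors)")
  structure(list(observed = observed, w_a = w_a, w_l = w_l,
                 n = max(observed$stand_age)),
            class = "objective_spec")
}

#' Average yearly weighted relative-error objective
#'
#' The misfit between simulated and observed aboveground woody (AC) and
#' leaf (LC) carbon densities over stand ages 1..n:
#' \deqn{f = \frac{\sum_{i<n} e_{A,i}^2 + \sum_{i<n} e_{L,i}^2
#'             + W_A e_{A,n}^2 + W_L e_{L,n}^2}{2(n-1) + W_A + W_L}}
#' with relative errors `e = (sim - obs)/obs`. The normaliser counts the
#' `2(n-1)` unweighted squared errors plus the two weights; `f = 0` iff
#' the simulation matches the observations at every age.
#'
#' @param sim a `carbon_density_series` sharing the observed ages.
#' @param spec an [objective_spec()].
#' @return scalar misfit, dimensionless and nonnegative.
#' @export
objective_f <- function(sim, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  obs <- spec$observed
  if (!all(obs$stand_age %in% sim$stand_age))
    stop("simulation does not cover the observed stand ages")
  i <- match(obs$stand_age, sim$stand_age)
  eA <- (sim$AC[i] - obs$AC) / obs$AC
  eL <- (sim$LC[i] - obs$LC) / obs$LC
  n <- length(i)
  last <- which.max(obs$stand_age)
  pre <- setdiff(seq_len(n), last)
  num <- sum(eA[pre]^2) + sum(eL[pre]^2) +
    spec$w_a * eA[last]^2 + spec$w_l * eL[last]^2
  num / (2 * (n - 1) + spec$w_a + spec$w_l)
}

#' Relative error of a simulated value
#'
#' `(sim - obs) / obs`, the elementary error entering the objective.
#'
#' @param sim,obs simulated and observed values (obs nonzero).
#' @return relative error (signed).
#' @export
relative_error <- function(sim, obs) {
  if (any(obs == 0)) stop("obs must be nonzero")
  (sim - obs) / obs
}

#' Derivative-free global optimization by dividing rectangles (DIRECT)
#'
#' Deterministic Lipschitzian global minimiser: the box is normalised to
#' the unit cube, and at every iteration the potentially optimal
#' hyperrectangles (the lower-right convex hull of the size-value cloud)
#' are trisected along their longest sides. No gradients, no randomness;
#' all evaluations stay inside the bounds and the best value is
#' nonincreasing.
#'
#' @param fn objective `function(x) -> scalar`.
#' @param lower,upper bound vectors (lower < upper).
#' @param budget maximum number of function evaluations.
#' @param eps potential-optimality slack on the current best value.
#' @return list with `par`, `value`, `evaluations`, `trace` (best-so-far
#'   after each evaluation), `par_trace` not kept.
#' @export
direct_optimize <- function(fn, lower, upper, budget = 2000, eps = 1e-4) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper), budget >= d + 1)
  span <- upper - lower
  nev <- 0L
  trace <- numeric(0)
  feval <- function(xu) {           # xu in unit cube
    nev <<- nev + 1L
    v <- fn(lower + xu * span)
    trace[nev] <<- if (nev == 1L) v else min(v, trace[nev - 1L])
    v
  }
  # rectangle store: centers (d x m), third-levels per dim (d x m), f (m)
  centers <- matrix(0.5, nrow = d, ncol = 1)
  levels <- matrix(0L, nrow = d, ncol = 1)
  fvals <- feval(centers[, 1])

  rect_size <- function(lv) {       # half-diagonal of a rectangle
    sqrt(sum((3^(-lv) / 2)^2))
  }
  while (nev < budget) {
    sizes <- vapply(seq_along(fvals),
                    function(j) rect_size(levels[, j]), numeric(1))
    fmin <- min(fvals)
    # potentially optimal rectangles: best of each size class, passing the
    # standard slope test (exists K > 0 making it the Lipschitz minimiser)
    # and the epsilon improvement test against the current best
    skey <- round(sizes, 12)
    usz <- sort(unique(skey))               # ascending sizes
    cand_j <- vapply(usz, function(s) {
      js <- which(skey == s)
      js[which.min(fvals[js])]
    }, integer(1))
    Fk <- fvals[cand_j]
    sel <- integer(0)
    m <- length(usz)
    for (k in seq_len(m)) {
      maxlo <- if (k > 1)
        max((Fk[k] - Fk[1:(k - 1)]) / (usz[k] - usz[1:(k - 1)])) else -Inf
      minup <- if (k < m)
        min((Fk[(k + 1):m] - Fk[k]) / (usz[(k + 1):m] - usz[k])) else Inf
      if (maxlo > minup + 1e-12) next
      if (k < m) {
        bound <- if (fmin != 0) fmin - eps * abs(fmin) else 0
        if (Fk[k] - minup * usz[k] > bound) next
      }
      sel <- c(sel, cand_j[k])
    }
    if (!length(sel)) sel <- cand_j[m]
    for (j in sel) {
      if (nev >= budget) break
      lv <- levels[, j]
      long <- which(lv == min(lv))   # longest sides
      delta <- 3^(-(min(lv) + 1))
      # sample center +/- delta along each longest dim
      cand <- list()
      for (i in long) {
        if (nev >= budget) break
        x1 <- centers[, j]; x1[i] <- x1[i] + delta
        x2 <- centers[, j]; x2[i] <- x2[i] - delta
        f1 <- feval(x1)
        f2 <- if (nev < budget) feval(x2) else Inf
        cand[[length(cand) + 1]] <- list(i = i, x1 = x1, f1 = f1,
                                         x2 = x2, f2 = f2)
      }
      if (!length(cand)) break
      # divide dims in order of their best sampled value
      ord <- order(vapply(cand, function(cc) min(cc$f1, cc$f2), numeric(1)))
      for (t in ord) {
        cc <- cand[[t]]
        lv[cc$i] <- lv[cc$i] + 1L
        centers <- cbind(centers, cc$x1, cc$x2)
        levels <- cbind(levels, lv, lv)
        fvals <- c(fvals, cc$f1, cc$f2)
      }
      levels[, j] <- lv              # shrunken parent keeps its center
    }
  }
  best <- which.min(fvals)
  list(par = as.numeric(lower + centers[, best] * span),
       value = fvals[best], evaluations = nev, trace = trace)
}

#' Evolutionary minimisation within bounds (seeded cross-check)
#'
#' A small real-coded (mu + lambda) evolutionary algorithm: tournament
#' selection, blend crossover and decaying Gaussian mutation, clipped to
#' the bounds. Stochastic but fully reproducible under `seed`; provided
#' as an independent cross-check for the deterministic DIRECT optimizer.
#'
#' @inheritParams direct_optimize
#' @param seed integer seed.
#' @param pop_size population size.
#' @return list with `par`, `value`, `evaluations`, `trace`.
#' @export
ea_optimize <- function(fn, lower, upper, budget = 2000, seed = 1L,
                        pop_size = 20) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper), budget >= pop_size)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  span <- upper - lower
  nev <- 0L
  trace <- numeric(0)
  feval <- function(x) {
    nev <<- nev + 1L
    v <- fn(x)
    trace[nev] <<- if (nev == 1L) v else min(v, trace[nev - 1L])
    v
  }
  pop <- t(replicate(pop_size, lower + stats::runif(d) * span))
  fit <- apply(pop, 1, feval)
  gen <- 0L
  while (nev < budget) {
    gen <- gen + 1L
    sigma <- 0.3 * exp(-6 * nev / budget)
    kids <- matrix(0, nrow = pop_size, ncol = d)
    for (k in seq_len(pop_size)) {
      i <- sample.int(pop_size, 2); i <- i[which.min(fit[i])]
      j <- sample.int(pop_size, 2); j <- j[which.min(fit[j])]
      w <- stats::runif(d, -0.25, 1.25)
      child <- w * pop[i, ] + (1 - w) * pop[j, ]
      child <- child + stats::rnorm(d, 0, sigma * span)
      kids[k, ] <- pmin(upper, pmax(lower, child))
    }
    for (k in seq_len(pop_size)) {
      if (nev >= budget) break
      fk <- feval(kids[k, ])
      worst <- which.max(fit)
      if (fk < fit[worst]) { pop[worst, ] <- kids[k, ]; fit[worst] <- fk }
    }
  }
  best <- which.min(fit)
  list(par = as.numeric(pop[best, ]), value = fit[best],
       evaluations = nev, trace = trace)
}

#' Default calibration bounds for the four free parameters
#'
#' `[0.2x, 3x]` the defaults of `frc_lc`, `sc_lc`, `sla` and `gsmax` — a
#' box wide enough to contain all stand-age-specific optima reported for
#' young plantations while keeping the physiology plausible.
#'
#' @param params baseline [ecophys_params()].
#' @return list with `lower` and `upper` named vectors.
#' @export
default_bounds <- function(params = ecophys_params()) {
  free <- c("frc_lc", "sc_lc", "sla", "gsmax")
  base <- unlist(params[free])
  list(lower = 0.2 * base, upper = 3 * base)
}

#' Calibrate ecophysiological parameters for a monitoring phase
#'
#' Phase `"i"` (planning) returns the defaults untouched. Phases `"ii"`
#' (first monitoring, stand ages 1-5) and `"iii"` (updated monitoring,
#' ages 1-n) minimise the weighted relative-error objective over the four
#' free parameters `frc_lc`, `sc_lc`, `sla`, `gsmax` with the coarse-root
#' allocation `crc_sc` pinned to the observed mean BC:AC ratio (it barely
#' affects AC or LC but fully determines BC).
#'
#' @param phase `"i"`, `"ii"` or `"iii"`.
#' @param observed a `carbon_density_series` of the monitored stand.
#' @param params_default baseline [ecophys_params()].
#' @param site a [site_info()].
#' @param forcing a `daily_climate` covering the observed ages.
#' @param optimizer `"direct"` or `"ea"`.
#' @param bounds list with `lower`/`upper` over the four free parameters;
#'   defaults to [default_bounds()].
#' @param budget optimizer evaluation budget.
#' @param w_a,w_l final-year objective weights.
#' @param seed seed for the stochastic optimizer.
#' @param init optional initial model state passed to [run_years()].
#' @param polish refine the global optimum with a bounded Nelder-Mead
#'   simplex (the global stage locates the basin, the simplex resolves
#'   it).
#' @param polish_maxit iteration cap for the refinement stage.
#' @return A `calibration_phase` list: `phase`, `years_used`, `params`
#'   (calibrated `ecophys_params`), `objective`, `evaluations`, `trace`.
#' @export
calibrate_phase <- function(phase = c("i", "ii", "iii"), observed = NULL,
                            params_default = ecophys_params(),
                            site = site_info(), forcing = NULL,
                            optimizer = c("direct", "ea"),
                            bounds = default_bounds(params_default),
                            budget = 1500, w_a = 25, w_l = 5, seed = 1L,
                            init = NULL, polish = TRUE,
                            polish_maxit = 3000) {
  phase <- match.arg(phase)
  optimizer <- match.arg(optimizer)
  if (phase == "i") {
    return(structure(list(phase = "i", years_used = integer(0),
                          params = params_default, objective = NA_real_,
                          evaluations = 0L, trace = numeric(0)),
                     class = "calibration_phase"))
  }
  stopifnot(!is.null(observed), !is.null(forcing))
  ages <- if (phase == "ii") 1:5 else seq_len(max(observed$stand_age))
  if (!all(ages %in% observed$stand_age))
    stop("observations do not cover stand ages ", paste(range(ages),
                                                        collapse = "-"))
  obs <- observed[observed$stand_age %in% ages, ]
  class(obs) <- c("carbon_density_series", "data.frame")
  spec <- objective_spec(obs, w_a = w_a, w_l = w_l)
  base <- params_default
  base$crc_sc <- bc_ac_mean_ratio(obs)
  free <- names(bounds$lower)
  nyears <- max(ages)
  fn <- function(x) {
    p <- base
    p[free] <- as.list(x)
    sim <- run_years(p, site, forcing, nyears, init = init)$series
    objective_f(sim, spec)
  }
  opt <- if (optimizer == "direct") {
    direct_optimize(fn, bounds$lower, bounds$upper, budget = budget)
  } else {
    ea_optimize(fn, bounds$lower, bounds$upper, budget = budget, seed = seed)
  }
  if (polish) {
    # local downhill-simplex refinement from the global optimum; the
    # global stage finds the basin, the simplex resolves it
    fn_box <- function(x) fn(pmin(bounds$upper, pmax(bounds$lower, x)))
    pol <- stats::optim(opt$par, fn_box, method = "Nelder-Mead",
                        control = list(maxit = polish_maxit,
                                       reltol = 1e-12))
    if (pol$value < opt$value) {
      opt$par <- pmin(bounds$upper, pmax(bounds$lower, pol$par))
      opt$value <- pol$value
    }
    opt$evaluations <- opt$evaluations + unname(pol$counts[1])
    opt$trace <- c(opt$trace, rep(opt$value, unname(pol$counts[1])))
  }
  best <- base
  best[free] <- as.list(opt$par)
  structure(list(phase = phase, years_used = ages,
                 params = best, objective = opt$value,
                 evaluations = opt$evaluations, trace = opt$trace),
            class = "calibration_phase")
}

#' @export
print.calibration_phase <- function(x, ...) {
  cat(sprintf("<calibration_phase> %s", x$phase))
  if (length(x$years_used))
    cat(sprintf(" (ages %d-%d, f = %.4g, %d evaluations)",
                min(x$years_used), max(x$years_used), x$objective,
                x$evaluations))
  cat("\n")
  invisible(x)
}
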