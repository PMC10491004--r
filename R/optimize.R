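# Box-constrained minimizers used to fine-tune the spherical-wavefront
# parameters, plus the domain-level wrapper optimize_sphere().
#
# Algorithm family (names follow the usual toolbox abbreviations):
#   fmc   - bounded quasi-Newton (L-BFGS-B)
#   fmu   - unbounded quasi-Newton (BFGS), result clamped to the box
#   fso   - derivative-free Nelder-Mead simplex, result clamped
#   sa    - simulated annealing with shrinking Gaussian proposals
#   pts   - threshold-accepting randomized pattern search
#   ps    - deterministic compass pattern search
#   ga    - real-coded genetic algorithm (tournament selection, blend
#           crossover, shrinking Gaussian mutation, elitism)
#   ga_ps - hybrid: GA to convergence, then PS refinement from its best point
# Any stochastic member is reproducible for a fixed rng_seed.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Minimize a cost over a box
#'
#' Generic front end to the package's minimizer family. All algorithms
#' respect the bounds `[lower, upper]` (unbounded local searches are clamped
#' to the box, so a minimum outside it lands on the boundary), count every
#' cost evaluation, and record a trace.
#'
#' @param fn cost function taking a numeric parameter vector, returning a
#'   finite scalar; a non-finite value aborts the search with an error naming
#'   the offending parameters.
#' @param par0 starting point (numeric vector, length >= 1).
#' @param lower,upper box bounds, same length as `par0`.
#' @param algorithm one of `"fmc"`, `"fmu"`, `"fso"`, `"sa"`, `"pts"`,
#'   `"ga"`, `"ps"`, `"ga_ps"`.
#' @param rng_seed integer seed for the stochastic members (sa, pts, ga,
#'   ga_ps); deterministic members ignore it.
#' @param control list of overrides: `ga_population` (default 15),
#'   `ga_max_generations` (100), `ga_reltol` (1e-6, over 10 generations),
#'   `sa_iterations` (1500), `max_evaluations` (5000), `ps_reltol` (1e-7).
#' @return List with `par`, `value`, `evaluations`, `trace` (data frame of
#'   evaluated points and costs), `converged`.
#' @export
minimize_cost <- function(fn, par0, lower, upper,
                          algorithm = c("ga_ps", "fmc", "fmu", "fso", "sa",
                                        "pts", "ga", "ps"),
                          rng_seed = 1L, control = list()) {
  algorithm <- match.arg(algorithm)
  d <- length(par0)
  stopifnot(length(lower) == d, length(upper) == d, all(lower < upper))
  ctl <- utils::modifyList(list(ga_population = 15L, ga_max_generations = 100L,
                                ga_reltol = 1e-6, sa_iterations = 1500L,
                                max_evaluations = 5000L, ps_reltol = 1e-7),
                           control)
  env <- new.env()
  env$n <- 0L
  env$tr <- vector("list", 256L)
  f <- function(p) {
    v <- fn(p)
    if (!is.finite(v))
      stop(sprintf("cost evaluation failed (non-finite) at parameters [%s]",
                   paste(signif(p, 6), collapse = ", ")), call. = FALSE)
    env$n <- env$n + 1L
    if (env$n > length(env$tr)) env$tr <- c(env$tr, vector("list", length(env$tr)))
    env$tr[[env$n]] <- c(p, v)
    v
  }
  clamp <- function(p) pmin(upper, pmax(lower, p))
  res <- switch(algorithm,
    fmc = {
      o <- stats::optim(par0, f, method = "L-BFGS-B", lower = lower,
                        upper = upper)
      list(par = o$par, converged = o$convergence == 0)
    },
    fmu = {
      o <- stats::optim(par0, f, method = "BFGS")
      list(par = clamp(o$par), converged = o$convergence == 0)
    },
    fso = {
      o <- if (d == 1L) stats::optim(par0, f, method = "Brent",
                                     lower = lower, upper = upper)
           else stats::optim(par0, f, method = "Nelder-Mead")
      list(par = clamp(o$par), converged = o$convergence == 0)
    },
    sa = with_local_seed(rng_seed, sa_search(f, par0, lower, upper, ctl)),
    pts = with_local_seed(rng_seed, pts_search(f, par0, lower, upper, ctl)),
    ps = ps_search(f, par0, lower, upper, ctl),
    ga = with_local_seed(rng_seed, ga_search(f, par0, lower, upper, ctl)),
    ga_ps = {
      g <- with_local_seed(rng_seed, ga_search(f, par0, lower, upper, ctl))
      p <- ps_search(f, g$par, lower, upper, ctl)
      best <- if (f_value(f, p$par) <= f_value(f, g$par)) p else g
      list(par = best$par, converged = g$converged || p$converged)
    })
  par <- clamp(res$par)
  value <- fn(par)
  tr <- do.call(rbind, env$tr[seq_len(env$n)])
  colnames(tr) <- c(paste0("par", seq_len(d)), "cost")
  list(par = par, value = value, evaluations = env$n,
       trace = as.data.frame(tr), converged = isTRUE(res$converged))
}

f_value <- function(f, p) f(p)

ps_search <- function(f, par0, lower, upper, ctl) {
  d <- length(par0)
  rng <- upper - lower
  x <- pmin(upper, pmax(lower, par0))
  fx <- f(x)
  step <- 0.25 * rng
  evals <- 1L
  while (max(step / rng) > ctl$ps_reltol && evals < ctl$max_evaluations) {
    improved <- FALSE
    for (i in seq_len(d)) {
      for (s in c(1, -1)) {
        y <- x
        y[i] <- min(upper[i], max(lower[i], x[i] + s * step[i]))
        if (y[i] == x[i]) next
        fy <- f(y); evals <- evals + 1L
        if (fy < fx) {
          x <- y; fx <- fy; improved <- TRUE
        }
      }
    }
    if (!improved) step <- step / 2
  }
  list(par = x, converged = max(step / rng) <= ctl$ps_reltol)
}

pts_search <- function(f, par0, lower, upper, ctl) {
  d <- length(par0)
  rng <- upper - lower
  x <- pmin(upper, pmax(lower, par0))
  fx <- f(x)
  best <- x; fbest <- fx
  step <- 0.25 * rng
  thresh <- 0.1 * max(abs(fx), 1e-8)
  evals <- 1L
  while (max(step / rng) > ctl$ps_reltol && evals < ctl$max_evaluations) {
    accepted <- FALSE
    for (i in sample(seq_len(d))) {
      for (s in sample(c(1, -1))) {
        y <- x
        y[i] <- min(upper[i], max(lower[i], x[i] + s * step[i]))
        if (y[i] == x[i]) next
        fy <- f(y); evals <- evals + 1L
        if (fy < fx + thresh) {       # threshold acceptance
          x <- y; fx <- fy
          accepted <- TRUE
          if (fy < fbest) { best <- y; fbest <- fy }
        }
      }
    }
    thresh <- 0.7 * thresh            # cooling: ends as a compass search
    if (!accepted) {
      step <- step / 2
      x <- best; fx <- fbest
    }
  }
  list(par = best, converged = max(step / rng) <= ctl$ps_reltol)
}

sa_search <- function(f, par0, lower, upper, ctl) {
  d <- length(par0)
  rng <- upper - lower
  x <- pmin(upper, pmax(lower, par0))
  fx <- f(x)
  best <- x; fbest <- fx
  n <- ctl$sa_iterations
  t0 <- max(abs(fx), 1e-6)
  for (k in seq_len(n)) {
    frac <- k / n
    scale <- 0.3 * rng * exp(-6 * frac)
    y <- pmin(upper, pmax(lower, x + stats::rnorm(d) * scale))
    fy <- f(y)
    temp <- t0 * exp(-8 * frac)
    if (fy < fx || stats::runif(1) < exp(-(fy - fx) / temp)) {
      x <- y; fx <- fy
      if (fy < fbest) { best <- y; fbest <- fy }
    }
  }
  list(par = best, converged = TRUE)
}

ga_search <- function(f, par0, lower, upper, ctl) {
  d <- length(par0)
  rng <- upper - lower
  npop <- ctl$ga_population
  pop <- matrix(stats::runif(npop * d, rep(lower, each = npop),
                             rep(upper, each = npop)), npop, d)
  pop[1, ] <- pmin(upper, pmax(lower, par0))
  fit <- apply(pop, 1, f)
  hist_best <- numeric(0)
  converged <- FALSE
  for (gen in seq_len(ctl$ga_max_generations)) {
    ord <- order(fit)
    newpop <- matrix(0, npop, d)
    newpop[1, ] <- pop[ord[1], ]                       # elitism
    mut_sd <- 0.1 * rng * 0.95^gen
    for (k in 2:npop) {
      pick <- function() {
        c2 <- sample.int(npop, 2L)
        pop[c2[which.min(fit[c2])], ]
      }
      a <- pick(); b <- pick()
      u <- stats::runif(d, -0.25, 1.25)                # blend crossover
      child <- a + u * (b - a)
      mut <- stats::runif(d) < 0.2
      child[mut] <- child[mut] + stats::rnorm(sum(mut)) * mut_sd[mut]
      newpop[k, ] <- pmin(upper, pmax(lower, child))
    }
    pop <- newpop
    fit <- apply(pop, 1, f)
    hist_best <- c(hist_best, min(fit))
    ng <- length(hist_best)
    if (ng > 10) {
      prev <- hist_best[ng - 10]
      if ((prev - hist_best[ng]) <= ctl$ga_reltol * max(abs(prev), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], converged = converged)
}

#' Fine-tune the spherical wavefront by cost minimization
#'
#' Wraps [minimize_cost()] around the compensation step: candidate curvatures
#' (and optionally the sphere centre) are turned into a conjugated spherical
#' wavefront, applied to the tilt-compensated field, and scored with the
#' selected cost ([cost_J1()] or [cost_J2()]). Bounds follow the
#' `+/- bounds_fraction` convention around the seed curvatures (default
#' 50 percent); when `refine_center` is on, the centre is bounded within
#' 10 percent of the image size around its seed.
#'
#' @param field tilt-compensated [complex_field()].
#' @param sphere0 seed [spherical_wavefront()] (curvatures, centre and sign
#'   set).
#' @param cost `"J2"` (phase standard deviation, default) or `"J1"`
#'   (wrap count).
#' @param algorithm minimizer name, see [minimize_cost()]; default the
#'   hybrid `"ga_ps"`.
#' @param bounds_fraction relative half-width of the curvature box
#'   (default 0.5).
#' @param ga_population GA population size (default 15).
#' @param refine_center logical; also search over `(h, g)` (default FALSE).
#' @param rng_seed seed for stochastic minimizers.
#' @param control passed through to [minimize_cost()].
#' @return List of class `dhm_optimization`: `best`
#'   ([spherical_wavefront()]), `cost_value`, `evaluations`, `trace`,
#'   `converged`, `cost`, `algorithm`.
#' @export
optimize_sphere <- function(field, sphere0, cost = c("J2", "J1"),
                            algorithm = "ga_ps", bounds_fraction = 0.5,
                            ga_population = 15L, refine_center = FALSE,
                            rng_seed = 1L, control = list()) {
  stopifnot(inherits(field, "complex_field"),
            inherits(sphere0, "spherical_wavefront"))
  if (sphere0$telecentric)
    stop("nothing to optimize for a telecentric wavefront", call. = FALSE)
  cost <- match.arg(cost)
  costfn <- if (cost == "J2") cost_J2 else cost_J1
  p <- field$params
  par0 <- c(sphere0$C_x, sphere0$C_y)
  lower <- par0 * (1 - bounds_fraction)
  upper <- par0 * (1 + bounds_fraction)
  if (any(par0 < 0)) {  # keep lower < upper for negative curvature values
    sw <- lower > upper
    tmp <- lower[sw]; lower[sw] <- upper[sw]; upper[sw] <- tmp
  }
  fn <- function(par) {
    # par: (C_x, C_y) or (C_x, C_y, h, g)
    sp <- spherical_wavefront(par[1], par[2],
                              h = if (length(par) > 2) par[3] else sphere0$h,
                              g = if (length(par) > 2) par[4] else sphere0$g,
                              sign = sphere0$sign)
    costfn(compensate_sphere(field, sp))
  }
  ctl <- utils::modifyList(list(ga_population = as.integer(ga_population)),
                           control)
  # stage 1: curvature search with the centre held at its seed. The cost
  # landscape is nearly flat in the curvatures away from the optimum, so
  # keeping this search two-dimensional is what makes the global stage
  # reliable within the +/-50% box.
  res <- minimize_cost(fn, par0, lower, upper, algorithm = algorithm,
                       rng_seed = rng_seed, control = ctl)
  evaluations <- res$evaluations
  trace <- res$trace
  par <- res$par
  hg <- c(sphere0$h, sphere0$g)
  if (refine_center) {
    # stage 2: the cost is smooth in (h, g) near the optimum (a centre error
    # leaves a linear ramp, not extra rings), so a deterministic pattern
    # search over all four parameters polishes curvatures and centre jointly
    lower4 <- c(lower, sphere0$h - 0.1 * p$X, sphere0$g - 0.1 * p$Y)
    upper4 <- c(upper, sphere0$h + 0.1 * p$X, sphere0$g + 0.1 * p$Y)
    res2 <- minimize_cost(fn, c(par, hg), lower4, upper4, algorithm = "ps",
                          rng_seed = rng_seed, control = ctl)
    evaluations <- evaluations + res2$evaluations
    if (res2$value <= res$value) {
      par <- res2$par[1:2]
      hg <- res2$par[3:4]
      res <- res2
    }
  }
  best <- spherical_wavefront(par[1], par[2], h = hg[1], g = hg[2],
                              sign = sphere0$sign)
  structure(list(best = best, cost_value = res$value,
                 evaluations = evaluations, trace = trace,
                 converged = res$converged, cost = cost,
                 algorithm = algorithm),
            class = "dhm_optimization")
}

#' @export
print.dhm_optimization <- function(x, ...) {
  cat(sprintf("<dhm_optimization> %s + %s: cost %.6g after %d evaluations%s\n",
              x$algorithm, x$cost, x$cost_value, x$evaluations,
              if (x$converged) " (converged)" else ""))
  print(x$best)
  invisible(x)
}

#' Export an optimization trace as CSV
#'
#' @param opt a `dhm_optimization` result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(opt, path) {
  stopifnot(inherits(opt, "dhm_optimization"))
  tr <- opt$trace
  tr$iteration <- seq_len(nrow(tr))
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
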