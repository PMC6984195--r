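#' Downhill simplex (Nelder-Mead) settings
#'
#' @param trans_step initial simplex step for translation parameters, mm.
#' @param rot_step initial simplex step for rotation parameters, degrees.
#' @param tol relative cost-spread convergence tolerance.
#' @param max_iter iteration cap (per start).
#' @param restarts number of re-initializations of the simplex at the best
#'   point found so far; a standard guard against the premature simplex
#'   collapse Nelder-Mead is prone to in 6 dimensions. A restart that fails
#'   to improve the cost ends the search early.
#' @return A `vs_simplex_settings` list.
#' @export
simplex_settings <- function(trans_step = 2, rot_step = 2, tol = 1e-4,
                             max_iter = 150L, restarts = 2L) {
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  if (restarts < 0L) stop("`restarts` must be >= 0")
  structure(list(trans_step = trans_step, rot_step = rot_step, tol = tol,
                 max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts)),
            class = "vs_simplex_settings")
}

#' Bound-constrained downhill simplex minimizer
#'
#' The Nelder-Mead reflection / expansion / contraction / shrink loop used to
#' search for the optimal MI at every level of the subdivision hierarchy.
#' Every candidate point is projected into the feasible set *before*
#' evaluation (clamping to `lower`/`upper`, or an arbitrary `project`
#' function), which enforces hard displacement caps rather than soft
#' penalties. Terminates when the relative cost spread across the simplex
#' drops below `settings$tol` or after `settings$max_iter` iterations, and
#' returns the best point seen over the whole search (never worse than the
#' start).
#'
#' @param cost function mapping a length-k numeric vector to a finite scalar;
#'   must be finite at `x0` (error otherwise).
#' @param x0 starting parameter vector.
#' @param step initial simplex step per parameter (scalar or length-k).
#' @param settings a [simplex_settings()].
#' @param lower,upper optional per-parameter bounds (used when `project` is
#'   `NULL`).
#' @param project optional function projecting a parameter vector into the
#'   feasible set; overrides `lower`/`upper`.
#' @return `list(par, value, iterations, evaluations, converged)`.
#' @examples
#' downhill_simplex(function(x) (x - 3)^2, 0, step = 1)$par
#' @export
downhill_simplex <- function(cost, x0, step = 1,
                             settings = simplex_settings(),
                             lower = NULL, upper = NULL, project = NULL) {
  x0 <- as.numeric(x0)
  k <- length(x0)
  if (is.null(project)) {
    lo <- if (is.null(lower)) rep(-Inf, k) else rep_len(as.numeric(lower), k)
    up <- if (is.null(upper)) rep(Inf, k) else rep_len(as.numeric(upper), k)
    project <- function(par) pmin(pmax(par, lo), up)
  }
  step <- rep_len(as.numeric(step), k)
  nev <- 0L
  best_par <- NULL
  best_val <- Inf
  f <- function(par) {
    par <- project(par)
    v <- cost(par)
    nev <<- nev + 1L
    if (!is.finite(v)) v <- Inf
    if (v < best_val) {
      best_val <<- v
      best_par <<- par
    }
    v
  }
  x0 <- project(x0)
  v0 <- cost(x0)
  nev <- nev + 1L
  if (!is.finite(v0)) stop("cost is non-finite at the starting point")
  best_val <- v0
  best_par <- x0
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  total_iter <- 0L
  converged <- FALSE
  run_once <- function(start, start_val, step) {
    simplex <- matrix(rep(start, k + 1), nrow = k + 1, byrow = TRUE)
    vals <- numeric(k + 1)
    vals[1] <- start_val
    for (i in seq_len(k)) {
      simplex[i + 1, i] <- simplex[i + 1, i] + step[i]
      simplex[i + 1, ] <- project(simplex[i + 1, ])
      vals[i + 1] <- f(simplex[i + 1, ])
    }
    iter <- 0L
    conv <- FALSE
    while (iter < settings$max_iter) {
      iter <- iter + 1L
      ord <- order(vals)
      simplex <- simplex[ord, , drop = FALSE]
      vals <- vals[ord]
      spread <- 2 * abs(vals[k + 1] - vals[1]) /
        (abs(vals[k + 1]) + abs(vals[1]) + 1e-10)
      if (spread < settings$tol) {
        conv <- TRUE
        break
      }
      centroid <- colMeans(simplex[1:k, , drop = FALSE])
      xr <- project(centroid + alpha * (centroid - simplex[k + 1, ]))
      fr <- f(xr)
      if (fr < vals[1]) {
        xe <- project(centroid + gamma * (centroid - simplex[k + 1, ]))
        fe <- f(xe)
        if (fe < fr) {
          simplex[k + 1, ] <- xe; vals[k + 1] <- fe
        } else {
          simplex[k + 1, ] <- xr; vals[k + 1] <- fr
        }
      } else if (fr < vals[k]) {
        simplex[k + 1, ] <- xr; vals[k + 1] <- fr
      } else {
        xc <- project(centroid + rho * (simplex[k + 1, ] - centroid))
        fc <- f(xc)
        if (fc < vals[k + 1]) {
          simplex[k + 1, ] <- xc; vals[k + 1] <- fc
        } else {
          for (i in 2:(k + 1)) {
            simplex[i, ] <- project(simplex[1, ] +
                                      sigma * (simplex[i, ] - simplex[1, ]))
            vals[i] <- f(simplex[i, ])
          }
        }
      }
    }
    total_iter <<- total_iter + iter
    conv
  }
  restarts <- if (is.null(settings$restarts)) 0L else settings$restarts
  for (r in 0:restarts) {
    prev_best <- best_val
    converged <- run_once(best_par, prev_best, step)
    if (r < restarts && best_val >= prev_best - 1e-12) break  # no improvement
  }
  list(par = best_par, value = best_val, iterations = total_iter,
       evaluations = nev, converged = converged)
}
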