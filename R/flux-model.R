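#' Pool sizes of the three measurable MEP pathway intermediates
#'
#' Constructs and validates the pool-size triple used as fixed parameters of
#' the label-incorporation model: DXP (`A`), MEcDP (`B`) and the combined
#' IDP+DMADP pool (`C`), all in pmol per mg dry weight.
#'
#' @param A DXP pool size (pmol mg^-1 DW), > 0.
#' @param B MEcDP pool size (pmol mg^-1 DW), > 0.
#' @param C IDP+DMADP pool size (pmol mg^-1 DW), > 0.
#' @return An object of class `pool_sizes` (named list with `A`, `B`, `C`).
#' @seealso [label_fraction()], [fit_flux()]
#' @export
#' @examples
#' pool_sizes(41.65, 85.59, 38.09)
pool_sizes <- function(A, B, C) {
  for (nm in c("A", "B", "C")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("pool size '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(list(A = A, B = B, C = C), class = "pool_sizes")
}

#' @export
print.pool_sizes <- function(x, ...) {
  cat(sprintf("MEP pool sizes (pmol mg-1 DW): DXP A=%.4g, MEcDP B=%.4g, IDP+DMADP C=%.4g\n",
              x$A, x$B, x$C))
  invisible(x)
}

as_pool_sizes <- function(pools) {
  if (inherits(pools, "pool_sizes")) return(pools)
  if (is.numeric(pools) && length(pools) == 3L) {
    nm <- names(pools)
    if (is.null(nm)) nm <- c("A", "B", "C")
    return(pool_sizes(pools[[which(nm == "A")]],
                      pools[[which(nm == "B")]],
                      pools[[which(nm == "C")]]))
  }
  if (is.list(pools) && all(c("A", "B", "C") %in% names(pools))) {
    return(pool_sizes(pools$A, pools$B, pools$C))
  }
  stop("cannot interpret 'pools' as pool sizes", call. = FALSE)
}

#' Are the three pool sizes pairwise distinct?
#'
#' The closed-form solution of the labeling cascade has pairwise differences
#' of the pool sizes in its denominators. Two pools closer than `tol`
#' (relative to their magnitude) make the closed form numerically unusable;
#' evaluation then falls back to direct ODE integration.
#'
#' @param pools A [pool_sizes()] object.
#' @param tol Relative tolerance for declaring two pools equal (default 1e-6).
#' @return `TRUE` if all three pairwise differences exceed the tolerance.
#' @export
pools_distinct <- function(pools, tol = 1e-6) {
  pools <- as_pool_sizes(pools)
  p <- c(pools$A, pools$B, pools$C)
  pr <- c(abs(p[1] - p[2]), abs(p[1] - p[3]), abs(p[2] - p[3]))
  scale <- max(p)
  all(pr > tol * scale)
}

#' Fractional labeling time course container
#'
#' Holds a single leaf run's fractional 13C labeling of isoprene, f(t),
#' with t in minutes since the switch to the 13CO2 atmosphere. Values are
#' clipped into [0, 1] on ingestion; excursions beyond a small measurement
#' tolerance are rejected as corrupt input.
#'
#' @param times Minutes since the atmosphere switch; non-negative, strictly
#'   increasing.
#' @param f Fractional labeling values; must lie in [-eps, 1+eps].
#' @param eps Measurement tolerance for out-of-range values (default 0.05).
#' @return A `label_curve` object (data.frame with `time_min`, `f_label`).
#' @export
label_curve <- function(times, f, eps = 0.05) {
  if (length(times) != length(f)) {
    stop("'times' and 'f' must have equal length", call. = FALSE)
  }
  if (!all(is.finite(times)) || !all(is.finite(f))) {
    stop("non-finite values in labeling curve", call. = FALSE)
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("'times' must be non-negative and strictly increasing", call. = FALSE)
  }
  if (any(f < -eps) || any(f > 1 + eps)) {
    stop("fractional labeling outside [-eps, 1+eps]; corrupt input", call. = FALSE)
  }
  structure(data.frame(time_min = as.numeric(times),
                       f_label = pmin(pmax(as.numeric(f), 0), 1)),
            class = c("label_curve", "data.frame"))
}

#' Closed-form fractional labeling of the IDP+DMADP pool
#'
#' Evaluates the analytical solution of the three-pool first-order labeling
#' cascade DXP -> MEcDP -> IDP+DMADP under a step change to a fully labeled
#' carbon source at t = 0:
#' \deqn{f(t) = m\left[1 - \frac{A^2 e^{-Jt/A}}{(A-B)(A-C)}
#'   - \frac{B^2 e^{-Jt/B}}{(B-A)(B-C)}
#'   - \frac{C^2 e^{-Jt/C}}{(C-A)(C-B)}\right]}
#' where A, B, C are the pool sizes (pmol mg^-1 DW), J the pathway flux
#' (pmol min^-1 mg^-1 DW) and m the maximal fractional labeling reached at
#' the end of the run. The three coefficients sum to one, so f(0) = 0, and
#' f(t) rises monotonically to the plateau m.
#'
#' When any two pool sizes coincide within `tol` (relative), the closed form
#' is singular and the function transparently evaluates the same cascade by
#' numerical ODE integration instead ([cascade_ode_oracle()]).
#'
#' @param t Time(s) in minutes since the label switch, >= 0 (vectorized).
#' @param pools A [pool_sizes()] object (or coercible).
#' @param J Pathway flux, pmol min^-1 mg^-1 DW, > 0.
#' @param m Maximal fractional labeling (plateau), in (0, 1].
#' @param tol Relative tolerance for the pool-distinctness test.
#' @return Numeric vector of fractional labeling values in [0, m].
#' @export
#' @examples
#' p <- pool_sizes(41.65, 85.59, 38.09)
#' label_fraction(c(0, 5, 20), p, J = 28.65, m = 0.912)
label_fraction <- function(t, pools, J, m, tol = 1e-6) {
  pools <- as_pool_sizes(pools)
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J) || J <= 0) {
    stop("'J' must be a single positive flux", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m <= 0 || m > 1) {
    stop("'m' must lie in (0, 1]", call. = FALSE)
  }
  if (!pools_distinct(pools, tol)) {
    # degenerate denominators: evaluate the cascade numerically instead
    return(.label_fraction_ode(t, pools, J, m))
  }
  A <- pools$A; B <- pools$B; C <- pools$C
  cA <- A^2 / ((A - B) * (A - C))
  cB <- B^2 / ((B - A) * (B - C))
  cC <- C^2 / ((C - A) * (C - B))
  f <- m * (1 - cA * exp(-J * t / A) - cB * exp(-J * t / B) - cC * exp(-J * t / C))
  # the exact solution lies in [0, m]; clip roundoff-level excursions
  pmin(pmax(f, 0), m)
}

.label_fraction_ode <- function(t, pools, J, m) {
  o <- order(t)
  grid <- t[o]
  curve <- cascade_ode_oracle(unique(c(0, grid)), pools, J, m)
  f <- curve$f_label[match(grid, curve$time_min)]
  out <- numeric(length(t))
  out[o] <- f
  out
}

#' Numerical oracle for the labeling cascade
#'
#' Integrates the label-incorporation cascade
#' \deqn{\dot a = (J/A)(m - a),\quad \dot b = (J/B)(a - b),\quad
#'   \dot c = (J/C)(b - c)}
#' from a = b = c = 0 and returns c(t), the fractional labeling of the
#' IDP+DMADP pool, on the requested grid. This route needs no pool
#' distinctness and serves as the independent check of the closed form (and
#' as its fallback for degenerate pool configurations).
#'
#' @param times Ascending minute grid, `times[1] >= 0`.
#' @param pools A [pool_sizes()] object (distinctness not required).
#' @param J Pathway flux, > 0.
#' @param m Plateau fractional labeling, in (0, 1].
#' @param rtol,atol Integrator tolerances passed to [deSolve::ode()].
#' @return A [label_curve()] on `times`.
#' @export
cascade_ode_oracle <- function(times, pools, J, m, rtol = 1e-10, atol = 1e-12) {
  pools <- as_pool_sizes(pools)
  stopifnot(is.numeric(times), all(is.finite(times)), times[1] >= 0,
            all(diff(times) > 0))
  if (J <= 0) stop("'J' must be positive", call. = FALSE)
  if (m <= 0 || m > 1) stop("'m' must lie in (0, 1]", call. = FALSE)
  grid <- times
  prepend <- grid[1] > 0
  if (prepend) grid <- c(0, grid)
  rhs <- function(t, y, p) {
    list(c(
      (p$J / p$A) * (p$m - y[1]),
      (p$J / p$B) * (y[1] - y[2]),
      (p$J / p$C) * (y[2] - y[3])
    ))
  }
  sol <- deSolve::ode(y = c(a = 0, b = 0, c = 0), times = grid, func = rhs,
                      parms = list(A = pools$A, B = pools$B, C = pools$C,
                                   J = J, m = m),
                      rtol = rtol, atol = atol)
  d <- diagnostics.deSolve.quiet(sol)
  if (!is.null(d) && d != 2L) {
    stop("cascade ODE integration failed to meet tolerance (istate = ", d, ")",
         call. = FALSE)
  }
  f <- sol[, "c"]
  if (prepend) f <- f[-1]
  label_curve(times, pmin(pmax(f, 0), 1), eps = 1e-6)
}

# lsoda's success istate is 2; pull it without printing diagnostics
diagnostics.deSolve.quiet <- function(sol) {
  st <- attr(sol, "istate")
  if (is.null(st)) NULL else st[1]
}

#' Fit pathway flux and labeling plateau to an observed labeling curve
#'
#' Least-squares estimation of the pathway flux J and the maximal labeling m
#' by Levenberg-Marquardt minimization of the residuals between
#' [label_fraction()] and the observed curve, with the three pool sizes held
#' fixed at their measured values. Only m and J are free; bounds are
#' J in (0, Inf) and m in (0, 1].
#'
#' Default initial guesses: `m` starts at the maximum observed labeling and
#' `J` at C divided by the time at which f first exceeds half its final
#' value (the IDP+DMADP turnover heuristic).
#'
#' @param curve A [label_curve()] (or data.frame with `time_min`, `f_label`).
#' @param pools Measured [pool_sizes()], entered as fixed parameters.
#' @param init_J,init_m Optional initial guesses.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A `flux_fit` object: list with `J`, `m`, `se_J`, `se_m`, `rss`,
#'   `n_points`, `converged`, `message`.
#' @export
#' @examples
#' p <- pool_sizes(41.65, 85.59, 38.09)
#' tt <- seq(0, 50, by = 0.5)
#' cv <- label_curve(tt, label_fraction(tt, p, J = 28.65, m = 0.912))
#' fit_flux(cv, p)
fit_flux <- function(curve, pools, init_J = NULL, init_m = NULL,
                     max_iter = 200L) {
  pools <- as_pool_sizes(pools)
  if (!inherits(curve, "label_curve")) {
    if (!is.data.frame(curve) || !all(c("time_min", "f_label") %in% names(curve))) {
      stop("'curve' must be a label_curve or data.frame with time_min, f_label",
           call. = FALSE)
    }
    curve <- label_curve(curve$time_min, curve$f_label)
  }
  tt <- curve$time_min
  ff <- curve$f_label
  n <- length(tt)
  fail <- function(msg) {
    structure(list(J = NA_real_, m = NA_real_, se_J = NA_real_,
                   se_m = NA_real_, rss = NA_real_, n_points = n,
                   converged = FALSE, message = msg),
              class = "flux_fit")
  }
  if (n < 3L) stop("need at least 3 observations to fit 2 parameters",
                   call. = FALSE)
  fmax <- max(ff)
  if (fmax <= 0) return(fail("all-zero labeling curve; flux not identifiable"))
  if (!any(ff < 0.9 * fmax)) {
    return(fail("curve is all plateau; transient not sampled, J not identifiable"))
  }
  if (is.null(init_m)) init_m <- min(max(fmax, 1e-3), 1)
  if (is.null(init_J)) {
    t_half <- tt[which(ff >= fmax / 2)[1]]
    init_J <- if (is.na(t_half) || t_half <= 0) pools$C else pools$C / t_half
  }
  resid_fn <- function(par) {
    J <- min(max(par[1], 1e-9), 1e12)
    m <- min(max(par[2], 1e-9), 1)
    label_fraction(tt, pools, J = J, m = m) - ff
  }
  # the model is linear in m; profile it out and scan J on a log grid to
  # locate the least-squares basin before the Levenberg-Marquardt polish
  # (the shape function saturates for large J, where LM alone can stall)
  scan <- .varpro_scan(tt, ff, pools)
  starts <- unique(list(c(J = init_J, m = init_m),
                        c(J = scan$J, m = scan$m)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(1e-9, 1e-9), upper = c(Inf, 1),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) return(fail("optimizer error"))
  fit <- best
  converged <- fit$info %in% 1:4 && all(is.finite(fit$par))
  J_hat <- min(max(unname(fit$par[1]), 1e-9), 1e12)
  m_hat <- min(max(unname(fit$par[2]), 1e-9), 1)
  rss <- sum(resid_fn(c(J_hat, m_hat))^2)
  se <- .fit_se(tt, ff, pools, J_hat, m_hat, rss, n)
  structure(list(J = J_hat, m = m_hat, se_J = se[1], se_m = se[2], rss = rss,
                 n_points = n, converged = converged,
                 message = fit$message),
            class = "flux_fit")
}

# separable least squares: for fixed J the optimal plateau is the linear
# projection m(J) = <g, f> / <g, g> with g(t) = f(t; J, m = 1); scanning a
# wide log grid of J gives a near-global start for the nonlinear polish
.varpro_scan <- function(tt, ff, pools, n_grid = 120L) {
  J_grid <- exp(seq(log(1e-3), log(1e6), length.out = n_grid))
  best <- list(rss = Inf, J = J_grid[1], m = max(ff))
  for (J in J_grid) {
    g <- label_fraction(tt, pools, J, 1)
    gg <- sum(g * g)
    if (gg <= 0) next
    m <- min(max(sum(g * ff) / gg, 1e-9), 1)
    rss <- sum((m * g - ff)^2)
    if (rss < best$rss) best <- list(rss = rss, J = J, m = m)
  }
  best
}

# standard errors from a forward-difference Jacobian at the optimum
.fit_se <- function(tt, ff, pools, J, m, rss, n) {
  h <- pmax(abs(c(J, m)), 1e-6) * 1e-6
  f0 <- label_fraction(tt, pools, J, m)
  m2 <- if (m + h[2] <= 1) m + h[2] else m - h[2]  # stay inside (0, 1]
  Jc <- cbind(
    (label_fraction(tt, pools, J + h[1], m) - f0) / h[1],
    (label_fraction(tt, pools, J, m2) - f0) / (m2 - m)
  )
  sigma2 <- rss / max(n - 2L, 1L)
  V <- tryCatch(solve(crossprod(Jc)) * sigma2, error = function(e) NULL)
  # singular Jacobian (e.g. all time constants below the grid spacing):
  # the parameter is unidentified, report infinite rather than small se
  if (is.null(V)) return(c(Inf, Inf))
  sqrt(pmax(diag(V), 0))
}

#' @export
print.flux_fit <- function(x, ...) {
  if (!x$converged) {
    cat("flux fit: NOT converged (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("flux fit: J = %.4g +/- %.2g pmol min-1 mg-1 DW, m = %.4g +/- %.2g (rss %.3g, n %d)\n",
              x$J, x$se_J, x$m, x$se_m, x$rss, x$n_points))
  invisible(x)
}

#' Read a fractional labeling curve from CSV
#'
#' Expects columns `time_min` and `f_label`.
#'
#' @param path CSV file path.
#' @return A [label_curve()].
#' @export
read_label_curve <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "f_label") %in% names(d))) {
    stop("'", path, "' must have columns time_min,f_label", call. = FALSE)
  }
  label_curve(d$time_min, d$f_label)
}

#' Write one or more flux fits as a TSV table
#'
#' @param fits Named list of `flux_fit` objects (names are sample ids), or a
#'   single fit with `sample_id` supplied.
#' @param path Output TSV path.
#' @param sample_id Sample id when `fits` is a single fit.
#' @return The table, invisibly.
#' @export
write_flux_fits <- function(fits, path, sample_id = "sample") {
  if (inherits(fits, "flux_fit")) fits <- stats::setNames(list(fits), sample_id)
  tab <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(sample_id = id, J = f$J, se_J = f$se_J, m = f$m, se_m = f$se_m,
               rss = f$rss, n_points = f$n_points, converged = f$converged)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
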