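# Explicit finite-difference solution of the Pennes bioheat equation
#
#   rho*cp dT/dt = div(k grad T) + wb*rho_b*cp_b*(Ta - T) + qm
#
# on a heterogeneous 2D grid. Interface conductivities between neighbouring
# pixels use the harmonic mean (flux continuity across piecewise-homogeneous
# media); updates are synchronous (Jacobi); background pixels and the outer
# grid border are Dirichlet nodes held at the boundary temperature.

#' Solver configuration
#'
#' @param dt time step, s.
#' @param dx spatial step, m; `NULL` derives it from the label map's pixel
#'   spacing (mm / 1000) at solve time.
#' @param t_init initial temperature, degC.
#' @param t_boundary Dirichlet boundary temperature, degC.
#' @param tol convergence tolerance: the solver stops once the maximum
#'   absolute node-wise change between successive sweeps falls below `tol`
#'   (degC).
#' @param max_iters iteration cap.
#' @param log_every if > 0, print a progress line every this many sweeps.
#' @return A `SolverConfig` list.
#' @export
solverConfig <- function(dt = 0.1, dx = NULL, t_init = 37, t_boundary = 37,
                         tol = 1e-7, max_iters = 2e6, log_every = 0) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (!is.null(dx) && (!is.finite(dx) || dx <= 0)) stop("dx must be positive")
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  if (max_iters < 1) stop("max_iters must be at least 1")
  structure(list(dt = dt, dx = dx, t_init = t_init, t_boundary = t_boundary,
                 tol = tol, max_iters = as.integer(max_iters),
                 log_every = as.integer(log_every)),
            class = "SolverConfig")
}

#' Harmonic-mean interface conductivity
#'
#' The thermal conductivity at the midpoint between two pixels of
#' piecewise-homogeneous media: `2 * k_a * k_b / (k_a + k_b)`. This is the
#' series (flux-continuous) combination; it returns 0 when either side is a
#' perfect insulator.
#'
#' @param k_a,k_b conductivities, W/(m.degC); vectorized, must be >= 0.
#' @return Interface conductivity, same shape as the inputs.
#' @export
#' @examples
#' midpointConductivity(0.503, 0.6)
midpointConductivity <- function(k_a, k_b) {
  if (any(k_a < 0) || any(k_b < 0))
    stop("conductivities must be non-negative")
  s <- k_a + k_b
  out <- k_a * k_b           # zero whenever either side is zero
  nz <- s > 0
  out[nz] <- 2 * out[nz] / s[nz]
  out
}

# neighbour-shifted copies of a matrix (edge-replicated); only interior
# values are consumed because border pixels are Dirichlet nodes
shiftN <- function(m) m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
shiftS <- function(m) m[c(seq_len(nrow(m) - 1) + 1, nrow(m)), , drop = FALSE]
shiftW <- function(m) m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
shiftE <- function(m) m[, c(seq_len(ncol(m) - 1) + 1, ncol(m)), drop = FALSE]

# default Dirichlet mask: outer border plus background pixels
fixedMask <- function(grids) {
  fixed <- grids$background
  if (is.null(fixed)) fixed <- matrix(FALSE, nrow(grids$k), ncol(grids$k))
  fixed[1, ] <- TRUE; fixed[nrow(fixed), ] <- TRUE
  fixed[, 1] <- TRUE; fixed[, ncol(fixed)] <- TRUE
  fixed
}

#' One synchronous finite-difference sweep
#'
#' Applies one explicit (Jacobi) update of the discretized bioheat equation
#' to every non-Dirichlet pixel:
#' `T' = T + dt/(rho*cp*dx^2) * sum_faces k_face * (T_nb - T)
#'        + dt/(rho*cp) * (wb*rho_b*cp_b*(t_a - T) + qm)`
#' with harmonic-mean face conductivities. Dirichlet pixels (grid border and
#' background) are held at `cfg$t_boundary`.
#'
#' @param temps numeric temperature matrix, degC.
#' @param grids property grids from [propertyGrids()].
#' @param blood a [bloodProperties()] object.
#' @param cfg a [solverConfig()]; `cfg$dx` must be set.
#' @param fixed optional logical matrix of Dirichlet pixels; defaults to the
#'   grid border plus background.
#' @return Updated temperature matrix.
#' @export
fdmStep <- function(temps, grids, blood, cfg = solverConfig(dx = 0.002),
                    fixed = NULL) {
  if (!all(vapply(grids[c("k", "rho", "cp", "qm", "wb")],
                  function(g) identical(dim(g), dim(temps)), logical(1))))
    stop("property grids and temperature grid must share one shape")
  if (any(!is.finite(temps))) stop("temperature grid contains non-finite values")
  if (is.null(cfg$dx)) stop("cfg$dx must be set for fdmStep")
  if (is.null(fixed)) fixed <- fixedMask(grids)
  k <- grids$k
  kE <- midpointConductivity(k, shiftE(k))
  kW <- midpointConductivity(k, shiftW(k))
  kS <- midpointConductivity(k, shiftS(k))
  kN <- midpointConductivity(k, shiftN(k))
  diffusion <- kE * (shiftE(temps) - temps) + kW * (shiftW(temps) - temps) +
    kS * (shiftS(temps) - temps) + kN * (shiftN(temps) - temps)
  rhocp <- grids$rho * grids$cp
  perfusion <- grids$wb * blood$rho_b * blood$cp_b * (blood$t_a - temps) +
    grids$qm
  new <- temps + cfg$dt / (rhocp * cfg$dx^2) * diffusion +
    cfg$dt / rhocp * perfusion
  new[fixed] <- cfg$t_boundary
  new
}

#' Explicit-scheme stability check
#'
#' Computes the most restrictive explicit-Euler time-step bound over all
#' updated pixels, `dt_max = min rho*cp / (4*k_max/dx^2 + wb*rho_b*cp_b)`
#' where `k_max` is the largest of the pixel's four harmonic-mean face
#' conductivities, and compares it with the configured `dt`.
#'
#' @inheritParams fdmStep
#' @return List with `pass` (logical) and `dt_max` (s, the limiting step).
#' @export
stabilityCheck <- function(grids, blood, cfg, fixed = NULL) {
  if (is.null(cfg$dx)) stop("cfg$dx must be set for stabilityCheck")
  if (is.null(fixed)) fixed <- fixedMask(grids)
  k <- grids$k
  kmax <- pmax(midpointConductivity(k, shiftE(k)),
               midpointConductivity(k, shiftW(k)),
               midpointConductivity(k, shiftS(k)),
               midpointConductivity(k, shiftN(k)))
  denom <- 4 * kmax / cfg$dx^2 + grids$wb * blood$rho_b * blood$cp_b
  active <- !fixed & denom > 0
  dt_max <- if (any(active))
    min((grids$rho * grids$cp)[active] / denom[active]) else Inf
  list(pass = cfg$dt <= dt_max, dt_max = dt_max)
}

#' Solve the bioheat equation to steady state
#'
#' Iterates synchronous finite-difference sweeps from a uniform initial
#' temperature until the maximum absolute node-wise change between two
#' successive sweeps falls below `cfg$tol`, or `cfg$max_iters` is reached
#' (in which case a warning is raised and `converged(field)` is `FALSE`).
#' The iteration loop runs in compiled code; [fdmStep()] is the reference
#' one-sweep implementation.
#'
#' @param map a [TissueLabelMap-class].
#' @param props named tissue property list, default [tissuePropertyTable()].
#' @param blood a [bloodProperties()] object.
#' @param cfg a [solverConfig()]; a `NULL` `dx` is derived from the map's
#'   pixel spacing.
#' @return A [TemperatureField-class].
#' @export
#' @examples
#' ph <- embedLesion(generateBrainPhantom(48, 48, seed = 1))
#' fld <- solveBioheat(ph, cfg = solverConfig(tol = 1e-4))
#' converged(fld)
solveBioheat <- function(map, props = tissuePropertyTable(),
                         blood = bloodProperties(), cfg = solverConfig()) {
  stopifnot(is(map, "TissueLabelMap"))
  if (is.null(cfg$dx)) cfg$dx <- spacing(map) / 1000
  grids <- propertyGrids(map, props)
  fixed <- fixedMask(grids)
  st <- stabilityCheck(grids, blood, cfg, fixed)
  if (!st$pass)
    stop(sprintf("explicit scheme unstable: dt=%g s exceeds dt_max=%g s",
                 cfg$dt, st$dt_max))
  t0 <- matrix(cfg$t_init, nrow(grids$k), ncol(grids$k))
  t0[fixed] <- cfg$t_boundary
  res <- solve_bioheat_cpp(t0, grids$k, grids$rho * grids$cp, grids$qm,
                           grids$wb * blood$rho_b * blood$cp_b,
                           fixed, cfg$dt, cfg$dx, cfg$t_boundary,
                           blood$t_a, cfg$tol, cfg$max_iters,
                           cfg$log_every)
  if (!res$converged)
    warning(sprintf("solver did not converge in %d iterations (delta %.3g)",
                    res$iterations, res$delta))
  new("TemperatureField", temps = res$temps, spacing = spacing(map),
      iterations = as.integer(res$iterations),
      converged = res$converged, finalDelta = res$delta, tol = cfg$tol)
}

#' Temperature profile along one grid row
#'
#' @param field a [TemperatureField-class].
#' @param row 1-based row index.
#' @return data.frame with `position` (mm, from the first column) and
#'   `temperature` (degC), one row per grid column.
#' @export
lineProfile <- function(field, row) {
  stopifnot(is(field, "TemperatureField"))
  temps <- tempMatrix(field)
  if (row < 1 || row > nrow(temps)) stop("row out of range")
  data.frame(position = (seq_len(ncol(temps)) - 1) * spacing(field),
             temperature = temps[row, ])
}

#' Dense steady-state solution of the discretized bioheat equations
#'
#' Builds and solves the sparse-free linear system obtained by setting the
#' explicit update to zero at every non-Dirichlet pixel:
#' `sum_faces k_face*(T_nb - T)/dx^2 + wb*rho_b*cp_b*(Ta - T) + qm = 0`.
#' Intended as an exact cross-check of the iterative solver on small grids.
#'
#' @inheritParams fdmStep
#' @return Temperature matrix of the steady state.
#' @export
denseSteadyState <- function(grids, blood, cfg, fixed = NULL) {
  if (is.null(cfg$dx)) stop("cfg$dx must be set")
  if (is.null(fixed)) fixed <- fixedMask(grids)
  nr <- nrow(grids$k); nc <- ncol(grids$k)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  n <- nr * nc
  A <- matrix(0, n, n)
  b <- numeric(n)
  k <- grids$k
  dx2 <- cfg$dx^2
  for (jj in seq_len(nc)) for (ii in seq_len(nr)) {
    p <- idx[ii, jj]
    if (fixed[ii, jj]) {
      A[p, p] <- 1
      b[p] <- cfg$t_boundary
      next
    }
    perf <- grids$wb[ii, jj] * blood$rho_b * blood$cp_b
    A[p, p] <- -perf
    b[p] <- -grids$qm[ii, jj] - perf * blood$t_a
    for (nb in list(c(ii - 1, jj), c(ii + 1, jj),
                    c(ii, jj - 1), c(ii, jj + 1))) {
      kf <- midpointConductivity(k[ii, jj], k[nb[1], nb[2]]) / dx2
      A[p, p] <- A[p, p] - kf
      A[p, idx[nb[1], nb[2]]] <- A[p, idx[nb[1], nb[2]]] + kf
    }
  }
  matrix(solve(A, b), nr, nc)
}
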