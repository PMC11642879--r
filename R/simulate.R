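#' Parameters of the two-gene toggle-switch model
#'
#' Mutual-inhibition / self-activation Hill kinetics driving a bifurcation:
#' \deqn{\dot x = a_1 x^n/(S_1^n + x^n) + b_1 K_1^n/(K_1^n + y^n) - \gamma_1 x}
#' and symmetrically for \eqn{\dot y}. The timescale is unity. The default
#' rate constants are repository choices (the model family fixes only the
#' structure): they place the symmetric progenitor state near (36, 36) and
#' the two committed attractors near (58, 1), so that trajectories span
#' tens of expression units and remain inside a sphere of radius 70 when
#' lifted to 3-D.
#'
#' @param a1,a2 maximal self-activation rates.
#' @param b1,b2 maximal basal/inhibition-controlled rates.
#' @param S1,S2 Hill thresholds of the activation terms.
#' @param K1,K2 Hill thresholds of the inhibition terms.
#' @param n Hill exponent (`>= 1`).
#' @param gamma1,gamma2 first-order decay rates.
#' @param sigma Euler-Maruyama noise amplitude.
#' @param x0 initial state (both genes low).
#' @param t_max simulated duration per cell.
#' @param dt integrator step.
#' @return List of class `toggle_switch_params`.
#' @export
toggle_switch_params <- function(a1 = 40, a2 = 40, b1 = 20, b2 = 20,
                                 S1 = 25, S2 = 25, K1 = 25, K2 = 25,
                                 n = 4, gamma1 = 1, gamma2 = 1,
                                 sigma = 2, x0 = c(1, 1),
                                 t_max = 15, dt = 0.01) {
  rates <- c(a1, a2, b1, b2, S1, S2, K1, K2, gamma1, gamma2)
  .gv_check(all(rates > 0), "all rates must be positive")
  .gv_check(n >= 1, "Hill exponent must be >= 1")
  .gv_check(sigma >= 0 && t_max > 0 && dt > 0, "invalid simulation controls")
  structure(list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, S1 = S1, S2 = S2,
                 K1 = K1, K2 = K2, n = n, gamma1 = gamma1, gamma2 = gamma2,
                 sigma = sigma, x0 = x0, t_max = t_max, dt = dt),
            class = "toggle_switch_params")
}

## deterministic drift of the toggle switch at states (x, y); vectorised
.toggle_drift <- function(x, y, p) {
  hx <- x^p$n; hy <- y^p$n
  dx <- p$a1 * hx / (p$S1^p$n + hx) + p$b1 * p$K1^p$n / (p$K1^p$n + hy) -
    p$gamma1 * x
  dy <- p$a2 * hy / (p$S2^p$n + hy) + p$b2 * p$K2^p$n / (p$K2^p$n + hx) -
    p$gamma2 * y
  cbind(dx, dy)
}

#' Simulate the toggle-switch bifurcation
#'
#' Each cell is an independent stochastic trajectory (Euler-Maruyama on the
#' Hill drift, reflected at zero) of duration drawn uniformly in
#' `[0, t_max]`, so the sampled population covers the progenitor state, the
#' decision region and both committed branches. The ground-truth velocity of
#' every sampled state is the deterministic drift evaluated there.
#'
#' @param p a [toggle_switch_params()].
#' @param n_cells number of cells (default 2000, the benchmark size).
#' @param seed RNG seed (reproducibility contract: same seed, same states).
#' @return A `simulation_result`: list with `states` (cells x 2),
#'   `velocities` (ground-truth drift), `velocities_true` (copy kept under
#'   noise injection), `times`, `labels` (committed branch or progenitor).
#' @export
simulate_toggle_switch <- function(p = toggle_switch_params(),
                                   n_cells = 2000L, seed = 0L) {
  .gv_check(inherits(p, "toggle_switch_params"), "p must be toggle_switch_params")
  .gv_check(n_cells >= 1L, "n_cells must be positive")
  set.seed(seed)
  n <- as.integer(n_cells)
  t_end <- runif(n, 0, p$t_max)
  x <- rep(p$x0[1], n); y <- rep(p$x0[2], n)
  n_steps <- ceiling(p$t_max / p$dt)
  sq <- sqrt(p$dt)
  for (s in seq_len(n_steps)) {
    t_now <- (s - 1) * p$dt
    act <- t_now < t_end            # cells still evolving
    if (!any(act)) break
    dr <- .toggle_drift(x[act], y[act], p)
    x[act] <- pmax(x[act] + dr[, 1] * p$dt + p$sigma * sq * rnorm(sum(act)), 0)
    y[act] <- pmax(y[act] + dr[, 2] * p$dt + p$sigma * sq * rnorm(sum(act)), 0)
  }
  states <- cbind(x = x, y = y)
  vel <- .toggle_drift(x, y, p)
  colnames(vel) <- c("x", "y")
  labels <- ifelse(pmax(x, y) < 2 * pmin(x, y), "progenitor",
                   ifelse(x > y, "branch_x", "branch_y"))
  structure(list(states = states, velocities = vel, velocities_true = vel,
                 times = t_end, labels = labels, normals = NULL),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result: ", nrow(x$states), " cells x ", ncol(x$states),
      " state dimensions\n", sep = "")
  invisible(x)
}

#' Sphere-embedding configuration
#'
#' @param r sphere radius (default 70, the benchmark geometry).
#' @param dt propagation step used for the finite-difference vertical
#'   velocity (default 1).
#' @return List of class `sphere_embed_config`.
#' @export
sphere_embed_config <- function(r = 70, dt = 1) {
  .gv_check(r > 0 && dt > 0, "r and dt must be positive")
  structure(list(r = r, dt = dt), class = "sphere_embed_config")
}

#' Lift a planar simulation onto a sphere
#'
#' Adds the vertical coordinate \eqn{z = \sqrt{\max(r^2 - x^2 - y^2, 0)}}
#' and the matching vertical velocity by finite propagation:
#' \eqn{\dot z = (z(x + \dot x \Delta t, y + \dot y \Delta t) - z)/\Delta t}.
#' As \eqn{\Delta t \to 0} this converges to the analytic tangent component
#' \eqn{-(x\dot x + y\dot y)/z}, so the lifted velocity field is tangent to
#' the sphere; at the benchmark step \eqn{\Delta t = 1} the residual normal
#' component is O(\eqn{\Delta t}). Unit radial normals are attached for
#' orthogonal noise injection.
#'
#' @param res a 2-D `simulation_result`.
#' @param cfg a [sphere_embed_config()].
#' @return A 3-D `simulation_result` with elements `states`, `velocities`
#'   (= `velocities_true`), `normals`.
#' @export
embed_on_sphere <- function(res, cfg = sphere_embed_config()) {
  .gv_check(inherits(res, "simulation_result"), "res must be a simulation_result")
  .gv_check(ncol(res$states) == 2L, "sphere embedding expects 2-D input")
  r <- cfg$r; dt <- cfg$dt
  x <- res$states[, 1]; y <- res$states[, 2]
  vx <- res$velocities[, 1]; vy <- res$velocities[, 2]
  zf <- function(x, y) sqrt(pmax(r^2 - x^2 - y^2, 0))
  z <- zf(x, y)
  vz <- (zf(x + vx * dt, y + vy * dt) - z) / dt
  states <- cbind(x = x, y = y, z = z)
  vel <- cbind(x = vx, y = vy, z = vz)
  normals <- states / pmax(.row_norms(states), .Machine$double.eps)
  structure(list(states = states, velocities = vel, velocities_true = vel,
                 times = res$times, labels = res$labels, normals = normals),
            class = "simulation_result")
}

#' Inject noise into simulated velocities
#'
#' Either isotropic Gaussian noise on every coordinate, or noise along the
#' manifold normal only (for the sphere, the radial direction) — the
#' component a tangent-space projection should remove entirely. Ground-truth
#' velocities are retained in `velocities_true`.
#'
#' @param res a `simulation_result`.
#' @param mode `"orthogonal"` (requires `res$normals`) or `"gaussian"`.
#' @param level noise standard deviation (same units as the velocities).
#' @param seed RNG seed.
#' @return The `simulation_result` with noisy `velocities`.
#' @export
add_noise <- function(res, mode = c("orthogonal", "gaussian"), level,
                      seed = 0L) {
  mode <- match.arg(mode)
  .gv_check(inherits(res, "simulation_result"), "res must be a simulation_result")
  .gv_check(level >= 0, "level must be non-negative")
  set.seed(seed)
  n <- nrow(res$states)
  v <- res$velocities_true
  if (mode == "gaussian") {
    v <- v + matrix(rnorm(length(v), 0, level), n, ncol(v))
  } else {
    if (is.null(res$normals))
      stop("orthogonal noise requires a manifold normal field", call. = FALSE)
    eps <- rnorm(n, 0, level)
    v <- v + res$normals * eps
  }
  res$velocities <- v
  res
}

#' Parameters of the miRNA-driven variable-degradation model
#'
#' A minimal regulatory motif in which an external signal drives a microRNA
#' that both represses transcription and accelerates degradation of the
#' target mRNA:
#' \deqn{dm/dt = \alpha_m - \gamma_m m, \quad
#'       du/dt = (\alpha_0 - k_\alpha m) - \beta u, \quad
#'       ds/dt = \beta u - (\gamma_0 + k_\gamma m)\, s,}
#' started at the unperturbed steady state \eqn{u_0 = \alpha_0/\beta},
#' \eqn{s_0 = \alpha_0/\gamma_0}, \eqn{m_0 = 0}. Along the trajectory the
#' effective degradation rate \eqn{\gamma(t) = \gamma_0 + k_\gamma m(t)}
#' rises monotonically, producing the rapid-degradation failure mode of
#' constant-rate velocity estimators. Defaults are the repository's standard
#' fixture.
#'
#' @param alpha0 baseline transcription rate.
#' @param beta splicing rate (the unit-rate convention downstream).
#' @param gamma0 baseline degradation rate.
#' @param k_alpha,k_gamma miRNA coupling strengths (transcription repression
#'   and degradation enhancement); must keep
#'   \eqn{k_\alpha m < \alpha_0} over the simulated range.
#' @param alpha_m,gamma_m miRNA synthesis and decay rates.
#' @param t_max simulated duration.
#' @param n_steps number of output time points.
#' @return List of class `degradation_params`.
#' @export
degradation_params <- function(alpha0 = 10, beta = 1, gamma0 = 1,
                               k_alpha = 2, k_gamma = 3,
                               alpha_m = 1, gamma_m = 0.5,
                               t_max = 10, n_steps = 400L) {
  .gv_check(all(c(alpha0, beta, gamma0, alpha_m, gamma_m, t_max) > 0),
            "rates and duration must be positive")
  .gv_check(k_alpha >= 0 && k_gamma >= 0, "couplings must be non-negative")
  m_inf <- alpha_m / gamma_m
  .gv_check(k_alpha * m_inf < alpha0,
            "k_alpha * m_infinity must stay below alpha0 ",
            "(transcription would go negative)")
  structure(list(alpha0 = alpha0, beta = beta, gamma0 = gamma0,
                 k_alpha = k_alpha, k_gamma = k_gamma,
                 alpha_m = alpha_m, gamma_m = gamma_m,
                 t_max = t_max, n_steps = as.integer(n_steps)),
            class = "degradation_params")
}

#' Simulate splicing kinetics with miRNA-driven degradation
#'
#' Deterministic integration (adaptive solver, `rtol = 1e-8`) of the
#' variable-degradation model in [degradation_params()], returning states
#' and exact derivatives at every output time.
#'
#' @param p a [degradation_params()].
#' @return List of class `kinetics_trajectory` with `times`, `m`, `u`, `s`,
#'   the true derivatives `du`, `ds`, `dm`, and the effective rates
#'   `alpha_t` (\eqn{\alpha_0 - k_\alpha m}) and `gamma_t`
#'   (\eqn{\gamma_0 + k_\gamma m}).
#' @export
simulate_variable_degradation <- function(p = degradation_params()) {
  .gv_check(inherits(p, "degradation_params"), "p must be degradation_params")
  deriv <- function(t, y, parms) {
    m <- y[1]; u <- y[2]; s <- y[3]
    dm <- p$alpha_m - p$gamma_m * m
    du <- (p$alpha0 - p$k_alpha * m) - p$beta * u
    ds <- p$beta * u - (p$gamma0 + p$k_gamma * m) * s
    list(c(dm, du, ds))
  }
  y0 <- c(m = 0, u = p$alpha0 / p$beta, s = p$alpha0 / p$gamma0)
  times <- seq(0, p$t_max, length.out = p$n_steps)
  sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  m <- sol[, "m"]; u <- sol[, "u"]; s <- sol[, "s"]
  structure(list(times = times, m = m, u = u, s = s,
                 dm = p$alpha_m - p$gamma_m * m,
                 du = (p$alpha0 - p$k_alpha * m) - p$beta * u,
                 ds = p$beta * u - (p$gamma0 + p$k_gamma * m) * s,
                 alpha_t = p$alpha0 - p$k_alpha * m,
                 gamma_t = p$gamma0 + p$k_gamma * m,
                 params = p),
            class = "kinetics_trajectory")
}

#' Simulate a transcription burst
#'
#' Constant-rate splicing kinetics (\eqn{du/dt = \alpha - \beta u},
#' \eqn{ds/dt = \beta u - \gamma s}) from zero initial conditions, with the
#' transcription rate jumping to `fold` times its value at `t_burst` — the
#' multiple-rate-kinetics pattern that misleads single-steady-state velocity
#' models. The discontinuity is integrated piecewise so both segments are
#' exact to solver tolerance.
#'
#' @param alpha,beta,gamma pre-burst rates.
#' @param t_burst burst onset time (`< t_max`).
#' @param fold fold change of the transcription rate at the burst
#'   (default 3).
#' @param t_max total duration.
#' @param n_steps number of output points.
#' @return A `kinetics_trajectory` with `times`, `u`, `s`, true derivatives
#'   `du`, `ds` and the instantaneous `alpha_t`.
#' @export
simulate_transcription_burst <- function(alpha = 5, beta = 1, gamma = 1,
                                         t_burst = 8, fold = 3,
                                         t_max = 20, n_steps = 400L) {
  .gv_check(all(c(alpha, beta, gamma) > 0), "rates must be positive")
  .gv_check(t_burst < t_max, "t_burst must precede t_max")
  deriv <- function(t, y, parms) {
    a <- parms
    list(c(a - beta * y[1], beta * y[1] - gamma * y[2]))
  }
  t1 <- seq(0, t_burst, length.out = max(2L, round(n_steps * t_burst / t_max)))
  sol1 <- deSolve::ode(c(u = 0, s = 0), t1, deriv, parms = alpha,
                       method = "lsoda", rtol = 1e-10, atol = 1e-12)
  t2 <- seq(t_burst, t_max, length.out = max(2L, n_steps - length(t1) + 1L))
  y1 <- c(u = unname(sol1[nrow(sol1), "u"]), s = unname(sol1[nrow(sol1), "s"]))
  sol2 <- deSolve::ode(y1, t2, deriv, parms = fold * alpha,
                       method = "lsoda", rtol = 1e-10, atol = 1e-12)
  times <- c(t1, t2[-1])
  u <- c(sol1[, "u"], sol2[-1, "u"])
  s <- c(sol1[, "s"], sol2[-1, "s"])
  alpha_t <- ifelse(times < t_burst, alpha, fold * alpha)
  structure(list(times = times, u = u, s = s,
                 du = alpha_t - beta * u, ds = beta * u - gamma * s,
                 alpha_t = alpha_t, t_burst = t_burst, fold = fold,
                 params = list(alpha = alpha, beta = beta, gamma = gamma)),
            class = "kinetics_trajectory")
}

#' Package a kinetics trajectory as a one-gene cell population
#'
#' Treats each time point as a cell with the spliced/unspliced abundances of
#' a single gene, with the exact derivatives as velocity layers — the
#' standard fixture for testing cell-specific rate recovery.
#'
#' @param traj a `kinetics_trajectory` with `u`, `s`, `du`, `ds`.
#' @param gene feature name.
#' @return A [cell_population()] with `X = s` and layers `spliced`,
#'   `unspliced`, `velocity` (ds/dt), `velocity_u` (du/dt), and the times in
#'   `obs$pseudotime`.
#' @export
kinetics_population <- function(traj, gene = "gene_1") {
  .gv_check(inherits(traj, "kinetics_trajectory"),
            "traj must be a kinetics_trajectory")
  n <- length(traj$times)
  as_col <- function(v) matrix(v, n, 1,
                               dimnames = list(paste0("cell_", seq_len(n)),
                                               gene))
  cell_population(as_col(traj$s),
                  layers = list(spliced = as_col(traj$s),
                                unspliced = as_col(traj$u),
                                velocity = as_col(traj$ds),
                                velocity_u = as_col(traj$du)),
                  obs = data.frame(pseudotime = traj$times,
                                   row.names = paste0("cell_", seq_len(n))))
}
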