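.simple_parm_vector <- function(p) {
  c(p$A_P, p$G_Pphi, p$G_Qphi, p$G_Qp, p$G_Qv, p$G_V, p$alpha_v, p$delta)
}

.detailed_parm_vector <- function(p, variant = "baseline",
                                  eps_pop = 1e-12, pop_gate = 1e-10) {
  c(p$A_P, p$A_V, p$G_Qp, p$G_Qphi, p$G_Qv, p$G_V, p$G_C, p$M_V, p$beta,
    p$delta, p$mu_v, p$alpha_v, .variant_code(variant), eps_pop, pop_gate)
}

.rate_scale <- function(model, p) {
  if (model == "simple")
    max(1, p$A_P, p$G_Q, p$G_V, p$alpha_v * p$G_Qv)
  else
    max(1, p$A_P, p$A_V, p$G_Qp, p$G_Qphi, p$G_Qv, p$G_V, p$G_C, p$M_V)
}

#' Default initial state for time courses
#'
#' A small founding host population meeting a smaller phage inoculum:
#' \code{P = 0.1}, \code{V = 0.01} (both in nondimensional units), all
#' other coordinates zero.
#'
#' @param model \code{"simple"} or \code{"detailed"}
#' @return named state vector of the requested model
#' @export
default_initial_state <- function(model = c("simple", "detailed")) {
  model <- match.arg(model)
  if (model == "simple") c(P = 0.1, Q = 0, V = 0.01)
  else detailed_state(P = 0.1, V = 0.01)
}

#' Integrate a model trajectory
#'
#' Integrates either model with the stiff-capable adaptive \code{lsoda}
#' integrator (compiled right-hand sides).  Negative solver excursions are
#' clipped to zero in the returned trajectory and counted in the metadata;
#' extinction events (a population falling and staying below
#' \code{extinction_threshold}) are annotated.
#'
#' @param model \code{"simple"} or \code{"detailed"}
#' @param p matching parameter object
#' @param s0 initial state; defaults to [default_initial_state()]
#' @param horizon integration horizon in nondimensional time units
#'   (default 50 for the simple model, 100 for the detailed model)
#' @param variant detailed-model variant tag
#' @param rtol,atol solver tolerances
#' @param nout number of output times (uniform grid including 0)
#' @param extinction_threshold density below which a population is
#'   reported extinct
#' @param eps_pop,pop_gate regularization constants, see [detailed_rhs()]
#' @param maxsteps maximum internal solver steps per output interval
#' @param maxords maximum order of the stiff (BDF) integrator; the
#'   default 2 keeps the method A-stable, which is required here because
#'   the damped predator-prey spiral puts eigenvalue pairs nearly on the
#'   imaginary axis while the quota dynamics demand steps far beyond the
#'   oscillation period
#' @return object of class \code{trajectory}: list with \code{times},
#'   \code{states} (matrix, one row per time), \code{events} (data.frame
#'   of species/time extinction annotations), and \code{meta}
#' @export
integrate_model <- function(model = c("simple", "detailed"), p, s0 = NULL,
                            horizon = NULL, variant = "baseline",
                            rtol = 1e-8, atol = 1e-12, nout = 201L,
                            extinction_threshold = 1e-10,
                            eps_pop = 1e-12, pop_gate = 1e-10,
                            maxsteps = 50000L, maxords = 2L) {
  model <- match.arg(model)
  if (is.null(s0)) s0 <- default_initial_state(model)
  if (any(!is.finite(s0)) || any(s0 < 0))
    stop("initial state must be finite and nonnegative", call. = FALSE)
  if (is.null(horizon)) horizon <- if (model == "simple") 50 else 100
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  times <- seq(0, horizon, length.out = max(2L, nout))

  if (model == "simple") {
    stopifnot(inherits(p, "simple_params"))
    func <- "crisprcoevo_derivs_simple"
    initf <- "crisprcoevo_init_simple"
    parms <- .simple_parm_vector(p)
    nm <- c("P", "Q", "V")
  } else {
    stopifnot(inherits(p, "detailed_params"))
    func <- "crisprcoevo_derivs_detailed"
    initf <- "crisprcoevo_init_detailed"
    parms <- .detailed_parm_vector(p, variant, eps_pop, pop_gate)
    nm <- .state_names_detailed
  }
  y0 <- setNames(as.numeric(s0), nm)

  sol <- withCallingHandlers(
    deSolve::ode(y = y0, times = times, func = func, parms = parms,
                 dllname = "crisprcoevo", initfunc = initf,
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = maxsteps, maxords = maxords),
    warning = function(w) invokeRestart("muffleWarning"))
  istate <- attr(sol, "istate")[1]
  if (is.null(istate)) istate <- 2L
  if (nrow(sol) < length(times) || istate < 0)
    stop(sprintf("integration failed (istate = %d) at t = %.6g",
                 istate, sol[nrow(sol), 1]), call. = FALSE)
  states <- unclass(sol)[, -1, drop = FALSE]
  if (any(!is.finite(states)))
    stop("integration produced non-finite state values", call. = FALSE)
  n_clipped <- sum(states < 0)
  states[states < 0] <- 0

  traj <- structure(list(
    times = as.numeric(sol[, 1]),
    states = states,
    events = NULL,
    meta = list(model = model, params = p, variant = variant,
                solver = list(method = "lsoda", rtol = rtol, atol = atol,
                              maxsteps = maxsteps),
                extinction_threshold = extinction_threshold,
                n_clipped = n_clipped)
  ), class = "trajectory")
  traj$events <- extinction_events(traj, threshold = extinction_threshold)
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s-model trajectory: %d time points on [0, %.4g]\n",
              x$meta$model, length(x$times), max(x$times)))
  if (nrow(x$events)) {
    cat("events:\n"); print(x$events)
  } else cat("events: none\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Extinction events of a trajectory
#'
#' For each population (\code{P}, \code{Q}, \code{V}) reports the first
#' time its density falls below \code{threshold} and stays there for the
#' remainder of the horizon.
#'
#' @param traj a \code{trajectory}
#' @param threshold extinction threshold in nondimensional density units
#' @return data.frame with columns \code{species} and \code{time}; zero
#'   rows when no population goes extinct
#' @export
extinction_events <- function(traj, threshold = 1e-10) {
  stopifnot(inherits(traj, "trajectory"))
  species <- intersect(c("P", "Q", "V"), colnames(traj$states))
  out <- lapply(species, function(sp) {
    x <- traj$states[, sp]
    below <- x < threshold
    if (!below[length(below)]) return(NULL)
    # last index not below, +1 = start of the terminal below-threshold run
    idx <- if (all(below)) 1L else max(which(!below)) + 1L
    data.frame(species = sp, time = traj$times[idx])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(species = character(), time = numeric())
  else out
}

#' Find a steady state by integration
#'
#' Integrates in doubling-horizon rounds until the normalized right-hand
#' side residual and the trailing-window drift both fall below tolerance,
#' then (detailed model) attempts a Newton polish of the terminal state.
#' The residual is \code{max |rhs|} divided by the largest nondimensional
#' rate group of the model, so that the tolerance has the same meaning for
#' parameterizations whose rates span many orders of magnitude; the drift
#' is the largest change of any coordinate over the trailing 10% of the
#' final round, relative to \code{max(|x|, 1)}.
#'
#' @inheritParams integrate_model
#' @param tol_residual convergence tolerance on the normalized residual
#' @param tol_drift convergence tolerance on the trailing-window drift
#' @param max_rounds maximum number of horizon-doubling rounds
#' @param horizon0 first-round horizon (defaults as in
#'   [integrate_model()])
#' @param polish attempt Newton refinement of the terminal state?
#' @return object of class \code{steady_state}: list with \code{state},
#'   \code{converged}, \code{residual}, \code{window_drift},
#'   \code{rounds}, \code{total_time}, \code{events}
#' @export
find_steady_state <- function(model = c("simple", "detailed"), p,
                              s0 = NULL, variant = "baseline",
                              tol_residual = 1e-8, tol_drift = 1e-6,
                              max_rounds = 10L, horizon0 = NULL,
                              rtol = 1e-8, atol = 1e-12,
                              extinction_threshold = 1e-10,
                              polish = TRUE, nout = 51L) {
  model <- match.arg(model)
  if (is.null(s0)) s0 <- default_initial_state(model)
  if (is.null(horizon0)) horizon0 <- if (model == "simple") 50 else 100
  scale <- .rate_scale(model, p)
  rhs_fn <- if (model == "simple") function(s) simple_rhs(s, p)
  else function(s) detailed_rhs(s, p, variant)

  s <- s0; h <- horizon0; total <- 0
  residual <- drift <- Inf
  events <- data.frame(species = character(), time = numeric())
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    traj <- tryCatch(
      integrate_model(model, p, s0 = s, horizon = h, variant = variant,
                      rtol = rtol, atol = atol, nout = nout,
                      extinction_threshold = extinction_threshold),
      error = function(e) e)
    if (inherits(traj, "error")) {
      # hard round (usually a marginal extinction transit): retry once
      # with a relaxed tolerance and a larger step budget
      traj <- tryCatch(
        integrate_model(model, p, s0 = s, horizon = h, variant = variant,
                        rtol = max(rtol, 1e-6), atol = max(atol, 1e-10),
                        nout = nout, maxsteps = 500000L,
                        extinction_threshold = extinction_threshold),
        error = function(e) e)
    }
    if (inherits(traj, "error")) {
      return(structure(list(state = s, converged = FALSE,
                            residual = residual, window_drift = drift,
                            rounds = rounds, total_time = total,
                            events = events,
                            error = conditionMessage(traj)),
                       class = "steady_state"))
    }
    n <- length(traj$times)
    s_new <- traj$states[n, ]
    win <- traj$states[seq(max(1L, floor(0.9 * n)), n), , drop = FALSE]
    # relative drift per coordinate; coordinates that stayed below the
    # extinction threshold over the whole window are settled-at-zero and
    # contribute nothing (otherwise a population decaying exponentially
    # towards zero would never register as converged, while one decaying
    # towards a small positive level must not register early)
    ref <- pmax(matrix(abs(s_new), nrow(win), ncol(win), byrow = TRUE),
                extinction_threshold)
    dr <- abs(sweep(win, 2, s_new)) / ref
    dr[abs(win) < extinction_threshold &
         matrix(abs(s_new) < extinction_threshold, nrow(win), ncol(win),
                byrow = TRUE)] <- 0
    res_vec <- abs(rhs_fn(s_new))
    # per-capita infected-cell quotas are undefined once the infected
    # pool is extinct; their formal coordinates do not block convergence
    if (model == "detailed" &&
        s_new[["Q"]] < extinction_threshold &&
        s_new[["V"]] < extinction_threshold) {
      inf_quota <- c("X_A", "Y_QA", "Y_QI", "Y_QS")
      dr[, colnames(win) %in% inf_quota] <- 0
      res_vec[inf_quota] <- 0
    }
    drift <- max(dr)
    residual <- max(res_vec) / scale
    if (nrow(traj$events)) {
      new_ev <- traj$events
      new_ev$time <- new_ev$time + total
      keep <- !new_ev$species %in% events$species
      events <- rbind(events, new_ev[keep, ])
    }
    total <- total + h
    s <- s_new
    if (residual < tol_residual && drift < tol_drift) break
    h <- 2 * h
  }

  # Newton polish: certifies the terminal state as an exact root.  When
  # the root is accepted and lies very close to the integrated endpoint,
  # the remaining trailing drift is just the tail of the slowest
  # relaxation mode (rate delta*G_C can be arbitrarily small) and the
  # state is taken as converged.
  polished <- FALSE
  polish_close <- FALSE
  if (polish && model == "detailed") {
    nr <- tryCatch(
      .newton_refine(s, rhs_fn, function(x) .numeric_jacobian(rhs_fn, x),
                     tol = tol_residual * scale, max_iter = 25L),
      error = function(e) NULL)
    if (!is.null(nr) && nr$converged && all(nr$state > -1e-9)) {
      prox <- max(abs(nr$state - s) / pmax(abs(s), 1))
      if (prox < 1e-2) {
        s <- pmax(nr$state, 0)
        residual <- max(abs(rhs_fn(s))) / scale
        polished <- TRUE
        polish_close <- prox < 1e-4
      }
    }
  }

  structure(list(state = s,
                 converged = residual < tol_residual &&
                   (drift < tol_drift || polish_close),
                 residual = residual, window_drift = drift,
                 rounds = rounds, total_time = total, events = events,
                 polished = polished),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s, residual %.3g, drift %.3g, t = %.4g):\n",
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$window_drift, x$total_time))
  print(x$state)
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' Writes the time/state table to \code{file} and, when \code{sidecar} is
#' true, a JSON sidecar (same path with extension \code{.json}) holding
#' the events and solver metadata.
#'
#' @param traj a \code{trajectory}
#' @param file output CSV path
#' @param sidecar also write the JSON sidecar?
#' @return invisibly, the CSV path
#' @export
write_trajectory_csv <- function(traj, file, sidecar = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  if (sidecar) {
    meta <- traj$meta
    meta$params <- unclass(meta$params)
    jsonlite::write_json(
      list(events = traj$events, meta = meta),
      sub("\\.csv$", ".json", file), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
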