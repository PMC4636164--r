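.with_param <- function(p, name, value) {
  fields <- unclass(p)
  fields$G_Q <- NULL  # derived, recomputed by the constructor
  if (!name %in% names(fields))
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  fields[[name]] <- value
  ctor <- switch(class(p)[1],
                 simple_params = simple_params,
                 detailed_params = detailed_params,
                 dim_simple_params = simple_params_dim,
                 dim_detailed_params = detailed_params_dim,
                 stop("unsupported parameter class", call. = FALSE))
  do.call(ctor, fields)
}

#' One-parameter continuation of fixed-point branches
#'
#' Tracks the analytic fixed-point families of the simple model (E*, F*,
#' C*) across a parameter range.  The coexistence branch is followed by
#' natural-parameter continuation: at each step the Newton refinement is
#' seeded from the previous point's root (closed form at the first
#' point); divergence truncates the branch with a logged reason.
#' Stability is assessed at every point, and special points are recorded
#' where branches collide (distance below \code{collision_tol}), lose
#' feasibility (coordinate sign change), or change stability.
#'
#' For the detailed model the phage-free branch (the only analytically
#' tracked family) is followed via [phage_free_fixed_point()].
#'
#' @param p parameter object
#' @param param name of the swept parameter (e.g. \code{"delta"})
#' @param range numeric length-2 range
#' @param steps number of points (>= 2)
#' @param model \code{"simple"} or \code{"detailed"}
#' @param variant detailed-model variant tag
#' @param collision_tol branch-distance threshold for collision detection
#' @return object of class \code{branch_set}: list of branches, each with
#'   \code{values}, \code{states}, \code{feasible}, \code{stability},
#'   \code{special_points}
#' @export
continue_fixed_point_1d <- function(p, param, range, steps = 101L,
                                    model = c("simple", "detailed"),
                                    variant = "baseline",
                                    collision_tol = 1e-6) {
  model <- match.arg(model)
  if (length(range) != 2L || !all(is.finite(range)) ||
      range[1] >= range[2])
    stop("'range' must be a finite increasing length-2 vector",
         call. = FALSE)
  if (steps < 2L) stop("'steps' must be at least 2", call. = FALSE)
  values <- seq(range[1], range[2], length.out = steps)

  if (model == "detailed") {
    recs <- lapply(values, function(v) {
      pv <- .with_param(p, param, v)
      tryCatch(phage_free_fixed_point(pv, variant),
               error = function(e) NULL)
    })
    br <- .assemble_branch("F", param, values, recs)
    return(structure(list(F = br), class = "branch_set"))
  }

  stopifnot(inherits(p, "simple_params"))
  kinds <- c("E", "F", "C")
  recs <- setNames(vector("list", 3), kinds)
  seed <- NULL
  per_kind <- lapply(kinds, function(k) vector("list", steps))
  names(per_kind) <- kinds
  truncated <- NULL
  for (i in seq_along(values)) {
    pv <- .with_param(p, param, values[i])
    fps <- tryCatch(fixed_points_simple(pv, refine = FALSE,
                                        assess = FALSE),
                    error = function(e) NULL)
    if (is.null(fps)) next
    # refine C by continuation from the previous root
    if (!is.null(fps$C) && !any(is.na(fps$C$state))) {
      s0 <- if (!is.null(seed)) seed else fps$C$state
      nr <- .newton_refine(s0, function(s) simple_rhs(s, pv),
                           function(s) simple_jacobian(s, pv))
      if (nr$converged) {
        fps$C$state <- nr$state
        fps$C$feasible <- all(nr$state >= -1e-12) &&
          nr$state[["P"]] <= 1 + 1e-12
        seed <- nr$state
      } else {
        truncated <- c(truncated, sprintf(
          "C branch truncated at %s = %.6g (Newton divergence)",
          param, values[i]))
        fps$C <- NULL
        seed <- NULL
      }
    }
    for (k in kinds) {
      if (!is.null(fps[[k]]) && !any(is.na(fps[[k]]$state)))
        per_kind[[k]][[i]] <- tryCatch(
          assess_stability(fps[[k]], pv), error = function(e) fps[[k]])
    }
  }
  out <- lapply(kinds, function(k)
    .assemble_branch(k, param, values, per_kind[[k]]))
  names(out) <- kinds

  # collisions: C meets F where their branch distance dips to zero; the
  # crossing generically falls between grid points, so accept an
  # interior distance minimum that is small compared with the local
  # branch motion per step and locate it by linear interpolation of the
  # two flanking slopes
  if (!is.null(out$C) && !is.null(out$F)) {
    d <- sqrt(rowSums((out$C$states - out$F$states)^2))
    ok <- which(!is.na(d))
    if (length(ok) >= 3) {
      k <- ok[which.min(d[ok])]
      if (k > min(ok) && k < max(ok)) {
        sl <- max(abs(d[k - 1] - d[k]), abs(d[k + 1] - d[k]))
        if (d[k] < max(2 * sl, collision_tol)) {
          # V-shaped |c(x - x*)| profile: vertex of the flank lines at
          # x* = x_k + h/2 * (d[k-1] - d[k+1]) / (d[k-1] - 2 d[k] + d[k+1])
          h <- values[k + 1] - values[k]
          den <- d[k - 1] - 2 * d[k] + d[k + 1]
          xstar <- if (den > 0)
            values[k] + 0.5 * h * (d[k - 1] - d[k + 1]) / den
          else values[k]
          sp <- data.frame(value = xstar, label = "fold/collision")
          out$C$special_points <- rbind(out$C$special_points, sp)
          out$F$special_points <- rbind(out$F$special_points, sp)
        }
      }
    }
  }
  structure(out, class = "branch_set",
            truncated = truncated)
}

.assemble_branch <- function(kind, param, values, recs) {
  n <- length(values)
  dim_n <- NULL
  for (r in recs) if (!is.null(r)) { dim_n <- length(r$state); break }
  if (is.null(dim_n)) return(NULL)
  states <- matrix(NA_real_, n, dim_n)
  feasible <- rep(NA, n)
  stability <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!is.null(recs[[i]])) {
      states[i, ] <- recs[[i]]$state
      feasible[i] <- recs[[i]]$feasible
      stability[i] <- recs[[i]]$stability
    }
  }
  colnames(states) <- names(recs[[which(!vapply(recs, is.null,
                                                TRUE))[1]]]$state)
  sp <- data.frame(value = numeric(), label = character())
  # feasibility losses
  ch <- which(diff(as.integer(feasible)) != 0)
  if (length(ch))
    sp <- rbind(sp, data.frame(value = values[ch + 1],
                               label = "infeasibility"))
  st_change <- which(!is.na(stability[-n]) & !is.na(stability[-1]) &
                       stability[-n] != stability[-1])
  if (length(st_change))
    sp <- rbind(sp, data.frame(value = values[st_change + 1],
                               label = "zero-crossing"))
  list(kind = kind, param = param, values = values, states = states,
       feasible = feasible, stability = stability, special_points = sp)
}

#' Classify the long-run outcome at one parameter point
#'
#' Runs [find_steady_state()] from \code{s0} and labels the outcome
#' \code{"host-extinct"} (terminal \code{P} below the extinction
#' threshold), \code{"phage-free"} (hosts persist, terminal \code{V}
#' below \code{phage_threshold}), or \code{"coexistence"}.
#'
#' @inheritParams find_steady_state
#' @param phage_threshold phage density below which the outcome is
#'   phage-free
#' @return list with \code{outcome}, \code{state}, \code{converged}
#' @export
classify_outcome <- function(model, p, s0 = NULL, variant = "baseline",
                             phage_threshold = 1e-6,
                             extinction_threshold = 1e-10, ...) {
  ss <- find_steady_state(model, p, s0 = s0, variant = variant,
                          extinction_threshold = extinction_threshold,
                          ...)
  st <- ss$state
  outcome <- if (st[["P"]] < extinction_threshold) "host-extinct"
  else if (st[["V"]] < phage_threshold) "phage-free"
  else "coexistence"
  list(outcome = outcome, state = st, converged = ss$converged)
}

#' Trace a critical boundary in a two-parameter plane
#'
#' Classifies the long-run outcome on a rectangular grid and refines each
#' boundary crossing between adjacent differing nodes by bisection (along
#' both grid directions) to a relative parameter tolerance.
#'
#' @param model \code{"simple"} or \code{"detailed"}
#' @param p parameter object (values of \code{param_x}, \code{param_y}
#'   are overridden)
#' @param param_x,param_y names of the plane parameters
#' @param xlim,ylim parameter ranges
#' @param resolution grid nodes per axis, length 1 or 2
#' @param rel_tol relative bisection tolerance on the boundary location
#' @param variant detailed-model variant tag
#' @param log_x,log_y scan the axis in log space?
#' @param ... passed to [classify_outcome()]
#' @return object of class \code{critical_curve}: data.frame of refined
#'   boundary points (\code{x}, \code{y}, \code{side_low},
#'   \code{side_high}, \code{direction}) with the outcome grid in
#'   attribute \code{grid}; zero rows (with a note) when the rectangle
#'   has a uniform outcome
#' @export
trace_boundary_2d <- function(model, p, param_x, param_y, xlim, ylim,
                              resolution = 11L, rel_tol = 1e-3,
                              variant = "baseline", log_x = FALSE,
                              log_y = FALSE, ...) {
  res <- rep(resolution, length.out = 2L)
  gx <- if (log_x) exp(seq(log(xlim[1]), log(xlim[2]),
                           length.out = res[1]))
  else seq(xlim[1], xlim[2], length.out = res[1])
  gy <- if (log_y) exp(seq(log(ylim[1]), log(ylim[2]),
                           length.out = res[2]))
  else seq(ylim[1], ylim[2], length.out = res[2])

  cls <- function(x, y) {
    pv <- .with_param(.with_param(p, param_x, x), param_y, y)
    classify_outcome(model, pv, variant = variant, ...)$outcome
  }
  grid <- matrix(NA_character_, length(gx), length(gy))
  for (i in seq_along(gx)) for (j in seq_along(gy))
    grid[i, j] <- cls(gx[i], gy[j])

  bisect <- function(lo, hi, fixed, along, out_lo) {
    # refine the crossing on [lo, hi]; out_lo is the outcome at lo
    while ((hi - lo) / max(abs(hi), abs(lo), .Machine$double.eps) >
           rel_tol) {
      mid <- if ((along == "x" && log_x) || (along == "y" && log_y))
        sqrt(lo * hi) else (lo + hi) / 2
      o <- if (along == "x") cls(mid, fixed) else cls(fixed, mid)
      if (identical(o, out_lo)) lo <- mid else hi <- mid
    }
    c(lo, hi)
  }

  pts <- list()
  for (j in seq_along(gy)) {
    for (i in seq_len(length(gx) - 1L)) {
      if (grid[i, j] != grid[i + 1L, j]) {
        b <- bisect(gx[i], gx[i + 1L], gy[j], "x", grid[i, j])
        pts[[length(pts) + 1L]] <- data.frame(
          x = mean(b), y = gy[j], side_low = grid[i, j],
          side_high = grid[i + 1L, j], direction = "x")
      }
    }
  }
  for (i in seq_along(gx)) {
    for (j in seq_len(length(gy) - 1L)) {
      if (grid[i, j] != grid[i, j + 1L]) {
        b <- bisect(gy[j], gy[j + 1L], gx[i], "y", grid[i, j])
        pts[[length(pts) + 1L]] <- data.frame(
          x = gx[i], y = mean(b), side_low = grid[i, j],
          side_high = grid[i, j + 1L], direction = "y")
      }
    }
  }
  curve <- if (length(pts)) do.call(rbind, pts)
  else data.frame(x = numeric(), y = numeric(),
                  side_low = character(), side_high = character(),
                  direction = character())
  structure(curve, class = c("critical_curve", "data.frame"),
            grid = grid, grid_x = gx, grid_y = gy,
            params = c(x = param_x, y = param_y),
            note = if (!length(pts)) "uniform outcome over the rectangle"
            else NULL)
}

#' Classify a steady state into regimes I-IV
#'
#' Regime labels of CRISPR operation at a converged detailed-model steady
#' state: \code{III} when the host is extinct; otherwise \code{I} when
#' the immune-advantage score
#' \code{(G_Qp*Y_QA + G_Qphi*Y_QS)/G_Qv} is below \code{eps_adv} (empty
#' cassettes, phage-limited hosts); otherwise \code{II} when the
#' restriction share \code{G_Qp*Y_QA/G_Qv} exceeds \code{eps_restrict}
#' (restriction and abortive infection both operate); otherwise \code{IV}
#' (the advantage is carried by self-targeting spacers alone -- a pure
#' abortive-infection system).
#'
#' @param ss a \code{steady_state} (or a named 10-component state vector
#'   from a converged run)
#' @param p the \code{detailed_params} used
#' @param eps_adv threshold on the immune-advantage score for regime I
#' @param eps_restrict threshold on the restriction share separating
#'   regimes II and IV
#' @param extinction_threshold host density defining extinction
#' @return one of \code{"I"}, \code{"II"}, \code{"III"}, \code{"IV"}
#' @export
classify_steady_state <- function(ss, p, eps_adv = 1e-3,
                                  eps_restrict = 1e-3,
                                  extinction_threshold = 1e-10) {
  if (inherits(ss, "steady_state")) {
    if (!ss$converged)
      stop("unclassifiable: steady state did not converge",
           call. = FALSE)
    st <- ss$state
  } else st <- ss
  if (st[["P"]] < extinction_threshold) return("III")
  if (p$G_Qv <= 0) stop("classification requires G_Qv > 0",
                        call. = FALSE)
  adv <- (p$G_Qp * st[["Y_QA"]] + p$G_Qphi * st[["Y_QS"]]) / p$G_Qv
  if (adv < eps_adv) return("I")
  restrict <- p$G_Qp * st[["Y_QA"]] / p$G_Qv
  if (restrict > eps_restrict) "II" else "IV"
}

#' Sweep the (beta, G_C) plane and label regimes
#'
#' Runs [find_steady_state()] on every grid cell (warm-starting each cell
#' from its neighbour at the next-larger \code{G_C} in the same
#' \code{beta} row) and labels each converged cell with
#' [classify_steady_state()].  Cells whose solve fails are labelled
#' \code{"unclassifiable"}; the sweep never aborts.
#'
#' Warm starts inherit the neighbour's quotas but floor the populations
#' at the default inoculum (\code{P >= 0.1}, \code{V >= 0.01}): an
#' extinct neighbour must not pin a viable cell at zero, and a
#' vanishingly small phage inoculum can fail to re-establish where a
#' standard one persists.  Rows are traversed from high \code{G_C}
#' (benign: low self-targeting load) towards low \code{G_C}, so inherited
#' self-targeting quotas approach their equilibria from below and never
#' transiently overshoot the autoimmune-crash threshold of the target
#' cell.
#'
#' @param p a \code{detailed_params} object (its \code{beta},
#'   \code{G_C}, and optionally \code{delta} are overridden per cell)
#' @param beta_grid,Gc_grid grid values (nonempty)
#' @param delta free-cell activation level for the whole sweep (default:
#'   the value in \code{p})
#' @param variant model variant tag
#' @param warm_start warm-start cells from their row neighbour?
#' @param ... passed to [find_steady_state()]
#' @return object of class \code{regime_map}: long-format data.frame with
#'   one row per cell (beta, G_C, delta, variant, the steady-state
#'   summary P, V, Y_QA, Y_QS, Y_PS, regime, converged)
#' @export
sweep_regimes <- function(p, beta_grid, Gc_grid, delta = NULL,
                          variant = "baseline", warm_start = TRUE, ...) {
  stopifnot(inherits(p, "detailed_params"))
  if (!length(beta_grid) || !length(Gc_grid))
    stop("grids must be nonempty", call. = FALSE)
  if (!is.null(delta)) p <- .with_param(p, "delta", delta)
  rows <- vector("list", length(beta_grid) * length(Gc_grid))
  k <- 0L
  for (b in beta_grid) {
    prev_state <- NULL
    for (gc in sort(Gc_grid, decreasing = TRUE)) {
      k <- k + 1L
      pv <- .with_param(.with_param(p, "beta", b), "G_C", gc)
      s0 <- if (warm_start && !is.null(prev_state)) {
        s <- prev_state
        s[["P"]] <- max(s[["P"]], 0.1)
        s[["V"]] <- max(s[["V"]], 0.01)
        s
      } else NULL
      ss <- tryCatch(find_steady_state("detailed", pv, s0 = s0,
                                       variant = variant, ...),
                     error = function(e) NULL)
      if (is.null(ss)) {
        rows[[k]] <- data.frame(beta = b, G_C = gc, delta = p$delta,
                                variant = variant, P = NA_real_,
                                V = NA_real_, Y_QA = NA_real_,
                                Y_QS = NA_real_, Y_PS = NA_real_,
                                regime = "unclassifiable",
                                converged = FALSE)
        next
      }
      st <- ss$state
      regime <- tryCatch(
        classify_steady_state(st, pv),
        error = function(e) "unclassifiable")
      if (!ss$converged && regime != "III") regime <- "unclassifiable"
      rows[[k]] <- data.frame(beta = b, G_C = gc, delta = p$delta,
                              variant = variant, P = st[["P"]],
                              V = st[["V"]], Y_QA = st[["Y_QA"]],
                              Y_QS = st[["Y_QS"]], Y_PS = st[["Y_PS"]],
                              regime = regime, converged = ss$converged)
      prev_state <- st
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$beta, beta_grid), out$G_C), ]
  rownames(out) <- NULL
  structure(out,
            class = c("regime_map", "data.frame"),
            beta_grid = beta_grid, Gc_grid = Gc_grid,
            delta = p$delta, variant = variant)
}

#' Compare model variants on a shared grid
#'
#' Runs [sweep_regimes()] for each variant on identical grids and tabulates
#' the per-cell differences of the steady-state free-cell and phage levels
#' and any regime-label changes, each variant against the first.
#'
#' @inheritParams sweep_regimes
#' @param variants character vector of at least two variant tags
#' @return list with \code{maps} (named list of \code{regime_map}) and
#'   \code{differences} (data.frame: beta, G_C, variant, dP, dV,
#'   regime_from, regime_to)
#' @export
compare_variants <- function(p, beta_grid, Gc_grid, delta = NULL,
                             variants = c("baseline", "no_abi"), ...) {
  if (length(variants) < 2L)
    stop("at least two variants are required", call. = FALSE)
  maps <- lapply(variants, function(v)
    sweep_regimes(p, beta_grid, Gc_grid, delta = delta, variant = v, ...))
  names(maps) <- variants
  ref <- maps[[1]]
  diffs <- do.call(rbind, lapply(variants[-1], function(v) {
    m <- maps[[v]]
    data.frame(beta = ref$beta, G_C = ref$G_C, variant = v,
               dP = m$P - ref$P, dV = m$V - ref$V,
               regime_from = ref$regime, regime_to = m$regime)
  }))
  list(maps = maps, differences = diffs)
}

#' Write a regime map as long-format CSV
#'
#' @param map a \code{regime_map}
#' @param file output path
#' @return invisibly, the path
#' @export
write_regime_map_csv <- function(map, file) {
  stopifnot(inherits(map, "regime_map"))
  utils::write.csv(as.data.frame(map), file, row.names = FALSE)
  invisible(file)
}
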