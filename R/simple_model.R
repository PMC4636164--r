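#' Right-hand side of the simple model
#'
#' Time derivatives of the three-variable regulated-autoimmunity model in
#' nondimensional form: free cells \code{P} grow logistically, phage
#' infection \code{P*V} creates infected cells \code{Q}, which are removed
#' by immunity (back to \code{P}), autoimmunity, or lysis (releasing
#' \code{alpha_v} phage each); free cells suffer autoimmunity at the
#' suppressed rate \code{delta * G_Pphi}.  The phage equation carries the
#' \code{-P*V} adsorption sink.
#'
#' @param state named or ordered numeric vector \code{c(P, Q, V)}
#' @param p a \code{simple_params} object
#' @return named numeric vector of derivatives \code{c(P, Q, V)}
#' @export
simple_rhs <- function(state, p) {
  stopifnot(inherits(p, "simple_params"))
  P <- state[[1]]; Q <- state[[2]]; V <- state[[3]]
  c(P = p$A_P * P * (1 - P - Q) - p$delta * p$G_Pphi * P + p$G_Qp * Q -
      P * V,
    Q = P * V - p$G_Q * Q,
    V = p$alpha_v * p$G_Qv * Q - p$G_V * V - P * V)
}

#' Analytic Jacobian of the simple model
#'
#' @inheritParams simple_rhs
#' @return 3x3 matrix of partial derivatives, rows/columns ordered
#'   \code{(P, Q, V)}
#' @export
simple_jacobian <- function(state, p) {
  stopifnot(inherits(p, "simple_params"))
  P <- state[[1]]; Q <- state[[2]]; V <- state[[3]]
  matrix(c(
    p$A_P * (1 - 2 * P - Q) - p$delta * p$G_Pphi - V,
    -p$A_P * P + p$G_Qp, -P,
    V, -p$G_Q, P,
    -V, p$alpha_v * p$G_Qv, -p$G_V - P
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("P", "Q", "V"), c("P", "Q", "V")))
}

#' Routh-Hurwitz test for a 3x3 Jacobian
#'
#' Computes the characteristic-polynomial coefficients
#' \eqn{\lambda^3 + a_1 \lambda^2 + a_2 \lambda + a_3} and the
#' Routh-Hurwitz stability conditions \eqn{a_1 > 0}, \eqn{a_3 > 0},
#' \eqn{a_1 a_2 > a_3}.  A verdict of \code{"marginal"} is returned when
#' any tested quantity lies within \code{tol} of zero.
#'
#' @param J a 3x3 Jacobian matrix
#' @param tol marginality tolerance on the nondimensional scale
#' @return list with \code{a1}, \code{a2}, \code{a3}, \code{h = a1*a2 -
#'   a3}, and \code{verdict} in \code{c("stable", "unstable", "marginal")}
#' @export
routh_hurwitz <- function(J, tol = 1e-9) {
  stopifnot(is.matrix(J), all(dim(J) == c(3, 3)))
  a1 <- -sum(diag(J))
  minor <- function(i, j) J[i, i] * J[j, j] - J[i, j] * J[j, i]
  a2 <- minor(1, 2) + minor(1, 3) + minor(2, 3)
  a3 <- -det(J)
  h <- a1 * a2 - a3
  q <- c(a1, a3, h)
  verdict <- if (any(abs(q) < tol)) "marginal"
  else if (all(q > 0)) "stable" else "unstable"
  list(a1 = a1, a2 = a2, a3 = a3, h = h, verdict = verdict)
}

.fixed_point <- function(kind, state, feasible, stability = NA_character_,
                         diagnostics = list()) {
  structure(list(kind = kind, state = state, feasible = feasible,
                 stability = stability, diagnostics = diagnostics),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("%s* fixed point (%s, %s)\n", x$kind,
              if (isTRUE(x$feasible)) "feasible" else "infeasible",
              x$stability))
  print(x$state)
  invisible(x)
}

#' Closed-form coexistence state of the simple model
#'
#' The coexistence fixed point in the limit where the adsorption sink in
#' the phage equation is negligible (\code{alpha_v * G_Qv / G_Q >> 1}):
#' \deqn{P_c = (G_V/\alpha_v)\,(1 + (G_{Q\phi} + G_{Qp})/G_{Qv})}
#' the phage-limited level times the immune-advantage factor, with
#' \deqn{V_c = G_Q\,[A_P(1 - P_c) - \delta G_{P\phi}]/(A_P P_c + G_{Q\phi}
#'   + G_{Qv})}
#' and \eqn{Q_c = P_c V_c / G_Q}.
#'
#' @param p a \code{simple_params} object
#' @return named numeric vector \code{c(P, Q, V)}
#' @keywords internal
closed_form_cstar <- function(p) {
  if (p$G_Qv <= 0 || p$alpha_v <= 0)
    stop("coexistence branch requires G_Qv > 0 and alpha_v > 0",
         call. = FALSE)
  Pc <- (p$G_V / p$alpha_v) * (1 + (p$G_Qphi + p$G_Qp) / p$G_Qv)
  Vc <- p$G_Q * (p$A_P * (1 - Pc) - p$delta * p$G_Pphi) /
    (p$A_P * Pc + p$G_Qphi + p$G_Qv)
  c(P = Pc, Q = Pc * Vc / p$G_Q, V = Vc)
}

.newton_refine <- function(state, rhs_fn, jac_fn, tol = 1e-12,
                           max_iter = 100L) {
  s <- state
  f <- rhs_fn(s)
  for (i in seq_len(max_iter)) {
    if (max(abs(f)) < tol)
      return(list(state = s, converged = TRUE, residual = max(abs(f)),
                  iterations = i - 1L))
    step <- tryCatch(solve(jac_fn(s), f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(state = s, converged = FALSE, residual = max(abs(f)),
                  iterations = i - 1L))
    lambda <- 1
    repeat {  # damped step: require the residual not to blow up
      s_new <- s - lambda * step
      f_new <- rhs_fn(s_new)
      if (all(is.finite(f_new)) &&
          (max(abs(f_new)) < max(abs(f)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    s <- s_new; f <- f_new
  }
  list(state = s, converged = max(abs(f)) < tol, residual = max(abs(f)),
       iterations = max_iter)
}

#' Analytic fixed points of the simple model
#'
#' Returns the three steady-state families: extinction \code{E* = 0},
#' the phage-free state \code{F*} with \code{P = 1 - delta*G_Pphi/A_P},
#' and the coexistence state \code{C*}.  \code{C*} is reported both in the
#' closed form of [closed_form_cstar()] and as a Newton-refined exact root
#' of [simple_rhs()] seeded there; their relative discrepancy is stored in
#' the diagnostics and the refined root is the \code{state} used
#' downstream.  Stability is assessed for every feasible point via
#' [assess_stability()].
#'
#' @param p a \code{simple_params} object
#' @param refine Newton-refine the closed-form coexistence root?
#' @param assess assess linear stability of each feasible point?
#' @return list of \code{fixed_point} records named \code{E}, \code{F},
#'   \code{C}
#' @export
fixed_points_simple <- function(p, refine = TRUE, assess = TRUE) {
  stopifnot(inherits(p, "simple_params"))
  out <- list()
  zero <- c(P = 0, Q = 0, V = 0)
  out$E <- .fixed_point("E", zero, feasible = TRUE)

  Pf <- if (p$A_P > 0) 1 - p$delta * p$G_Pphi / p$A_P else NA_real_
  out$F <- .fixed_point("F", c(P = Pf, Q = 0, V = 0),
                        feasible = is.finite(Pf) && Pf >= 0 && Pf <= 1)

  if (p$G_Qv <= 0 || p$alpha_v <= 0) {
    out$C <- .fixed_point("C", c(P = NA_real_, Q = NA_real_, V = NA_real_),
                          feasible = FALSE,
                          diagnostics = list(
                            absent = "coexistence branch requires G_Qv > 0 and alpha_v > 0"))
  } else {
    cf <- closed_form_cstar(p)
    state <- cf; diag <- list(closed_form = cf)
    if (refine) {
      nr <- .newton_refine(cf, function(s) simple_rhs(s, p),
                           function(s) simple_jacobian(s, p))
      if (nr$converged) {
        state <- nr$state
        diag$refined <- nr$state
        diag$discrepancy <- max(abs(nr$state - cf) /
                                  pmax(abs(nr$state), 1e-12))
        diag$residual <- nr$residual
      } else {
        diag$closed_form_only <- TRUE
        diag$residual <- nr$residual
      }
    }
    diag$validity_ratio <- p$alpha_v * p$G_Qv / p$G_Q
    out$C <- .fixed_point("C", state,
                          feasible = all(state >= 0) && state[["P"]] <= 1,
                          diagnostics = diag)
  }
  if (assess) {
    out <- lapply(out, function(f) {
      if (!any(is.na(f$state)))
        tryCatch(assess_stability(f, p), error = function(e) f)
      else f
    })
  }
  out
}

#' Critical activation thresholds of the simple model
#'
#' \code{delta1 = A_P / G_Pphi} is the free-cell activation level above
#' which the phage-free state loses feasibility and hosts go extinct;
#' \code{delta2 = A_P (1 - P_c) / G_Pphi} (with the closed-form
#' coexistence level \code{P_c}) is the tighter level above which
#' coexistence is infeasible.  Whenever \code{0 < P_c < 1},
#' \code{delta2 < delta1}.
#'
#' @param p a \code{simple_params} object
#' @return list with \code{delta1}, \code{delta2} (NA outside
#'   \code{0 < P_c < 1}), and \code{P_c}
#' @export
delta_thresholds <- function(p) {
  stopifnot(inherits(p, "simple_params"))
  if (p$G_Pphi == 0)
    return(list(delta1 = Inf, delta2 = Inf, P_c = NA_real_,
                note = "G_Pphi = 0: free-cell autoimmunity absent, no constraint"))
  delta1 <- p$A_P / p$G_Pphi
  Pc <- tryCatch(closed_form_cstar(p)[["P"]], error = function(e) NA_real_)
  delta2 <- if (is.finite(Pc) && Pc > 0 && Pc < 1)
    p$A_P * (1 - Pc) / p$G_Pphi else NA_real_
  list(delta1 = delta1, delta2 = delta2, P_c = Pc)
}

#' Critical coexistence line of the simple model
#'
#' In the \code{(delta, G_Qphi)} plane the boundary between coexistence
#' and phage evasion is, in the limit \code{alpha_v*G_Qv/G_Q >> 1}, the
#' line \code{delta/K1 + G_Qphi/K2 = 1} with intercepts
#' \deqn{K_1 = (A_P/G_{P\phi})[1 - (G_V/\alpha_v)(1 + G_{Qp}/G_{Qv})]}
#' \deqn{K_2 = G_{Qv}[\alpha_v/G_V - (1 + G_{Qp}/G_{Qv})]}
#'
#' @param p a \code{simple_params} object
#' @return list with \code{K1}, \code{K2} and the validity ratio
#'   \code{alpha_v*G_Qv/G_Q}
#' @export
coexistence_boundary <- function(p) {
  stopifnot(inherits(p, "simple_params"))
  if (p$G_V <= 0) stop("G_V must be positive", call. = FALSE)
  if (p$G_Qv <= 0) stop("G_Qv must be positive", call. = FALSE)
  wedge <- p$alpha_v / p$G_V - (1 + p$G_Qp / p$G_Qv)
  if (wedge <= 0)
    stop("no coexistence wedge: alpha_v/G_V must exceed 1 + G_Qp/G_Qv",
         call. = FALSE)
  K1 <- (p$A_P / p$G_Pphi) *
    (1 - (p$G_V / p$alpha_v) * (1 + p$G_Qp / p$G_Qv))
  K2 <- p$G_Qv * wedge
  list(K1 = K1, K2 = K2, validity_ratio = p$alpha_v * p$G_Qv / p$G_Q)
}

#' Linear stability of a fixed point
#'
#' Builds the Jacobian at the fixed-point state and classifies stability
#' two ways: by the Routh-Hurwitz conditions on the characteristic
#' polynomial (3-variable model) and by the numerically computed
#' eigenvalue spectrum.  A disagreement between the two routes beyond the
#' marginality tolerance is reported as \code{"marginal"} with a
#' diagnostic.  For states of dimension other than 3 only the eigenvalue
#' route is used (with a central-difference Jacobian of the supplied
#' right-hand side).
#'
#' @param f a \code{fixed_point} record
#' @param p parameter object matching the model of \code{f}
#' @param variant detailed-model variant tag (10-variable states only)
#' @param tol_marginal Routh-Hurwitz marginality tolerance
#' @param tol_residual largest right-hand-side residual accepted at
#'   \code{f$state}
#' @return \code{f} with \code{stability} set and Routh-Hurwitz
#'   coefficients plus the eigenvalue spectrum in \code{diagnostics}
#' @export
assess_stability <- function(f, p, variant = "baseline",
                             tol_marginal = 1e-9, tol_residual = 1e-6) {
  stopifnot(inherits(f, "fixed_point"))
  n <- length(f$state)
  if (n == 3L) {
    res <- simple_rhs(f$state, p)
    scale <- max(1, p$A_P, p$G_Q, p$G_V, p$alpha_v * p$G_Qv)
    if (max(abs(res)) / scale > tol_residual)
      stop("not a fixed point: residual ", max(abs(res)), call. = FALSE)
    J <- simple_jacobian(f$state, p)
    rh <- routh_hurwitz(J, tol = tol_marginal)
    ev <- eigen(J, only.values = TRUE)$values
    mx <- max(Re(ev))
    ev_verdict <- if (abs(mx) < tol_marginal) "marginal"
    else if (mx < 0) "stable" else "unstable"
    stability <- if (rh$verdict == ev_verdict) rh$verdict else "marginal"
    f$diagnostics$routh_hurwitz <- rh
    f$diagnostics$eigenvalues <- ev
    if (rh$verdict != ev_verdict)
      f$diagnostics$stability_disagreement <-
        c(routh_hurwitz = rh$verdict, eigen = ev_verdict)
    f$stability <- stability
  } else {
    rhs_fn <- function(s) detailed_rhs(s, p, variant)
    res <- rhs_fn(f$state)
    scale <- max(1, p$A_P, p$A_V, p$G_Qp, p$G_Qphi, p$G_Qv, p$G_V, p$G_C)
    if (max(abs(res)) / scale > tol_residual)
      stop("not a fixed point: residual ", max(abs(res)), call. = FALSE)
    J <- .numeric_jacobian(rhs_fn, f$state)
    ev <- eigen(J, only.values = TRUE)$values
    mx <- max(Re(ev)) / scale
    f$diagnostics$eigenvalues <- ev
    f$stability <- if (abs(mx) < tol_marginal) "marginal"
    else if (mx < 0) "stable" else "unstable"
  }
  f
}

.numeric_jacobian <- function(fn, x, rel_h = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- rel_h * max(abs(x[j]), 1)
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  dimnames(J) <- list(names(x), names(x))
  J
}

#' Export fixed points as a data frame
#'
#' One row per fixed point with the state coordinates, feasibility,
#' stability, and the analytic thresholds/boundary constants where
#' defined.
#'
#' @param fps list of \code{fixed_point} records (e.g. from
#'   [fixed_points_simple()])
#' @param p the \code{simple_params} object used to compute them
#' @return data.frame with columns kind, P, Q, V, feasible, stability,
#'   delta1, delta2, K1, K2
#' @export
fixed_points_table <- function(fps, p) {
  th <- delta_thresholds(p)
  cb <- tryCatch(coexistence_boundary(p),
                 error = function(e) list(K1 = NA_real_, K2 = NA_real_))
  do.call(rbind, lapply(fps, function(f) {
    data.frame(kind = f$kind, P = f$state[[1]], Q = f$state[[2]],
               V = f$state[[3]], feasible = f$feasible,
               stability = f$stability, delta1 = th$delta1,
               delta2 = th$delta2, K1 = cb$K1, K2 = cb$K2,
               row.names = NULL)
  }))
}
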