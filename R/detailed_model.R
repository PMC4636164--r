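.variants <- c("baseline", "no_abi", "deletion_constitutive",
               "deletion_inverse")

.variant_code <- function(variant) {
  match(match.arg(variant, .variants), .variants) - 1L
}

#' State vector of the detailed model
#'
#' Builds the named 10-component state: population densities \code{P}
#' (free cells), \code{Q} (infected cells), \code{V} (phage, in burst-size
#' units), the active phage-protospacer quota \code{X_A} per infected
#' cell, and the active/inactive/self-targeting spacer quotas per infected
#' (\code{Y_Q*}) and free (\code{Y_P*}) cell, all quotas in units of the
#' phage protospacer complement.
#'
#' @param P,Q,V,X_A,Y_QA,Y_QI,Y_QS,Y_PA,Y_PI,Y_PS coordinates (all >= 0)
#' @return named numeric vector of length 10
#' @export
detailed_state <- function(P = 0, Q = 0, V = 0, X_A = 0, Y_QA = 0,
                           Y_QI = 0, Y_QS = 0, Y_PA = 0, Y_PI = 0,
                           Y_PS = 0) {
  s <- c(P = P, Q = Q, V = V, X_A = X_A, Y_QA = Y_QA, Y_QI = Y_QI,
         Y_QS = Y_QS, Y_PA = Y_PA, Y_PI = Y_PI, Y_PS = Y_PS)
  if (any(!is.finite(s)) || any(s < 0))
    stop("detailed state coordinates must be finite and nonnegative",
         call. = FALSE)
  s
}

.state_names_detailed <- c("P", "Q", "V", "X_A", "Y_QA", "Y_QI", "Y_QS",
                           "Y_PA", "Y_PI", "Y_PS")

#' Right-hand side of the detailed CRISPR model
#'
#' Nondimensional time derivatives of the ten-variable model on the CRISPR
#' evolutionary time scale.  Infected cells acquire active spacers from
#' their phage protospacer pool \code{X_A} and self-targeting spacers at
#' rate \code{beta}; free cells run all CRISPR reactions (self-targeting
#' acquisition \code{delta*beta}, deletion \code{delta*G_C}, autoimmunity
#' \code{delta*G_Qphi*Y_PS}) at the suppressed level \code{delta}.
#' Immune evasions return infected cells (and their quotas) to the free
#' pool, producing the inheritance mixing terms
#' \code{G_Qp*Y_QA*(Q/P)*[Y_Q. - Y_P.]}; infections dilute infected-cell
#' quotas through the per-capita flux \code{A_V*P*V/Q}.
#'
#' The singular per-capita ratios (the infection-dilution flux
#' \code{A_V*P*V/Q} and the inheritance mixing rate
#' \code{G_Qp*Y_QA*Q/P}) are regularized by flooring the denominator at
#' \code{eps_pop} and gating the whole ratio smoothly to zero as the
#' carrier population falls below \code{pop_gate} (the extinction
#' threshold), via the C1 ramp \code{x^2/(x^2 + pop_gate^2)} -- a
#' discontinuous cutoff makes the integrator chatter whenever a dying
#' population hovers at the threshold.  The non-singular quota reactions
#' stay active, so after infected cells go extinct their formal
#' per-capita quotas relax to the acquisition/deletion balance, the
#' zero-density limit of the dynamics.
#'
#' @param state a [detailed_state()] vector (small negative solver
#'   excursions are clamped to zero for rate evaluation)
#' @param p a \code{detailed_params} object
#' @param variant one of \code{"baseline"}, \code{"no_abi"} (infected-cell
#'   autoimmunity loss removed from the Q equation; free-cell autoimmunity
#'   retained), \code{"deletion_constitutive"} (free-cell spacer deletion
#'   at full rate \code{G_C}), \code{"deletion_inverse"} (free-cell
#'   deletion at \code{G_C}, infected-cell deletion repressed to 0)
#' @param eps_pop denominator floor for the per-capita ratios
#' @param pop_gate population level below which per-capita quota fluxes
#'   are gated to zero
#' @return named numeric vector of 10 derivatives
#' @export
detailed_rhs <- function(state, p, variant = "baseline", eps_pop = 1e-12,
                         pop_gate = 1e-10) {
  stopifnot(inherits(p, "detailed_params"))
  if (any(is.na(state)))
    stop("NaN/NA in detailed-model state", call. = FALSE)
  s <- pmax(as.numeric(state), 0)
  names(s) <- .state_names_detailed
  P <- s[["P"]]; Q <- s[["Q"]]; V <- s[["V"]]; X_A <- s[["X_A"]]
  Y_QA <- s[["Y_QA"]]; Y_QI <- s[["Y_QI"]]; Y_QS <- s[["Y_QS"]]
  Y_PA <- s[["Y_PA"]]; Y_PI <- s[["Y_PI"]]; Y_PS <- s[["Y_PS"]]
  variant <- match.arg(variant, .variants)

  del_free <- switch(variant,
                     deletion_constitutive = p$G_C,
                     deletion_inverse = p$G_C,
                     p$delta * p$G_C)
  del_inf <- switch(variant, deletion_inverse = 0, p$G_C)
  abi <- if (variant == "no_abi") 0 else p$G_Qphi * Y_QS

  # smooth C1 gates on the singular per-capita ratios: -> 1 well above
  # pop_gate, -> 0 quadratically below
  gQ <- Q^2 / (Q^2 + pop_gate^2)
  gP <- P^2 / (P^2 + pop_gate^2)
  fluxQ <- gQ * p$A_V * P * V / max(Q, eps_pop)
  mixP <- gP * p$G_Qp * Y_QA * Q / max(P, eps_pop)

  c(P = p$A_P * P * (1 - P - Q) + p$G_Qp * Y_QA * Q - p$A_V * P * V -
      p$delta * p$G_Qphi * Y_PS * P,
    Q = p$A_V * P * V - (p$G_Qp * Y_QA + abi + p$G_Qv) * Q,
    V = p$G_Qv * Q - p$G_V * V - (p$A_V / p$alpha_v) * P * V,
    X_A = fluxQ * ((1 - p$mu_v) - X_A),
    Y_QA = X_A + fluxQ * (Y_PA - Y_QA) - del_inf * Y_QA,
    Y_QI = fluxQ * (Y_PI - Y_QI) - del_inf * Y_QI,
    Y_QS = p$beta + fluxQ * (Y_PS - Y_QS) - del_inf * Y_QS,
    Y_PA = p$M_V * (Y_PI - Y_PA) + mixP * (Y_QA - Y_PA) - del_free * Y_PA,
    Y_PI = p$M_V * (Y_PA - Y_PI) + mixP * (Y_QI - Y_PI) - del_free * Y_PI,
    Y_PS = p$delta * p$beta + mixP * (Y_QS - Y_PS) - del_free * Y_PS)
}

#' Phage-free fixed point of the detailed model
#'
#' With phage absent the system reduces to the free-cell population and
#' its quotas; active and inactive spacers are progressively lost while
#' the self-targeting quota equilibrates at the acquisition/deletion
#' balance.  For the baseline and \code{no_abi} variants this is
#' \code{Y_PS* = beta/G_C}; for the decoupled-deletion variants free-cell
#' deletion runs at the full rate \code{G_C}, reducing the balance to
#' \code{delta*beta/G_C}.  The free-cell level is
#' \code{P* = 1 - delta*G_Qphi*Y_PS*/A_P}, feasible only while positive
#' (the survival constraint on \code{delta}).
#'
#' The formal infected-cell self-targeting quota coordinate also carries
#' its acquisition/deletion balance \code{beta/G_C} (the zero-density
#' limit of its per-capita equation), so the returned state is an exact
#' root of [detailed_rhs()]; under \code{deletion_inverse} (no
#' infected-cell deletion) that coordinate has no equilibrium and is
#' reported as 0 with a diagnostic.
#'
#' @param p a \code{detailed_params} object
#' @param variant model variant tag
#' @return a \code{fixed_point} record with a 10-component state
#' @export
phage_free_fixed_point <- function(p, variant = "baseline") {
  stopifnot(inherits(p, "detailed_params"))
  variant <- match.arg(variant, .variants)
  del_free <- switch(variant,
                     deletion_constitutive = p$G_C,
                     deletion_inverse = p$G_C,
                     p$delta * p$G_C)
  src <- p$delta * p$beta
  if (del_free == 0) {
    if (src > 0)
      stop("no phage-free steady state: self-targeting spacers accumulate without deletion (G_C = 0)",
           call. = FALSE)
    Y_PS <- 0  # free-cell quota dynamics frozen; empty cassette assumed
  } else {
    Y_PS <- src / del_free
  }
  del_inf <- switch(variant, deletion_inverse = 0, p$G_C)
  Y_QS <- if (del_inf > 0) p$beta / del_inf else 0
  Pstar <- if (p$A_P > 0) 1 - p$delta * p$G_Qphi * Y_PS / p$A_P else 0
  state <- c(P = max(Pstar, 0), Q = 0, V = 0, X_A = 0, Y_QA = 0,
             Y_QI = 0, Y_QS = Y_QS, Y_PA = 0, Y_PI = 0, Y_PS = Y_PS)
  diag <- list(P_unclipped = Pstar, variant = variant, Y_PS_star = Y_PS)
  if (del_inf == 0 && p$beta > 0)
    diag$no_infected_quota_equilibrium <- TRUE
  .fixed_point("F", state, feasible = Pstar > 0, diagnostics = diag)
}

#' Critical free-cell activation bound
#'
#' The survival constraint of the phage-free system: hosts persist only
#' while \code{delta < A_P * G_C / (G_Qphi * beta)}, i.e. while free-cell
#' autoimmunity from the equilibrated self-targeting quota
#' \code{beta/G_C} stays below the growth rate.  Returns \code{Inf} (no
#' constraint) when \code{beta = 0} (perfect self/non-self discrimination)
#' or \code{G_Qphi = 0}.
#'
#' @param p a \code{detailed_params} object
#' @return the critical activation level (possibly \code{Inf})
#' @export
delta_max <- function(p) {
  stopifnot(inherits(p, "detailed_params"))
  if (p$beta == 0 || p$G_Qphi == 0) return(Inf)
  p$A_P * p$G_C / (p$G_Qphi * p$beta)
}

#' Reduce the detailed model to the simple model at frozen quotas
#'
#' Under equilibrated spacer levels \code{(Y_QA*, Y_QS*, Y_PS*)} the
#' population block of the detailed model is exactly the simple model with
#' the quota-dependent rates frozen into constants:
#' \code{G_Qp_eff = G_Qp*Y_QA*}, \code{G_Qphi_eff = G_Qphi*Y_QS*},
#' \code{G_Pphi_eff = G_Qphi*Y_PS*}.  The returned parameters are
#' expressed in the simple model's conventions (time unit
#' \eqn{1/(\alpha_q\Phi_p)}, phage in carrying-capacity units), i.e. every
#' detailed-model rate group is multiplied by \code{alpha_v/A_V} and the
#' phage coordinate maps as \code{V_simple = alpha_v * V_detailed}.  With
#' this mapping [simple_rhs()] on the mapped state equals the
#' \code{(P, Q, V)} block of [detailed_rhs()] at frozen quotas, up to the
#' time-unit factor stored in the \code{conversion} attribute.
#'
#' @param p a \code{detailed_params} object
#' @param quotas named numeric with elements \code{Y_QA}, \code{Y_QS},
#'   \code{Y_PS} (equilibrated quota levels, >= 0)
#' @return a \code{simple_params} object with attribute \code{conversion}
#'   (list: \code{time} = detailed-to-simple time-unit ratio
#'   \code{A_V/alpha_v}, \code{V} = phage-coordinate factor
#'   \code{alpha_v})
#' @export
reduce_to_simple <- function(p, quotas) {
  stopifnot(inherits(p, "detailed_params"))
  q <- quotas[c("Y_QA", "Y_QS", "Y_PS")]
  if (any(is.na(q)) || any(q < 0))
    stop("'quotas' must supply nonnegative Y_QA, Y_QS, Y_PS",
         call. = FALSE)
  if (p$A_V <= 0)
    stop("reduction requires A_V > 0", call. = FALSE)
  cf <- p$alpha_v / p$A_V  # alpha_c / (alpha_q * Phi_p)
  sp <- simple_params(
    A_P = cf * p$A_P,
    G_Pphi = cf * p$G_Qphi * q[["Y_PS"]],
    G_Qphi = cf * p$G_Qphi * q[["Y_QS"]],
    G_Qp = cf * p$G_Qp * q[["Y_QA"]],
    G_Qv = cf * p$G_Qv,
    G_V = cf * p$G_V,
    alpha_v = p$alpha_v,
    delta = p$delta
  )
  attr(sp, "conversion") <- list(time = p$A_V / p$alpha_v, V = p$alpha_v)
  sp
}
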