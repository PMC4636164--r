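#' @useDynLib crisprcoevo, .registration = TRUE
#' @importFrom stats setNames
NULL

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single nonnegative number", name),
         call. = FALSE)
  x
}

# The biological range of the regulation scale is [0, 1] (free cells at
# most as active as infected cells); the containers allow delta > 1 so
# that bifurcation scans can cross the delta = 1 extinction line.  The
# run-spec validator enforces the biological range for user configs.
.check_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0)
    stop("'delta' must be a single nonnegative number", call. = FALSE)
  delta
}

.check_delta_strict <- function(delta) {
  .check_delta(delta)
  if (delta > 1) stop("'delta' must lie in [0, 1]", call. = FALSE)
  delta
}

#' Dimensional parameters of the simple regulated-autoimmunity model
#'
#' Container for the dimensional rate constants of the three-variable
#' prokaryote-phage model with a regulated autoimmunity side effect.  All
#' rates are per hour; densities are per ml.
#'
#' @param alpha_p free-cell reproduction rate (1/hr)
#' @param Phi_p environmental carrying capacity (cells/ml)
#' @param alpha_q phage adsorption rate (ml/phage/hr)
#' @param alpha_v phage burst size (dimensionless)
#' @param gamma_v phage deactivation rate (1/hr)
#' @param gamma_qp immunity rate of infected cells (1/hr)
#' @param gamma_qphi autoimmunity (abortive infection) rate of infected
#'   cells (1/hr)
#' @param gamma_pphi autoimmunity rate of free cells, applied at the
#'   suppressed level \code{delta * gamma_pphi} (1/hr)
#' @param gamma_qv lysis rate of infected cells (1/hr)
#' @param delta regulation scale for free-cell autoimmunity, in [0, 1];
#'   0 means complete repression in uninfected cells
#' @return an object of class \code{dim_simple_params}
#' @seealso [nondimensionalize_simple()], [preset()]
#' @export
simple_params_dim <- function(alpha_p, Phi_p, alpha_q, alpha_v, gamma_v,
                              gamma_qp, gamma_qphi, gamma_pphi, gamma_qv,
                              delta) {
  p <- list(
    alpha_p    = .check_nonneg(alpha_p, "alpha_p"),
    Phi_p      = .check_nonneg(Phi_p, "Phi_p"),
    alpha_q    = .check_nonneg(alpha_q, "alpha_q"),
    alpha_v    = .check_nonneg(alpha_v, "alpha_v"),
    gamma_v    = .check_nonneg(gamma_v, "gamma_v"),
    gamma_qp   = .check_nonneg(gamma_qp, "gamma_qp"),
    gamma_qphi = .check_nonneg(gamma_qphi, "gamma_qphi"),
    gamma_pphi = .check_nonneg(gamma_pphi, "gamma_pphi"),
    gamma_qv   = .check_nonneg(gamma_qv, "gamma_qv"),
    delta      = .check_delta(delta)
  )
  if (p$Phi_p <= 0) stop("'Phi_p' must be positive", call. = FALSE)
  structure(p, class = "dim_simple_params")
}

#' Nondimensional parameters of the simple model
#'
#' Parameter groups of the simple model after measuring state variables in
#' units of the carrying capacity and time in units of
#' \eqn{1/(\alpha_q \Phi_p)}: \code{A_P} is the rescaled growth rate and
#' each \code{G_x} a rescaled removal rate.  The derived total
#' infected-cell removal rate \code{G_Q = G_Qphi + G_Qp + G_Qv} is stored
#' alongside.
#'
#' @param A_P rescaled free-cell growth rate
#' @param G_Pphi rescaled free-cell autoimmunity rate
#' @param G_Qphi rescaled infected-cell autoimmunity (abortive infection)
#'   rate
#' @param G_Qp rescaled immunity (restriction) rate
#' @param G_Qv rescaled lysis rate
#' @param G_V rescaled phage deactivation rate
#' @param alpha_v phage burst size
#' @param delta free-cell regulation scale in [0, 1]
#' @return an object of class \code{simple_params}
#' @export
simple_params <- function(A_P, G_Pphi, G_Qphi, G_Qp, G_Qv, G_V, alpha_v,
                          delta) {
  p <- list(
    A_P     = .check_nonneg(A_P, "A_P"),
    G_Pphi  = .check_nonneg(G_Pphi, "G_Pphi"),
    G_Qphi  = .check_nonneg(G_Qphi, "G_Qphi"),
    G_Qp    = .check_nonneg(G_Qp, "G_Qp"),
    G_Qv    = .check_nonneg(G_Qv, "G_Qv"),
    G_V     = .check_nonneg(G_V, "G_V"),
    alpha_v = .check_nonneg(alpha_v, "alpha_v"),
    delta   = .check_delta(delta)
  )
  p$G_Q <- p$G_Qphi + p$G_Qp + p$G_Qv
  structure(p, class = "simple_params")
}

#' Dimensional parameters of the detailed CRISPR model
#'
#' Container for the dimensional constants of the ten-variable model with
#' explicit spacer-quota kinetics.  Immunity and autoimmunity rates are per
#' spacer per cell; \code{alpha_c}/\code{gamma_c} are the spacer
#' acquisition/deletion rates of infected cells, and free-cell CRISPR
#' reactions run at the suppressed level \code{delta} relative to infected
#' cells.
#'
#' @inheritParams simple_params_dim
#' @param gamma_qp immunity rate per active spacer per infected cell
#'   ((spacers/cell)^-1/hr)
#' @param gamma_qphi autoimmunity rate per self-targeting spacer
#'   ((spacers/cell)^-1/hr)
#' @param alpha_c spacer acquisition rate in infected cells (1/hr)
#' @param gamma_c spacer deletion rate in infected cells (1/hr)
#' @param pi_v protospacers per phage genome
#' @param beta host-to-phage protospacer ratio (the host genome carries
#'   \code{beta * pi_v} self-targeting protospacers); \code{beta = 0}
#'   corresponds to perfect self/non-self discrimination
#' @param mu_v phage mutation rate per protospacer
#' @return an object of class \code{dim_detailed_params}
#' @export
detailed_params_dim <- function(alpha_p, Phi_p, alpha_q, alpha_v, gamma_v,
                                gamma_qp, gamma_qphi, gamma_qv, alpha_c,
                                gamma_c, pi_v, beta, mu_v, delta) {
  p <- list(
    alpha_p    = .check_nonneg(alpha_p, "alpha_p"),
    Phi_p      = .check_nonneg(Phi_p, "Phi_p"),
    alpha_q    = .check_nonneg(alpha_q, "alpha_q"),
    alpha_v    = .check_nonneg(alpha_v, "alpha_v"),
    gamma_v    = .check_nonneg(gamma_v, "gamma_v"),
    gamma_qp   = .check_nonneg(gamma_qp, "gamma_qp"),
    gamma_qphi = .check_nonneg(gamma_qphi, "gamma_qphi"),
    gamma_qv   = .check_nonneg(gamma_qv, "gamma_qv"),
    alpha_c    = .check_nonneg(alpha_c, "alpha_c"),
    gamma_c    = .check_nonneg(gamma_c, "gamma_c"),
    pi_v       = .check_nonneg(pi_v, "pi_v"),
    beta       = .check_nonneg(beta, "beta"),
    mu_v       = .check_nonneg(mu_v, "mu_v"),
    delta      = .check_delta(delta)
  )
  if (p$Phi_p <= 0) stop("'Phi_p' must be positive", call. = FALSE)
  if (p$pi_v <= 0) stop("'pi_v' must be positive", call. = FALSE)
  if (p$mu_v >= 1) stop("'mu_v' must be below 1", call. = FALSE)
  structure(p, class = "dim_detailed_params")
}

#' Nondimensional parameters of the detailed model
#'
#' Parameter groups of the detailed model after measuring cell densities in
#' units of the carrying capacity, phage density in units of
#' \eqn{\alpha_v \Phi_p}, spacer quotas in units of \eqn{\pi_v}, and time
#' in units of the spacer acquisition time \eqn{1/\alpha_c} (CRISPR
#' evolutionary time).
#'
#' @param A_P rescaled growth rate, \code{alpha_p / alpha_c}
#' @param A_V rescaled infection coupling,
#'   \code{alpha_v * alpha_q * Phi_p / alpha_c}
#' @param G_Qp rescaled per-active-spacer immunity rate,
#'   \code{gamma_qp * pi_v / alpha_c}
#' @param G_Qphi rescaled per-self-targeting-spacer autoimmunity rate,
#'   \code{gamma_qphi * pi_v / alpha_c}
#' @param G_Qv rescaled lysis rate
#' @param G_V rescaled phage deactivation rate
#' @param G_C spacer deletion-to-acquisition rate ratio
#' @param M_V rescaled spacer inactivation (PAM mutation) flux; defaults to
#'   \code{mu_v / alpha_c} in [nondimensionalize_detailed()]
#' @param beta host-to-phage protospacer ratio
#' @param delta free-cell regulation scale in [0, 1]
#' @param mu_v phage mutation rate per protospacer
#' @param alpha_v phage burst size (appears explicitly in the adsorption
#'   sink of the phage equation)
#' @return an object of class \code{detailed_params}
#' @export
detailed_params <- function(A_P, A_V, G_Qp, G_Qphi, G_Qv, G_V, G_C, M_V,
                            beta, delta, mu_v, alpha_v) {
  p <- list(
    A_P     = .check_nonneg(A_P, "A_P"),
    A_V     = .check_nonneg(A_V, "A_V"),
    G_Qp    = .check_nonneg(G_Qp, "G_Qp"),
    G_Qphi  = .check_nonneg(G_Qphi, "G_Qphi"),
    G_Qv    = .check_nonneg(G_Qv, "G_Qv"),
    G_V     = .check_nonneg(G_V, "G_V"),
    G_C     = .check_nonneg(G_C, "G_C"),
    M_V     = .check_nonneg(M_V, "M_V"),
    beta    = .check_nonneg(beta, "beta"),
    delta   = .check_delta(delta),
    mu_v    = .check_nonneg(mu_v, "mu_v"),
    alpha_v = .check_nonneg(alpha_v, "alpha_v")
  )
  if (p$mu_v >= 1) stop("'mu_v' must be below 1", call. = FALSE)
  structure(p, class = "detailed_params")
}

#' Nondimensionalize the simple model
#'
#' Converts dimensional rates to the nondimensional groups of the simple
#' model: \code{A_P = alpha_p / (alpha_q * Phi_p)} and each
#' \code{G_x = gamma_x / (alpha_q * Phi_p)}; the burst size and
#' \code{delta} pass through unchanged.  The time/density scales are kept
#' as attributes so [redimensionalize_simple()] round-trips exactly.
#'
#' @param p a \code{dim_simple_params} object
#' @return a \code{simple_params} object with attribute \code{scales}
#' @export
nondimensionalize_simple <- function(p) {
  stopifnot(inherits(p, "dim_simple_params"))
  s <- p$alpha_q * p$Phi_p
  if (s == 0) stop("degenerate time scale: alpha_q * Phi_p = 0",
                   call. = FALSE)
  np <- simple_params(
    A_P = p$alpha_p / s, G_Pphi = p$gamma_pphi / s,
    G_Qphi = p$gamma_qphi / s, G_Qp = p$gamma_qp / s,
    G_Qv = p$gamma_qv / s, G_V = p$gamma_v / s,
    alpha_v = p$alpha_v, delta = p$delta
  )
  attr(np, "scales") <- list(alpha_q = p$alpha_q, Phi_p = p$Phi_p)
  np
}

#' Recover dimensional simple-model parameters
#'
#' Inverse of [nondimensionalize_simple()].  Scales default to those stored
#' on the nondimensional object.
#'
#' @param np a \code{simple_params} object
#' @param alpha_q,Phi_p the dimensional scales to restore
#' @return a \code{dim_simple_params} object
#' @export
redimensionalize_simple <- function(np, alpha_q = NULL, Phi_p = NULL) {
  stopifnot(inherits(np, "simple_params"))
  sc <- attr(np, "scales")
  if (is.null(alpha_q)) alpha_q <- sc$alpha_q
  if (is.null(Phi_p)) Phi_p <- sc$Phi_p
  if (is.null(alpha_q) || is.null(Phi_p))
    stop("dimensional scales 'alpha_q' and 'Phi_p' are required",
         call. = FALSE)
  s <- alpha_q * Phi_p
  simple_params_dim(
    alpha_p = np$A_P * s, Phi_p = Phi_p, alpha_q = alpha_q,
    alpha_v = np$alpha_v, gamma_v = np$G_V * s,
    gamma_qp = np$G_Qp * s, gamma_qphi = np$G_Qphi * s,
    gamma_pphi = np$G_Pphi * s, gamma_qv = np$G_Qv * s, delta = np$delta
  )
}

#' Nondimensionalize the detailed model
#'
#' Converts dimensional rates to the nondimensional groups of the detailed
#' model on the CRISPR evolutionary time scale \eqn{1/\alpha_c}:
#' \code{A_V = alpha_v * alpha_q * Phi_p / alpha_c},
#' \code{G_Qp = gamma_qp * pi_v / alpha_c} (and likewise \code{G_Qphi};
#' the per-cell immunity rate \code{gamma_qp * y_qA} with quotas measured
#' in units of \code{pi_v} forces this grouping), and the remaining rates
#' divided by \code{alpha_c}.  The spacer-inactivation flux defaults to
#' \code{M_V = mu_v / alpha_c} and can be overridden.
#'
#' @param p a \code{dim_detailed_params} object
#' @param M_V optional override for the rescaled inactivation flux
#' @return a \code{detailed_params} object with attribute \code{scales}
#' @export
nondimensionalize_detailed <- function(p, M_V = NULL) {
  stopifnot(inherits(p, "dim_detailed_params"))
  if (p$alpha_c == 0)
    stop("degenerate CRISPR time scale: alpha_c = 0", call. = FALSE)
  if (is.null(M_V)) M_V <- p$mu_v / p$alpha_c
  np <- detailed_params(
    A_P = p$alpha_p / p$alpha_c,
    A_V = p$alpha_v * p$alpha_q * p$Phi_p / p$alpha_c,
    G_Qp = p$gamma_qp * p$pi_v / p$alpha_c,
    G_Qphi = p$gamma_qphi * p$pi_v / p$alpha_c,
    G_Qv = p$gamma_qv / p$alpha_c,
    G_V = p$gamma_v / p$alpha_c,
    G_C = p$gamma_c / p$alpha_c,
    M_V = M_V,
    beta = p$beta, delta = p$delta, mu_v = p$mu_v, alpha_v = p$alpha_v
  )
  attr(np, "scales") <- list(alpha_q = p$alpha_q, Phi_p = p$Phi_p,
                             alpha_c = p$alpha_c, pi_v = p$pi_v)
  np
}

#' Recover dimensional detailed-model parameters
#'
#' Inverse of [nondimensionalize_detailed()] (for the default definition of
#' \code{M_V}).
#'
#' @param np a \code{detailed_params} object
#' @param alpha_q,Phi_p,alpha_c,pi_v the dimensional scales to restore
#' @return a \code{dim_detailed_params} object
#' @export
redimensionalize_detailed <- function(np, alpha_q = NULL, Phi_p = NULL,
                                      alpha_c = NULL, pi_v = NULL) {
  stopifnot(inherits(np, "detailed_params"))
  sc <- attr(np, "scales")
  if (is.null(alpha_q)) alpha_q <- sc$alpha_q
  if (is.null(Phi_p)) Phi_p <- sc$Phi_p
  if (is.null(alpha_c)) alpha_c <- sc$alpha_c
  if (is.null(pi_v)) pi_v <- sc$pi_v
  if (is.null(alpha_q) || is.null(Phi_p) || is.null(alpha_c) ||
      is.null(pi_v))
    stop("dimensional scales are required", call. = FALSE)
  detailed_params_dim(
    alpha_p = np$A_P * alpha_c, Phi_p = Phi_p, alpha_q = alpha_q,
    alpha_v = np$alpha_v, gamma_v = np$G_V * alpha_c,
    gamma_qp = np$G_Qp * alpha_c / pi_v,
    gamma_qphi = np$G_Qphi * alpha_c / pi_v,
    gamma_qv = np$G_Qv * alpha_c, alpha_c = alpha_c,
    gamma_c = np$G_C * alpha_c, pi_v = pi_v, beta = np$beta,
    mu_v = np$mu_v, delta = np$delta
  )
}

## ---- presets --------------------------------------------------------

.presets <- function() {
  list(
    ## Bifurcation-figure parameterization of the simple model.  Only
    ## alpha_p, Phi_p, alpha_q, gamma_v and alpha_v are pinned by the
    ## source; the remaining rates are documented defaults: gamma_pphi is
    ## chosen so that G_Pphi = A_P (placing the host-extinction line at
    ## delta = 1), gamma_qp = gamma_qphi = gamma_qv = 1/hr.
    `fig1-simple` = list(
      build = function() simple_params_dim(
        alpha_p = 1, Phi_p = 1e8, alpha_q = 5e-9, alpha_v = 50,
        gamma_v = 5, gamma_qp = 1, gamma_qphi = 1, gamma_pphi = 1,
        gamma_qv = 1, delta = 0),
      varied = c("gamma_qphi", "gamma_pphi", "delta")
    ),
    ## Reference kinetics of the detailed model.  Burst size is not listed
    ## in the source table; 50 (the simple-model figure value) is the
    ## documented default.  gamma_qp is listed as the range 1e-6..1 per
    ## spacer per cell per hour; the preset uses 1.  The varied parameters
    ## get reproducible defaults: gamma_c = alpha_c (G_C = 1),
    ## gamma_qphi = gamma_qp, beta = 1, delta = 0.01.
    `table2-detailed` = list(
      build = function() detailed_params_dim(
        alpha_p = 1, Phi_p = 1e8, alpha_q = 5e-9, alpha_v = 50,
        gamma_v = 5, gamma_qp = 1, gamma_qphi = 1, gamma_qv = 1,
        alpha_c = 1e-6, gamma_c = 1e-6, pi_v = 1000, beta = 1,
        mu_v = 30e-8, delta = 0.01),
      varied = c("gamma_c", "gamma_qphi", "beta", "delta", "alpha_v")
    )
  )
}

#' Named parameter presets
#'
#' Returns a fully populated dimensional parameter record for a documented
#' preset.  Fields that the source parameterization leaves open ("varied")
#' receive documented defaults and are listed in the \code{varied}
#' attribute of the result.
#'
#' @param name one of [preset_names()]
#' @return a \code{dim_simple_params} or \code{dim_detailed_params} object
#'   with attribute \code{varied}
#' @examples
#' p <- preset("fig1-simple")
#' nondimensionalize_simple(p)$A_P  # 2
#' @export
preset <- function(name) {
  reg <- .presets()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop(sprintf("no such preset: '%s' (available: %s)",
                 paste(name, collapse = ","),
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  p <- reg[[name]]$build()
  attr(p, "varied") <- reg[[name]]$varied
  attr(p, "preset") <- name
  p
}

#' @rdname preset
#' @export
preset_names <- function() names(.presets())

#' @export
print.simple_params <- function(x, ...) {
  cat("Nondimensional simple-model parameters:\n")
  print(unlist(x[c("A_P", "G_Pphi", "G_Qphi", "G_Qp", "G_Qv", "G_V",
                   "alpha_v", "delta", "G_Q")]))
  invisible(x)
}

#' @export
print.detailed_params <- function(x, ...) {
  cat("Nondimensional detailed-model parameters:\n")
  print(unlist(x[c("A_P", "A_V", "G_Qp", "G_Qphi", "G_Qv", "G_V", "G_C",
                   "M_V", "beta", "delta", "mu_v", "alpha_v")]))
  invisible(x)
}

#' @export
print.dim_simple_params <- function(x, ...) {
  cat("Dimensional simple-model parameters (rates per hr):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.dim_detailed_params <- function(x, ...) {
  cat("Dimensional detailed-model parameters (rates per hr):\n")
  print(unlist(x))
  invisible(x)
}
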