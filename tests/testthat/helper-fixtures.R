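# shared fixtures and small utilities for the suite

fig1_params <- function(delta = 0) {
  p <- nondimensionalize_simple(preset("fig1-simple"))
  if (delta != 0) p <- crisprcoevo:::.with_param(p, "delta", delta)
  p
}

table2_params <- function(delta = NULL, beta = NULL, G_C = NULL) {
  p <- nondimensionalize_detailed(preset("table2-detailed"))
  if (!is.null(delta)) p <- crisprcoevo:::.with_param(p, "delta", delta)
  if (!is.null(beta)) p <- crisprcoevo:::.with_param(p, "beta", beta)
  if (!is.null(G_C)) p <- crisprcoevo:::.with_param(p, "G_C", G_C)
  p
}

# a simple-model parameter set deep inside the validity regime
# alpha_v*G_Qv/G_Q >> 1 of the closed-form coexistence state
validity_params <- function(delta = 0, G_Qphi = 0.5) {
  simple_params(A_P = 2, G_Pphi = 2, G_Qphi = G_Qphi, G_Qp = 0.2,
                G_Qv = 2, G_V = 10, alpha_v = 250, delta = delta)
}

random_simple_params <- function(validity_min = 0) {
  repeat {
    p <- simple_params(
      A_P = runif(1, 0.5, 4), G_Pphi = runif(1, 0.5, 4),
      G_Qphi = runif(1, 0, 2), G_Qp = runif(1, 0, 2),
      G_Qv = runif(1, 1, 5), G_V = runif(1, 2, 20),
      alpha_v = 10^runif(1, 1.7, 3.5), delta = 0)
    if (p$alpha_v * p$G_Qv / p$G_Q >= validity_min &&
        (p$G_V / p$alpha_v) * p$G_Q / p$G_Qv < 0.9)
      return(p)
  }
}

# number of connected components of a logical matrix under
# 8-connectivity (diagonal bands on a coarse grid count as contiguous)
n_components8 <- function(mask) {
  lbl <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lbl[i, j] == 0L) {
      k <- k + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        cij <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- cij[1]; b <- cij[2]
        if (a < 1 || b < 1 || a > nrow(mask) || b > ncol(mask) ||
            !mask[a, b] || lbl[a, b] > 0L) next
        lbl[a, b] <- k
        for (da in -1:1) for (db in -1:1)
          if (da != 0L || db != 0L)
            stack <- c(stack, list(c(a + da, b + db)))
      }
    }
  }
  k
}

regime_matrix <- function(map) {
  gg <- sort(attr(map, "Gc_grid"))
  matrix(map$regime, nrow = length(gg))  # rows G_C asc, cols beta asc
}
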