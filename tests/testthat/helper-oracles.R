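# Independent oracles used across the test suite. Everything here is kept
# deliberately separate from the package's own integration code paths:
# closed-form flows, matrix exponentials, and a plain-R fixed-step RK4
# pruner.

# --- constant-rate birth-death pruning with the closed-form branch flow ----
# Along a branch, with y = 1 - E and r = lambda - mu:
#   y(t) = r y0 e^{rt} / (r + lambda y0 (e^{rt} - 1))
#   D(t) = D0 e^{rt} (r / (r + lambda y0 (e^{rt} - 1)))^2
bd_flow <- function(E0, D0, lambda, mu, t) {
  r <- lambda - mu
  y0 <- 1 - E0
  ert <- exp(r * t)
  den <- r + lambda * y0 * (ert - 1)
  list(E = 1 - r * y0 * ert / den, D = D0 * ert * (r / den)^2)
}

bd_loglik_oracle <- function(phy, lambda, mu, rho, condition = TRUE) {
  po <- ape::reorder.phylo(phy, "postorder")
  n <- ape::Ntip(phy)
  E <- numeric(n + phy$Nnode)
  D <- numeric(n + phy$Nnode)
  E[1:n] <- 1 - rho
  D[1:n] <- rho
  seen <- integer(n + phy$Nnode)
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    f <- bd_flow(E[ch], D[ch], lambda, mu, po$edge.length[k])
    if (seen[pa] == 0) {
      E[pa] <- f$E
      D[pa] <- f$D
      seen[pa] <- 1
    } else {
      D[pa] <- lambda * D[pa] * f$D
      seen[pa] <- 2
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  L <- if (condition) D[root] / (lambda * (1 - E[root])^2) else D[root]
  log(L)
}

# --- symmetric k-state Mk pruning with closed-form transition probabilities
# P(stay) = 1/k + (k-1)/k e^{-k q t}; P(switch) = 1/k - 1/k e^{-k q t}
mk_loglik_oracle <- function(phy, states, q, k = 3) {
  Pt <- function(t) {
    stay <- 1 / k + (k - 1) / k * exp(-k * q * t)
    sw <- 1 / k - 1 / k * exp(-k * q * t)
    m <- matrix(sw, k, k)
    diag(m) <- stay
    m
  }
  po <- ape::reorder.phylo(phy, "postorder")
  n <- ape::Ntip(phy)
  Dm <- matrix(0, n + phy$Nnode, k)
  for (i in seq_len(n)) Dm[i, states[phy$tip.label[i]]] <- 1
  seen <- integer(n + phy$Nnode)
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    v <- Pt(po$edge.length[e]) %*% Dm[ch, ]
    if (seen[pa] == 0) {
      Dm[pa, ] <- v
      seen[pa] <- 1
    } else {
      Dm[pa, ] <- Dm[pa, ] * v
      seen[pa] <- 2
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  log(mean(Dm[root, ]))
}

# --- dense plain-R recomputation of the full hidden-state SSE likelihood ---
# Fixed-step classical RK4 on the joint E/D system, pruned in R. Used as the
# brute-force oracle on tiny trees; `h` is the step size.
sse_deriv_R <- function(y, params) {
  S <- length(params$lambda)
  E <- y[1:S]
  D <- y[S + 1:S]
  Qm <- params$Q
  qtot <- rowSums(Qm)
  dE <- params$mu - (params$lambda + params$mu + qtot) * E +
    params$lambda * E^2 + as.vector(Qm %*% E)
  dD <- -(params$lambda + params$mu + qtot) * D +
    2 * params$lambda * E * D + as.vector(Qm %*% D)
  c(dE, dD)
}

rk4_branch_R <- function(E0, D0, params, len, h = 1e-3) {
  y <- c(E0, D0)
  nstep <- max(1L, ceiling(len / h))
  dt <- len / nstep
  for (s in seq_len(nstep)) {
    k1 <- sse_deriv_R(y, params)
    k2 <- sse_deriv_R(y + dt / 2 * k1, params)
    k3 <- sse_deriv_R(y + dt / 2 * k2, params)
    k4 <- sse_deriv_R(y + dt * k3, params)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  S <- length(params$lambda)
  list(E = y[1:S], D = y[S + 1:S])
}

sse_loglik_oracle_R <- function(phy, states, params, settings, h = 1e-3) {
  S <- length(params$lambda)
  ne <- params$n_examined
  ex <- state_examined(seq_len(S), ne)
  po <- ape::reorder.phylo(phy, "postorder")
  n <- ape::Ntip(phy)
  E <- vector("list", n + phy$Nnode)
  D <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) {
    obs <- states[phy$tip.label[i]]
    E[[i]] <- 1 - settings$rho[ex]
    D[[i]] <- ifelse(ex == obs, settings$rho[obs], 0)
  }
  seen <- integer(n + phy$Nnode)
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    f <- rk4_branch_R(E[[ch]], D[[ch]], params, po$edge.length[k], h)
    if (seen[pa] == 0) {
      E[[pa]] <- f$E
      D[[pa]] <- f$D
      seen[pa] <- 1
    } else {
      E[[pa]] <- (E[[pa]] + f$E) / 2
      D[[pa]] <- params$lambda * D[[pa]] * f$D
      seen[pa] <- 2
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  Dr <- D[[root]]
  Er <- E[[root]]
  w <- switch(settings$root_weighting,
              fitzjohn = Dr / sum(Dr),
              equal = rep(1 / S, S),
              fixed = settings$root_probs)
  terms <- w * Dr
  if (settings$condition_on_survival) {
    terms <- terms / (params$lambda * (1 - Er)^2)
  }
  log(sum(terms))
}

# --- small fixture trees -----------------------------------------------
balanced4 <- function(bl = 1) {
  ape::read.tree(text = sprintf("((t1:%g,t2:%g):%g,(t3:%g,t4:%g):%g);",
                                bl, bl, bl, bl, bl, bl))
}

caterpillar4 <- function() {
  ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")
}

pectinate <- function(n) {
  phy <- ape::stree(n, "left")
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

# generating modes used throughout (the study's stated rates)
etd_mode <- function(mu = 0.001) generating_mode("ETD", c(0.1, 0.3, 0.5), mu, 0.4)
ctd_mode <- function(mu = 0.001) generating_mode("CTD", c(0.1, 0.3, 0.5), mu, 0.4)
cr_mode <- function(mu = 0.001) generating_mode("CR", 0.3, mu, 0.4)
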