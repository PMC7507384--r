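# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the BVP oracle is a dense finite-difference solve,
# the graph oracle a hand-rolled BFS, the nodal oracle a dense linear solve.

MMHG <- 1333.22
UMCM <- 1e-4
NLMIN <- 1e-6 / 60

# Finite-difference solve of u'' = a^2 u on [0, L] (CGS), Dirichlet ends.
# Returns u at n+1 grid points and the end flows -L/R u'(x) by one-sided
# second-order differences.
fd_bvp <- function(p_i, p_j, p_BS, R, R_f, L_um, n = 1e4) {
  L <- L_um * UMCM
  a2 <- if (is.finite(R_f)) R / (R_f * L^2) else 0
  h <- L / n
  # tridiagonal system for interior points: u_{k-1} - (2 + a2 h^2) u_k + u_{k+1} = 0
  d <- rep(-(2 + a2 * h^2), n - 1)
  lo <- rep(1, n - 2); up <- rep(1, n - 2)
  rhs <- numeric(n - 1)
  u0 <- (p_i - p_BS) * MMHG; un <- (p_j - p_BS) * MMHG
  rhs[1] <- -u0; rhs[n - 1] <- -un
  # Thomas algorithm
  cp <- numeric(n - 1); dp <- numeric(n - 1)
  cp[1] <- up[1] / d[1]; dp[1] <- rhs[1] / d[1]
  for (k in 2:(n - 1)) {
    m <- d[k] - lo[k - 1] * cp[k - 1]
    if (k < n - 1) cp[k] <- up[k] / m
    dp[k] <- (rhs[k] - lo[k - 1] * dp[k - 1]) / m
  }
  u <- numeric(n - 1)
  u[n - 1] <- dp[n - 1]
  for (k in (n - 2):1) u[k] <- dp[k] - cp[k] * u[k + 1]
  u <- c(u0, u, un)
  x <- seq(0, L, length.out = n + 1)
  # end flows from integral identities of the ODE (roundoff-robust, unlike
  # one-sided numerical differentiation):
  #   int_0^L Q dx = (L/R)(u0 - uL)  and  Q(x) = Q(0) - int_0^x u/(R_f L),
  # hence Q(0) = (u0 - uL)/R + int (L - s) u(s) ds / (R_f L^2)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * h)
  filt <- if (is.finite(R_f)) trap(u) / (R_f * L) else 0
  q0 <- (u0 - un) / R +
    if (is.finite(R_f)) trap((L - x) * u) / (R_f * L^2) else 0
  list(x = x, u = u,
       Q_in = q0 / NLMIN,
       Q_out = (q0 - filt) / NLMIN,
       csgfr = filt / NLMIN)
}

# Richardson-extrapolated FD end flows (removes the O(h^2) error term)
fd_bvp_rich <- function(p_i, p_j, p_BS, R, R_f, L_um, n = 5e3) {
  a <- fd_bvp(p_i, p_j, p_BS, R, R_f, L_um, n = n)
  b <- fd_bvp(p_i, p_j, p_BS, R, R_f, L_um, n = 2 * n)
  list(Q_in = (4 * b$Q_in - a$Q_in) / 3,
       Q_out = (4 * b$Q_out - a$Q_out) / 3,
       csgfr = (4 * b$csgfr - a$csgfr) / 3)
}

# brute-force BFS distances from a source node over an undirected edge list
bfs_distances <- function(edges, n_nodes, source) {
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dist <- rep(Inf, n_nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

# dense nodal analysis of a pure-resistor network: conductance matrix solve
# in u = p - p_BS with boundary conductances to u_a, u_e (all CGS)
nodal_analysis <- function(edges, R, n_nodes, inlet, outlet,
                           R_AA, R_EA, u_a, u_e) {
  G <- matrix(0, n_nodes, n_nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]; g <- 1 / R[r]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  b <- numeric(n_nodes)
  G[inlet, inlet] <- G[inlet, inlet] + 1 / R_AA
  b[inlet] <- u_a / R_AA
  G[outlet, outlet] <- G[outlet, outlet] + 1 / R_EA
  b[outlet] <- b[outlet] + u_e / R_EA
  solve(G, b)
}

# independent scalar evaluation of the published in-vitro relative viscosity
# law (written out rather than calling the package)
oracle_relative_viscosity <- function(D, Ht) {
  mu45 <- 220 * exp(-1.3 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  Cc <- (0.8 + exp(-0.075 * D)) * (-1 + 1 / (1 + 1e-11 * D^12)) +
    1 / (1 + 1e-11 * D^12)
  1 + (mu45 - 1) * ((1 - Ht)^Cc - 1) / ((1 - 0.45)^Cc - 1)
}

# independent scalar evaluation of the published phase-separation law
oracle_split_fraction <- function(fq, Da, Db, Df, Ht) {
  x0 <- 0.4 / Df
  if (fq <= x0) return(0)
  if (fq >= 1 - x0) return(1)
  A <- -6.96 * log(Da / Db) / Df
  B <- 1 + 6.98 * (1 - Ht) / Df
  z <- A + B * log(((fq - x0) / (1 - 2 * x0)) / (1 - (fq - x0) / (1 - 2 * x0)))
  1 / (1 + exp(-z))
}
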