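# Shared fixtures and independent oracles for the test suite.

# Quick structural connectome from a bare matrix.
tiny_sc <- function(W, directed = TRUE, labels = NULL, hemisphere = NULL,
                    base = NULL) {
  n <- nrow(W)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  structural_connectome(W, labels, hemisphere = hemisphere,
                        directed = directed, base = base)
}

# Quick FC network from a bare symmetric matrix.
tiny_fc <- function(M, labels = NULL, source = "empirical") {
  n <- nrow(M)
  if (is.null(labels)) labels <- sprintf("n%02d", seq_len(n))
  diag(M) <- 1
  fc_network(M, labels, source = source)
}

# Fabricated kuramoto_run carrying a given phase matrix.
fake_run <- function(theta, regions = NULL) {
  if (is.null(regions)) regions <- sprintf("n%02d", seq_len(ncol(theta)))
  R <- order_parameter(theta)
  structure(list(theta = theta, times = seq_len(nrow(theta)),
                 order_param = R, synchrony = mean(R),
                 metastability = stats::sd(R), regions = regions),
            class = "kuramoto_run")
}

# Brute-force weighted global efficiency: enumerate all simple paths per
# ordered pair, edge length = 1 / weight. Only for n <= 6.
brute_ge <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  shortest <- function(cur, target, visited, len) {
    if (cur == target) return(len)
    best <- Inf
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && W[cur, nxt] > 0) {
        v <- visited; v[nxt] <- TRUE
        best <- min(best, shortest(nxt, target, v, len + 1 / W[cur, nxt]))
      }
    }
    best
  }
  tot <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    vis <- rep(FALSE, n); vis[a] <- TRUE
    d <- shortest(a, b, vis, 0)
    if (is.finite(d)) tot <- tot + 1 / d
  }
  tot / (n * (n - 1))
}

# Reference dense matrix exponential for the oracles.
expm_ref <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# Discretized brute-force minimum-energy control: zero-order-hold
# discretization at n_steps, minimum-norm least squares for the stacked
# input, energy = h * sum of squares. Independent of the Gramian route.
brute_force_energy <- function(A, x0, xT, horizon = 1, n_steps = 2000) {
  n <- nrow(A)
  h <- horizon / n_steps
  Ad <- expm_ref(A * h)
  Bd <- solve(A, Ad - diag(n))
  blocks <- vector("list", n_steps)
  Mk <- diag(n)
  for (k in n_steps:1) {
    blocks[[k]] <- Mk %*% Bd
    Mk <- Ad %*% Mk
  }
  G <- do.call(cbind, blocks)            # x_N = Mk x0 + G u_stack
  v <- xT - drop(Mk %*% x0)
  u <- drop(t(G) %*% solve(G %*% t(G), v))
  U <- matrix(u, nrow = n)               # node by time
  list(energy = h * rowSums(U^2), total = h * sum(u^2))
}

# Deterministic stable random system for control tests.
random_stable_system <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  diag(W) <- 0
  A <- stabilize(W)
  x0 <- stats::rnorm(n)
  xT <- stats::rnorm(n)
  list(A = A, x0 = x0, xT = xT)
}
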