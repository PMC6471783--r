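# Independent brute-force maximiser of the binomial log-likelihood:
# cyclic coordinate search with stats::optimize() per coordinate. Shares no
# code path with the package's IRLS.
brute_force_logit <- function(X, events, deliveries, sweeps = 80,
                              half_width = 15) {
  ll <- function(beta) {
    p <- stats::plogis(drop(X %*% beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(stats::dbinom(events, deliveries, p, log = TRUE))
  }
  beta <- numeric(ncol(X))
  for (s in seq_len(sweeps)) {
    for (j in seq_len(ncol(X))) {
      f <- function(b) { bb <- beta; bb[j] <- b; -ll(bb) }
      opt <- stats::optimize(f, beta[j] + c(-half_width, half_width),
                             tol = 1e-10)
      beta[j] <- opt$minimum
    }
  }
  beta
}

# three-cluster measures fixture with one missing reach measure for B
toy_measures <- function() {
  data.frame(
    cluster_id = rep(c("A", "B", "C"), times = 4),
    measure_name = rep(c("f1", "f2", "r1", "a1"), each = 3),
    domain = rep(c("fidelity", "fidelity", "reach", "adoption"), each = 3),
    direction = "higher_is_better",
    value = c(10, 20, 30,   # f1: C best
              3, 2, 1,      # f2: A best
              0.5, NA, 0.9, # r1: B missing
              1, 5, 3),     # a1: B best
    stringsAsFactors = FALSE)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "swpeval")
  stopifnot(nzchar(path))
  path
}

# deterministic cluster-period table with constant event rate
flat_cells <- function(p = 0.05, deliveries = 1000, n_clusters = 4,
                       n_periods = 6) {
  d <- generate_design(n_clusters, 2, n_periods %/% 3, seed = 1)
  cells <- design_lattice(d)
  cells$deliveries <- deliveries
  cells$events <- round(deliveries * p)
  cells
}
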