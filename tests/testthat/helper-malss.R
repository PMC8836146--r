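# Shared fixture builders for the test suite. Everything is generated in
# code; no fixture files.

# A tiny hand-written protein set: the worked three-segment example plus a
# few companions covering distinct segment counts and location labels.
tiny_proteins <- function() {
  protein_records(
    accession = c("P1", "P2", "P3", "P4"),
    seq_length = c(100L, 60L, 40L, 150L),
    segments = list(c(29L, 15L, 20L), c(10L, 10L), c(7L), c(12L, 9L, 14L, 5L)),
    kinds = list(c("H", "E", "H"), c("H", "H"), c("E"), c("H", "E", "H", "E")),
    locations = list("Cell membrane", c("Cytoplasm", "Nucleus"), character(0), "Cytoplasm")
  )
}

# Bins simulated directly at the bin level: y_bar_j = f(x_j) + eps_j with
# eps_j ~ N(0, sigma^2 / w_j), weights w = n * x from a right-skewed n.
simulate_bins <- function(model_id, params, n_bins = 100, sigma = 8, seed = 1L) {
  set.seed(seed)
  x <- seq_len(n_bins)
  n <- pmax(1L, round(3000 * x^(-1.6)))
  w <- n * x
  mu <- eval_model(model_id, params, x)
  y <- mu + stats::rnorm(n_bins, sd = sigma / sqrt(w))
  y <- pmax(y, 0.5)  # bin means must stay positive
  tibble::tibble(x = as.integer(x), n = as.integer(n),
                 total_segments = as.integer(w),
                 total_residues = y * w, y_bar = y, weight = as.numeric(w))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate every size-n subset of N items of which M carry the feature and
# count subsets with at least x carriers. Only usable for small N.
hyper_tail_enum <- function(x, n, M, N) {
  if (x <= 0) return(1)
  if (n == 0) return(0)
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= M)  # items 1..M carry the feature
  mean(hits >= x)
}

# Grid-search oracle for the two-parameter power law: iteratively refined
# exhaustive search over (a, b), independent of the Gauss-Newton path.
grid_fit_model2 <- function(bins, weighted = TRUE) {
  w <- if (weighted) bins$weight else rep(1, nrow(bins))
  sse <- function(a, b) sum(w * (bins$y_bar - a * bins$x^b)^2)
  a_rng <- c(1, 40); b_rng <- c(-1.5, 0.5)
  steps <- c(0.1, 0.01, 1e-3, 1e-4)
  best <- c(a = mean(a_rng), b = mean(b_rng))
  for (st in steps) {
    a_grid <- seq(a_rng[1], a_rng[2], by = st)
    b_grid <- seq(b_rng[1], b_rng[2], by = st)
    obj <- outer(a_grid, b_grid, Vectorize(sse))
    idx <- arrayInd(which.min(obj), dim(obj))
    best <- c(a = a_grid[idx[1]], b = b_grid[idx[2]])
    # generous window: the (a, b) objective has a long correlated valley
    a_rng <- best[["a"]] + c(-30, 30) * st
    b_rng <- best[["b"]] + c(-30, 30) * st
  }
  best
}
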