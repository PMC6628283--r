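# Independent oracles used across the suite. Everything here is written
# against the mathematical definitions, never against the package internals.

# membership of a triangle/trapezoid, evaluated from raw breakpoints
oracle_degree <- function(shape, params, x) {
  if (shape == "trimf") params <- c(params[1], params[2], params[2], params[3])
  a <- params[1]; b <- params[2]; c2 <- params[3]; d <- params[4]
  vapply(x, function(z) {
    if (z >= b && z <= c2) return(1)
    if (z > a && z < b) return((z - a) / (b - a))
    if (z > c2 && z < d) return((d - z) / (d - c2))
    0
  }, numeric(1))
}

# brute-force Mamdani inference for a single-output system: evaluates the
# aggregated membership analytically from the MF parameters and integrates
# numerator/denominator by the midpoint rule on a grid `factor` times finer
# than the system resolution (midpoint cells aligned so every kink of the
# sampled aggregate falls on a cell edge).
oracle_aggregate_mu <- function(system, xrow, z) {
  mu <- rep(0, length(z))
  out_mfs <- system$outputs[[1]]$mfs
  for (r in system$rules) {
    degs <- numeric(0)
    for (j in seq_along(system$inputs)) {
      if (r$antecedent[j] == 0) next
      m <- system$inputs[[j]]$mfs[[r$antecedent[j]]]
      v <- system$inputs[[j]]
      xj <- min(max(xrow[j], v$range[1]), v$range[2])
      degs <- c(degs, oracle_degree(m$shape, m$params, xj))
    }
    s <- r$weight * (if (r$connector == "and") min(degs) else max(degs))
    cm <- out_mfs[[r$consequent[1]]]
    mu <- pmax(mu, pmin(s, oracle_degree(cm$shape, cm$params, z)))
  }
  mu
}

oracle_infer_centroid <- function(system, xrow, factor = 10) {
  v <- system$outputs[[1]]
  n_cells <- factor * (system$resolution - 1)
  h <- diff(v$range) / n_cells
  mid <- v$range[1] + (seq_len(n_cells) - 0.5) * h
  mu <- oracle_aggregate_mu(system, xrow, mid)
  sum(mu * mid) / sum(mu)
}

# midpoint-rule centroid of the piecewise-linear interpolant of (grid, mu),
# integrated on a 10x finer mesh whose cell edges contain every grid node
oracle_centroid_of_samples <- function(grid, mu, factor = 10) {
  n_cells <- factor * (length(grid) - 1)
  h <- (grid[length(grid)] - grid[1]) / n_cells
  mid <- grid[1] + (seq_len(n_cells) - 0.5) * h
  mu_f <- stats::approx(grid, mu, xout = mid)$y
  sum(mu_f * mid) / sum(mu_f)
}

# exhaustive minimum within-cluster sum of squares over contiguous
# partitions of sorted 1-D data (global optimum; small n only)
oracle_best_partition <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  wss <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- NULL; best_cost <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    groups <- lapply(seq_len(k), function(i) x[(bounds[i] + 1):bounds[i + 1]])
    cost <- sum(vapply(groups, wss, numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best <- groups }
  }
  list(groups = best, cost = best_cost)
}

# O(n^2) pairwise Mann-Whitney AUC
oracle_pairwise_auc <- function(truth, scores, positive) {
  ps <- scores[truth == positive]
  ns <- scores[truth != positive]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# random single-output Mamdani system for round-trip and property tests
random_system <- function(seed, resolution = 301L) {
  withr::with_seed(seed, {
    n_in <- sample(1:3, 1)
    make_var <- function(name) {
      k <- sample(2:4, 1)
      # Ruspini-style family from sorted breakpoints
      bp <- sort(stats::runif(2 * k, 0, 10))
      mfs <- lapply(seq_len(k), function(i) {
        b <- bp[2 * i - 1]; c2 <- bp[2 * i]
        a <- if (i == 1) b else bp[2 * (i - 1)]
        d <- if (i == k) c2 else bp[2 * i + 1]
        fz_trapmf(a, b, c2, d, label = paste0("MF", i))
      })
      fz_variable(name, bp[1], bp[2 * k], mfs)
    }
    inputs <- lapply(seq_len(n_in), function(i) make_var(paste0("x", i)))
    output <- make_var("y")
    n_rules <- sample(2:5, 1)
    rules <- lapply(seq_len(n_rules), function(r) {
      fz_rule(
        antecedent = vapply(inputs, function(v) sample(seq_along(v$mfs), 1),
                            numeric(1)),
        consequent = sample(seq_along(output$mfs), 1),
        weight = sample(c(1, 1, 0.5), 1),
        connector = sample(c("and", "or"), 1)
      )
    })
    fz_system(inputs, output = list(output), rules,
              name = paste0("rand", seed), resolution = resolution)
  })
}

random_probes <- function(system, n, seed) {
  withr::with_seed(seed, {
    X <- vapply(system$inputs, function(v) {
      stats::runif(n, v$range[1] - 1, v$range[2] + 1)
    }, numeric(n))
    as.data.frame(X)
  })
}

# tiny perfectly separable two-feature table: feature levels predict class
toy_separable <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    class <- rep(1:2, length.out = n)
    f1 <- ifelse(class == 1, stats::runif(n, 1, 2), stats::runif(n, 8, 9))
    f2 <- ifelse(class == 1, stats::runif(n, 10, 12), stats::runif(n, 30, 33))
    tibble::tibble(f1 = f1, f2 = f2, class = class)
  })
}
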