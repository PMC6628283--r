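make_two_rule_system <- function(resolution = 1001L) {
  inputs <- list(
    fz_variable("x1", 0, 10, list(fz_trapmf(0, 0, 3, 5, label = "lo"),
                                  fz_trapmf(3, 5, 10, 10, label = "hi"))),
    fz_variable("x2", 0, 10, list(fz_trapmf(0, 0, 3, 5, label = "lo"),
                                  fz_trapmf(3, 5, 10, 10, label = "hi")))
  )
  output <- fz_variable("y", 0, 4, list(fz_trimf(0, 1, 2, label = "low"),
                                        fz_trimf(2, 3, 4, label = "high")))
  rules <- list(fz_rule(c(1, 1), 1), fz_rule(c(2, 2), 2))
  fz_system(inputs, list(output), rules, resolution = resolution)
}

test_that("rule firing strength is weight times min (AND) or max (OR)", {
  sys <- make_two_rule_system()
  # degrees at x = (1, 4): MF1 -> (1, 0.5)
  r_and <- fz_rule(c(1, 1), 1)
  expect_equal(rule_fire_strength(sys, r_and, c(1, 4)), 0.5)
  r_or <- fz_rule(c(1, 1), 1, connector = "or")
  expect_equal(rule_fire_strength(sys, r_or, c(1, 4)), 1)
  r_w <- fz_rule(c(1, 1), 1, weight = 0.5)
  expect_equal(rule_fire_strength(sys, r_w, c(1, 4)), 0.25)
  # three-degree spot check on a 3-input system: min(0.8, 0.3, 1) = 0.3
  v <- fz_variable("v", 0, 10, list(fz_trapmf(0, 0, 5, 10)))
  sys3 <- fz_system(list(v, v, v), list(sys$outputs[[1]]),
                    list(fz_rule(c(1, 1, 1), 1)))
  x <- c(9, 9.65, 2) # degrees 0.2, 0.07, 1
  expect_equal(rule_fire_strength(sys3, sys3$rules[[1]], x), 0.07)
  expect_error(rule_fire_strength(sys, r_and, c(1, 2, 3)), "input values")
})

test_that("centroid defuzzification handles symmetric and closed-form shapes", {
  grid <- seq(0, 2, length.out = 1001)
  tri <- pmax(0, 1 - abs(grid - 1))
  expect_equal(defuzzify(grid, tri, "centroid"), 1)
  grid4 <- seq(0, 4, length.out = 1001)
  flat <- rep(1, 1001)
  expect_equal(defuzzify(grid4, flat, "centroid"), 2)
  expect_equal(defuzzify(grid4, flat, "som"), 0)
  expect_equal(defuzzify(grid4, flat, "lom"), 4)
  expect_equal(defuzzify(grid4, flat, "mom"), 2)
  # mu(x) = x on [0, 1]: closed form integral ratio = 2/3
  g <- seq(0, 1, length.out = 1001)
  expect_equal(defuzzify(g, g, "centroid"), 2 / 3, tolerance = 1e-6)
  expect_error(defuzzify(g, rep(0, length(g)), "centroid"),
               class = "fuzzydx_no_rule_fired")
  expect_error(defuzzify(c(0, 0, 1), c(0, 1, 0), "centroid"),
               "strictly increasing")
})

test_that("centroid matches a 10x-resolution integration oracle on random aggregates", {
  worst <- 0
  for (seed in 1:60) {
    agg <- withr::with_seed(seed, {
      lo <- stats::runif(1, -5, 0); hi <- lo + stats::runif(1, 1, 10)
      grid <- seq(lo, hi, length.out = 501)
      mu <- rep(0, length(grid))
      for (i in seq_len(sample(1:4, 1))) {
        p <- sort(stats::runif(4, lo, hi)); s <- stats::runif(1)
        mu <- pmax(mu, pmin(s, oracle_degree("trapmf", p, grid)))
      }
      list(grid = grid, mu = mu)
    })
    if (sum(agg$mu) == 0) next
    got <- defuzzify(agg$grid, agg$mu, "centroid")
    want <- oracle_centroid_of_samples(agg$grid, agg$mu, factor = 10)
    worst <- max(worst, abs(got - want) / diff(range(agg$grid)))
  }
  expect_lt(worst, 1e-6)
})

test_that("inference returns consequent centroids for simple rule firings", {
  sys <- make_two_rule_system()
  # x deep inside both 'lo' plateaus: only rule 1 fires, at strength 1
  out <- fis_infer(sys, data.frame(x1 = 1, x2 = 1))
  expect_equal(out$y, 1, tolerance = 1e-9)   # symmetric triangle at 1
  expect_true(out$fired)
  # both rules firing equally: aggregate symmetric about 2
  mid <- fis_infer(sys, data.frame(x1 = 4, x2 = 4))
  expect_equal(mid$y, 2, tolerance = 1e-9)
})

test_that("inference agrees with a brute-force Riemann oracle on staggered systems", {
  output <- fz_variable("y", 0, 10,
                        list(fz_trapmf(0, 0, 2, 4, label = "a"),
                             fz_trapmf(2, 4, 6, 8, label = "b"),
                             fz_trapmf(6, 8, 10, 10, label = "c")))
  input <- fz_variable("x", 0, 1, list(
    fz_trimf(0, 0, 1, label = "l"), fz_trimf(0, 0.5, 1, label = "m"),
    fz_trimf(0, 1, 1, label = "h")))
  sys <- fz_system(list(input), list(output),
                   list(fz_rule(1, 1), fz_rule(2, 2), fz_rule(3, 3)),
                   resolution = 1001L)
  for (x in c(0.2, 0.35, 0.5, 0.8)) {
    got <- fis_infer(sys, data.frame(x = x))$y
    want <- oracle_infer_centroid(sys, x, factor = 10)
    expect_lt(abs(got - want) / 10, 1e-6)
  }
  # and on random systems/probes (rows that fire at least one rule)
  for (seed in 1:5) {
    sys <- random_system(seed, resolution = 2001L)
    X <- random_probes(sys, 5, seed + 10)
    inf <- fis_infer(sys, X)
    keep <- which(inf$fired)
    want <- vapply(keep, function(i) {
      oracle_infer_centroid(sys, as.numeric(X[i, ]))
    }, numeric(1))
    span <- diff(sys$outputs[[1]]$range)
    expect_lt(max(abs(inf$y[keep] - want) / span), 1e-6)
  }
})

test_that("inference is deterministic and translation-equivariant", {
  sys <- make_two_rule_system()
  X <- data.frame(x1 = c(1, 4, 7), x2 = c(2, 5, 9))
  expect_identical(fis_infer(sys, X), fis_infer(sys, X))
  # shift every output MF and the range by delta: centroid shifts by delta
  delta <- 3.7
  shifted_out <- fz_variable("y", 0 + delta, 4 + delta,
                             list(fz_trimf(0 + delta, 1 + delta, 2 + delta),
                                  fz_trimf(2 + delta, 3 + delta, 4 + delta)))
  sys_shift <- fz_system(sys$inputs, list(shifted_out), sys$rules)
  expect_equal(fis_infer(sys_shift, X)$y, fis_infer(sys, X)$y + delta,
               tolerance = 1e-9)
})

test_that("rows firing no rule fall back to the output midpoint and are flagged", {
  # single rule that cannot fire at x = 10 (degree 0 for 'lo')
  inputs <- list(fz_variable("x", 0, 10, list(fz_trimf(0, 0, 5, label = "lo"),
                                              fz_trimf(5, 10, 10, label = "hi"))))
  output <- fz_variable("y", 0, 4, list(fz_trimf(0, 1, 2), fz_trimf(2, 3, 4)))
  sys <- fz_system(inputs, list(output), list(fz_rule(1, 1)))
  out <- fis_infer(sys, data.frame(x = c(1, 10)))
  expect_true(out$fired[1])
  expect_false(out$fired[2])
  expect_equal(out$y[2], 2) # midpoint of [0, 4]
})

test_that("out-of-range inputs are clamped to the variable range", {
  sys <- make_two_rule_system()
  expect_equal(fis_infer(sys, data.frame(x1 = -50, x2 = -2))$y,
               fis_infer(sys, data.frame(x1 = 0, x2 = 0))$y)
})

test_that("crisp values decode to the class of the highest-degree output MF", {
  out1 <- fz_variable("y", 0, 3, list(fz_trimf(0, 1, 2), fz_trimf(1, 2, 3)))
  expect_equal(decode_class(out1, 1.1, c(1, 2)), 1)  # nearer peak 1
  expect_equal(decode_class(out1, 1.5, c(1, 2)), 1)  # exact tie -> lower index
  # plateau wins even off its peak midpoint
  out2 <- fz_variable("y", 0, 3,
                      list(fz_trimf(0, 1, 2), fz_trapmf(1, 1.8, 2.2, 3)))
  expect_equal(decode_class(out2, 1.9, c(1, 2)), 2)
  expect_equal(decode_class(out1, c(0.2, 2.9), c(1, 2)), c(1, 2)) # vectorised
  expect_error(decode_class(out1, 1, c(1, 2, 3)), "one code per")
})
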