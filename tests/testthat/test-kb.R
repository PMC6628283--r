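test_that("unique-value counting matches the pivot-table semantics", {
  expect_equal(unique_value_count(c(1, 1, 2, 3, 3, 3)), 3)
  expect_equal(unique_value_count(rep(7, 50)), 1)
  expect_equal(unique_value_count(rep(1:10, length.out = 699)), 10)
  expect_error(unique_value_count(numeric(0)), "non-empty")
})

test_that("optimal cluster count applies the rounded-square-root rule above 20", {
  # printed unique-row counts of the two breast-cancer case studies
  expect_equal(optimal_cluster_count(seq_len(110)), 10)  # BMI
  expect_equal(optimal_cluster_count(seq_len(113)), 11)  # insulin: 10.63 up
  expect_equal(optimal_cluster_count(seq_len(51)), 7)    # age: 7.14 down
  expect_equal(optimal_cluster_count(seq_len(116)), 11)
  expect_equal(optimal_cluster_count(c(0, 1:10)), 11)    # <= 20 branch
  expect_equal(optimal_cluster_count(rep(5, 9)), 2)      # minimum of two
  # property: always in [2, 20]; identity on [2, 20]
  for (u in c(1, 2, 5, 19, 20, 21, 150, 400, 441)) {
    k <- optimal_cluster_count(seq_len(u))
    expect_gte(k, 2); expect_lte(k, 20)
    if (u >= 2 && u <= 20) expect_equal(k, u)
  }
  # half-away-from-zero rounding: 420 -> sqrt = 20.49 -> 20; 930.25 edge
  expect_equal(optimal_cluster_count(seq_len(420)), 20)
})

test_that("ward clustering separates well-separated 1-D groups with canonical labels", {
  cm <- cluster_variable(c(1, 1, 1, 9, 9, 9), k = 2)
  expect_equal(cm$labels, c(1, 1, 1, 2, 2, 2))
  expect_equal(cm$summaries$min, c(1, 9))
  expect_equal(cm$summaries$max, c(1, 9))
  expect_equal(cm$summaries$n, c(3L, 3L))
  # k = number of unique values: one cluster per value, in rank order
  cm10 <- cluster_variable(sample(1:10), k = 10)
  expect_equal(cm10$k, 10)
  expect_equal(cm10$summaries$min, as.numeric(1:10))
  # k reduced with warning when distinct values are scarce
  expect_warning(cmr <- cluster_variable(c(1, 1, 2, 2), k = 3), "reducing k")
  expect_equal(cmr$k, 2)
  expect_error(cluster_variable(1:5, k = 1), "at least 2")
})

test_that("1-D ward matches the exhaustive minimum-variance contiguous partition", {
  cases <- list(
    list(values = c(1, 2, 8, 9, 20), k = 3),
    list(values = c(0, 0.5, 1, 5, 5.5, 6, 11, 12), k = 3),
    list(values = c(2, 2.2, 7, 7.1, 7.3, 15, 16, 30, 31, 32), k = 4)
  )
  for (cs in cases) {
    cm <- cluster_variable(cs$values, k = cs$k)
    got_groups <- split(cs$values, cm$labels)
    want <- oracle_best_partition(cs$values, cs$k)
    got_cost <- sum(vapply(got_groups, function(g) sum((g - mean(g))^2),
                           numeric(1)))
    expect_equal(got_cost, want$cost, tolerance = 1e-12)
  }
})

test_that("k-means clustering is seeded and canonical", {
  v <- c(rnorm(20, 0), rnorm(20, 10), rnorm(20, 25))
  a <- cluster_variable(v, k = 3, method = "kmeans", seed = 5)
  b <- cluster_variable(v, k = 3, method = "kmeans", seed = 5)
  expect_identical(a$labels, b$labels)
  expect_true(!is.unsorted(a$summaries$min))
})

test_that("membership functions from clusters form a Ruspini partition", {
  # worked example: clusters {1,1} and {2,3}
  cm <- cluster_variable(c(1, 1, 2, 3), k = 2)
  v <- mfs_from_cluster_model(cm)
  expect_equal(v$mfs[[1]]$shape, "trimf")
  expect_equal(v$mfs[[1]]$params, c(1, 1, 2))
  expect_equal(v$mfs[[2]]$shape, "trapmf")
  expect_equal(v$mfs[[2]]$params, c(1, 2, 3, 3))
  # single cluster spanning [0, 10] would be one flat trapezoid; constant
  # coverage requires >= 2 distinct values
  cm1 <- cluster_variable(c(0, 2, 10), k = 2)
  v1 <- mfs_from_cluster_model(cm1)
  expect_equal(v1$range, c(0, 10))
  # Ruspini coverage on random training columns
  for (seed in 1:20) {
    vals <- withr::with_seed(seed, {
      if (seed %% 2 == 0) sample(1:10, 60, replace = TRUE)
      else stats::rlnorm(60, 2, 0.8)
    })
    k <- withr::with_seed(seed + 1, sample(2:6, 1))
    vv <- mfs_from_cluster_model(
      suppressWarnings(cluster_variable(vals, k = k, seed = seed)))
    grid <- seq(vv$range[1], vv$range[2], length.out = 501)
    cover <- Reduce(`+`, lapply(vv$mfs, membership_degree, x = grid))
    expect_lt(max(abs(cover - 1)), 1e-9)
  }
})

test_that("rule extraction deduplicates rows and keeps both sides of contradictions", {
  # seven distinct clustered rows of a small obstetric table
  tab <- data.frame(
    i1 = c(1, 2, 3, 4, 4, 5, 6),
    i2 = c(2, 2, 4, 4, 4, 4, 3),
    i3 = c(3, 2, 3, 1, 3, 1, 2),
    i4 = c(2, 3, 1, 3, 2, 2, 2),
    i5 = c(1, 1, 2, 1, 2, 2, 2),
    out = c(2, 2, 2, 1, 1, 1, 2)
  )
  rules <- extract_rule_base(tab, n_outputs = 1)
  expect_length(rules, 7)
  expect_equal(rules[[1]]$antecedent, c(1L, 2L, 3L, 2L, 1L))
  expect_equal(rules[[1]]$consequent, 2L)
  expect_equal(rules[[1]]$weight, 1)
  expect_equal(rules[[1]]$connector, "and")
  # one row repeated 100x -> one rule
  rep_tab <- tab[rep(3, 100), ]
  expect_length(extract_rule_base(rep_tab, 1), 1)
  # contradictory antecedents: both retained with a warning...
  contra <- data.frame(a = c(1, 1, 1), b = c(2, 2, 2), out = c(1, 2, 2))
  expect_warning(both <- extract_rule_base(contra, 1), "contradictory")
  expect_length(both, 2)
  # ...unless majority resolution is requested (majority consequent wins)
  suppressWarnings(res <- extract_rule_base(contra, 1,
                                            resolve_contradictions = TRUE))
  expect_length(res, 1)
  expect_equal(res[[1]]$consequent, 2L)
  # majority tie breaks toward the lower consequent index
  tie <- data.frame(a = c(1, 1), out = c(2, 1))
  suppressWarnings(res2 <- extract_rule_base(tie, 1,
                                             resolve_contradictions = TRUE))
  expect_equal(res2[[1]]$consequent, 1L)
})

test_that("rule counts match a hash-set oracle on random clustered tables", {
  for (seed in 1:5) {
    tab <- withr::with_seed(seed, as.data.frame(
      matrix(sample(1:3, 200 * 4, replace = TRUE), 200, 4)))
    rules <- suppressWarnings(extract_rule_base(tab, n_outputs = 1))
    want <- length(unique(apply(tab, 1, paste, collapse = "|")))
    expect_length(rules, want)
  }
})

test_that("feature-subset enumeration is complete, sorted and lexicographic", {
  s92 <- enumerate_feature_subsets(9, 2)
  s93 <- enumerate_feature_subsets(9, 3)
  expect_length(s92, 36)
  expect_length(s93, 84)
  expect_equal(s92[[1]], c(1L, 2L))
  expect_equal(s92[[36]], c(8L, 9L))
  expect_true(all(vapply(s93, function(s) !is.unsorted(s), logical(1))))
  expect_false(any(duplicated(lapply(s93, paste, collapse = ","))))
  expect_equal(enumerate_feature_subsets(5, 5), list(1:5))
  expect_error(enumerate_feature_subsets(3, 4), "1 <= k <= n")
})

test_that("a separable toy yields a two-rule system with perfect training accuracy", {
  toy <- toy_separable(n = 40, seed = 3)
  kb <- build_knowledge_base(toy, "class", k_inputs = 2, k_output = 2)
  expect_length(kb$rules, 2)
  pred <- predict(kb, toy)
  expect_equal(mean(pred$.class == toy$class), 1)
  expect_equal(kb$class_codes, c(1, 2))
  # duplicated feature leaves the unique-row count unchanged
  toy_dup <- dplyr::mutate(toy, f1b = f1)
  kb_dup <- build_knowledge_base(toy_dup, "class",
                                 features = c("f1", "f1b", "f2"),
                                 k_inputs = 2, k_output = 2)
  expect_length(kb_dup$rules, 2)
})

test_that("one-row tables and degenerate inputs are handled", {
  one <- tibble::tibble(a = 1, b = 2, class = 1)
  expect_error(suppressWarnings(build_knowledge_base(one, "class")),
               "constant|zero-width")
  expect_error(build_knowledge_base(one[0, ], "class"), "empty")
  expect_error(build_knowledge_base(toy_separable(), "nope"), "not found")
})

test_that("rule count never exceeds rows or the cluster-count product", {
  for (seed in 1:5) {
    gen <- generate_fuzzy_data(n_rows = 80, n_informative = 2, n_noise = 2,
                               separation = 1, seed = seed)
    ks <- withr::with_seed(seed, sample(2:4, 4, replace = TRUE))
    kb <- suppressWarnings(
      build_knowledge_base(gen$data, "class", k_inputs = ks, k_output = 2))
    expect_lte(length(kb$rules),
               min(nrow(gen$data), prod(kb$k_inputs) * kb$k_output))
  }
})

test_that("nominal features cluster as one singleton per code", {
  df <- tibble::tibble(
    sex = rep(c(1, 2), 20),
    marker = c(rnorm(20, 0), rnorm(20, 8)),
    class = rep(c(1, 2), each = 20)
  )
  kb <- build_knowledge_base(df, "class", k_inputs = c(2, 2),
                             nominal = "sex", k_output = 2)
  cm_sex <- kb$cluster_models[[1]]
  expect_equal(cm_sex$k, 2)
  expect_equal(cm_sex$summaries$min, cm_sex$summaries$max)
  expect_equal(kb$system$inputs[[1]]$mfs[[1]]$shape, "trimf")
})

test_that("relabelling invariance: predictions depend on data, not label order", {
  toy <- toy_separable(n = 30, seed = 9)
  kb1 <- build_knowledge_base(toy, "class", k_inputs = 2, k_output = 2)
  kb2 <- build_knowledge_base(toy[rev(seq_len(nrow(toy))), ], "class",
                              k_inputs = 2, k_output = 2)
  probe <- toy[1:10, ]
  expect_equal(predict(kb1, probe)$.class, predict(kb2, probe)$.class)
})
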