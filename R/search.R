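#' Seeded random permutation of rows
#'
#' @param data Non-empty data frame.
#' @param seed Integer seed.
#' @return A tibble with the same rows in a seeded uniform random order.
#' @export
permute_rows <- function(data, seed = 1L) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) rlang::abort("`data` must be non-empty")
  idx <- withr::with_seed(seed, sample.int(nrow(data)))
  data[idx, , drop = FALSE]
}

#' Random-sampling split
#'
#' Partitions rows into disjoint, exhaustive subsets by named fractions
#' (default 70% training / 30% validation). Non-training subset sizes are the
#' rounded fractions; the training subset absorbs the remainder.
#'
#' @param data Data frame with at least 2 rows.
#' @param fractions Named numeric vector summing to 1; must include `train`.
#' @param seed Integer seed.
#' @param stratify_by Optional column name; when given, splitting is done
#'   within each class so small classes appear in every subset.
#' @return Named list of tibbles, one per fraction.
#' @export
random_split <- function(data, fractions = c(train = 0.7, validation = 0.3),
                         seed = 1L, stratify_by = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) < 2) rlang::abort("`data` must have at least 2 rows")
  if (is.null(names(fractions)) || !"train" %in% names(fractions)) {
    rlang::abort("`fractions` must be named and include 'train'")
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    rlang::abort("`fractions` must be non-negative and sum to 1")
  }
  assign_split <- function(n, seed) {
    others <- setdiff(names(fractions), "train")
    sizes <- stats::setNames(round_half_up(fractions[others] * n), others)
    sizes <- c(train = n - sum(sizes), sizes)
    idx <- withr::with_seed(seed, sample.int(n))
    rep(names(sizes), times = sizes)[order(idx)]
  }
  if (is.null(stratify_by)) {
    lab <- assign_split(nrow(data), seed)
  } else {
    lab <- character(nrow(data))
    groups <- split(seq_len(nrow(data)), data[[stratify_by]])
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      lab[g] <- assign_split(length(g), seed + gi)
    }
  }
  out <- lapply(names(fractions), function(nm) data[lab == nm, , drop = FALSE])
  names(out) <- names(fractions)
  bad <- names(fractions)[fractions > 0 & vapply(out, nrow, integer(1)) == 0]
  if (length(bad)) {
    rlang::abort(sprintf("subset '%s' received zero rows", bad[1]))
  }
  out
}

#' k-fold cross-validation partitions
#'
#' Randomly partitions rows into `k` folds of sizes differing by at most one;
#' each row serves as test data exactly once.
#'
#' @param data Data frame.
#' @param k Number of folds, `2 <= k <= nrow(data)`.
#' @param seed Integer seed.
#' @return A list of `k` elements, each `list(fold, train, test)`.
#' @export
kfold_partitions <- function(data, k = 10L, seed = 1L) {
  data <- tibble::as_tibble(data)
  k <- as.integer(k)
  n <- nrow(data)
  if (k < 2 || k > n) rlang::abort("`k` must satisfy 2 <= k <= nrow(data)")
  idx <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- rep(seq_len(k), times = sizes)[order(idx)]
  lapply(seq_len(k), function(f) {
    list(fold = f,
         train = data[fold_of != f, , drop = FALSE],
         test = data[fold_of == f, , drop = FALSE])
  })
}

#' Search configuration
#'
#' Collects the knobs of the iterative design loop. Defaults follow the
#' study conditions of the induced clinical systems: a 70/30 random-sampling
#' split or 10-fold cross-validation, at most 3000 candidate models, subset
#' sizes from two up to all features, and per-variable cluster counts swept
#' from 2 to each variable's [optimal_cluster_count()].
#'
#' @param partition `"random_sampling"` or `"cross_validation"`.
#' @param train_frac Training fraction for random sampling (validation gets
#'   the rest unless `test_frac > 0`).
#' @param test_frac Optional test fraction (default 0).
#' @param k_folds Folds for cross-validation.
#' @param max_iterations Candidate budget.
#' @param subset_sizes Integer vector of feature-subset sizes (default
#'   `2:n_features`, resolved at search time).
#' @param cluster_min Lower bound of every cluster-count sweep.
#' @param cluster_max Optional named upper bounds per feature (default each
#'   feature's [optimal_cluster_count()]).
#' @param method Clustering method: `"auto"`, `"ward"` or `"kmeans"`.
#' @param selection_metric Metric used to rank candidates (a column of
#'   [fz_metric_set()], default `"accuracy"`).
#' @param resolution Defuzzification grid size.
#' @param stratify Stratify the random split by the outcome?
#' @param resolve_contradictions Passed to [extract_rule_base()].
#' @return A list of class `fz_search_control`.
#' @export
fz_search_control <- function(partition = c("random_sampling", "cross_validation"),
                              train_frac = 0.7, test_frac = 0,
                              k_folds = 10L, max_iterations = 3000L,
                              subset_sizes = NULL, cluster_min = 2L,
                              cluster_max = NULL,
                              method = c("auto", "ward", "kmeans"),
                              selection_metric = "accuracy",
                              resolution = 1001L, stratify = FALSE,
                              resolve_contradictions = FALSE) {
  partition <- match.arg(partition)
  method <- match.arg(method)
  stopifnot(train_frac > 0, train_frac < 1, test_frac >= 0,
            train_frac + test_frac < 1, k_folds >= 2, max_iterations >= 1)
  structure(
    list(partition = partition, train_frac = train_frac, test_frac = test_frac,
         k_folds = as.integer(k_folds),
         max_iterations = as.integer(max_iterations),
         subset_sizes = subset_sizes, cluster_min = as.integer(cluster_min),
         cluster_max = cluster_max, method = method,
         selection_metric = selection_metric,
         resolution = as.integer(resolution), stratify = stratify,
         resolve_contradictions = resolve_contradictions),
    class = "fz_search_control"
  )
}

# deterministic candidate stream for one subset size: list of
# list(subset = int vector, ks = int vector). Candidates are ordered by
# ascending cluster-count product (expected rule-base complexity), with a
# seeded shuffle inside each complexity stratum, so the budget is spent on
# parsimonious systems first. Enumerated exhaustively when the grid is small;
# sampled uniformly (seeded) when it explodes.
candidate_stream <- function(subsets, kmax_by_feature, cluster_min, seed,
                             cap = 50000L) {
  combos_per_subset <- vapply(subsets, function(s) {
    prod(pmax(kmax_by_feature[s] - cluster_min + 1, 1))
  }, numeric(1))
  total <- sum(combos_per_subset)
  cands <- if (total <= cap) {
    out <- list()
    for (s in subsets) {
      ranges <- lapply(kmax_by_feature[s],
                       function(km) seq(cluster_min, max(km, cluster_min)))
      grid <- expand.grid(ranges, KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(grid))) {
        out[[length(out) + 1L]] <- list(subset = s, ks = as.integer(grid[i, ]))
      }
    }
    out
  } else {
    withr::with_seed(seed, {
      lapply(seq_len(cap), function(i) {
        s <- subsets[[sample.int(length(subsets), 1)]]
        ks <- vapply(kmax_by_feature[s], function(km) {
          sample(seq(cluster_min, max(km, cluster_min)), 1)
        }, numeric(1))
        list(subset = s, ks = as.integer(ks))
      })
    })
  }
  complexity <- vapply(cands, function(cd) prod(cd$ks), numeric(1))
  key <- withr::with_seed(seed, stats::runif(length(cands)))
  cands[order(complexity, key)]
}

#' Iterative search over feature subsets and cluster counts
#'
#' The design loop: rows are permuted, the data are partitioned (one 70/30
#' random-sampling split, or k-fold cross-validation), and candidate models —
#' a feature subset paired with per-feature cluster counts — are enumerated
#' in ascending subset size, then ascending cluster-count product (so the
#' budget favours parsimonious rule bases), seeded-shuffled within each
#' complexity stratum, and evaluated until the iteration budget is spent.
#' Every candidate's
#' clustering, membership ranges and rules are derived from its training rows
#' only. Candidates are ranked by the selection metric (validation-split
#' metrics for random sampling, fold averages for cross-validation).
#'
#' @param data Preprocessed data frame.
#' @param outcome Name of the class column.
#' @param features Candidate feature columns (default all others).
#' @param control An [fz_search_control()].
#' @param seed Integer seed driving the permutation, the partition, candidate
#'   shuffling and k-means restarts.
#' @param nominal Character vector of nominal feature names.
#' @return An object of class `fz_search` whose `$results` tibble holds one
#'   ranked row per evaluated candidate.
#' @export
fis_search <- function(data, outcome, features = NULL,
                       control = fz_search_control(), seed = 1L,
                       nominal = NULL) {
  stopifnot(inherits(control, "fz_search_control"))
  data <- tibble::as_tibble(data)
  if (is.null(features)) features <- setdiff(names(data), outcome)
  n_feat <- length(features)
  if (n_feat < 1) rlang::abort("no candidate features")

  data <- permute_rows(data, seed = seed)

  subset_sizes <- control$subset_sizes
  if (is.null(subset_sizes)) subset_sizes <- seq(min(2L, n_feat), n_feat)
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (any(subset_sizes < 1 | subset_sizes > n_feat)) {
    rlang::abort("`subset_sizes` out of range")
  }

  kmax <- control$cluster_max
  if (is.null(kmax)) {
    kmax <- vapply(data[features], optimal_cluster_count, integer(1))
  }
  kmax <- stats::setNames(rep_len(as.integer(kmax), n_feat), features)

  # partitions
  if (control$partition == "random_sampling") {
    fr <- c(train = control$train_frac,
            validation = 1 - control$train_frac - control$test_frac)
    if (control$test_frac > 0) fr <- c(fr, test = control$test_frac)
    sp <- random_split(data, fr, seed = seed,
                       stratify_by = if (control$stratify) outcome else NULL)
    parts <- list(list(fold = 1L, train = sp$train, test = sp$validation))
  } else {
    parts <- kfold_partitions(data, k = control$k_folds, seed = seed)
  }

  positive <- max(data[[outcome]])
  budget <- control$max_iterations
  rows <- list()
  iter <- 0L
  for (size in subset_sizes) {
    if (iter >= budget) break
    subsets <- enumerate_feature_subsets(n_feat, size)
    cands <- candidate_stream(subsets, kmax, control$cluster_min,
                              seed = seed + size)
    for (cand in cands) {
      if (iter >= budget) break
      iter <- iter + 1L
      feats <- features[cand$subset]
      fold_rows <- purrr::map_dfr(parts, function(p) {
        evaluate_candidate(p$train, p$test, outcome, feats, cand$ks,
                           control, seed, nominal, positive, p$fold)
      })
      mean_row <- fold_rows |>
        dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean)) |>
        dplyr::mutate(fold = NA_integer_)
      rows[[iter]] <- tibble::tibble(
        iteration = iter,
        size = size,
        features = paste(feats, collapse = ","),
        subset = list(cand$subset),
        ks = paste(cand$ks, collapse = ","),
        ks_vec = list(cand$ks),
        n_rules = mean_row$n_rules,
        mean_row[setdiff(names(mean_row), c("fold", "n_rules"))],
        fold_metrics = list(fold_rows)
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  metric <- control$selection_metric
  if (!metric %in% names(results)) {
    rlang::abort(sprintf("selection metric '%s' was not computed", metric))
  }
  results <- dplyr::arrange(
    results, dplyr::desc(.data[[metric]]), .data$size, .data$n_rules,
    .data$iteration
  )
  results$rank <- seq_len(nrow(results))
  structure(
    list(results = results, control = control, seed = seed,
         outcome = outcome, features = features, nominal = nominal,
         data = data, partitions = parts, positive = positive),
    class = "fz_search"
  )
}

# fit one candidate on train, score on test; returns a one-row tibble
evaluate_candidate <- function(train, test, outcome, feats, ks, control,
                               seed, nominal, positive, fold) {
  out <- tryCatch(
    evaluate_candidate_impl(train, test, outcome, feats, ks, control,
                            seed, nominal, positive, fold),
    error = function(e) {
      # e.g. a feature constant on this training split: unusable candidate
      tibble::tibble(fold = fold, n_rules = NA_real_, no_rule_count = NA_real_,
                     accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, precision = NA_real_,
                     recall = NA_real_, f_measure = NA_real_,
                     kappa = NA_real_, auc = NA_real_)
    }
  )
  out
}

evaluate_candidate_impl <- function(train, test, outcome, feats, ks, control,
                                    seed, nominal, positive, fold) {
  kb <- suppressWarnings(build_knowledge_base(
    train, outcome, features = feats, k_inputs = ks,
    method = control$method, nominal = nominal, seed = seed,
    resolution = control$resolution,
    resolve_contradictions = control$resolve_contradictions
  ))
  pred <- predict(kb, test)
  scores <- orient_scores(pred$.crisp, kb$class_codes, positive)
  ms <- suppressWarnings(
    fz_metric_set(test[[outcome]], pred$.class, scores, positive = positive)
  )
  tibble::tibble(fold = fold, n_rules = length(kb$rules),
                 no_rule_count = sum(!pred$fired),
                 ms[setdiff(names(ms), "auc_category")])
}

# crisp outputs ranked so that larger = more like the positive class
orient_scores <- function(crisp, class_codes, positive) {
  if (class_codes[which.max(class_codes)] == positive) crisp else -crisp
}

#' Pick the winning model of a search
#'
#' Selects the candidate maximising the selection metric, breaking ties by
#' fewer input variables, then fewer rules, then lower iteration index, and
#' refits it: on the training split for a random-sampling search, on the full
#' dataset for cross-validation (fold averages having already judged the
#' configuration).
#'
#' @param search An [fis_search()] result.
#' @return A list of class `fz_best`: the refitted `$kb`, the winning
#'   `$provenance` row and its `$metrics`.
#' @export
select_best <- function(search) {
  stopifnot(inherits(search, "fz_search"))
  res <- search$results
  if (nrow(res) == 0) rlang::abort("the search evaluated no candidates")
  top <- res[1, ]
  feats <- search$features[top$subset[[1]]]
  refit_data <- if (search$control$partition == "random_sampling") {
    search$partitions[[1]]$train
  } else {
    search$data
  }
  kb <- suppressWarnings(build_knowledge_base(
    refit_data, search$outcome, features = feats,
    k_inputs = top$ks_vec[[1]], method = search$control$method,
    nominal = search$nominal, seed = search$seed,
    resolution = search$control$resolution,
    resolve_contradictions = search$control$resolve_contradictions
  ))
  structure(
    list(kb = kb, provenance = top,
         metrics = top[setdiff(names(top),
                               c("subset", "ks_vec", "fold_metrics"))]),
    class = "fz_best"
  )
}

#' @export
print.fz_search <- function(x, ...) {
  cat(sprintf("<fz_search> %d candidate(s), partition=%s, ranked by %s\n",
              nrow(x$results), x$control$partition,
              x$control$selection_metric))
  print(utils::head(dplyr::select(x$results, -dplyr::any_of(
    c("subset", "ks_vec", "fold_metrics")))))
  invisible(x)
}

#' @export
print.fz_best <- function(x, ...) {
  cat("<fz_best>\n")
  print(x$kb)
  print(dplyr::select(x$provenance, -dplyr::any_of(
    c("subset", "ks_vec", "fold_metrics"))))
  invisible(x)
}

#' Tidy the ranked results of a search
#'
#' @param x An `fz_search`.
#' @param ... Unused.
#' @return The ranked results tibble without list columns.
#' @method tidy fz_search
#' @export
tidy.fz_search <- function(x, ...) {
  dplyr::select(x$results, -dplyr::any_of(c("subset", "ks_vec", "fold_metrics")))
}

#' One-row summary of a search
#'
#' @param x An `fz_search`.
#' @param ... Unused.
#' @return A tibble with the winning candidate and search bookkeeping.
#' @method glance fz_search
#' @export
glance.fz_search <- function(x, ...) {
  top <- tidy(x)[1, ]
  tibble::tibble(
    n_candidates = nrow(x$results),
    partition = x$control$partition,
    selection_metric = x$control$selection_metric,
    best_features = top$features,
    best_ks = top$ks,
    best_n_rules = top$n_rules,
    best_metric = top[[x$control$selection_metric]]
  )
}

#' Plot search progress
#'
#' Selection metric of every evaluated candidate against its iteration index,
#' coloured by subset size.
#'
#' @param object An `fz_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fz_search
#' @export
autoplot.fz_search <- function(object, ...) {
  metric <- object$control$selection_metric
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data[[metric]],
                                   colour = factor(.data$size))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "iteration", y = metric, colour = "subset size")
}
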