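#' Firing strength of a rule
#'
#' Combines the antecedent membership degrees of one rule at one crisp input
#' vector: the min over degrees for AND rules, the max for OR rules, scaled by
#' the rule weight. Antecedent index 0 marks an input the rule does not use.
#'
#' @param system An [fz_system()].
#' @param rule An [fz_rule()] compatible with the system.
#' @param x Numeric vector, one crisp value per system input (already within
#'   variable ranges; [fis_infer()] clamps for you).
#' @return A single firing strength in `[0, 1]`.
#' @export
rule_fire_strength <- function(system, rule, x) {
  stopifnot(inherits(system, "fz_system"), inherits(rule, "fz_rule"))
  if (length(x) != length(system$inputs)) {
    rlang::abort(sprintf("expected %d input values, got %d",
                         length(system$inputs), length(x)))
  }
  used <- which(rule$antecedent > 0)
  degs <- vapply(used, function(j) {
    membership_degree(system$inputs[[j]]$mfs[[rule$antecedent[j]]], x[j])
  }, numeric(1))
  if (length(degs) == 0) return(rule$weight)
  comb <- if (rule$connector == "and") min(degs) else max(degs)
  rule$weight * comb
}

# firing strengths for a whole data matrix: returns n_rows x n_rules
fire_strength_matrix <- function(system, X) {
  rm <- rule_matrices(system)
  n <- nrow(X); R <- nrow(rm$ant)
  # degree cache: per input j, per mf m
  deg <- lapply(seq_along(system$inputs), function(j) {
    v <- system$inputs[[j]]
    xj <- pmin(pmax(X[, j], v$range[1]), v$range[2])
    matrix(vapply(v$mfs, membership_degree, numeric(n), x = xj), nrow = n)
  })
  strengths <- matrix(NA_real_, n, R)
  for (r in seq_len(R)) {
    is_and <- rm$connector[r] == "and"
    acc <- rep(if (is_and) 1 else 0, n)
    for (j in seq_along(system$inputs)) {
      m <- rm$ant[r, j]
      if (m == 0) next
      dj <- deg[[j]][, m, drop = TRUE]
      acc <- if (is_and) pmin(acc, dj) else pmax(acc, dj)
    }
    strengths[, r] <- rm$weight[r] * acc
  }
  strengths
}

#' Defuzzify an aggregated output set
#'
#' Collapses a sampled fuzzy set (`grid`, `mu`) to one crisp value. The
#' centroid is the discrete centre of gravity: the ratio of the integrals
#' of `mu * z` and `mu`, both discretised by the trapezoidal rule on the
#' grid (a weighted sum with half weight at the two endpoints, exact for
#' piecewise-linear sets sampled at their breakpoints).
#' `som`/`mom`/`lom` are the smallest/mean/largest grid points attaining the
#' maximum of `mu` (within a small tolerance).
#'
#' @param grid Strictly increasing numeric vector sampling the output range.
#' @param mu Membership degrees in `[0, 1]`, same length as `grid`.
#' @param method One of `"centroid"`, `"som"`, `"mom"`, `"lom"`.
#' @return A crisp value.
#' @export
defuzzify <- function(grid, mu, method = c("centroid", "som", "mom", "lom")) {
  method <- match.arg(method)
  stopifnot(length(grid) == length(mu), length(grid) >= 2)
  if (any(diff(grid) <= 0)) rlang::abort("`grid` must be strictly increasing")
  if (any(mu < 0 | mu > 1)) rlang::abort("`mu` values must lie in [0, 1]")
  total <- sum(mu)
  if (method == "centroid") {
    if (total == 0) {
      rlang::abort("cannot take the centroid of an all-zero aggregate",
                   class = "fuzzydx_no_rule_fired")
    }
    w <- trapezoid_weights(length(grid))
    return(sum(w * mu * grid) / sum(w * mu))
  }
  if (total == 0 && method == "mom") {
    rlang::abort("cannot take the mean of maxima of an all-zero aggregate",
                 class = "fuzzydx_no_rule_fired")
  }
  peak <- max(mu)
  at_peak <- grid[mu >= peak - 1e-12]
  switch(method,
    som = min(at_peak),
    lom = max(at_peak),
    mom = mean(at_peak)
  )
}

# trapezoid-rule quadrature weights on a uniform grid (common spacing cancels
# in the centroid ratio, so only the relative endpoint halving matters)
trapezoid_weights <- function(n) c(0.5, rep(1, n - 2), 0.5)

# aggregated mu over the output grid for a batch of rows:
# strengths is n x R; returns list(grid, mu = n x G matrix)
aggregate_output <- function(system, out_index, strengths) {
  v <- system$outputs[[out_index]]
  G <- system$resolution
  grid <- seq(v$range[1], v$range[2], length.out = G)
  rm <- rule_matrices(system)
  n <- nrow(strengths)
  # consequent MF degrees on the grid, one row per rule
  cons_deg <- t(vapply(seq_len(nrow(rm$cons)), function(r) {
    membership_degree(v$mfs[[rm$cons[r, out_index]]], grid)
  }, numeric(G)))
  mu <- matrix(0, n, G)
  for (r in seq_len(nrow(cons_deg))) {
    imp <- pmin(matrix(strengths[, r], n, G),
                matrix(cons_deg[r, ], n, G, byrow = TRUE))
    mu <- pmax(mu, imp)
  }
  list(grid = grid, mu = mu)
}

#' Run Mamdani inference on crisp inputs
#'
#' For every row of `newdata`: fuzzify (with clamping to each variable's
#' range), fire all rules, clip each rule's consequent set at its firing
#' strength (min implication), superpose rules pointwise by max, and
#' defuzzify. Rows firing no rule at all fall back to the midpoint of the
#' output range and are flagged in the `fired` column.
#'
#' @param system An [fz_system()].
#' @param newdata Data frame or matrix whose first columns (matched by input
#'   variable names when present) supply one crisp value per input.
#' @return A tibble with one crisp column per output variable plus a logical
#'   `fired` column (`FALSE` where the midpoint fallback was used).
#' @export
fis_infer <- function(system, newdata) {
  stopifnot(inherits(system, "fz_system"))
  X <- as_input_matrix(system, newdata)
  strengths <- fire_strength_matrix(system, X)
  fired <- rowSums(strengths) > 0
  out <- lapply(seq_along(system$outputs), function(oi) {
    v <- system$outputs[[oi]]
    agg <- aggregate_output(system, oi, strengths)
    crisp <- rep(mean(v$range), nrow(X))
    if (system$defuzz_method == "centroid") {
      w <- trapezoid_weights(length(agg$grid))
      den <- as.vector(agg$mu %*% w)
      ok <- den > 0
      num <- as.vector(agg$mu[ok, , drop = FALSE] %*% (w * agg$grid))
      crisp[ok] <- num / den[ok]
    } else {
      for (i in which(fired)) {
        crisp[i] <- defuzzify(agg$grid, agg$mu[i, ], system$defuzz_method)
      }
    }
    crisp
  })
  names(out) <- vapply(system$outputs, `[[`, character(1), "name")
  res <- tibble::as_tibble(out)
  res$fired <- fired
  res
}

as_input_matrix <- function(system, newdata) {
  in_names <- vapply(system$inputs, `[[`, character(1), "name")
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  if (!is.data.frame(newdata)) {
    newdata <- as.data.frame(as.list(newdata), col.names = in_names)
  }
  if (all(in_names %in% names(newdata))) {
    newdata <- newdata[in_names]
  } else if (ncol(newdata) < length(in_names)) {
    rlang::abort(sprintf("`newdata` must supply %d input columns", length(in_names)))
  } else {
    newdata <- newdata[, seq_along(in_names), drop = FALSE]
  }
  X <- as.matrix(newdata)
  if (!is.numeric(X)) rlang::abort("input columns must be numeric")
  X
}

#' Decode a crisp output value to a class code
#'
#' The induced systems encode each class as one output membership function.
#' A defuzzified value is mapped back to a class by evaluating every output
#' MF at the crisp value and taking the code of the MF with the largest
#' degree; ties go to the lower MF index (the lower-coded class).
#'
#' @param output_var The output [fz_variable()].
#' @param crisp Numeric vector of defuzzified values.
#' @param class_codes Vector of class codes, one per output MF, in MF order.
#' @return Vector of class codes, same length as `crisp`.
#' @export
decode_class <- function(output_var, crisp, class_codes) {
  stopifnot(inherits(output_var, "fz_variable"))
  if (length(class_codes) != length(output_var$mfs)) {
    rlang::abort("`class_codes` must have one code per output membership function")
  }
  crisp <- pmin(pmax(crisp, output_var$range[1]), output_var$range[2])
  degs <- vapply(output_var$mfs, membership_degree, numeric(length(crisp)), x = crisp)
  if (length(crisp) == 1) degs <- matrix(degs, nrow = 1)
  class_codes[max.col(degs, ties.method = "first")]
}

#' Predict class labels from a fitted knowledge base
#'
#' Convenience wrapper: runs [fis_infer()] with the system stored in an
#' [build_knowledge_base()] fit and decodes the crisp output to class codes.
#'
#' @param object An `fz_kb` object.
#' @param newdata Data frame containing the fitted input columns.
#' @param ... Unused.
#' @return A tibble with columns `.crisp`, `.class` and `fired`.
#' @export
predict.fz_kb <- function(object, newdata, ...) {
  inf <- fis_infer(object$system, newdata)
  out_name <- object$system$outputs[[1]]$name
  tibble::tibble(
    .crisp = inf[[out_name]],
    .class = decode_class(object$system$outputs[[1]], inf[[out_name]],
                          object$class_codes),
    fired = inf$fired
  )
}
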