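#' Fuzzy IF-THEN rule
#'
#' One Mamdani rule: antecedent membership-function indices (one per system
#' input, 1-based; 0 marks an unused input), consequent indices (one per
#' output), a weight in (0, 1] and a connector. Weights and connectors default
#' to 1 and AND, the values used throughout the induced systems.
#'
#' @param antecedent Integer vector of MF indices, one per input.
#' @param consequent Integer vector of MF indices, one per output.
#' @param weight Rule weight in (0, 1].
#' @param connector `"and"` (min over antecedent degrees) or `"or"` (max).
#' @return An object of class `fz_rule`.
#' @export
fz_rule <- function(antecedent, consequent, weight = 1, connector = c("and", "or")) {
  connector <- match.arg(connector)
  antecedent <- as.integer(antecedent)
  consequent <- as.integer(consequent)
  if (any(antecedent < 0) || any(consequent < 1)) {
    rlang::abort("antecedent indices must be >= 0 and consequent indices >= 1")
  }
  if (!(is.numeric(weight) && length(weight) == 1 && weight > 0 && weight <= 1)) {
    rlang::abort("`weight` must be a single value in (0, 1]")
  }
  structure(
    list(antecedent = antecedent, consequent = consequent,
         weight = weight, connector = connector),
    class = "fz_rule"
  )
}

#' Mamdani fuzzy inference system
#'
#' Assembles variables and rules into a Mamdani system with the classical
#' min/max operator set: AND = min, OR = max, implication = min,
#' aggregation = max. Defuzzification defaults to the centroid (centre of
#' gravity) of the aggregated output set, discretised on `resolution` grid
#' points per output range.
#'
#' @param inputs,outputs Lists of [fz_variable()] objects.
#' @param rules List of [fz_rule()] objects (non-empty).
#' @param name System name.
#' @param defuzz_method One of `"centroid"`, `"som"`, `"mom"`, `"lom"`.
#' @param resolution Positive integer, grid points per output range.
#' @return An object of class `fz_system`.
#' @export
fz_system <- function(inputs, outputs, rules, name = "fis",
                      defuzz_method = c("centroid", "som", "mom", "lom"),
                      resolution = 1001L) {
  defuzz_method <- match.arg(defuzz_method)
  check_var_list <- function(vs, what) {
    if (!is.list(vs) || length(vs) == 0 ||
        !all(vapply(vs, inherits, logical(1), "fz_variable"))) {
      rlang::abort(sprintf("`%s` must be a non-empty list of fz_variable", what))
    }
  }
  check_var_list(inputs, "inputs")
  check_var_list(outputs, "outputs")
  if (!is.list(rules) || length(rules) == 0 ||
      !all(vapply(rules, inherits, logical(1), "fz_rule"))) {
    rlang::abort("`rules` must be a non-empty list of fz_rule objects")
  }
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 2L)

  n_in <- length(inputs); n_out <- length(outputs)
  n_mfs_in <- vapply(inputs, function(v) length(v$mfs), integer(1))
  n_mfs_out <- vapply(outputs, function(v) length(v$mfs), integer(1))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (length(r$antecedent) != n_in || length(r$consequent) != n_out) {
      rlang::abort(sprintf("rule %d has the wrong arity for this system", i))
    }
    if (any(r$antecedent > n_mfs_in) || any(r$consequent > n_mfs_out)) {
      rlang::abort(sprintf("rule %d references a membership function that does not exist", i))
    }
  }

  structure(
    list(name = name, inputs = inputs, outputs = outputs, rules = rules,
         and_method = "min", or_method = "max",
         imp_method = "min", agg_method = "max",
         defuzz_method = defuzz_method, resolution = resolution),
    class = "fz_system"
  )
}

#' @export
print.fz_system <- function(x, ...) {
  cat(sprintf("<fz_system> '%s': %d input(s), %d output(s), %d rule(s)\n",
              x$name, length(x$inputs), length(x$outputs), length(x$rules)))
  cat(sprintf("  operators: and=min or=max imp=min agg=max; defuzz=%s (%d pts)\n",
              x$defuzz_method, x$resolution))
  invisible(x)
}

# rule list -> integer matrices (antecedents n_rules x n_in etc.)
rule_matrices <- function(system) {
  list(
    ant = do.call(rbind, lapply(system$rules, `[[`, "antecedent")),
    cons = do.call(rbind, lapply(system$rules, `[[`, "consequent")),
    weight = vapply(system$rules, `[[`, numeric(1), "weight"),
    connector = vapply(system$rules, `[[`, character(1), "connector")
  )
}

#' Tidy a fuzzy system into a readable rule table
#'
#' @param x An `fz_system`.
#' @param ... Unused.
#' @return A tibble with one row per rule: the MF label chosen for each input
#'   and output, the weight, the connector and an English `statement`.
#' @method tidy fz_system
#' @export
tidy.fz_system <- function(x, ...) {
  rm <- rule_matrices(x)
  purrr::map_dfr(seq_along(x$rules), function(i) {
    ant <- rm$ant[i, ]; cons <- rm$cons[i, ]
    parts <- purrr::map_chr(seq_along(x$inputs), function(j) {
      if (ant[j] == 0) return(NA_character_)
      sprintf("%s is %s", x$inputs[[j]]$name, x$inputs[[j]]$mfs[[ant[j]]]$label)
    })
    then <- purrr::map_chr(seq_along(x$outputs), function(j) {
      sprintf("%s is %s", x$outputs[[j]]$name, x$outputs[[j]]$mfs[[cons[j]]]$label)
    })
    joiner <- if (rm$connector[i] == "and") " AND " else " OR "
    row <- stats::setNames(
      as.list(c(ant, cons)),
      c(paste0("in_", vapply(x$inputs, `[[`, character(1), "name")),
        paste0("out_", vapply(x$outputs, `[[`, character(1), "name")))
    )
    tibble::tibble(
      rule = i, !!!row, weight = rm$weight[i], connector = rm$connector[i],
      statement = paste0("IF ", paste(stats::na.omit(parts), collapse = joiner),
                         " THEN ", paste(then, collapse = " AND "))
    )
  })
}

#' One-row summary of a fuzzy system
#'
#' @param x An `fz_system`.
#' @param ... Unused.
#' @return A tibble with input/output/rule counts and configuration.
#' @method glance fz_system
#' @export
glance.fz_system <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_inputs = length(x$inputs),
    n_outputs = length(x$outputs),
    n_rules = length(x$rules),
    n_mfs = sum(vapply(c(x$inputs, x$outputs), function(v) length(v$mfs), integer(1))),
    defuzz_method = x$defuzz_method,
    resolution = x$resolution
  )
}

#' Plot every variable of a fuzzy system
#'
#' @param object An `fz_system`.
#' @param n Grid points per curve.
#' @param ... Unused.
#' @return A ggplot object faceted by variable.
#' @method autoplot fz_system
#' @export
autoplot.fz_system <- function(object, n = 201, ...) {
  vars <- c(object$inputs, object$outputs)
  df <- purrr::map_dfr(vars, function(v) {
    grid <- seq(v$range[1], v$range[2], length.out = n)
    purrr::map_dfr(v$mfs, function(m) {
      tibble::tibble(variable = v$name, label = m$label, x = grid,
                     degree = membership_degree(m, grid))
    })
  })
  df$variable <- factor(df$variable, levels = unique(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$degree,
                                   colour = .data$label)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "membership degree")
}
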