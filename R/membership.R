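#' Triangular membership function
#'
#' A triangular fuzzy set with left foot `a`, peak `b` and right foot `c`.
#' Membership rises linearly from `a` to 1 at `b` and falls back to 0 at `c`.
#'
#' @param a,b,c Breakpoints with `a <= b <= c`. `b` is the peak.
#' @param label Name of the set (defaults to `"MF"`).
#' @return An object of class `fz_mf`.
#' @examples
#' mf <- fz_trimf(0, 1, 2)
#' membership_degree(mf, c(0.5, 1, 2.5))
#' @export
fz_trimf <- function(a, b, c, label = "MF") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!(a <= b && b <= c)) {
    rlang::abort("triangular membership function requires a <= b <= c")
  }
  new_fz_mf(label, "trimf", params = c(a, b, c))
}

#' Trapezoidal membership function
#'
#' A trapezoidal fuzzy set with feet `a`, `d` and plateau `[b, c]` at degree 1.
#'
#' @param a,b,c,d Breakpoints with `a <= b <= c <= d`.
#' @param label Name of the set.
#' @return An object of class `fz_mf`.
#' @examples
#' membership_degree(fz_trapmf(0, 1, 2, 3), 0.5)
#' @export
fz_trapmf <- function(a, b, c, d, label = "MF") {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d))
  if (!(a <= b && b <= c && c <= d)) {
    rlang::abort("trapezoidal membership function requires a <= b <= c <= d")
  }
  new_fz_mf(label, "trapmf", params = c(a, b, c, d))
}

new_fz_mf <- function(label, shape, params) {
  structure(
    list(label = label, shape = shape, params = as.numeric(params)),
    class = "fz_mf"
  )
}

# internal canonical form: every mf as (a, b, c, d); a triangle has b == c
mf_abcd <- function(mf) {
  p <- mf$params
  if (mf$shape == "trimf") c(p[1], p[2], p[2], p[3]) else p
}

#' Degree of membership
#'
#' Evaluates a piecewise-linear membership function. Degenerate (zero-width)
#' ramps are treated as vertical edges with degree 1 at the breakpoint, so a
#' set like `trapmf(1, 1, 3, 3)` still attains degree 1 on `[1, 3]`.
#'
#' @param mf An [fz_trimf()] or [fz_trapmf()] object.
#' @param x Numeric vector of crisp values.
#' @return Numeric vector of degrees in `[0, 1]`, same length as `x`.
#' @export
membership_degree <- function(mf, x) {
  stopifnot(inherits(mf, "fz_mf"), is.numeric(x))
  p <- mf_abcd(mf)
  a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
  deg <- numeric(length(x))
  on_plateau <- x >= b & x <= c
  deg[on_plateau] <- 1
  if (b > a) {
    left <- x >= a & x < b
    deg[left] <- (x[left] - a) / (b - a)
  }
  if (d > c) {
    right <- x > c & x <= d
    deg[right] <- (d - x[right]) / (d - c)
  }
  deg
}

#' Fuzzy linguistic variable
#'
#' Bundles a variable name, its admissible range and an ordered family of
#' membership functions. Inputs outside the range are clamped before
#' fuzzification, so coverage over `[range_lo, range_hi]` is what matters.
#'
#' @param name Variable name.
#' @param range_lo,range_hi Range endpoints, `range_lo < range_hi`.
#' @param mfs List of [fz_trimf()]/[fz_trapmf()] objects, ordered by peak.
#' @return An object of class `fz_variable`.
#' @export
fz_variable <- function(name, range_lo, range_hi, mfs) {
  if (!is.list(mfs) || length(mfs) == 0 ||
      !all(vapply(mfs, inherits, logical(1), "fz_mf"))) {
    rlang::abort("`mfs` must be a non-empty list of fz_mf objects")
  }
  if (!(range_lo < range_hi)) {
    rlang::abort(sprintf("variable '%s' has a zero-width range [%g, %g]",
                         name, range_lo, range_hi))
  }
  peaks <- vapply(mfs, function(m) mf_abcd(m)[2], numeric(1))
  if (is.unsorted(peaks)) {
    rlang::abort("membership functions must be ordered by ascending peak (b)")
  }
  structure(
    list(name = name, range = c(range_lo, range_hi), mfs = mfs),
    class = "fz_variable"
  )
}

#' @export
print.fz_mf <- function(x, ...) {
  cat(sprintf("<fz_mf> %s: %s [%s]\n", x$label, x$shape,
              paste(format(x$params, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
print.fz_variable <- function(x, ...) {
  cat(sprintf("<fz_variable> %s, range [%g, %g], %d membership function(s)\n",
              x$name, x$range[1], x$range[2], length(x$mfs)))
  for (m in x$mfs) print(m)
  invisible(x)
}

#' Tidy a fuzzy variable into its membership-function table
#'
#' @param x An `fz_variable`.
#' @param ... Unused.
#' @return A tibble with one row per membership function (label, shape and
#'   the `a`, `b`, `c`, `d` breakpoints; `d` is `NA` for triangles).
#' @method tidy fz_variable
#' @export
tidy.fz_variable <- function(x, ...) {
  purrr::map_dfr(seq_along(x$mfs), function(i) {
    m <- x$mfs[[i]]
    p <- m$params
    tibble::tibble(
      variable = x$name, index = i, label = m$label, shape = m$shape,
      a = p[1], b = p[2],
      c = if (m$shape == "trimf") p[2] else p[3],
      d = if (m$shape == "trimf") p[3] else p[4]
    )
  })
}

#' Plot the membership functions of a variable
#'
#' @param object An `fz_variable`.
#' @param n Number of grid points used to trace each curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fz_variable
#' @export
autoplot.fz_variable <- function(object, n = 401, ...) {
  grid <- seq(object$range[1], object$range[2], length.out = n)
  df <- purrr::map_dfr(object$mfs, function(m) {
    tibble::tibble(label = m$label, x = grid, degree = membership_degree(m, grid))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$degree,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$name, y = "membership degree", colour = NULL) +
    ggplot2::ylim(0, 1)
}
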