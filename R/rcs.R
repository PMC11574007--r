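#' Restricted cubic spline basis with three knots
#'
#' Computes the two-column basis (linear term, restricted cubic term) of a
#' three-knot restricted cubic spline in the Harrell normalization. The cubic
#' term is
#' \deqn{C(x) = \frac{(x-t_1)_+^3 - (x-t_2)_+^3 (t_3-t_1)/(t_3-t_2) +
#'   (x-t_3)_+^3 (t_2-t_1)/(t_3-t_2)}{(t_3-t_1)^2}}
#' which is zero below the first knot, has continuous value, first and second
#' derivatives everywhere, and is linear beyond both boundary knots. With
#' three knots the EYO design therefore contributes exactly two columns: the
#' linear component and this cubic component.
#'
#' @param x numeric vector of evaluation points (EYO in years).
#' @param knots numeric vector of 3 strictly increasing knot locations, or a
#'   spline spec from [choose_knots()].
#' @return numeric matrix with columns `linear` and `cubic`, one row per `x`.
#' @seealso [choose_knots()]
#' @examples
#' rcs_basis(c(-25, -8, 20), knots = c(-20, -8, 10))
#' @export
rcs_basis <- function(x, knots) {
  if (inherits(knots, "rcs_spec")) knots <- knots$knots
  if (length(knots) != 3L || any(!is.finite(knots))) {
    stop("'knots' must be 3 finite values", call. = FALSE)
  }
  if (is.unsorted(knots, strictly = TRUE)) {
    stop("'knots' must be strictly increasing", call. = FALSE)
  }
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  p3 <- function(u) pmax(u, 0)^3
  cub <- (p3(x - t1) -
            p3(x - t2) * (t3 - t1) / (t3 - t2) +
            p3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(linear = x, cubic = cub)
}

#' Choose restricted-cubic-spline knots from EYO quantiles
#'
#' Places the three knots at the 0.10, 0.50 and 0.90 empirical quantiles of
#' the EYO values in the analysis sample, using the linear-interpolation
#' quantile definition (R type 7). Knots are chosen on the pooled sample
#' (carriers and non-carriers together) for each outcome.
#'
#' @param eyo_values numeric vector of EYO values (years); at least 10
#'   distinct values required.
#' @param probs quantile levels for the knots (default `c(0.1, 0.5, 0.9)`).
#' @return an object of class `rcs_spec`: list with `knots` and `probs`.
#' @examples
#' choose_knots(1:11)  # knots at 2, 6, 10
#' @export
choose_knots <- function(eyo_values, probs = c(0.10, 0.50, 0.90)) {
  eyo_values <- eyo_values[is.finite(eyo_values)]
  if (length(unique(eyo_values)) < 10L) {
    stop("need at least 10 distinct finite EYO values to place knots",
         call. = FALSE)
  }
  k <- unname(quantile(eyo_values, probs = probs, type = 7))
  if (is.unsorted(k, strictly = TRUE)) {
    stop("degenerate EYO distribution: quantile knots are not distinct",
         call. = FALSE)
  }
  structure(list(knots = k, probs = probs), class = "rcs_spec")
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat("Restricted cubic spline spec (3 knots, Harrell normalization)\n")
  cat(sprintf("  knots at EYO quantiles (%s): %s\n",
              paste(format(x$probs), collapse = ", "),
              paste(format(round(x$knots, 3)), collapse = ", ")))
  invisible(x)
}
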