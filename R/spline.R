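# Centered B-spline basis for the temperature exposure-response curve.
# Centering at the reference temperature makes the fitted hazard ratio
# exactly 1 there, with a degenerate confidence interval.

#' Specification of the centered exposure spline basis
#'
#' A cubic B-spline basis with `df` columns, centered so that the basis row
#' evaluated at the reference exposure is the zero vector (hence HR = 1 at
#' the reference by construction). With `df = 3` (the default) the basis has
#' no interior knots; for `df > 3`, `df - 3` interior knots are placed
#' equally spaced inside the boundary unless given explicitly.
#'
#' Boundary knots default to the observed exposure range (extended to include
#' the reference) and are resolved by [expand_counting_process()]; evaluation
#' outside the boundary is an error, never silent extrapolation.
#'
#' @param df degrees of freedom (number of basis columns), >= 3.
#' @param reference reference exposure value where HR is pinned to 1
#'   (default 21 degC).
#' @param boundary length-2 numeric boundary knots, or `NULL` to resolve from
#'   data.
#' @param knots interior knots, or `NULL`.
#' @return an object of class `spline_basis_spec`.
#' @export
spline_basis_spec <- function(df = 3L, reference = 21, boundary = NULL,
                              knots = NULL) {
  df <- as.integer(df)
  if (is.na(df) || df < 3L) {
    stop("spline df must be an integer >= 3 (cubic basis)", call. = FALSE)
  }
  if (!is.null(boundary)) {
    boundary <- as.numeric(boundary)
    if (length(boundary) != 2L || anyNA(boundary) || boundary[1] >= boundary[2]) {
      stop("`boundary` must be two increasing numbers", call. = FALSE)
    }
    if (reference < boundary[1] || reference > boundary[2]) {
      stop("the reference exposure must lie inside the boundary knots",
           call. = FALSE)
    }
  }
  if (!is.null(knots)) {
    knots <- sort(as.numeric(knots))
    if (length(knots) != df - 3L) {
      stop(sprintf("df = %d requires exactly %d interior knot(s)", df, df - 3L),
           call. = FALSE)
    }
  }
  structure(list(df = df, reference = reference, boundary = boundary,
                 knots = knots),
            class = "spline_basis_spec")
}

#' @export
print.spline_basis_spec <- function(x, ...) {
  cat(sprintf("<spline_basis_spec> df = %d, reference = %g", x$df, x$reference))
  if (is.null(x$boundary)) {
    cat(", boundary unresolved (taken from data at expansion)\n")
  } else {
    cat(sprintf(", boundary [%g, %g]\n", x$boundary[1], x$boundary[2]))
  }
  invisible(x)
}

# Fill in boundary (and interior knots if needed) from observed exposures;
# the boundary is widened to include the reference so centering is defined.
resolve_spline_spec <- function(spec, values) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  if (is.null(spec$boundary)) {
    spec$boundary <- range(c(values, spec$reference))
    if (spec$boundary[1] >= spec$boundary[2]) {
      stop("cannot resolve spline boundary: exposure values are constant",
           call. = FALSE)
    }
  }
  if (is.null(spec$knots) && spec$df > 3L) {
    k <- spec$df - 3L
    spec$knots <- spec$boundary[1] +
      seq_len(k) / (k + 1) * diff(spec$boundary)
  }
  spec
}

#' Evaluate the centered spline basis
#'
#' @param values numeric exposure values; every value must lie within the
#'   spec's boundary knots (extrapolation is an error).
#' @param spec a resolved [spline_basis_spec()] (boundary set, e.g. by
#'   [expand_counting_process()] or explicitly).
#' @return a numeric matrix with `spec$df` columns named `temp_sp1..`;
#'   rows evaluated at `spec$reference` are exactly zero.
#' @export
#' @examples
#' sp <- spline_basis_spec(boundary = c(10, 30))
#' spline_basis(21, sp) # zero row
spline_basis <- function(values, spec) {
  stopifnot(inherits(spec, "spline_basis_spec"))
  if (is.null(spec$boundary)) {
    stop("spline basis boundary is unresolved; pass boundary= explicitly or ",
         "let expand_counting_process() resolve it from the data",
         call. = FALSE)
  }
  values <- as.numeric(values)
  out_of_range <- values < spec$boundary[1] | values > spec$boundary[2]
  if (anyNA(values) || any(out_of_range)) {
    stop(sprintf("exposure value outside the spline boundary [%g, %g]; %s",
                 spec$boundary[1], spec$boundary[2],
                 "extrapolation is not supported"), call. = FALSE)
  }
  basis_at <- function(x) {
    splines::bs(x, degree = 3L, knots = spec$knots,
                Boundary.knots = spec$boundary, intercept = FALSE)
  }
  b <- basis_at(values)
  b_ref <- basis_at(spec$reference)
  out <- sweep(unclass(b), 2L, as.numeric(b_ref), `-`)
  attributes(out) <- list(dim = dim(out))
  colnames(out) <- paste0("temp_sp", seq_len(ncol(out)))
  out
}
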