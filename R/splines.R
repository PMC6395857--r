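#' Quantile-based knots for linear splines
#'
#' Places candidate inflection points (knots) for a covariate at empirical
#' quantiles, by default the 0.2, 0.4, 0.6 and 0.8 quantiles. Duplicate knots
#' (from heavily tied data) are collapsed with a warning.
#'
#' @param x numeric covariate vector.
#' @param levels quantile levels in (0, 1); default \code{c(0.2, 0.4, 0.6, 0.8)}.
#' @return A list of class \code{"spline_spec"} with \code{knots} (strictly
#'   increasing, possibly empty) and \code{levels} (the levels retained).
#' @examples
#' quantile_knots(1:100)
#' @export
quantile_knots <- function(x, levels = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(is.numeric(x), all(levels > 0), all(levels < 1))
  k <- stats::quantile(x, probs = levels, names = FALSE, type = 7)
  keep <- !duplicated(k)
  if (!all(keep)) {
    warning("duplicate knots collapsed (", sum(!keep), " removed)")
    k <- k[keep]; levels <- levels[keep]
  }
  # knots equal to the data maximum yield an all-zero hinge column; drop them
  inner <- k < max(x)
  if (!all(inner)) {
    warning("knots at or above max(x) dropped (", sum(!inner), " removed)")
    k <- k[inner]; levels <- levels[inner]
  }
  if (length(unique(x)) <= length(k)) {
    warning("fewer distinct values than requested knots; knot set reduced")
    k <- unique(k[k > min(x)])
    levels <- levels[seq_along(k)]
  }
  structure(list(knots = as.numeric(k), levels = as.numeric(levels)),
            class = "spline_spec")
}

#' Linear-spline (hinge) basis
#'
#' Expands a covariate into the basis \code{[x, (x - k1)+, ..., (x - kK)+]}
#' where \code{(.)+} is the positive part. Any continuous piecewise-linear
#' function with breaks at the knots is exactly representable in this basis
#' plus an intercept.
#'
#' @param x numeric covariate vector.
#' @param spec a \code{"spline_spec"} from [quantile_knots()], or a numeric
#'   vector of knots.
#' @return Numeric matrix with \code{1 + K} columns named \code{"x"} and
#'   \code{"x_k<j>"}.
#' @examples
#' linear_spline_basis(seq(0, 1, 0.1), quantile_knots(seq(0, 1, 0.1)))
#' @export
linear_spline_basis <- function(x, spec) {
  knots <- if (inherits(spec, "spline_spec")) spec$knots else as.numeric(spec)
  B <- cbind(x, vapply(knots, function(k) pmax(x - k, 0), numeric(length(x))))
  colnames(B) <- c("x", if (length(knots)) paste0("x_k", seq_along(knots)))
  B
}

#' Standardize design columns
#'
#' Centres and scales each column to mean zero and unit variance, recording
#' the transformation so it can be re-applied to new data at prediction time.
#' Constant columns are dropped with a warning.
#'
#' @param X numeric matrix (or data frame) of covariates.
#' @param center,scale optional numeric vectors of per-column centres and
#'   scales; when supplied (e.g. from a training fit) they are applied as-is.
#' @param sd_type \code{"population"} (divide by n, the default) or
#'   \code{"sample"} (divide by n - 1).
#' @return Standardized matrix with attributes \code{"center"} and
#'   \code{"scale"}.
#' @examples
#' standardize_columns(cbind(a = 1:3, b = c(2, 4, 9)))
#' @export
standardize_columns <- function(X, center = NULL, scale = NULL,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(center)) {
    center <- colMeans(X)
    v <- colMeans(sweep(X, 2, center)^2)
    if (sd_type == "sample") v <- v * nrow(X) / max(nrow(X) - 1, 1)
    scale <- sqrt(v)
    keep <- scale > 1e-12
    if (!all(keep)) {
      warning("dropping constant column(s): ",
              paste(colnames(X)[!keep], collapse = ", "))
      X <- X[, keep, drop = FALSE]
      center <- center[keep]; scale <- scale[keep]
    }
  }
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  Z
}

# Invert standardize_columns using its recorded attributes.
destandardize_columns <- function(Z) {
  X <- sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, attr(Z, "center"), "+")
  attr(X, "center") <- NULL; attr(X, "scale") <- NULL
  X
}
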