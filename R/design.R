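#' Build a model design from raw covariates
#'
#' Optionally expands each covariate into a linear-spline basis with quantile
#' knots, then standardizes all resulting columns to mean zero and unit
#' variance. The returned object records the knots and the standardization so
#' the identical transformation can be applied to new data. The design never
#' contains an intercept column: in the ordinal probit model the intercept is
#' absorbed by the breakpoints, so including one would be unidentifiable.
#'
#' @param X numeric matrix or data frame of raw covariates (columns named).
#' @param splines logical; expand each covariate into \code{[x, (x - k)+]}
#'   hinge columns with knots from [quantile_knots()].
#' @param levels quantile levels for the knots when \code{splines = TRUE}.
#' @param standardize logical; standardize the final columns (recommended --
#'   the N(0, I) prior on the regression coefficients assumes unit-scale
#'   covariates).
#' @return An object of class \code{"mn_design"}: list with the design matrix
#'   \code{M}, per-covariate \code{specs} (knots or NULL), \code{center},
#'   \code{scale}, \code{groups} (map from design columns to source
#'   covariates) and the source column names.
#' @examples
#' d <- build_design(cbind(x1 = runif(50), x2 = runif(50)), splines = TRUE)
#' ncol(d$M)  # 2 covariates x (1 linear + up to 4 hinge columns)
#' @export
build_design <- function(X, splines = FALSE, levels = c(0.2, 0.4, 0.6, 0.8),
                         standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vars <- colnames(X)
  specs <- stats::setNames(vector("list", length(vars)), vars)
  cols <- list(); groups <- character(0)
  for (v in vars) {
    if (splines) {
      specs[[v]] <- quantile_knots(X[, v], levels = levels)
      B <- linear_spline_basis(X[, v], specs[[v]])
      colnames(B) <- sub("^x", v, colnames(B))
    } else {
      B <- X[, v, drop = FALSE]
    }
    cols[[v]] <- B
    groups <- c(groups, rep(v, ncol(B)))
  }
  M <- do.call(cbind, cols)
  center <- NULL; scl <- NULL
  if (standardize) {
    M <- standardize_columns(M)
    keep <- colnames(M)
    groups <- groups[match(keep, unlist(lapply(cols, colnames)))]
    center <- attr(M, "center"); scl <- attr(M, "scale")
    attr(M, "center") <- NULL; attr(M, "scale") <- NULL
  }
  structure(list(M = M, specs = specs, center = center, scale = scl,
                 groups = groups, vars = vars, splines = splines),
            class = "mn_design")
}

# Apply a fitted design's transformation to new raw covariates.
apply_design <- function(design, Xnew) {
  Xnew <- as.matrix(Xnew)
  storage.mode(Xnew) <- "double"
  if (is.null(colnames(Xnew)) && ncol(Xnew) == length(design$vars))
    colnames(Xnew) <- design$vars
  missing <- setdiff(design$vars, colnames(Xnew))
  if (length(missing))
    stop("new data lacks covariate(s): ", paste(missing, collapse = ", "))
  cols <- list()
  for (v in design$vars) {
    if (design$splines) {
      B <- linear_spline_basis(Xnew[, v], design$specs[[v]])
      colnames(B) <- sub("^x", v, colnames(B))
    } else {
      B <- Xnew[, v, drop = FALSE]
    }
    cols[[v]] <- B
  }
  M <- do.call(cbind, cols)
  M <- M[, colnames(design$M), drop = FALSE]
  if (!is.null(design$center))
    M <- sweep(sweep(M, 2, design$center), 2, design$scale, "/")
  M
}

#' @export
print.mn_design <- function(x, ...) {
  cat("Design:", ncol(x$M), "columns from", length(x$vars), "covariates",
      if (x$splines) "(linear-spline bases)" else "(linear)",
      if (!is.null(x$center)) "- standardized" else "", "\n")
  invisible(x)
}
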