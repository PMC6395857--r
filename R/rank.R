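#' Rank-transform observed counts
#'
#' Maps a vector of non-negative integer counts to consecutive ranks
#' \code{1..J} of its unique values, ties sharing a rank. The ordinal probit
#' model operates on these ranks; the ordered unique values \code{u} carry the
#' count scale and are used to form expected counts.
#'
#' @param w vector of non-negative integer counts (length >= 1).
#' @return A list of class \code{"rank_mapping"} with components
#'   \item{u}{strictly increasing unique count values,}
#'   \item{y}{integer ranks in \code{1..J}, same length as \code{w},}
#'   \item{J}{number of unique values.}
#' @examples
#' rank_counts(c(0, 3, 0, 7))
#' @export
rank_counts <- function(w) {
  if (length(w) < 1L) stop("'w' must be non-empty")
  if (anyNA(w)) stop("'w' contains missing values")
  if (!is.numeric(w)) stop("'w' must be numeric counts")
  if (any(w < 0)) stop("'w' contains negative values; counts must be >= 0")
  if (any(w != round(w))) stop("'w' contains non-integer values")
  u <- sort(unique(as.numeric(w)))
  y <- match(as.numeric(w), u)
  structure(list(u = u, y = as.integer(y), J = length(u)),
            class = "rank_mapping")
}

#' @export
print.rank_mapping <- function(x, ...) {
  cat("Rank mapping: n =", length(x$y), ", J =", x$J,
      "unique counts in [", x$u[1], ",", x$u[x$J], "]\n")
  invisible(x)
}
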