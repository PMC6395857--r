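#' Load and validate a count-data table
#'
#' Reads a CSV with a header, checks that the response column holds
#' non-negative integers (naming the first offending row otherwise), and
#' reports basic zero-inflation diagnostics.
#'
#' @param path CSV file path.
#' @param response name of the count response column.
#' @param covariates optional character vector of covariate columns (checked
#'   for presence and numeric type).
#' @param cluster optional cluster-id column name.
#' @return List with \code{data} (the data frame), \code{n},
#'   \code{zero_fraction}, \code{max_count} and the column roles.
#' @export
load_table <- function(path, response, covariates = NULL, cluster = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(response, covariates, cluster)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  w <- df[[response]]
  if (!is.numeric(w)) stop("response column '", response, "' is not numeric")
  bad <- which(is.na(w) | w < 0 | w != round(w))
  if (length(bad))
    stop("response column '", response, "' is not a non-negative integer ",
         "count at row ", bad[1])
  for (v in covariates)
    if (!is.numeric(df[[v]])) stop("covariate '", v, "' is not numeric")
  out <- list(data = df, n = nrow(df), zero_fraction = mean(w == 0),
              max_count = max(w), response = response,
              covariates = covariates, cluster = cluster)
  message(sprintf("loaded %d rows: zero fraction %.2f, max count %d",
                  out$n, out$zero_fraction, out$max_count))
  out
}

#' Write a fitted chain and summary to a directory
#'
#' Serializes the stored draws to CSV (coefficients, breaks, log-likelihood
#' and, for selection fits, the inclusion indicators), a JSON summary
#' (posterior medians and intervals), and an echo of the run configuration.
#' File contents are deterministic: re-running the same fit writes
#' byte-identical output.
#'
#' @param fit an \code{"mnfit"}.
#' @param dir output directory (created if needed).
#' @param config optional named list echoed verbatim to \code{config.json}.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(fit, dir, config = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  chain <- data.frame(fit$beta, fit$b, llk = fit$llk, check.names = FALSE)
  names(chain) <- c(colnames(fit$beta),
                    paste0("b", seq_len(ncol(fit$b))), "llk")
  chain_path <- file.path(dir, "chain.csv")
  utils::write.csv(format(chain, digits = 17, trim = TRUE, scientific = NA),
                   chain_path, row.names = FALSE, quote = FALSE)
  if (isTRUE(fit$selection)) {
    utils::write.csv(data.frame(fit$inclusion * 1L, check.names = FALSE),
                     file.path(dir, "inclusion.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  sm <- summary(fit)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    model = if (isTRUE(fit$selection)) "mnms" else "mn",
    n = length(fit$w), J = fit$J, draws = nrow(fit$beta),
    u = fit$u, seed = fit$seed, n_iter = fit$n_iter, burn = fit$burn,
    thin = fit$thin,
    coefficients = as.data.frame(sm$coefficients),
    breaks = as.data.frame(sm$breaks),
    llk = as.list(stats::setNames(sm$llk, c("median", "lower", "upper"))),
    inclusion = if (isTRUE(fit$selection)) as.list(sm$inclusion)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(chain = chain_path, summary = summary_path,
              config = config_path))
}

#' Read back a chain written by [write_report()]
#'
#' @param dir directory previously written by [write_report()].
#' @return List with \code{chain} (data frame of draws), \code{summary}
#'   (parsed JSON) and, if present, \code{inclusion}.
#' @export
read_report <- function(dir) {
  out <- list(
    chain = utils::read.csv(file.path(dir, "chain.csv"),
                            check.names = FALSE),
    summary = jsonlite::read_json(file.path(dir, "summary.json"),
                                  simplifyVector = TRUE))
  inc <- file.path(dir, "inclusion.csv")
  if (file.exists(inc))
    out$inclusion <- utils::read.csv(inc, check.names = FALSE)
  out
}
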