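#' Read a behavioral series from CSV
#'
#' Timing series need a column `estimate_s` (plus attribute column
#' `target_s` or the `target` argument); naming series need `iri_s` and
#' optionally `label`. Rows with missing or nonpositive values are
#' rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param task `"timing"` or `"naming"`.
#' @param target Target interval (s) for timing series; overrides a
#'   `target_s` column.
#' @return A [time_estimate_series()] or [iri_series()].
#' @export
read_series_csv <- function(path, task = c("timing", "naming"),
                            target = NULL) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  col <- if (task == "timing") "estimate_s" else "iri_s"
  if (!col %in% names(df))
    stop("missing required column `", col, "` in ", path)
  v <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad))
    stop("nonpositive or malformed ", col, " at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  if (task == "timing") {
    if (is.null(target)) {
      if (!"target_s" %in% names(df))
        stop("timing series needs `target` or a `target_s` column")
      target <- df$target_s[1]
    }
    time_estimate_series(v, target)
  } else {
    iri_series(v, if ("label" %in% names(df)) df$label else NULL)
  }
}

#' Write a behavioral series to CSV
#'
#' @param series A [time_estimate_series()] or [iri_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- if (inherits(series, "time_estimate_series")) {
    data.frame(index = seq_along(series$estimates),
               estimate_s = series$estimates,
               target_s = series$target)
  } else if (inherits(series, "iri_series")) {
    d <- data.frame(index = seq_along(series$iris), iri_s = series$iris)
    if (!is.null(series$labels)) d$label <- series$labels
    d
  } else stop("`series` must be a time_estimate_series or iri_series")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a semantic space from CSV
#'
#' Expects columns `name,x,y` and optionally `category`.
#'
#' @param path CSV file path.
#' @return A [semantic_space()].
#' @export
read_semantic_space_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  if (!all(need %in% names(df)))
    stop("semantic space CSV needs columns name,x,y")
  semantic_space(df$name, cbind(df$x, df$y),
                 if ("category" %in% names(df)) df$category else NULL)
}

#' Write a semantic space to CSV
#'
#' @param space A [semantic_space()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_semantic_space_csv <- function(space, path) {
  stopifnot(inherits(space, "semantic_space"))
  df <- data.frame(name = space$names, x = space$coords[, 1],
                   y = space$coords[, 2])
  if (!is.null(space$categories)) df$category <- space$categories
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a mixture target to JSON
#'
#' @param target A [mixture_target()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mixture_json <- function(target, path) {
  stopifnot(inherits(target, "mixture_target"))
  jsonlite::write_json(
    list(weights = target$weights,
         means = target$means,
         covariances = target$covariances),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}

#' Read a mixture target from JSON
#'
#' @param path JSON path written by [write_mixture_json()].
#' @return A [mixture_target()].
#' @export
read_mixture_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- x$covariances
  if (is.array(covs) && length(dim(covs)) == 3L)
    covs <- lapply(seq_len(dim(covs)[1]), function(k) covs[k, , ])
  mixture_target(x$weights, x$means, covs)
}

#' Export a sample trace to CSV
#'
#' Columns `iteration,x[,y],accepted`.
#'
#' @param trace A `"sample_trace"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sample_trace"))
  df <- data.frame(iteration = seq_len(nrow(trace$samples)))
  df$x <- trace$samples[, 1]
  if (ncol(trace$samples) > 1L) df$y <- trace$samples[, 2]
  df$accepted <- trace$accept_flags
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
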