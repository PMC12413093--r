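#' Tidy a stationary covariance into long format
#'
#' One row per (i, j) entry with the local, cross and recurrent
#' contributions alongside the total, so variance can be attributed to
#' mechanism with ordinary data-frame tools.
#'
#' @param x A `stationary_cov`.
#' @param ... Unused.
#' @return A tibble with columns `i`, `j`, `input`, `cross`, `recurrent`,
#'   `sigma`.
#' @export
tidy.stationary_cov <- function(x, ...) {
  N <- nrow(x$sigma)
  tibble::tibble(
    i = rep(seq_len(N), times = N),
    j = rep(seq_len(N), each = N),
    input = as.vector(x$component_terms$input),
    cross = as.vector(x$component_terms$cross),
    recurrent = as.vector(x$component_terms$recurrent),
    sigma = as.vector(x$sigma)
  )
}

#' One-row summary of a stationary covariance
#'
#' @param x A `stationary_cov`.
#' @param ... Unused.
#' @return A tibble with the formula tag, trace, the trace share of each
#'   component term, and the participation ratio of the spectrum.
#' @export
glance.stationary_cov <- function(x, ...) {
  ev <- eigen(x$sigma, symmetric = TRUE, only.values = TRUE)$values
  tibble::tibble(
    formula_tag = x$formula_tag,
    N = nrow(x$sigma),
    trace = sum(diag(x$sigma)),
    trace_input = sum(diag(x$component_terms$input)),
    trace_cross = sum(diag(x$component_terms$cross)),
    trace_recurrent = sum(diag(x$component_terms$recurrent)),
    participation_ratio = participation_ratio(pmax(ev, 0))
  )
}

#' Heatmap of a stationary covariance
#'
#' @param object A `stationary_cov`.
#' @param ... Unused.
#' @return A ggplot heatmap of the covariance entries.
#' @export
autoplot.stationary_cov <- function(object, ...) {
  df <- tidy.stationary_cov(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$sigma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Stationary covariance [",
                                 object$formula_tag, "]")) +
    ggplot2::theme_minimal()
}

#' Export a covariance matrix to CSV with a JSON sidecar
#'
#' @param cov A `stationary_cov` or plain matrix.
#' @param path Output CSV path; a `<path>.json` sidecar records the
#'   formula tag and dimensions when `cov` is a `stationary_cov`.
#' @export
write_covariance_csv <- function(cov, path) {
  sigma <- if (inherits(cov, "stationary_cov")) cov$sigma else as.matrix(cov)
  readr::write_csv(tibble::as_tibble(sigma, .name_repair = ~ paste0("V", seq_along(.x))), path)
  if (inherits(cov, "stationary_cov")) {
    jsonlite::write_json(
      list(formula_tag = cov$formula_tag, N = nrow(sigma),
           ensemble_mode = cov$ensemble_mode),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
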