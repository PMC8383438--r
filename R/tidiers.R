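#' @method tidy covariate_selection
#' @export
tidy.covariate_selection <- function(x, ...) {
  if (length(x$iterations) == 0) {
    return(tibble(iteration = integer(), selected = character(),
                  min_p = numeric(), threshold = numeric()))
  }
  purrr::imap_dfr(x$iterations, function(it, i) {
    tibble(
      iteration = i,
      selected = it$selected,
      min_p = min(it$pvals, na.rm = TRUE),
      threshold = it$threshold
    )
  })
}

#' @method glance covariate_selection
#' @export
glance.covariate_selection <- function(x, ...) {
  tibble(
    n_selected = length(x$selected),
    selected = paste(x$selected, collapse = ","),
    n_iterations = length(x$iterations),
    stop_reason = x$stop_reason
  )
}

#' Heatmap of candidate-PC association p-values per selection iteration
#'
#' @param object A `covariate_selection` result.
#' @param iteration Which iteration to show (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot covariate_selection
#' @export
autoplot.covariate_selection <- function(object, iteration = 1, ...) {
  it <- object$iterations[[iteration]]
  if (is.null(it)) abort("no such iteration")
  df <- as_tibble(as.data.frame(it$pvals), rownames = "candidate") |>
    tidyr::pivot_longer(-"candidate", names_to = "pc", values_to = "p")
  df$pc <- factor(df$pc, levels = colnames(it$pvals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$candidate,
                                   fill = -log10(pmax(.data$p, 1e-12)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("iteration %d (selected: %s)",
                                  iteration, it$selected)) +
    ggplot2::theme_minimal()
}
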