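#' Plot movement gradients
#'
#' Line plot of one or more gradients (observed, model-predicted,
#' chance) over absolute source distance.
#'
#' @param ... Named `movement_gradient` objects (names become the
#'   legend labels).
#' @return A ggplot object.
#' @export
plot_gradient <- function(...) {
  gs <- list(...)
  if (is.null(names(gs)) || any(names(gs) == "")) {
    names(gs) <- vapply(gs, function(g) attr(g, "source"), character(1))
  }
  df <- dplyr::bind_rows(lapply(names(gs), function(nm) {
    tibble::tibble(series = nm,
                   distance = seq_along(gs[[nm]]),
                   proportion = as.numeric(gs[[nm]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$proportion,
                                   colour = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(max(df$distance))) +
    ggplot2::labs(x = "Absolute source distance (events)",
                  y = "Error proportion", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot absolute event activation against production rate
#'
#' Mean activation of the current event and of its contextual events
#' over the excerpt positions, as a function of the interonset interval,
#' for one or more sequence layouts (e.g. the long and short contexts).
#'
#' @param scores Named list of `score` objects.
#' @param a Memory parameter (default 0.85).
#' @param tactus_weight Tactus weight for the accent profile (default
#'   0.25, equal weights).
#' @param iois IOI grid in seconds.
#' @return A ggplot object.
#' @export
plot_activation_by_ioi <- function(scores, a = 0.85, tactus_weight = 0.25,
                                   iois = seq(0.15, 0.6, by = 0.05)) {
  df <- dplyr::bind_rows(lapply(names(scores), function(nm) {
    sc <- scores[[nm]]
    profile <- score_profile(sc, tactus_weight)
    ex <- excerpt_positions(sc, base = 1L)
    dplyr::bind_rows(lapply(iois, function(t) {
      params <- range_params(a = a, t = t, weights = profile$weights)
      e0 <- mean(event_activation(profile, ex, params))
      ctx <- mean(vapply(ex, function(i)
        mean(contextual_activations(profile, i, params)$activation),
        numeric(1)))
      tibble::tibble(layout = nm, ioi = t,
                     current = e0, contextual = ctx)
    }))
  }))
  long <- tidyr::pivot_longer(df, c("current", "contextual"),
                              names_to = "what", values_to = "activation")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ioi, y = .data$activation,
                                     colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~layout, scales = "free_y") +
    ggplot2::labs(x = "Interonset interval (s)", y = "Activation",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
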