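#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   geom_vline geom_raster labs scale_fill_gradient2 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the training loss trace of an embedding fit
#'
#' One line per loss component over epochs, on a free y scale.
#'
#' @param object A `cs_rsee_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cs_rsee_fit
#' @export
autoplot.cs_rsee_fit <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~.data$component, scales = "free_y") +
    labs(x = "epoch", y = "loss component",
         title = "Hybrid embedding loss over training") +
    theme_minimal()
}

#' Plot a threshold-tuning utility curve
#'
#' The utility as a step function of the screening threshold, with the
#' selected threshold marked.
#'
#' @param object A `cs_tuning`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cs_tuning
#' @export
autoplot.cs_tuning <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$tau, y = .data$utility)) +
    geom_step() +
    geom_vline(xintercept = object$tau, linetype = "dashed") +
    labs(x = "screening threshold", y = "utility",
         title = sprintf("Utility curve (tau* = %.3f)", object$tau)) +
    theme_minimal()
}

#' Plot a screening surface
#'
#' The exertional risk field over the embedding-space grid with the
#' extracted near-level-set points overlaid. For 1-d embeddings the risk
#' is drawn as a curve; for 2-d as a raster.
#'
#' @param object A `cs_surface`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cs_surface
#' @export
autoplot.cs_surface <- function(object, ...) {
  grid <- attr(object, "grid")
  tau <- attr(object, "tau")
  if (!"h_2" %in% names(grid)) {
    ggplot(grid, aes(x = .data$h_1, y = .data$risk)) +
      geom_line() +
      geom_point(data = as_tibble(object), colour = "red") +
      geom_vline(xintercept = object$h_1, linetype = "dotted") +
      labs(x = "embedding coordinate", y = "exertional risk",
           title = sprintf("Screening level set at tau = %.2f", tau)) +
      theme_minimal()
  } else {
    ggplot(grid, aes(x = .data$h_1, y = .data$h_2)) +
      geom_raster(aes(fill = .data$risk - tau)) +
      scale_fill_gradient2(name = "risk - tau") +
      geom_point(data = as_tibble(object), size = 0.4) +
      labs(x = "embedding dim 1", y = "embedding dim 2",
           title = sprintf("Screening surface at tau = %.2f", tau)) +
      theme_minimal()
  }
}
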