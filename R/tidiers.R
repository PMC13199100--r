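#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.alps_result <- function(x, ...) {
  tibble::tibble(hemisphere = c("left", "right", "mean"),
                 alps = c(x$alps_left, x$alps_right, x$alps_mean))
}

#' @export
tidy.motion_qc <- function(x, ...) {
  n <- x$n_volumes
  tibble::tibble(volume = seq_len(n), fd = x$fd_series,
                 rotation_delta_deg = x$rotation_series,
                 flagged = seq_len(n) %in% x$flagged_volumes,
                 replaced = seq_len(n) %in% x$replaced_volumes)
}

#' @export
glance.motion_qc <- function(x, ...) {
  tibble::tibble(n_volumes = x$n_volumes, mean_fd = x$mean_fd,
                 n_flagged = length(x$flagged_volumes),
                 n_replaced = length(x$replaced_volumes),
                 flagged_fraction = length(x$flagged_volumes) / x$n_volumes,
                 excluded = x$excluded, reason = x$reason)
}

#' @export
tidy.interaction_fit <- function(x, ...) x$coefficients

#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, r.squared = x$r.squared,
                 sigma = sqrt(x$sigma2), df.residual = x$df, nobs = x$n,
                 standardized = x$standardized)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  if (x$type == "categorical") {
    tibble::tibble(variable = x$variable, test = x$test,
                   statistic = x$statistic, p = x$p)
  } else {
    tibble::tibble(variable = x$variable, test = x$test,
                   statistic = x$statistic, p = x$p,
                   n_posthoc = nrow(x$posthoc))
  }
}

#' @export
tidy.tensor_field <- function(x, ...) {
  shape <- dim(x$D)[1:3]
  coords <- grid_coordinates(shape, x$voxel_size, x$origin)
  tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 dxx = as.vector(x$dxx), dyy = as.vector(x$dyy),
                 dzz = as.vector(x$dzz), md = as.vector(x$md),
                 fa = as.vector(x$fa))
}

#' FD trace plot
#'
#' Framewise displacement per volume with the flag threshold and flagged
#' volumes highlighted.
#'
#' @param object A `motion_qc` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motion_qc <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$volume, y = .data$fd)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 1.5) +
    ggplot2::geom_hline(yintercept = object$thresholds$fd_flag_mm,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "volume", y = "framewise displacement (mm)",
                  color = "flagged",
                  title = sprintf("mean FD %.2f mm; %d/%d flagged%s",
                                  object$mean_fd,
                                  length(object$flagged_volumes),
                                  object$n_volumes,
                                  if (object$excluded) " [excluded]" else "")) +
    ggplot2::theme_minimal()
}

#' ROI diffusivity plot
#'
#' Axis-wise mean diffusivities per ROI underlying the ALPS ratio.
#'
#' @param object An `alps_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alps_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$diffusivities,
                           cols = c("dxx", "dyy", "dzz"),
                           names_to = "axis", values_to = "diffusivity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$diffusivity,
                                  fill = .data$axis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "mean diffusivity (mm²/s)", x = NULL,
                  title = sprintf("ALPS: left %.3f, right %.3f, mean %.3f",
                                  object$alps_left, object$alps_right,
                                  object$alps_mean)) +
    ggplot2::theme_minimal()
}

#' Group box plot
#'
#' Box plot of a continuous variable across groups, annotated with the
#' omnibus test.
#'
#' @param object A continuous `group_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  if (object$type != "continuous")
    stop("autoplot is defined for continuous comparisons only")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$value,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = object$variable,
                  title = sprintf("%s: %s p = %s", object$variable,
                                  object$test,
                                  format.pval(object$p, digits = 2))) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
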