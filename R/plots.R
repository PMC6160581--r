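#' Plot a capillary network projection
#'
#' Two-dimensional projection of the vessel centerlines, colored by a
#' per-vessel quantity (RBC speed by default when flow is solved).
#'
#' @param object A `capnet`.
#' @param color Name of a vessel column to map to color.
#' @param plane Projection plane: `"xy"`, `"xz"` or `"yz"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.capnet <- function(object, color = NULL,
                            plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  dims <- match(ax, c("x", "y", "z"))
  if (is.null(color)) {
    color <- if ("v_rbc" %in% names(object$vessels)) "v_rbc" else "diameter"
  }
  df <- purrr::map_dfr(seq_len(nrow(object$vessels)), function(k) {
    cl <- object$vessels$centerline[[k]]
    tibble::tibble(vessel = object$vessels$vessel[k],
                   a = cl[, dims[1]], b = cl[, dims[2]],
                   value = abs(object$vessels[[color]][k]))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, group = .data$vessel,
                                   color = .data$value)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = paste0(ax[1], " [um]"), y = paste0(ax[2], " [um]"),
                  color = color) +
    ggplot2::theme_minimal()
}

#' Plot the three-way COSH comparison
#'
#' @param object A `cosh_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosh_comparison <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = c("ode_geometric",
                                            "ode_functional", "lagrangian"))
  ggplot2::ggplot(tab, ggplot2::aes(.data$model, .data$cosh)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$cosh)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "COSH (flow-weighted SD of distal HS)",
                  subtitle = sprintf("total reduction %.1f%%",
                                     object$reduction_total)) +
    ggplot2::theme_minimal()
}

#' Plot flow-weighted outflow saturation distributions
#'
#' @param study A `cosh_study`.
#' @param binwidth Histogram bin width in saturation units.
#' @return A ggplot object (one panel per model).
#' @export
plot_outflow_distributions <- function(study, binwidth = 0.02) {
  df <- dplyr::bind_rows(
    tibble::tibble(model = "ode_geometric", s = study$paths_geo$s_v,
                   w = study$paths_geo$weight),
    tibble::tibble(model = "ode_functional", s = study$paths_fun$s_v,
                   w = study$paths_fun$weight),
    tibble::tibble(model = "lagrangian", s = study$lag_paths$s_v,
                   w = study$lag_paths$weight)
  )
  df$model <- factor(df$model, levels = c("ode_geometric", "ode_functional",
                                          "lagrangian"))
  ggplot2::ggplot(df, ggplot2::aes(.data$s, weight = .data$w)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "firebrick",
                            color = "white") +
    ggplot2::facet_wrap(~model, ncol = 1) +
    ggplot2::labs(x = "distal hemoglobin saturation S_v",
                  y = "RBC-flow weighted frequency") +
    ggplot2::theme_minimal()
}

#' Plot saturation heterogeneity decay along vessels
#'
#' Rate of change of the within-vessel saturation SD across each vessel
#' against its inlet SD, by vessel class (the signature of RBC diffusive
#' interaction damping strong heterogeneity while hematocrit fluctuations
#' seed weak heterogeneity).
#'
#' @param study A `cosh_study`.
#' @return A ggplot object.
#' @export
plot_sigma_evolution <- function(study) {
  vs <- study$run$vessel_stats
  cls <- classify_bifurcations(study$net)
  df <- dplyr::left_join(vs, cls, by = "vessel")
  df$rate <- (df$sigma_v - df$sigma_a) / df$length
  ggplot2::ggplot(df, ggplot2::aes(.data$sigma_a, .data$rate,
                                   shape = .data$class,
                                   color = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(sigma[S * ",a"]),
                  y = expression(d * sigma[S] / d * x ~ "[1/um]"),
                  shape = "vessel type", color = "vessel type") +
    ggplot2::theme_minimal()
}

#' Plot saturation drop against transit time
#'
#' @param study A `cosh_study`.
#' @return A ggplot object.
#' @export
plot_drop_vs_transit <- function(study) {
  ggplot2::ggplot(study$lag_paths,
                  ggplot2::aes(.data$tau, .data$delta_s)) +
    ggplot2::geom_point(alpha = 0.4, color = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "black", linewidth = 0.5) +
    ggplot2::labs(x = "transit time [s]", y = expression(Delta * S)) +
    ggplot2::theme_minimal()
}
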