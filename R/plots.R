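#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a delay-wavelength heat map for [ta_cube()] (log-scaled positive delays),
#' component spectra for a [fit_global()] result, and a donor-acceptor
#' time-constant matrix for a [cluster_network()] table.
#' `plot_rate_map()` draws the classified pigment-pair rate map in the
#' membrane (x-y) plane.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot.
#' @name eetscape-plots
NULL

#' @rdname eetscape-plots
#' @export
autoplot.ta_cube <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$delay_ps, y = .data$wavelength_nm,
                 fill = .data$signal)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "delay (ps)", y = "wavelength (nm)", fill = "signal") +
    theme_minimal()
}

#' @rdname eetscape-plots
#' @export
autoplot.das_fit <- function(object, ...) {
  df <- augment(object)
  df$component <- factor(paste0(signif(df$lifetime_ps, 3), " ps"),
                         levels = paste0(signif(object$lifetimes_ps, 3),
                                         " ps"))
  ggplot(df, aes(x = .data$wavelength_nm, y = .data$amplitude,
                 color = .data$component)) +
    geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    geom_line() +
    labs(x = "wavelength (nm)", y = "DAS amplitude",
         color = "lifetime") +
    theme_minimal()
}

#' @rdname eetscape-plots
#' @export
autoplot.eet_cluster_table <- function(object, ...) {
  df <- as_tibble(object)
  df$tau_shown <- ifelse(is.finite(df$tau_ps), df$tau_ps, NA_real_)
  ggplot(df, aes(x = .data$acceptor, y = .data$donor,
                 fill = log10(.data$tau_shown))) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey90", direction = -1) +
    labs(x = "acceptor cluster", y = "donor cluster",
         fill = "log10 tau (ps)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' @rdname eetscape-plots
#' @param model the [eet_structure()] the network was computed from.
#' @param net a classified rate map from [classify_rates()].
#' @export
plot_rate_map <- function(model, net) {
  dip <- pigment_dipoles(model)
  pos <- setNames(seq_len(nrow(dip)), dip$pigment_id)
  df <- as_tibble(net)
  df$x <- dip$x[pos[df$donor]]
  df$y <- dip$y[pos[df$donor]]
  df$xend <- dip$x[pos[df$acceptor]]
  df$yend <- dip$y[pos[df$acceptor]]
  ggplot() +
    geom_point(data = dip, aes(x = .data$x, y = .data$y),
               color = "grey70", size = 0.8) +
    geom_segment(data = df,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, color = .data$class,
                     linewidth = .data$class)) +
    scale_color_manual(values = c("red", "grey30", "black")[
      seq_len(length(levels(df$class)))]) +
    scale_linewidth_manual(values = c(0.9, 0.6, 0.3)[
      seq_len(length(levels(df$class)))]) +
    coord_equal() +
    labs(x = "x (A)", y = "y (A)", color = "time constant",
         linewidth = "time constant") +
    theme_minimal()
}
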