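## ggplot2 views of the result objects.

#' Plot a parcel-wise association map
#'
#' Lollipop view of per-parcel covariate-adjusted Spearman correlations,
#' significant parcels (FDR) highlighted.
#'
#' @param assoc Output of [parcelwise_association()].
#' @return A ggplot object.
#' @export
plot_association_map <- function(assoc) {
  assoc$idx <- seq_len(nrow(assoc))
  ggplot(assoc, aes(x = .data$idx, y = .data$r)) +
    geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    geom_segment(aes(xend = .data$idx, yend = 0), colour = "grey70") +
    geom_point(aes(colour = .data$significant), size = 1.2) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                        name = "FDR significant") +
    labs(x = "parcel", y = "adjusted Spearman r",
         title = "Parcel-wise brain-behavior association") +
    theme_minimal()
}

#' Plot a network summary of bootstrap ratios
#'
#' @param net Output of [network_summary()] (optionally with a `component`
#'   column, which is faceted).
#' @return A ggplot object.
#' @export
plot_network_summary <- function(net) {
  long <- tidyr::pivot_longer(net,
    c("positive_contribution", "negative_contribution"),
    names_to = "direction", values_to = "contribution")
  long$direction <- ifelse(long$direction == "positive_contribution",
                           "BSR > 2", "BSR < -2")
  p <- ggplot(long, aes(x = .data$network, y = .data$contribution,
                        fill = .data$direction)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "size-controlled contribution",
         title = "Functional-network contributions") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 35, hjust = 1))
  if ("component" %in% names(net)) p <- p + facet_wrap(~component)
  p
}

#' @describeIn fit_pls Behavior-salience profiles and explained covariance
#'   per latent component.
#' @export
autoplot.pls_fit <- function(object, ...) {
  u <- object$behavior_saliences
  d <- tibble(
    trait = rep(rownames(u), ncol(u)),
    component = rep(sprintf("LC%d (%.0f%%)", seq_len(ncol(u)),
                            100 * object$explained_cov), each = nrow(u)),
    salience = as.vector(u))
  ggplot(d, aes(x = .data$trait, y = .data$salience)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~component) +
    labs(x = NULL, y = "behavior salience",
         title = "PLS behavior saliences") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 35, hjust = 1))
}

#' @describeIn run_heritability Heritability estimates with standard-error
#'   bars across scanned traits/parcels.
#' @param object A heritability scan tibble from [run_heritability()].
#' @param ... Unused.
#' @export
plot_heritability <- function(object, ...) {
  object$idx <- seq_len(nrow(object))
  ggplot(object, aes(x = .data$idx, y = .data$h2)) +
    geom_pointrange(aes(ymin = pmax(0, .data$h2 - .data$se_h2),
                        ymax = pmin(1, .data$h2 + .data$se_h2),
                        colour = .data$significant)) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                        name = "FDR significant") +
    labs(x = "trait / parcel", y = expression(h^2),
         title = "Heritability scan") +
    theme_minimal()
}
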