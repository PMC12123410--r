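#' Plot methods for pipeline result objects
#'
#' ggplot2 `autoplot()` methods: NES per TF for `tfa_mra`, PC1/PC2 sample
#' map for `tfa_structure`, Kaplan-Meier step curves for `tfa_km`, and
#' activity distributions for `tfa_activity`.
#'
#' @param object the result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name tfa-plots
NULL

#' @rdname tfa-plots
#' @export
autoplot.tfa_mra <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$nes)) %>%
    arrange(.data$nes) %>%
    mutate(tf = factor(.data$tf, levels = .data$tf))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$tf,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NES (tumor vs NAT)", y = NULL, fill = "p <= alpha") +
    ggplot2::theme_minimal()
}

#' @rdname tfa-plots
#' @export
autoplot.tfa_activity <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$tf, y = .data$score,
                               fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "TF activity score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname tfa-plots
#' @export
autoplot.tfa_structure <- function(object, ...) {
  pct <- round(100 * object$explained[1:2], 1)
  ggplot2::ggplot(object$pca,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$condition)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' @rdname tfa-plots
#' @export
autoplot.tfa_km <- function(object, ...) {
  df <- tidy(object)
  # prepend the t = 0, S = 1 point per group
  df0 <- df %>% distinct(.data$group) %>%
    mutate(time = 0, estimate = 1)
  ggplot2::ggplot(bind_rows(df0, df),
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p)) +
    ggplot2::theme_minimal()
}

#' Plot group-wise kinase activity profiles
#'
#' @param profile tibble from [group_kinase_profile()].
#' @return a ggplot object.
#' @export
plot_kinase_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.2) +
    ggplot2::facet_wrap(~kinase, scales = "free_y") +
    ggplot2::labs(x = "Patient group", y = "Mean kinase activity (z)") +
    ggplot2::theme_minimal()
}
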