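#' Plot cross-validated test concordance indices
#'
#' Boxplot of the outer-fold test CIs of one or more cross-validation runs;
#' pass a named list to compare representations side by side.
#'
#' @param object a `netnorm_cv` or a named list of them.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot netnorm_cv
#' @export
autoplot.netnorm_cv <- function(object, ...) {
  runs <- if (inherits(object, "netnorm_cv")) list(cv = object) else object
  df <- purrr::imap_dfr(runs, function(cv, nm) {
    dplyr::mutate(cv$results, run = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$test_ci)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "test concordance index") +
    ggplot2::theme_minimal()
}

#' Plot a consensus co-clustering matrix
#'
#' Heatmap of the consensus matrix with patients ordered by the final
#' hierarchical clustering, so stable subtypes appear as crisp blocks.
#'
#' @param object a `consensus_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- object$hclust$order
  M <- object$Cmat[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$value <- M[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1), name = "consensus") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("N = %d, PAC = %.3f", object$N, object$PAC)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by subtype
#'
#' Step-function survival curves for each group, the standard display for
#' judging whether subtypes separate in survival.
#'
#' @param surv data frame with columns `time` and `event`.
#' @param groups group labels, one per patient.
#' @return a ggplot object.
#' @export
plot_km <- function(surv, groups) {
  s <- as_survival(surv)
  fit <- survival::survfit(survival::Surv(s$y, s$delta) ~ g,
                           data = data.frame(g = as.factor(groups)))
  strata <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  df <- tibble(time = fit$time, surv = fit$surv,
               group = sub("^g=", "", strata))
  df0 <- dplyr::distinct(df, .data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  ggplot2::ggplot(dplyr::bind_rows(df0, df),
                  ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = "subtype") +
    ggplot2::theme_minimal()
}
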