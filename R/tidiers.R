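# broom-style accessors and plotting helpers for fitted objects and result
# tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Goldman-Yang fit
#'
#' @param x A `"gy_fit"` object from [fit_gy()].
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity (`t`, `omega`, the
#'   free exchangeability rates, `ka`, `ks`).
#' @export
tidy.gy_fit <- function(x, ...) {
  rate_names <- c("r_AC", "r_AG", "r_AT", "r_CG", "r_CT", "r_GT")
  free <- GY_MODELS[[x$model]]$template > 0
  tibble::tibble(
    term = c("t", "omega", rate_names[free], "ka", "ks"),
    estimate = c(x$t, x$omega, x$rates[free], x$ka, x$ks)
  )
}

#' Summarise a Goldman-Yang fit in one row
#'
#' @inheritParams tidy.gy_fit
#' @return A one-row tibble: `model`, `n` (codons), `k`, `lnL`, `AICc`,
#'   `t`, `omega`, `ka`, `ks`, `converged`.
#' @export
glance.gy_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, k = x$k, lnL = x$lnL,
                 AICc = x$AICc, t = x$t, omega = x$omega, ka = x$ka,
                 ks = x$ks, converged = x$converged)
}

#' Tidy a model-selection result
#'
#' @param x A `"gy_model_set"` from [model_select()].
#' @param ... Unused.
#' @return The ranked tibble of candidate fits (model, k, lnL, AICc,
#'   delta, weight, t, omega, ka, ks).
#' @export
tidy.gy_model_set <- function(x, ...) x$table

#' @rdname tidy.gy_model_set
#' @export
glance.gy_model_set <- function(x, ...) {
  tibble::tibble(n_models = nrow(x$table), best = x$table$model[1],
                 best_AICc = x$table$AICc[1],
                 best_weight = x$table$weight[1])
}

#' Akaike-weight profile of a model-selection result
#'
#' @param object A `"gy_model_set"` from [model_select()].
#' @param ... Unused.
#' @return A ggplot: candidate models (in AICc order) against their Akaike
#'   weights.
#' @export
autoplot.gy_model_set <- function(object, ...) {
  tab <- object$table
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = paste("Model support,", object$sequence)) +
    ggplot2::theme_minimal()
}

#' Ka versus Ks scatter of a result table
#'
#' Plots each (pair, method) result in the (Ks, Ka) plane with the neutral
#' `Ka = Ks` diagonal; points above the line indicate positive selection.
#'
#' @param results A [kaks()] result tibble.
#' @return A ggplot object.
#' @export
plot_kaks <- function(results) {
  df <- dplyr::filter(results, !is.na(.data$ka), !is.na(.data$ks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks, y = .data$ka,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Ks (synonymous substitutions per site)",
                  y = "Ka (nonsynonymous substitutions per site)") +
    ggplot2::theme_minimal()
}
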