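#' Tidy a stag-hunt run into its per-generation record
#'
#' @param x A `stag_run` from [evolve()] or [gt_evolve()].
#' @param ... Unused.
#' @return A tibble with one row per generation: `generation`,
#'   `mean_fitness`, `stag_pct` (percentage of stags hunted successfully
#'   among all prey hunted), mean per-episode prey counts, plus the
#'   condition, model and seed identifiers.
#' @export
tidy.stag_run <- function(x, ...) {
  dplyr::mutate(x$record,
                model = x$model,
                condition = x$config$condition,
                seed = x$seed)
}

#' One-row summary of a stag-hunt run
#'
#' @param x A `stag_run`.
#' @param ... Unused.
#' @return A one-row tibble: identifiers, generations run, final-genera-
#'   tion mean fitness and successful-stag percentage, and whether the
#'   run ended majority-stag (final `stag_pct > 50`).
#' @export
glance.stag_run <- function(x, ...) {
  g <- nrow(x$record)
  final <- if (g > 0) x$record[g, ] else
    tibble::tibble(mean_fitness = NA_real_, stag_pct = NA_real_)
  tibble::tibble(model = x$model,
                 condition = x$config$condition,
                 seed = x$seed,
                 n_generations = g,
                 final_mean_fitness = final$mean_fitness,
                 final_stag_pct = final$stag_pct,
                 majority_stag = !is.na(final$stag_pct) & final$stag_pct > 50)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the evolution of cooperative hunting in a run
#'
#' @param object A `stag_run`.
#' @param ... Unused.
#' @return A ggplot of the successful-stag percentage per generation.
#' @export
autoplot.stag_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$stag_pct)) +
    ggplot2::geom_line(colour = "#c0392b") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(
      x = "Generation",
      y = "Stags hunted successfully (% of prey hunted)",
      title = paste0(object$config$condition, " (", object$model, " model)")) +
    ggplot2::theme_minimal()
}

#' Plot per-generation curves for a set of runs
#'
#' Overlays the successful-stag percentage of several runs, the standard
#' presentation of an experimental condition.
#'
#' @param runs A list of `stag_run` objects.
#' @return A ggplot with one line per run.
#' @export
plot_stag_curves <- function(runs) {
  if (inherits(runs, "stag_run")) runs <- list(runs)
  df <- dplyr::bind_rows(purrr::imap(runs, function(r, i) {
    dplyr::mutate(tidy(r), run = i)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$stag_pct,
                                   group = .data$run)) +
    ggplot2::geom_line(alpha = 0.4, colour = "#c0392b") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "Generation",
                  y = "Stags hunted successfully (% of prey hunted)") +
    ggplot2::theme_minimal()
}

#' Stacked prey-count bars for the last generation of each run
#'
#' Mirrors the standard condition summary figure: per run, the mean
#' per-episode number of hares hunted, stags hunted cooperatively, and
#' stags hunted alone (failed hunts under the baseline rewards).
#'
#' @param summary A [last_generation_summary()] tibble.
#' @return A ggplot.
#' @export
plot_last_generation <- function(summary) {
  long <- tidyr::pivot_longer(
    summary,
    cols = c("hares_mean", "coop_stags_mean", "solo_stags_mean"),
    names_to = "category", values_to = "mean_count")
  long$category <- factor(long$category,
                          levels = c("solo_stags_mean", "coop_stags_mean",
                                     "hares_mean"),
                          labels = c("stags hunted alone",
                                     "stags hunted cooperatively",
                                     "hares hunted"))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$run),
                                     y = .data$mean_count,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c("grey60", "#e91e63", "#4caf50")) +
    ggplot2::labs(x = "Run", y = "Mean prey hunted per episode",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
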