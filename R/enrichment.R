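# Rare-cell enrichment calculus: how classifier operating characteristics
# translate into fold enrichment of a rare target population in the sorted
# (classifier-positive) fraction.

#' Expected enrichment of a rare population after classifier sorting
#'
#' For a target population at prior fraction `prior` (rarity), a sorter
#' that keeps classifier-positive cells yields a sorted sample whose target
#' concentration is the Bayes precision
#' `tpr * p / (tpr * p + fpr * (1 - p))`; enrichment is that precision
#' divided by the prior. An uninformative classifier (tpr = fpr) gives
#' enrichment 1; a perfect one (tpr = 1, fpr = 0) gives the ceiling 1/p.
#'
#' @param tpr True positive rate(s) in [0, 1].
#' @param fpr False positive rate(s) in [0, 1].
#' @param prior Target rarity (prior fraction) in (0, 1).
#' @return Tibble: `prior`, `tpr`, `fpr`, `precision`, `enrichment`.
#' @export
enrichment <- function(tpr, fpr, prior) {
  n <- max(length(tpr), length(fpr), length(prior))
  tpr <- rep_len(tpr, n); fpr <- rep_len(fpr, n); prior <- rep_len(prior, n)
  if (any(tpr < 0 | tpr > 1) || any(fpr < 0 | fpr > 1)) {
    stop("tpr and fpr must lie in [0, 1]", call. = FALSE)
  }
  if (any(prior <= 0 | prior >= 1)) {
    stop("prior must lie in (0, 1)", call. = FALSE)
  }
  den <- tpr * prior + fpr * (1 - prior)
  if (any(den == 0)) {
    stop("classifier selects nothing (tpr = fpr = 0): enrichment undefined",
         call. = FALSE)
  }
  precision <- tpr * prior / den
  tibble::tibble(prior = prior, tpr = tpr, fpr = fpr,
                 precision = precision, enrichment = precision / prior)
}

#' Enrichment as a function of false positive rate
#'
#' Evaluates [enrichment()] over a grid of false positive rates at fixed
#' TPR and prior; enrichment increases steeply as the false positive rate
#' drops below the prior-scaled regime, saturating at 1/prior.
#'
#' @param tpr True positive rate.
#' @param prior Target rarity in (0, 1).
#' @param fpr_grid Grid of false positive rates in (0, 1].
#' @return Tibble as in [enrichment()], one row per grid point, ordered by
#'   `fpr`.
#' @export
enrichment_curve <- function(tpr, prior,
                             fpr_grid = 10^seq(-4, 0, length.out = 41)) {
  if (any(fpr_grid <= 0 | fpr_grid > 1)) {
    stop("fpr_grid must lie in (0, 1]", call. = FALSE)
  }
  dplyr::arrange(enrichment(tpr, fpr_grid, prior), .data$fpr)
}

#' Expected composition of a sorted sample
#'
#' Expected-value accounting of a sort of `n` cells: how many target and
#' non-target cells the classifier selects.
#'
#' @inheritParams enrichment
#' @param n Total cells processed.
#' @return Tibble: `target_selected`, `nontarget_selected`,
#'   `total_selected`, `target_fraction`.
#' @export
sorted_composition <- function(tpr, fpr, prior, n) {
  ts <- n * prior * tpr
  ns <- n * (1 - prior) * fpr
  tibble::tibble(target_selected = ts, nontarget_selected = ns,
                 total_selected = ts + ns,
                 target_fraction = ifelse(ts + ns > 0, ts / (ts + ns), NA_real_))
}

#' @describeIn enrichment_curve Log-log enrichment curve plot.
#' @param curve Tibble from [enrichment_curve()].
#' @export
plot_enrichment_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$fpr, .data$enrichment)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "false positive rate",
                  y = sprintf("fold enrichment (prior %.4g)", curve$prior[1]))
}
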