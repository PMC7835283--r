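# Group-level statistics of coupling change across seizure phases:
# per-pair h2 differences against a control period, exact Wilcoxon
# signed-rank tests with the seizures as replicates, and Benjamini-Hochberg
# step-up control of the false discovery rate.

#' Per-pair h2 differences between seizure phases and a control period
#'
#' For each unordered pair of contacts on distinct electrodes, collapses
#' the two directed h2 values to one (the maximum over directions by
#' default), then subtracts the seizure-matched control-period value from
#' the event-phase value — one difference per seizure. Seizures in which a
#' phase is absent simply contribute no difference for that phase.
#'
#' @param coupling Long coupling table (`seizure_id, phase, src, dst, h2`),
#'   e.g. from [event_coupling()], containing both the event phases and the
#'   control phase.
#' @param control_phase Phase label serving as the control period; default
#'   `"baseline"` (the pre-ictal normative window).
#' @param collapse How to collapse the two directions of a pair: `"max"`
#'   (default) or `"mean"`.
#' @return A tibble `pair_a, pair_b, phase, seizure_id, diff` with one row
#'   per pair, phase and contributing seizure.
#' @export
pair_differences <- function(coupling, control_phase = "baseline",
                             collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  fn <- if (collapse == "max") max else mean
  pairs <- coupling |>
    dplyr::mutate(pair_a = pmin(.data$src, .data$dst),
                  pair_b = pmax(.data$src, .data$dst)) |>
    dplyr::filter(contact_electrode(.data$pair_a) !=
                    contact_electrode(.data$pair_b)) |>
    dplyr::group_by(.data$seizure_id, .data$phase,
                    .data$pair_a, .data$pair_b) |>
    dplyr::summarise(h2 = fn(.data$h2), .groups = "drop")
  ctl <- pairs |>
    dplyr::filter(.data$phase == control_phase) |>
    dplyr::select("seizure_id", "pair_a", "pair_b", h2_control = "h2")
  pairs |>
    dplyr::filter(.data$phase != control_phase) |>
    dplyr::inner_join(ctl, by = c("seizure_id", "pair_a", "pair_b")) |>
    dplyr::mutate(diff = .data$h2 - .data$h2_control) |>
    dplyr::select("pair_a", "pair_b", "phase", "seizure_id", "diff") |>
    dplyr::arrange(.data$phase, .data$pair_a, .data$pair_b, .data$seizure_id)
}

# exact null distribution of 2*W (doubled ranks keep ties integral):
# probability vector over 0..sum(r2)
signrank_exact_dist <- function(r2) {
  f <- 1
  for (r in r2) {
    g <- c(f, numeric(r))
    g[(r + 1L):length(g)] <- g[(r + 1L):length(g)] + f
    f <- g / 2
  }
  f
}

#' Wilcoxon signed-rank test of paired differences
#'
#' Tests whether paired differences are symmetric about zero. Zero
#' differences are dropped (the standard convention); the statistic is the
#' sum of the ranks of the positive differences among the absolute values
#' (ties get average ranks). For up to 25 nonzero differences the
#' two-sided p-value comes from the exact tie-aware null distribution
#' (enumeration over sign assignments via convolution); above that a
#' tie-corrected normal approximation is used. All differences zero gives
#' `W = 0`, `p = 1`.
#'
#' @param diffs Numeric vector of paired differences (length >= 1).
#' @param exact_max Largest `n_effective` for which the exact distribution
#'   is used; default 25.
#' @return A one-row tibble: `n_effective`, `statistic` (W), `p_value`,
#'   `method`.
#' @examples
#' signed_rank(c(0.2, 0.1, 0.3, 0.15, 0.25))  # n = 5, all positive
#' @export
signed_rank <- function(diffs, exact_max = 25L) {
  stopifnot(length(diffs) >= 1L)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble(n_effective = 0L, statistic = 0, p_value = 1,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    f <- signrank_exact_dist(r2)
    w2 <- as.integer(round(2 * W))
    cdf <- cumsum(f)
    p_le <- cdf[w2 + 1L]
    p_ge <- if (w2 == 0L) 1 else 1 - cdf[w2]
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
    z <- (W - mu) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble(n_effective = n, statistic = W, p_value = p, method = method)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the p-values, computes the per-rank critical values
#' `c_i = i * q / m`, and declares significant the largest prefix of the
#' sorted order whose p-value lies at or below its critical value
#' (everything up to `max{i : p_(i) <= c_i}`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate; default 0.05.
#' @return A tibble of class `bh_result`, in ascending-p order: `index`
#'   (position in the input), `p_value`, `rank`, `critical`,
#'   `significant`; the cutoff rank is attached as attribute
#'   `"cutoff_index"` (0 when nothing is significant).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) {
    stop_ictalnet("empty p-value vector", "ictalnet_stats_error")
  }
  if (any(p_values < 0 | p_values > 1)) {
    stop_ictalnet("p-values must lie in [0, 1]", "ictalnet_stats_error")
  }
  stopifnot(q > 0, q < 1)
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  crit <- seq_len(m) * q / m
  below <- which(ps <= crit)
  cutoff <- if (length(below)) max(below) else 0L
  out <- tibble(index = ord, p_value = ps, rank = seq_len(m),
                critical = crit,
                significant = seq_len(m) <= cutoff)
  attr(out, "cutoff_index") <- cutoff
  attr(out, "q") <- q
  class(out) <- unique(c("bh_result", class(out)))
  out
}

#' Signed-rank tests for every pair and phase, with B-H control
#'
#' Runs [signed_rank()] on each pair's difference vector, separately per
#' phase, and applies [bh_adjust()] within each phase (each phase is its
#' own family of tests).
#'
#' @param diffs A [pair_differences()] table.
#' @param q False discovery rate; default 0.05.
#' @return A tibble of class `ictal_ranktest`: `pair_a, pair_b, phase, n,
#'   statistic, p_value, bh_critical, significant`, sorted by phase then
#'   ascending p (ties by pair label). The difference table is attached as
#'   attribute `"diffs"` for plotting.
#' @export
phase_signed_rank <- function(diffs, q = 0.05) {
  res <- diffs |>
    dplyr::group_by(.data$phase, .data$pair_a, .data$pair_b) |>
    dplyr::summarise(signed_rank(.data$diff), .groups = "drop") |>
    dplyr::rename(n = "n_effective") |>
    dplyr::select(-"method")
  res <- res |>
    dplyr::group_by(.data$phase) |>
    dplyr::group_modify(function(g, key) {
      bh <- bh_adjust(g$p_value, q = q)
      g$bh_critical <- bh$critical[order(bh$index)]
      g$significant <- bh$significant[order(bh$index)]
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$phase, .data$p_value, .data$pair_a, .data$pair_b)
  attr(res, "diffs") <- diffs
  attr(res, "q") <- q
  class(res) <- unique(c("ictal_ranktest", class(res)))
  res
}

#' @rdname phase_signed_rank
#' @param x An `ictal_ranktest` table.
#' @param ... Unused.
#' @export
glance.ictal_ranktest <- function(x, ...) {
  x |>
    as_tibble() |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(n_tests = dplyr::n(),
                     n_significant = sum(.data$significant),
                     min_p = min(.data$p_value), .groups = "drop")
}

#' Pairs with the smallest p-values, with their difference vectors
#'
#' Selects the `k` tests with the smallest p-values (per phase when the
#' input covers several), ties broken lexicographically by pair label, and
#' attaches each pair's per-seizure differences in long format — the data
#' behind the phase-change boxplots.
#'
#' @param results An [phase_signed_rank()] table (or any tibble with
#'   `pair_a, pair_b, phase, p_value`).
#' @param diffs The matching [pair_differences()] table; defaults to the
#'   one attached to `results`.
#' @param k Number of pairs to keep per phase; default 25. When fewer
#'   tests exist, all are returned with a warning.
#' @return A tibble `pair_a, pair_b, phase, p_value, seizure_id, diff` in
#'   ascending-p order within phase.
#' @export
top_pairs <- function(results, diffs = attr(results, "diffs"), k = 25L) {
  stopifnot(!is.null(diffs))
  sel <- results |>
    as_tibble() |>
    dplyr::group_by(.data$phase) |>
    dplyr::arrange(.data$p_value, .data$pair_a, .data$pair_b,
                   .by_group = TRUE) |>
    dplyr::mutate(p_rank = dplyr::row_number()) |>
    dplyr::ungroup()
  if (k > max(sel$p_rank)) {
    warn(sprintf("k = %d exceeds the %d available tests; returning all",
                 k, max(sel$p_rank)))
  }
  sel |>
    dplyr::filter(.data$p_rank <= k) |>
    dplyr::select("pair_a", "pair_b", "phase", "p_value", "p_rank") |>
    dplyr::inner_join(diffs, by = c("pair_a", "pair_b", "phase")) |>
    dplyr::arrange(.data$phase, .data$p_rank, .data$seizure_id)
}

#' Boxplots of the top pairs' phase-minus-control differences
#'
#' @param top A [top_pairs()] table.
#' @return A ggplot object, one boxplot per pair, faceted by phase.
#' @export
plot_top_pairs <- function(top) {
  top <- dplyr::mutate(top, pair = paste(.data$pair_a, .data$pair_b,
                                         sep = "-"))
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$p_rank), y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = NULL,
                  y = expression(h^2 ~ "difference vs control")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
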