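#' Percent-of-maximum recovery
#'
#' Recovering plots cannot be expected to reach perfect similarity with
#' their reference: undisturbed plots drift apart over time and differ among
#' themselves in space. Recovery is therefore expressed as the observed
#' similarity as a percentage of the maximum attainable similarity for the
#' comparison design (see [assess_recovery()]).
#'
#' @param observed observed mean similarity (>= 0).
#' @param maximum maximum-attainable mean similarity (> 0).
#' @return `100 * observed / maximum`, at full precision. For display the
#'   convention is integer percent, half-up: `round_half_up(x)`.
#' @examples
#' recovery_percent(0.50, 0.74)                 # 67.57...
#' round_half_up(recovery_percent(0.50, 0.74))  # 68
#' @export
recovery_percent <- function(observed, maximum) {
  if (any(maximum <= 0))
    abort_undefined("recovery is undefined when the maximum similarity is <= 0")
  if (any(observed < 0))
    abort_validation("observed similarity must be non-negative")
  100 * observed / maximum
}

complete_pairs <- function(collection) {
  meta <- collection$meta
  paired <- meta[!is.na(meta$pair_id), ]
  if (nrow(paired) == 0) return(data.frame(pair_id = character(0)))
  pid <- sort(unique(paired$pair_id), method = "radix")
  data.frame(
    pair_id = pid,
    gap_plot = vapply(pid, function(p)
      paired$plot_id[paired$pair_id == p & paired$treatment == "gap"], ""),
    control_plot = vapply(pid, function(p)
      paired$plot_id[paired$pair_id == p & paired$treatment == "control"], ""),
    row.names = NULL)
}

paired_t <- function(obs, max_) {
  d <- obs - max_
  n <- length(d)
  if (n < 2) return(NULL)
  if (stats::sd(d) == 0) {
    # degenerate: identical differences across pairs; t.test() refuses
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  tt <- stats::t.test(obs, max_, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Assess forest recovery against its maximum-attainable similarity
#'
#' Runs one of the two comparison designs on a collection of paired
#' gap/control plot censuses, for one similarity index:
#'
#' * **temporal** — how similar is each gap plot now to its own pre-
#'   disturbance composition? Observed = sim(pre-gap, post-gap) per pair;
#'   maximum attainable = sim(pre-control, post-control), i.e. how much an
#'   *undisturbed* plot resembles its own past over the same interval.
#' * **spatial** (space-for-time substitution) — how similar is each gap
#'   plot now to its contemporaneous undisturbed control? Observed =
#'   sim(post-gap, post-control); maximum = sim(pre-gap, pre-control), the
#'   similarity the pair had before disturbance.
#'
#' The recovery figure is `100 * mean(observed) / mean(maximum)` (ratio of
#' means, not mean of per-pair ratios), and a two-tailed paired t-test
#' (paired by `pair_id`) asks whether observed similarities are still
#' distinguishable from their maxima.
#'
#' Gap plots without a monitored control (`pair_id` NA) contribute to the
#' temporal observed mean — their own history is reference enough — but are
#' excluded from spatial comparisons and from the paired test;
#' `strict_pairs = TRUE` excludes them everywhere.
#'
#' @param collection a [census_collection()].
#' @param mode `"temporal"` or `"spatial"`.
#' @param index_name similarity index (see [pairwise_similarity()]).
#' @param pre_label,post_label census labels of the pre- and
#'   post-disturbance enumerations.
#' @param strict_pairs drop unpaired gap plots everywhere.
#' @param alpha significance level for the printed annotation.
#' @return A `recovery_assessment`: per-pair observed/maximum values, their
#'   means, `percent_of_maximum`, and the paired test (`t`, `df`, `p`).
#' @examples
#' coll <- simulate_censuses(sim_config(seed = 42))
#' assess_recovery(coll, "temporal", "tanner")
#' @export
assess_recovery <- function(collection, mode = c("temporal", "spatial"),
                            index_name = "tanner",
                            pre_label = "pre", post_label = "post",
                            strict_pairs = FALSE, alpha = 0.05) {
  mode <- match.arg(mode)
  index_name <- match.arg(index_name, similarity_index_names)
  pairs <- complete_pairs(collection)
  if (nrow(pairs) == 0)
    abort_design("no complete gap/control pair in the collection")

  sim <- function(pa, ca, pb, cb)
    similarity_value(collection, pa, ca, pb, cb, index_name)

  if (mode == "temporal") {
    pairs$observed <- mapply(function(g, ...) sim(g, pre_label, g, post_label),
                             pairs$gap_plot)
    pairs$maximum <- mapply(function(c, ...) sim(c, pre_label, c, post_label),
                            pairs$control_plot)
  } else {
    pairs$observed <- mapply(function(g, c) sim(g, post_label, c, post_label),
                             pairs$gap_plot, pairs$control_plot)
    pairs$maximum <- mapply(function(g, c) sim(g, pre_label, c, pre_label),
                            pairs$gap_plot, pairs$control_plot)
  }

  unpaired <- collection$meta[is.na(collection$meta$pair_id) &
                                collection$meta$treatment == "gap", "plot_id"]
  extra <- data.frame(plot_id = character(0), observed = numeric(0))
  if (mode == "temporal" && !strict_pairs && length(unpaired) > 0) {
    extra <- data.frame(
      plot_id = unpaired,
      observed = vapply(unpaired, function(g)
        sim(g, pre_label, g, post_label), numeric(1)),
      row.names = NULL)
  }

  mean_observed <- mean(c(pairs$observed, extra$observed))
  mean_maximum <- mean(pairs$maximum)
  if (mean_maximum <= 0)
    abort_undefined("mean maximum similarity is 0; recovery undefined")

  test <- paired_t(pairs$observed, pairs$maximum)
  structure(list(
    mode = mode, index_name = index_name,
    pre_label = pre_label, post_label = post_label,
    per_pair = pairs, unpaired = extra,
    mean_observed = mean_observed, mean_maximum = mean_maximum,
    percent_of_maximum = recovery_percent(mean_observed, mean_maximum),
    comparison_test = test,
    significant = if (is.null(test)) NA else test$p <= alpha,
    alpha = alpha),
    class = "recovery_assessment")
}

#' @export
print.recovery_assessment <- function(x, ...) {
  cat(sprintf("Recovery assessment (%s, %s)\n", x$mode, x$index_name))
  cat(sprintf("  observed  = %.2f (mean of %d comparisons)\n",
              round_half_up(x$mean_observed, 2),
              nrow(x$per_pair) + nrow(x$unpaired)))
  cat(sprintf("  maximum   = %.2f (mean of %d comparisons)\n",
              round_half_up(x$mean_maximum, 2), nrow(x$per_pair)))
  cat(sprintf("  recovery  = %d%% of maximum\n",
              round_half_up(x$percent_of_maximum)))
  if (!is.null(x$comparison_test))
    cat(sprintf("  paired t  = %.3f on %d df, two-tailed p = %.4f%s\n",
                x$comparison_test$t, x$comparison_test$df,
                x$comparison_test$p,
                if (isTRUE(x$significant))
                  sprintf(" (significant at alpha = %g)", x$alpha) else ""))
  invisible(x)
}

#' Baseline inter-plot similarity within reference forest
#'
#' Quantifies how similar undisturbed plots of the same forest type are to
#' each other — the natural spatial variability against which recovery
#' comparisons should be judged. Every plot of the selected treatment is
#' compared with every other plot in the same group (all unordered pairs,
#' so `sum(choose(n_g, 2))` comparisons); because each plot enters many
#' comparisons, means are reported without error estimates.
#'
#' @param collection a [census_collection()]; the selected plots must each
#'   have exactly one census.
#' @param group_by metadata column defining the groups (default
#'   `"forest_type"`).
#' @param index_name similarity index.
#' @param treatment which plots to use (default `"reference"`).
#' @return List with `per_group` (group, mean similarity, n comparisons),
#'   `overall_mean` (over all comparisons pooled) and `n_comparisons`.
#' @export
baseline_similarity <- function(collection, group_by = "forest_type",
                                index_name = "tanner",
                                treatment = "reference") {
  index_name <- match.arg(index_name, similarity_index_names)
  meta <- collection$meta[collection$meta$treatment %in% treatment, ]
  if (!group_by %in% names(collection$meta))
    abort_format(sprintf("unknown metadata field: %s", group_by))
  if (nrow(meta) == 0)
    abort_design(sprintf("no plots with treatment %s",
                         paste(treatment, collapse = "/")))

  keys <- census_keys(collection)
  label_of <- function(plot) {
    lab <- keys$census_label[keys$plot_id == plot]
    if (length(lab) != 1)
      abort_design(sprintf(
        "baseline plots must have exactly one census; plot %s has %d",
        plot, length(lab)))
    lab
  }

  groups <- split(meta$plot_id, meta[[group_by]])
  vals_by_group <- lapply(groups, function(plots) {
    if (length(plots) < 2)
      abort_design(sprintf("a baseline group has fewer than 2 plots"))
    cmb <- utils::combn(sort(plots, method = "radix"), 2)
    vapply(seq_len(ncol(cmb)), function(i)
      similarity_value(collection,
                       cmb[1, i], label_of(cmb[1, i]),
                       cmb[2, i], label_of(cmb[2, i]), index_name),
      numeric(1))
  })

  per_group <- data.frame(
    group = names(vals_by_group),
    mean_similarity = vapply(vals_by_group, mean, numeric(1)),
    n_comparisons = vapply(vals_by_group, length, integer(1)),
    row.names = NULL)
  all_vals <- unlist(vals_by_group, use.names = FALSE)
  list(per_group = per_group,
       overall_mean = mean(all_vals),
       n_comparisons = length(all_vals),
       index_name = index_name)
}
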