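#' Species importance values for a pooled set of censuses
#'
#' The importance value of a species is the mean of its relative density
#' (percent of all stems) and relative basal area (percent of total basal
#' area), IV = (relative density + relative basal area) / 2, computed after
#' pooling the requested censuses. Importance values sum to 100 across
#' species and weight a species by both how numerous and how large its
#' stems are.
#'
#' @param collection a [census_collection()].
#' @param plot_ids plots to pool.
#' @param census_label census to use for every pooled plot.
#' @return data.frame (species, stems, basal_area_m2, relative_density,
#'   relative_ba, iv), sorted by descending iv, ties broken by species name.
#' @examples
#' coll <- simulate_censuses(sim_config(seed = 7))
#' gaps <- coll$meta$plot_id[coll$meta$treatment == "gap"]
#' head(importance_values(coll, gaps, "post"))
#' @export
importance_values <- function(collection, plot_ids, census_label) {
  stopifnot(inherits(collection, "census_collection"))
  rows <- collection$census[collection$census$plot_id %in% plot_ids &
                              collection$census$census_label == census_label, ]
  if (nrow(rows) == 0 || sum(rows$stems) == 0)
    abort_design("importance values need at least one stem in scope")
  stems <- tapply(rows$stems, rows$species, sum)
  ba <- tapply(rows$basal_area_m2, rows$species, sum)
  out <- data.frame(species = names(stems),
                    stems = as.integer(stems),
                    basal_area_m2 = as.numeric(ba),
                    row.names = NULL)
  out <- out[out$stems > 0 | out$basal_area_m2 > 0, ]
  out$relative_density <- 100 * out$stems / sum(out$stems)
  out$relative_ba <- if (sum(out$basal_area_m2) > 0)
    100 * out$basal_area_m2 / sum(out$basal_area_m2) else 0 * out$basal_area_m2
  out$iv <- (out$relative_density + out$relative_ba) / 2
  out[order(-out$iv, out$species, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

change_variables <- c("stem_density", "species_density", "endemic_density",
                      "basal_area")

# per-plot value of one stand variable at one census; basal area in m2/ha
plot_variable <- function(collection, plot, census_label, variable,
                          exclude_species = NULL, endemics = NULL) {
  rows <- collection$census[collection$census$plot_id == plot &
                              collection$census$census_label == census_label, ]
  if (!is.null(exclude_species))
    rows <- rows[!rows$species %in% exclude_species, ]
  present <- rows$species[rows$stems > 0]
  switch(variable,
    stem_density = sum(rows$stems),
    species_density = length(unique(present)),
    endemic_density = length(unique(intersect(present, endemics))),
    basal_area = {
      area <- collection$meta$area_m2[collection$meta$plot_id == plot]
      sum(rows$basal_area_m2) / area * 1e4
    })
}

#' Paired change tests between two censuses
#'
#' For each stand variable, computes the per-plot change from the pre- to
#' the post-census and tests whether the change in the gap plots differs
#' from the change in their paired control plots, with a two-tailed paired
#' t-test (paired by `pair_id`). Means and standard errors are reported over
#' *all* gap and control plots (unpaired gap plots included), while the test
#' uses complete pairs only.
#'
#' Variables: `stem_density` (stems per plot), `species_density` (species
#' per plot), `endemic_density` (species per plot restricted to a supplied
#' endemics list), `basal_area` (m² ha⁻¹, converted using each plot's area).
#' When `exclude_species` is given, each variable is additionally recomputed
#' with those species removed — e.g. to separate an invading alien's
#' contribution from the native community's.
#'
#' @param collection a [census_collection()].
#' @param pre_label,post_label census labels.
#' @param variables subset of the variables above.
#' @param exclude_species optional species name(s) for exclusion variants.
#' @param endemics character vector of endemic species names; required if
#'   `endemic_density` is requested.
#' @return data.frame with one row per variable (and per exclusion
#'   variant): means and SEs of gap and control changes, `t`, `df`,
#'   `p_two_tailed`.
#' @export
change_tests <- function(collection, pre_label = "pre", post_label = "post",
                         variables = change_variables,
                         exclude_species = NULL, endemics = NULL) {
  variables <- match.arg(variables, change_variables, several.ok = TRUE)
  if ("endemic_density" %in% variables && is.null(endemics))
    abort_config("endemic_density requires an endemic species list")
  pairs <- complete_pairs(collection)
  if (nrow(pairs) < 2)
    abort_design("change tests need at least 2 complete gap/control pairs")

  meta <- collection$meta
  gap_plots <- meta$plot_id[meta$treatment == "gap"]
  control_plots <- meta$plot_id[meta$treatment == "control"]

  one <- function(variable, excl) {
    chg <- function(plot)
      plot_variable(collection, plot, post_label, variable, excl, endemics) -
        plot_variable(collection, plot, pre_label, variable, excl, endemics)
    gap_d <- vapply(gap_plots, chg, numeric(1))
    ctl_d <- vapply(control_plots, chg, numeric(1))
    test <- paired_t(vapply(pairs$gap_plot, chg, numeric(1)),
                     vapply(pairs$control_plot, chg, numeric(1)))
    data.frame(
      variable = if (is.null(excl)) variable
                 else sprintf("%s without %s", variable,
                              paste(excl, collapse = "+")),
      gap_change = mean(gap_d),
      gap_se = stats::sd(gap_d) / sqrt(length(gap_d)),
      control_change = mean(ctl_d),
      control_se = stats::sd(ctl_d) / sqrt(length(ctl_d)),
      t = test$t, df = test$df, p_two_tailed = test$p,
      row.names = NULL)
  }

  res <- lapply(variables, one, excl = NULL)
  if (!is.null(exclude_species))
    res <- c(res, lapply(variables, one, excl = exclude_species))
  do.call(rbind, res)
}

#' Individual-based rarefaction
#'
#' Expected species richness in a random subsample of `n` individuals drawn
#' without replacement from a census, used to compare species richness of
#' stands at equal stem number. The analytic form is the hypergeometric
#' expectation
#' \deqn{E[S(n)] = \sum_s \left[1 - \binom{N - N_s}{n} \big/ \binom{N}{n}\right]}
#' with \eqn{N} total stems and \eqn{N_s} stems of species \eqn{s}, with the
#' Heck et al. (1975) variance. A seeded Monte Carlo subsampling mode is
#' provided as a cross-check.
#'
#' @param counts non-negative integer vector of per-species stem counts
#'   (a pooled or single-census abundance vector).
#' @param n_target subsample size, between 1 and `sum(counts)`.
#' @param method `"analytic"` (exact expectation) or `"resample"`
#'   (Monte Carlo).
#' @param n_resample number of resamples when `method = "resample"`.
#' @param seed RNG seed for the resampling mode.
#' @return List with `expected_species`, `variance` and `n_target`.
#' @examples
#' rarefy(c(5, 3, 2), 4)
#' @export
rarefy <- function(counts, n_target, method = c("analytic", "resample"),
                   n_resample = 999, seed = NULL) {
  method <- match.arg(method)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("counts must be non-negative integers")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (length(n_target) != 1 || n_target < 1 || n_target > N ||
      n_target != round(n_target))
    abort_domain(sprintf(
      "n_target must be an integer in [1, %d] (total stems); got %s",
      N, as.character(n_target)))

  if (method == "resample") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    pool <- rep(seq_along(counts), counts)
    s <- vapply(seq_len(n_resample), function(i)
      length(unique(sample(pool, n_target))), numeric(1))
    return(list(expected_species = mean(s), variance = stats::var(s),
                n_target = as.integer(n_target), method = method))
  }

  # P(species s entirely missed) computed on the log scale for stability
  a <- exp(lchoose(N - counts, n_target) - lchoose(N, n_target))
  a[N - counts < n_target] <- 0
  expected <- sum(1 - a)

  var_term <- sum(a * (1 - a))
  if (length(counts) > 1) {
    idx <- utils::combn(length(counts), 2)
    both <- N - counts[idx[1, ]] - counts[idx[2, ]]
    ab <- ifelse(both < n_target, 0,
                 exp(lchoose(both, n_target) - lchoose(N, n_target)))
    var_term <- var_term + 2 * sum(ab - a[idx[1, ]] * a[idx[2, ]])
  }
  list(expected_species = expected, variance = max(var_term, 0),
       n_target = as.integer(n_target), method = method)
}
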