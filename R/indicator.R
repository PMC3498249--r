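#' Indicator species analysis (IndVal)
#'
#' Dufrene & Legendre (1997) indicator value analysis for a plots-by-species
#' abundance matrix and a grouping of plots (e.g. gap vs control). For
#' species \eqn{s} and group \eqn{g}:
#' \deqn{A_{sg} = \bar{x}_{sg} \big/ \sum_{g'} \bar{x}_{sg'}, \qquad
#'       B_{sg} = \mathrm{freq}_{sg}, \qquad
#'       \mathrm{IndVal}_{sg} = A_{sg} \times B_{sg}}
#' where \eqn{\bar{x}_{sg}} is the species' mean abundance in group \eqn{g}
#' (means, not sums, so unequal group sizes do not bias specificity) and
#' \eqn{\mathrm{freq}_{sg}} the fraction of the group's plots where it
#' occurs. Each species is reported for the group maximizing its IndVal, on
#' a 0–1 scale (1 = perfect indicator: all abundance concentrated in the
#' group and present in every plot of it).
#'
#' Significance is by Monte Carlo permutation of group labels over plots
#' (free relabeling, seeded), with
#' \eqn{p = (r + 1) / (n_{perm} + 1)} where \eqn{r} counts permutations
#' whose maximum IndVal for the species is >= the observed one. With
#' `exhaustive = TRUE` all distinct label assignments are enumerated instead
#' and `p` is the exact proportion (the identity assignment included).
#'
#' @param x numeric matrix, plots in rows, species in columns (column
#'   names are species names).
#' @param groups group label per plot (length `nrow(x)`), >= 2 groups.
#' @param n_permutations Monte Carlo permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all distinct label assignments instead of
#'   sampling; only feasible for small plot counts.
#' @return data.frame (species, group, specificity_A, fidelity_B, indval,
#'   p_value, n_permutations) sorted by descending indval.
#' @examples
#' coll <- simulate_censuses(sim_config(seed = 3))
#' m <- census_matrix(coll, "post")
#' grp <- coll$meta$treatment[match(rownames(m), coll$meta$plot_id)]
#' head(indval(m, grp, n_permutations = 99, seed = 1))
#' @export
indval <- function(x, groups, n_permutations = 999, seed = NULL,
                   exhaustive = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("sp", seq_len(ncol(x)))
  groups <- as.character(groups)
  if (length(groups) != nrow(x))
    abort_shape("groups must have one label per plot (row of x)")
  tab <- table(groups)
  if (length(tab) < 2)
    abort_design("indicator analysis needs at least 2 groups")
  if (any(tab == 0))
    abort_design("every group needs at least one plot")
  if (!exhaustive && n_permutations < 1)
    abort_validation("n_permutations must be >= 1")

  stat <- function(g) indval_stat(x, g)
  obs <- stat(groups)

  if (exhaustive) {
    perms <- unique_label_assignments(groups)
    greater <- matrix(0, nrow = ncol(x), ncol = 1)
    count <- 0L
    for (p in perms) {
      count <- count + 1L
      greater <- greater + (stat(p)$indval >= obs$indval - 1e-12)
    }
    p_value <- as.numeric(greater) / count
    n_used <- count
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    greater <- numeric(ncol(x))
    for (i in seq_len(n_permutations))
      greater <- greater + (stat(sample(groups))$indval >= obs$indval - 1e-12)
    p_value <- (greater + 1) / (n_permutations + 1)
    n_used <- as.integer(n_permutations)
  }

  # all-zero species carry no information: indval 0 by construction, p = 1
  p_value[colSums(x) == 0] <- 1

  out <- data.frame(species = colnames(x),
                    group = obs$group,
                    specificity_A = obs$A,
                    fidelity_B = obs$B,
                    indval = as.numeric(obs$indval),
                    p_value = p_value,
                    n_permutations = n_used,
                    row.names = NULL)
  out[order(-out$indval, out$species, method = "radix"), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# per-species max-over-groups IndVal and its components
indval_stat <- function(x, groups) {
  glev <- sort(unique(groups), method = "radix")
  means <- vapply(glev, function(g)
    colMeans(x[groups == g, , drop = FALSE]), numeric(ncol(x)))
  freqs <- vapply(glev, function(g)
    colMeans(x[groups == g, , drop = FALSE] > 0), numeric(ncol(x)))
  means <- matrix(means, ncol = length(glev))
  freqs <- matrix(freqs, ncol = length(glev))
  tot <- rowSums(means)
  A <- means / ifelse(tot > 0, tot, 1)
  iv <- A * freqs
  best <- max.col(iv, ties.method = "first")
  sel <- cbind(seq_len(nrow(iv)), best)
  list(indval = iv[sel], A = A[sel], B = freqs[sel], group = glev[best])
}

# all distinct assignments of the multiset of labels to positions
unique_label_assignments <- function(groups) {
  n <- length(groups)
  positions <- seq_len(n)
  glev <- sort(unique(groups), method = "radix")
  counts <- table(factor(groups, levels = glev))
  out <- list()
  recurse <- function(remaining, assignment, gi) {
    if (gi == length(glev)) {
      assignment[remaining] <- glev[gi]
      out[[length(out) + 1]] <<- assignment
      return(invisible())
    }
    k <- counts[[gi]]
    for (idx in utils::combn(length(remaining), k, simplify = FALSE)) {
      a2 <- assignment
      a2[remaining[idx]] <- glev[gi]
      recurse(remaining[-idx], a2, gi + 1)
    }
  }
  recurse(positions, character(n), 1)
  out
}

#' Plots-by-species abundance matrix from a collection
#'
#' Convenience builder for [indval()]: one row per plot having the given
#' census, one column per species in the collection's species union, stem
#' counts as entries.
#'
#' @param collection a [census_collection()].
#' @param census_label which census to extract.
#' @param measure `"density"` or `"basal_area"`.
#' @return Numeric matrix with plot ids as row names.
#' @export
census_matrix <- function(collection, census_label,
                          measure = c("density", "basal_area")) {
  measure <- match.arg(measure)
  keys <- census_keys(collection)
  plots <- sort(unique(keys$plot_id[keys$census_label == census_label]),
                method = "radix")
  if (length(plots) == 0)
    abort_lookup(sprintf("no plots with census %s", census_label))
  m <- t(vapply(plots, function(p)
    abundance_vectors(collection, p, census_label, measure),
    numeric(length(collection$species_union))))
  rownames(m) <- plots
  m
}
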