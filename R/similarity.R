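#' Quantitative Bray-Curtis similarity
#'
#' Similarity form of the Bray-Curtis index on abundance vectors:
#' \deqn{BC_{jk} = \frac{2\sum_i \min(Y_{ij}, Y_{ik})}{\sum_i Y_{ij} + \sum_i Y_{ik}}}
#' where \eqn{Y_{ij}} is the abundance (stem count, or basal area) of species
#' \eqn{i} in plot \eqn{j}. Unlike proportionate indices
#' ([horn_morisita()], [chao_jaccard()]) it is *not* invariant to uniform
#' scaling of one community: a plot with twice as many trees per species as
#' its reference scores 2/3, not 1.
#'
#' @param x,y non-negative numeric vectors of equal length (same species
#'   order). At least one must have a positive sum.
#' @return Similarity in \[0, 1\]. The dissimilarity is `1 - value`.
#' @examples
#' bray_curtis(c(5, 3, 2), c(10, 6, 4))  # doubled community: 2/3
#' bray_curtis(c(4, 1, 0), c(2, 3, 5))   # 0.4
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

check_pair <- function(x, y) {
  if (length(x) != length(y))
    abort_shape(sprintf("abundance vectors differ in length (%d vs %d)",
                        length(x), length(y)))
  if (any(x < 0) || any(y < 0))
    abort_validation("abundance vectors must be non-negative")
  if (sum(x) == 0 && sum(y) == 0)
    abort_undefined("similarity is undefined when both communities are empty")
  invisible(TRUE)
}

#' Tanner recovery index for a pair of censuses
#'
#' The Tanner index (BC_RI) is the mean of the quantitative Bray-Curtis
#' similarities computed on per-species stem densities (BC_density) and on
#' per-species basal areas (BC_ba). By combining a count-based and a
#' size-weighted measure it penalizes both compositional divergence and
#' size-structure divergence, where density-only indices over-estimate
#' recovery of stands whose stems are back but still small.
#'
#' @param collection a [census_collection()].
#' @param plot_a,census_a,plot_b,census_b the two censuses to compare.
#' @return Named list with `bc_density`, `bc_ba` and their mean `bc_ri`.
#' @examples
#' coll <- simulate_censuses(sim_config(seed = 1))
#' tanner_index(coll, "g1", "pre", "g1", "post")
#' @export
tanner_index <- function(collection, plot_a, census_a, plot_b, census_b) {
  dx <- abundance_vectors(collection, plot_a, census_a, "density")
  dy <- abundance_vectors(collection, plot_b, census_b, "density")
  bx <- abundance_vectors(collection, plot_a, census_a, "basal_area")
  by <- abundance_vectors(collection, plot_b, census_b, "basal_area")
  bc_density <- bray_curtis(dx, dy)
  bc_ba <- bray_curtis(bx, by)
  list(bc_density = bc_density, bc_ba = bc_ba,
       bc_ri = (bc_density + bc_ba) / 2)
}

#' Morisita-Horn similarity
#'
#' \deqn{MH = \frac{2\sum_i x_i y_i}{(\sum_i x_i^2/X^2 + \sum_i y_i^2/Y^2)\, XY}}
#' with \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}. A proportionate index:
#' it depends only on relative abundances, so `horn_morisita(x, 2 * x)` is
#' exactly 1 — the blind spot the Tanner index exists to fix.
#'
#' @inheritParams bray_curtis
#' @return Similarity in \[0, 1\].
#' @export
horn_morisita <- function(x, y) {
  check_pair(x, y)
  X <- sum(x); Y <- sum(y)
  if (X == 0 || Y == 0) return(0)
  val <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  min(max(val, 0), 1)
}

#' Abundance-based Chao-Jaccard similarity
#'
#' Abundance-based Jaccard estimator of Chao, Chazdon, Colwell & Shen
#' (2005): \eqn{J = UV / (U + V - UV)} where \eqn{U} (resp. \eqn{V}) is the
#' total relative abundance in `x` (resp. `y`) of the species shared between
#' the two samples. With `corrected = TRUE` (default, matching standard
#' community-ecology software), U and V include the correction terms for
#' unseen shared species built from counts of shared species occurring once
#' (\eqn{f_{+1}}) and twice (\eqn{f_{+2}}) in the other sample; when
#' \eqn{f_{+2} = 0} it is replaced by 1. The corrected estimator requires
#' integer counts; it is therefore only meaningful for stem densities, not
#' basal areas. Also a proportionate index when uncorrected:
#' `chao_jaccard(x, 2 * x, corrected = FALSE)` is 1.
#'
#' @inheritParams bray_curtis
#' @param corrected logical; apply the unseen-shared-species correction.
#' @return Similarity in \[0, 1\]; 0 when no species are shared.
#' @export
chao_jaccard <- function(x, y, corrected = TRUE) {
  check_pair(x, y)
  if (corrected && (any(x != round(x)) || any(y != round(y))))
    abort_validation("corrected Chao-Jaccard requires integer counts")
  n <- sum(x); m <- sum(y)
  if (n == 0 || m == 0) return(0)
  shared <- x > 0 & y > 0
  if (!any(shared)) return(0)
  U <- sum(x[shared]) / n
  V <- sum(y[shared]) / m
  if (corrected) {
    f1y <- sum(shared & y == 1); f2y <- sum(shared & y == 2)
    f1x <- sum(shared & x == 1); f2x <- sum(shared & x == 2)
    U <- U + (m - 1) / m * f1y / (2 * max(f2y, 1)) * sum(x[shared & y == 1]) / n
    V <- V + (n - 1) / n * f1x / (2 * max(f2x, 1)) * sum(y[shared & x == 1]) / m
    U <- min(U, 1); V <- min(V, 1)
  }
  min(max(U * V / (U + V - U * V), 0), 1)
}

similarity_index_names <- c("bray_curtis_density", "bray_curtis_ba", "tanner",
                            "chao_jaccard", "horn_morisita")

# dispatch one named index on a pair of censuses
similarity_value <- function(collection, plot_a, census_a, plot_b, census_b,
                             index_name) {
  index_name <- match.arg(index_name, similarity_index_names)
  vec <- function(plot, cen, measure)
    abundance_vectors(collection, plot, cen, measure)
  switch(index_name,
    bray_curtis_density = bray_curtis(vec(plot_a, census_a, "density"),
                                      vec(plot_b, census_b, "density")),
    bray_curtis_ba = bray_curtis(vec(plot_a, census_a, "basal_area"),
                                 vec(plot_b, census_b, "basal_area")),
    tanner = tanner_index(collection, plot_a, census_a, plot_b, census_b)$bc_ri,
    chao_jaccard = chao_jaccard(vec(plot_a, census_a, "density"),
                                vec(plot_b, census_b, "density")),
    horn_morisita = horn_morisita(vec(plot_a, census_a, "density"),
                                  vec(plot_b, census_b, "density")))
}

#' Pairwise similarities over a comparison list
#'
#' Applies one similarity index to an explicit list of census pairs and
#' returns one row per comparison, in input order.
#'
#' @param collection a [census_collection()].
#' @param comparisons data.frame with columns `plot_a`, `census_a`,
#'   `plot_b`, `census_b`.
#' @param index_name one of `"bray_curtis_density"`, `"bray_curtis_ba"`,
#'   `"tanner"`, `"chao_jaccard"`, `"horn_morisita"`.
#' @return data.frame with the comparison columns, `index_name` and `value`.
#' @export
pairwise_similarity <- function(collection, comparisons, index_name) {
  index_name <- match.arg(index_name, similarity_index_names)
  need <- c("plot_a", "census_a", "plot_b", "census_b")
  miss <- setdiff(need, names(comparisons))
  if (length(miss) > 0)
    abort_format(sprintf("comparisons table is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  vals <- vapply(seq_len(nrow(comparisons)), function(i) {
    similarity_value(collection,
                     comparisons$plot_a[i], comparisons$census_a[i],
                     comparisons$plot_b[i], comparisons$census_b[i],
                     index_name)
  }, numeric(1))
  out <- comparisons[need]
  out$index_name <- rep(index_name, length.out = nrow(out))
  out$value <- vals
  out
}
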