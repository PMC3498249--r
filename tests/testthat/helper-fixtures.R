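# In-code fixtures: tiny hand-built collections used across test files.

toy_census_df <- function() {
  data.frame(plot_id = "p1", census_label = "pre",
             species = c("A", "B"), stems = c(3L, 2L),
             basal_area_m2 = c(0.05, 0.01))
}

toy_meta_df <- function(plot_id = "p1", treatment = "gap", pair_id = NA) {
  data.frame(plot_id = plot_id, pair_id = pair_id, treatment = treatment,
             area_m2 = 100, forest_type = "ridge")
}

# collection in which each gap plot is an exact copy of its control:
# recovery must come out at exactly 100% of maximum in both designs
mirrored_pairs_collection <- function() {
  mk <- function(plot, label, stems, ba)
    data.frame(plot_id = plot, census_label = label,
               species = c("A", "B", "C"), stems = stems,
               basal_area_m2 = ba)
  census <- rbind(
    mk("g1", "pre", c(5L, 3L, 2L), c(0.2, 0.1, 0.1)),
    mk("g1", "post", c(4L, 4L, 1L), c(0.25, 0.12, 0.05)),
    mk("c1", "pre", c(5L, 3L, 2L), c(0.2, 0.1, 0.1)),
    mk("c1", "post", c(4L, 4L, 1L), c(0.25, 0.12, 0.05)),
    mk("g2", "pre", c(7L, 1L, 4L), c(0.3, 0.05, 0.15)),
    mk("g2", "post", c(6L, 2L, 3L), c(0.33, 0.07, 0.1)),
    mk("c2", "pre", c(7L, 1L, 4L), c(0.3, 0.05, 0.15)),
    mk("c2", "post", c(6L, 2L, 3L), c(0.33, 0.07, 0.1)))
  meta <- data.frame(
    plot_id = c("g1", "c1", "g2", "c2"),
    pair_id = rep(c("pair1", "pair2"), each = 2),
    treatment = rep(c("gap", "control"), 2),
    area_m2 = 100, forest_type = "ridge")
  census_collection(census, meta)
}

# single-census reference plots for baseline tests, hand-set counts
reference_collection <- function(counts_list, forest_type = "colA") {
  census <- do.call(rbind, lapply(seq_along(counts_list), function(i) {
    cts <- counts_list[[i]]
    data.frame(plot_id = sprintf("r%d", i), census_label = "ref",
               species = names(cts), stems = as.integer(cts),
               basal_area_m2 = as.numeric(cts) * 0.01)
  }))
  meta <- data.frame(plot_id = sprintf("r%d", seq_along(counts_list)),
                     pair_id = NA, treatment = "reference", area_m2 = 100,
                     forest_type = forest_type)
  census_collection(census, meta)
}
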