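#' Configuration for the paired-plot census generator
#'
#' Collects every knob of [simulate_censuses()] in one validated object.
#' Defaults describe a small tropical montane forest gap experiment: four
#' gap/control pairs plus one unpaired gap plot of 90–100 m², a ~30 species
#' pool with log-normal relative abundances, ~55 stems per plot, right-
#' skewed (gamma) per-stem basal areas averaging ~0.0115 m² (so a plot
#' carries roughly 65 m² ha⁻¹), a disturbance killing 30% of stems biased
#' toward the largest, partial basal-area recovery (55% of the
#' pre-disturbance total) and a post-disturbance alien invader that is
#' abundant in gaps and rare in controls.
#'
#' @param n_pairs number of gap/control pairs.
#' @param n_unpaired_gaps gap plots without a monitored control.
#' @param n_species size of the native species pool (>= 2).
#' @param plot_area_m2 per-plot area(s); default 90.25 m² for the first
#'   three pairs and 100 m² for the rest.
#' @param mean_stems_per_plot expected pre-disturbance stems per plot.
#' @param sdlog_regional,sdlog_pair,sdlog_plot log-normal sd of species
#'   relative abundances at the regional, pair and plot level (larger
#'   plot-level sd = less similar plots within a pair).
#' @param ba_shape,ba_mean_m2,ba_min_m2 gamma shape, mean and lower bound of
#'   per-stem basal area (m²); the bound is a 3 cm dbh stem.
#' @param recruit_ba_mean_m2 mean basal area of newly recruited stems.
#' @param background_survival per-stem survival over the census interval in
#'   undisturbed conditions.
#' @param survivor_growth multiplicative basal-area growth of surviving
#'   stems over the interval.
#' @param recruit_fraction expected recruits as a fraction of
#'   `mean_stems_per_plot`.
#' @param disturbance_mortality fraction of gap-plot stems killed by the
#'   disturbance, removed largest-basal-area first (felling takes the
#'   canopy).
#' @param ba_recovery_fraction target ratio of post- to pre-disturbance
#'   total basal area in gap plots (native regrowth is scaled to meet it).
#' @param invader `NULL`, or list(name, stems, per_stem_ba_m2,
#'   control_stems): an alien species absent pre-disturbance, abundant
#'   post-gap, rare post-control.
#' @param pioneer_recruitment `NULL`, or list(k, stems_each): k pioneer
#'   species absent pre-disturbance recruiting into gaps.
#' @param reference_groups `NULL`, or a named integer vector
#'   (forest type -> number of plots) of single-census undisturbed
#'   reference plots for baseline variability analyses.
#' @param pre_label,post_label census labels to emit.
#' @param seed integer RNG seed; the same seed reproduces the collection
#'   byte for byte.
#' @param worked_example if `TRUE`, skip all stochastic draws and return a
#'   fixed two-pair collection whose downstream statistics are hand-
#'   checkable (see [worked_example_collection()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 4, n_unpaired_gaps = 1, n_species = 30,
                       plot_area_m2 = NULL, mean_stems_per_plot = 55,
                       sdlog_regional = 1.2, sdlog_pair = 0.5,
                       sdlog_plot = 0.9,
                       ba_shape = 0.8, ba_mean_m2 = 0.0115,
                       ba_min_m2 = 0.0007, recruit_ba_mean_m2 = 0.003,
                       background_survival = 0.8, survivor_growth = 1.35,
                       recruit_fraction = 0.25,
                       disturbance_mortality = 0.30,
                       ba_recovery_fraction = 0.55,
                       invader = list(name = "alien_invader", stems = 24,
                                      per_stem_ba_m2 = 0.0064,
                                      control_stems = 2),
                       pioneer_recruitment = list(k = 3, stems_each = 3),
                       reference_groups = NULL,
                       pre_label = "pre", post_label = "post",
                       seed = 1, worked_example = FALSE) {
  n_plots <- n_pairs + n_unpaired_gaps
  if (is.null(plot_area_m2))
    plot_area_m2 <- c(rep(90.25, min(3, n_plots)),
                      rep(100, max(0, n_plots - 3)))
  cfg <- list(n_pairs = n_pairs, n_unpaired_gaps = n_unpaired_gaps,
              n_species = n_species, plot_area_m2 = plot_area_m2,
              mean_stems_per_plot = mean_stems_per_plot,
              sdlog_regional = sdlog_regional, sdlog_pair = sdlog_pair,
              sdlog_plot = sdlog_plot, ba_shape = ba_shape,
              ba_mean_m2 = ba_mean_m2, ba_min_m2 = ba_min_m2,
              recruit_ba_mean_m2 = recruit_ba_mean_m2,
              background_survival = background_survival,
              survivor_growth = survivor_growth,
              recruit_fraction = recruit_fraction,
              disturbance_mortality = disturbance_mortality,
              ba_recovery_fraction = ba_recovery_fraction,
              invader = invader, pioneer_recruitment = pioneer_recruitment,
              reference_groups = reference_groups,
              pre_label = pre_label, post_label = post_label,
              seed = seed, worked_example = worked_example)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      abort_validation(sprintf("%s must be a fraction in [0, 1]", nm))
  }
  frac(cfg$disturbance_mortality, "disturbance_mortality")
  frac(cfg$ba_recovery_fraction, "ba_recovery_fraction")
  frac(cfg$background_survival, "background_survival")
  if (cfg$n_species < 2)
    abort_validation("n_species must be >= 2")
  if (cfg$n_pairs < 1 && cfg$n_unpaired_gaps < 1)
    abort_validation("need at least one plot")
  if (any(cfg$plot_area_m2 <= 0))
    abort_validation("plot_area_m2 must be positive")
  if (cfg$mean_stems_per_plot <= 0)
    abort_validation("mean_stems_per_plot must be positive")
  if (!is.null(cfg$invader)) {
    if (is.null(cfg$invader$name) || cfg$invader$stems < 0 ||
        cfg$invader$control_stems < 0 || cfg$invader$per_stem_ba_m2 < 0)
      abort_validation("invader stems/basal area must be non-negative")
  }
  if (!is.null(cfg$pioneer_recruitment)) {
    if (cfg$pioneer_recruitment$k < 0 || cfg$pioneer_recruitment$stems_each < 0)
      abort_validation("pioneer_recruitment k and stems_each must be non-negative")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    abort_validation("seed must be a single integer")
  invisible(cfg)
}

# per-stem basal areas: bounded below by the census dbh threshold,
# right-skewed above it
draw_stem_ba <- function(n, cfg, mean_m2 = cfg$ba_mean_m2) {
  excess <- max(mean_m2 - cfg$ba_min_m2, 1e-6)
  cfg$ba_min_m2 + stats::rgamma(n, shape = cfg$ba_shape,
                                scale = excess / cfg$ba_shape)
}

# one plot's stem table: species index + per-stem basal area
draw_stand <- function(probs, cfg) {
  n <- max(1L, stats::rpois(1, cfg$mean_stems_per_plot))
  sp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  data.frame(species = sp, ba = draw_stem_ba(n, cfg))
}

survive_and_grow <- function(stand, cfg) {
  keep <- stats::runif(nrow(stand)) < cfg$background_survival
  out <- stand[keep, , drop = FALSE]
  out$ba <- out$ba * cfg$survivor_growth *
    stats::rlnorm(nrow(out), 0, 0.1)
  out
}

recruit_stand <- function(probs, cfg) {
  n <- stats::rpois(1, cfg$recruit_fraction * cfg$mean_stems_per_plot)
  if (n == 0) return(data.frame(species = integer(0), ba = numeric(0)))
  data.frame(species = sample.int(length(probs), n, replace = TRUE,
                                  prob = probs),
             ba = draw_stem_ba(n, cfg, cfg$recruit_ba_mean_m2))
}

#' Simulate paired gap/control plot censuses
#'
#' Generates a [census_collection()] with the structure a paired disturbance
#' experiment assumes: pre- and post-disturbance censuses for gap and
#' control plots (plus optional unpaired gaps and single-census reference
#' plots). Control plots change only by demographic noise (background
#' mortality, growth of survivors, recruitment). Gap plots lose
#' `disturbance_mortality` of their stems *largest basal area first* —
#' felling removes the canopy — then regain stems through surviving-stem
#' regrowth, native and pioneer recruitment and an optional invader, so
#' stem counts can recover to or beyond their pre-disturbance level while
#' total basal area stays depressed at `ba_recovery_fraction` of its
#' pre-disturbance value. That asymmetry — counts back, size structure not —
#' is the signature the Tanner index is designed to detect (high BC_density,
#' low BC_ba).
#'
#' @param config a [sim_config()].
#' @return A `census_collection`.
#' @examples
#' coll <- simulate_censuses(sim_config(seed = 11))
#' assess_recovery(coll, "temporal", "tanner")
#' @export
simulate_censuses <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  if (isTRUE(config$worked_example)) return(worked_example_collection())

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  cfg <- config
  pool <- sprintf("sp%02d", seq_len(cfg$n_species))
  pioneers <- if (!is.null(cfg$pioneer_recruitment) &&
                  cfg$pioneer_recruitment$k > 0)
    sprintf("pioneer%02d", seq_len(cfg$pioneer_recruitment$k)) else character(0)
  all_names <- c(pool, pioneers,
                 if (!is.null(cfg$invader)) cfg$invader$name)

  regional <- stats::rlnorm(cfg$n_species, 0, cfg$sdlog_regional)
  regional <- regional / sum(regional)

  census_rows <- list()
  meta_rows <- list()
  emit <- function(plot, label, stand) {
    # an empty stand still gets one explicit zero row so the census exists
    if (nrow(stand) == 0) {
      census_rows[[length(census_rows) + 1]] <<- data.frame(
        plot_id = plot, census_label = label, species = all_names[1],
        stems = 0L, basal_area_m2 = 0)
      return(invisible())
    }
    stems <- tapply(stand$ba, stand$species, length)
    ba <- tapply(stand$ba, stand$species, sum)
    census_rows[[length(census_rows) + 1]] <<- data.frame(
      plot_id = plot, census_label = label,
      species = names(stems), stems = as.integer(stems),
      basal_area_m2 = as.numeric(ba), row.names = NULL)
  }

  gap_post_stand <- function(pre, probs) {
    # felling: remove the largest-basal-area fraction of stems
    n_kill <- round(cfg$disturbance_mortality * nrow(pre))
    survivors <- pre[order(-pre$ba), , drop = FALSE]
    survivors <- survivors[seq_len(nrow(survivors))[-seq_len(n_kill)], ,
                           drop = FALSE]
    if (n_kill == 0) survivors <- pre
    post <- survive_and_grow(survivors, cfg)
    post <- rbind(post, recruit_stand(probs, cfg))
    for (p in pioneers)
      post <- rbind(post, data.frame(
        species = rep(p, cfg$pioneer_recruitment$stems_each),
        ba = draw_stem_ba(cfg$pioneer_recruitment$stems_each, cfg,
                          cfg$recruit_ba_mean_m2)))
    # calibrate native regrowth so total post basal area sits at the
    # configured fraction of the pre-disturbance total
    invader_ba <- if (!is.null(cfg$invader))
      cfg$invader$stems * cfg$invader$per_stem_ba_m2 else 0
    target_native <- max(cfg$ba_recovery_fraction * sum(pre$ba) - invader_ba, 0)
    if (nrow(post) > 0 && sum(post$ba) > 0 && target_native > 0)
      post$ba <- post$ba * target_native / sum(post$ba)
    if (!is.null(cfg$invader) && cfg$invader$stems > 0)
      post <- rbind(post, data.frame(
        species = rep(cfg$invader$name, cfg$invader$stems),
        ba = cfg$invader$per_stem_ba_m2 *
          stats::rlnorm(cfg$invader$stems, 0, 0.2)))
    post
  }

  control_post_stand <- function(pre, probs) {
    post <- rbind(survive_and_grow(pre, cfg), recruit_stand(probs, cfg))
    if (!is.null(cfg$invader) && cfg$invader$control_stems > 0)
      post <- rbind(post, data.frame(
        species = rep(cfg$invader$name, cfg$invader$control_stems),
        ba = cfg$invader$per_stem_ba_m2 *
          stats::rlnorm(cfg$invader$control_stems, 0, 0.2)))
    post
  }

  # species column may hold pool indices (draws) or names (pioneers/invader)
  to_names <- function(stand) {
    if (nrow(stand) == 0) return(stand)
    idx <- suppressWarnings(as.integer(stand$species))
    stand$species <- ifelse(!is.na(idx) & stand$species == as.character(idx),
                            pool[idx], as.character(stand$species))
    stand
  }

  n_plots <- cfg$n_pairs + cfg$n_unpaired_gaps
  areas <- rep(cfg$plot_area_m2, length.out = n_plots)
  ftypes <- rep(c("col", "col", "col", "mor", "mull"), length.out = n_plots)

  for (i in seq_len(n_plots)) {
    paired <- i <= cfg$n_pairs
    pair_noise <- stats::rlnorm(cfg$n_species, 0, cfg$sdlog_pair)
    pair_probs <- regional * pair_noise
    gplot <- sprintf("g%d", i)
    plot_probs <- pair_probs * stats::rlnorm(cfg$n_species, 0, cfg$sdlog_plot)
    pre <- draw_stand(plot_probs / sum(plot_probs), cfg)
    emit(gplot, cfg$pre_label, to_names(pre))
    emit(gplot, cfg$post_label,
         to_names(gap_post_stand(pre, plot_probs / sum(plot_probs))))
    meta_rows[[length(meta_rows) + 1]] <- data.frame(
      plot_id = gplot, pair_id = if (paired) sprintf("pair%d", i) else NA,
      treatment = "gap", area_m2 = areas[i], forest_type = ftypes[i])

    if (paired) {
      cplot <- sprintf("c%d", i)
      cprobs <- pair_probs * stats::rlnorm(cfg$n_species, 0, cfg$sdlog_plot)
      cpre <- draw_stand(cprobs / sum(cprobs), cfg)
      emit(cplot, cfg$pre_label, to_names(cpre))
      emit(cplot, cfg$post_label,
           to_names(control_post_stand(cpre, cprobs / sum(cprobs))))
      meta_rows[[length(meta_rows) + 1]] <- data.frame(
        plot_id = cplot, pair_id = sprintf("pair%d", i),
        treatment = "control", area_m2 = areas[i], forest_type = ftypes[i])
    }
  }

  if (!is.null(cfg$reference_groups)) {
    for (ft in names(cfg$reference_groups)) {
      for (j in seq_len(cfg$reference_groups[[ft]])) {
        rplot <- sprintf("r_%s_%02d", ft, j)
        rprobs <- regional * stats::rlnorm(cfg$n_species, 0, cfg$sdlog_plot)
        emit(rplot, "ref", to_names(draw_stand(rprobs / sum(rprobs), cfg)))
        meta_rows[[length(meta_rows) + 1]] <- data.frame(
          plot_id = rplot, pair_id = NA, treatment = "reference",
          area_m2 = 100, forest_type = ft)
      }
    }
  }

  census_collection(do.call(rbind, census_rows), do.call(rbind, meta_rows))
}

#' Fixed worked-example collection
#'
#' A deterministic two-pair collection (species A, B, C and an invader V)
#' small enough that every downstream statistic — Bray-Curtis components,
#' Tanner index, recovery percentages, importance values — can be checked
#' by hand. Used by the test suite as a known-answer fixture and returned by
#' [simulate_censuses()] when `worked_example = TRUE`.
#'
#' @return A `census_collection`.
#' @export
worked_example_collection <- function() {
  row <- function(plot, label, sp, stems, ba)
    data.frame(plot_id = plot, census_label = label, species = sp,
               stems = stems, basal_area_m2 = ba)
  census <- rbind(
    row("g1", "pre",  c("A", "B", "C"), c(10L, 5L, 5L), c(0.30, 0.10, 0.10)),
    row("g1", "post", c("A", "B", "V"), c(6L, 4L, 10L), c(0.06, 0.04, 0.05)),
    row("c1", "pre",  c("A", "B", "C"), c(8L, 6L, 6L),  c(0.24, 0.12, 0.12)),
    row("c1", "post", c("A", "B", "C"), c(8L, 5L, 5L),  c(0.26, 0.11, 0.11)),
    row("g2", "pre",  c("A", "B", "C"), c(12L, 4L, 4L), c(0.36, 0.08, 0.08)),
    row("g2", "post", c("A", "C", "V"), c(7L, 3L, 8L),  c(0.07, 0.03, 0.04)),
    row("c2", "pre",  c("A", "B", "C"), c(10L, 5L, 5L), c(0.30, 0.10, 0.10)),
    row("c2", "post", c("A", "B", "C"), c(9L, 5L, 6L),  c(0.29, 0.105, 0.125)))
  meta <- data.frame(
    plot_id = c("g1", "c1", "g2", "c2"),
    pair_id = c("pair1", "pair1", "pair2", "pair2"),
    treatment = c("gap", "control", "gap", "control"),
    area_m2 = 100, forest_type = "montane")
  census_collection(census, meta)
}
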