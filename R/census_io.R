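#' Plot census collections
#'
#' A `census_collection` bundles long-form census records (one row per plot,
#' census and species) with per-plot metadata, after validation. It is the
#' input container for every analysis in the package.
#'
#' The census table must have columns `plot_id`, `census_label`, `species`,
#' `stems` (non-negative integers) and `basal_area_m2` (non-negative reals,
#' the plot total over that species' stems). The metadata table must have
#' columns `plot_id`, `pair_id` (may be empty/NA for unpaired plots),
#' `treatment` (one of `gap`, `control`, `reference`, case-insensitive),
#' `area_m2` (> 0) and `forest_type`.
#'
#' Stem density is deliberately stem count per plot, not per unit area:
#' paired plots share an area, so pair-wise comparisons are unaffected, and
#' `area_m2` is retained for unit conversions (e.g. basal area per hectare)
#' at reporting time.
#'
#' @param census data.frame of census records (columns above).
#' @param meta data.frame of plot metadata (columns above).
#' @return An object of class `census_collection` with elements `census`
#'   (validated records), `meta` (validated metadata, `treatment` lower-case)
#'   and `species_union` (all species names, lexicographic, each once).
#' @seealso [read_censuses()], [abundance_vectors()]
#' @examples
#' cen <- data.frame(plot_id = "p1", census_label = "pre",
#'                   species = c("A", "B"), stems = c(3L, 2L),
#'                   basal_area_m2 = c(0.05, 0.01))
#' meta <- data.frame(plot_id = "p1", pair_id = NA, treatment = "gap",
#'                    area_m2 = 100, forest_type = "ridge")
#' census_collection(cen, meta)
#' @export
census_collection <- function(census, meta) {
  census_cols <- c("plot_id", "census_label", "species", "stems", "basal_area_m2")
  meta_cols <- c("plot_id", "pair_id", "treatment", "area_m2", "forest_type")
  miss <- setdiff(census_cols, names(census))
  if (length(miss) > 0)
    abort_format(sprintf("census table is missing column(s): %s",
                         paste(miss, collapse = ", ")))
  miss <- setdiff(meta_cols, names(meta))
  if (length(miss) > 0)
    abort_format(sprintf("meta table is missing column(s): %s",
                         paste(miss, collapse = ", ")))

  census <- as.data.frame(census)[census_cols]
  meta <- as.data.frame(meta)[meta_cols]

  census$plot_id <- trimws(as.character(census$plot_id))
  census$census_label <- trimws(as.character(census$census_label))
  census$species <- trimws(as.character(census$species))
  census$basal_area_m2 <- as.numeric(census$basal_area_m2)

  stems_num <- suppressWarnings(as.numeric(census$stems))
  bad <- which(is.na(stems_num) | stems_num < 0 | stems_num != round(stems_num))
  if (length(bad) > 0)
    abort_validation(sprintf(
      "stems must be non-negative integers; offending row %d (plot %s, census %s, species %s, stems = %s)",
      bad[1], census$plot_id[bad[1]], census$census_label[bad[1]],
      census$species[bad[1]], as.character(census$stems[bad[1]])))
  census$stems <- as.integer(stems_num)

  bad <- which(is.na(census$basal_area_m2) | census$basal_area_m2 < 0)
  if (length(bad) > 0)
    abort_validation(sprintf(
      "basal_area_m2 must be non-negative; offending row %d (plot %s, species %s)",
      bad[1], census$plot_id[bad[1]], census$species[bad[1]]))

  bad <- which(census$stems == 0 & census$basal_area_m2 > 0)
  if (length(bad) > 0)
    abort_validation(sprintf(
      "species with 0 stems must have 0 basal area; offending row %d (plot %s, species %s)",
      bad[1], census$plot_id[bad[1]], census$species[bad[1]]))

  key <- paste(census$plot_id, census$census_label, census$species, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    abort_validation(sprintf(
      "duplicated (plot_id, census_label, species) row: (%s, %s, %s)",
      census$plot_id[dup[1]], census$census_label[dup[1]], census$species[dup[1]]))

  meta$plot_id <- trimws(as.character(meta$plot_id))
  meta$treatment <- tolower(trimws(as.character(meta$treatment)))
  meta$pair_id <- as.character(meta$pair_id)
  meta$pair_id[!is.na(meta$pair_id) & trimws(meta$pair_id) == ""] <- NA_character_
  meta$area_m2 <- as.numeric(meta$area_m2)
  meta$forest_type <- as.character(meta$forest_type)

  if (any(duplicated(meta$plot_id)))
    abort_validation(sprintf("duplicated plot_id in meta table: %s",
                             meta$plot_id[duplicated(meta$plot_id)][1]))
  bad <- setdiff(meta$treatment, c("gap", "control", "reference"))
  if (length(bad) > 0)
    abort_validation(sprintf("unknown treatment value: %s", bad[1]))
  if (any(is.na(meta$area_m2) | meta$area_m2 <= 0))
    abort_validation("area_m2 must be positive for every plot")

  for (pid in unique(stats::na.omit(meta$pair_id))) {
    trt <- sort(meta$treatment[!is.na(meta$pair_id) & meta$pair_id == pid])
    if (!identical(trt, c("control", "gap")))
      abort_validation(sprintf(
        "pair_id %s must group exactly one gap and one control plot (found: %s)",
        pid, paste(trt, collapse = ", ")))
  }

  orphan <- setdiff(unique(census$plot_id), meta$plot_id)
  if (length(orphan) > 0)
    abort_referential(sprintf("census plot_id %s has no row in the meta table",
                              orphan[1]))

  structure(
    list(census = census, meta = meta,
         species_union = sort(unique(census$species), method = "radix")),
    class = "census_collection")
}

#' @export
print.census_collection <- function(x, ...) {
  key <- unique(x$census[c("plot_id", "census_label")])
  cat(sprintf("census_collection: %d censuses, %d plots, %d species\n",
              nrow(key), nrow(x$meta), length(x$species_union)))
  cat(sprintf("  treatments: %s\n",
              paste(sprintf("%s=%d", names(table(x$meta$treatment)),
                            table(x$meta$treatment)), collapse = ", ")))
  invisible(x)
}

delim_for <- function(path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_checked <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    quote = "\"", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    fileEncoding = "UTF-8")
}

#' Read a census collection from delimited files
#'
#' Reads the census and metadata tables (CSV, or TSV when the file extension
#' is `.tsv`/`.tab`; header row required; lines starting with `#` ignored)
#' and returns a validated [census_collection()]. Duplicate
#' (plot, census, species) rows are an error, never summed.
#'
#' @param census_table path to the census table.
#' @param meta_table path to the plot metadata table.
#' @return A `census_collection`.
#' @export
read_censuses <- function(census_table, meta_table) {
  census_collection(read_table_checked(census_table),
                    read_table_checked(meta_table))
}

#' Write a census collection to delimited files
#'
#' Inverse of [read_censuses()]: writes the two tables so that reading them
#' back reproduces the collection exactly.
#'
#' @param collection a `census_collection`.
#' @param census_table,meta_table output paths (CSV, or TSV by extension).
#' @param header_lines optional character vector of comment lines (each
#'   prefixed with `"# "`) written before the header of both files.
#' @return Invisibly, `collection`.
#' @export
write_censuses <- function(collection, census_table, meta_table,
                           header_lines = NULL) {
  stopifnot(inherits(collection, "census_collection"))
  write_one <- function(df, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (length(header_lines) > 0)
      writeLines(paste("#", header_lines), con)
    utils::write.table(df, con, sep = delim_for(path), row.names = FALSE,
                       quote = FALSE)
  }
  write_one(collection$census, census_table)
  write_one(collection$meta, meta_table)
  invisible(collection)
}

has_census <- function(collection, plot_id, census_label) {
  any(collection$census$plot_id == plot_id &
        collection$census$census_label == census_label)
}

#' Per-species abundance vector for one census
#'
#' Materializes the abundance vector over the collection's full species
#' union for one (plot, census): the common-currency input of every
#' similarity index. Species absent from the census get 0; the order is the
#' collection's `species_union` (lexicographic), so vectors from the same
#' collection are always conformable.
#'
#' @param collection a [census_collection()].
#' @param plot_id,census_label identify the census.
#' @param measure `"density"` for stem counts per plot or `"basal_area"`
#'   for per-species summed basal area (m² per plot).
#' @return Named numeric vector over `collection$species_union`.
#' @export
abundance_vectors <- function(collection, plot_id, census_label,
                              measure = c("density", "basal_area")) {
  stopifnot(inherits(collection, "census_collection"))
  measure <- match.arg(measure)
  rows <- collection$census[collection$census$plot_id == plot_id &
                              collection$census$census_label == census_label, ]
  if (nrow(rows) == 0 && !has_census(collection, plot_id, census_label)) {
    # distinguish "no such census" from "census recorded as empty": an empty
    # census can only exist through explicit zero-stem rows, so no rows at
    # all means the census was never taken
    abort_lookup(sprintf("no census for plot %s at census %s",
                         plot_id, census_label))
  }
  v <- stats::setNames(numeric(length(collection$species_union)),
                       collection$species_union)
  val <- if (measure == "density") as.numeric(rows$stems) else rows$basal_area_m2
  v[rows$species] <- val
  v
}

# all (plot_id, census_label) combinations present in the collection
census_keys <- function(collection) {
  unique(collection$census[c("plot_id", "census_label")])
}
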