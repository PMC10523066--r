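## Occurrence-data treatment: from a raw occurrence table in the
## Paleobiology Database download dialect to per-class capture histories
## with standardized covariates.
##
## Treatment rules, applied in order (the end state is order-independent):
##   1. subgenera elevated to genus level;
##   2. genera without a body-size trait entry removed;
##   3. occurrences not resolved to a single stage of the working stage
##      table removed (this also drops Cambrian occurrences, which predate
##      the table);
##   4. genera left without any stage-resolved occurrence removed;
##   5. classes with fewer than `min_genera` remaining genera removed.

default_column_map <- function() {
  list(genus = "genus", subgenus = "subgenus", class_name = "class",
       early_interval = "early_interval", late_interval = "late_interval",
       lng = "lng", lat = "lat", paleo_lng = "paleolng", paleo_lat = "paleolat")
}

#' Read an occurrence table in PBDB download dialect
#'
#' Reads a CSV of fossil occurrences with a configurable column map
#' (defaults cover the standard PBDB occurrence download: `genus`, `class`,
#' `early_interval`, `late_interval`, `lng`, `lat`, `paleolng`, `paleolat`).
#' An occurrence is stage-resolved when its early and late intervals name
#' the same stage of `stage_table` (an empty late interval counts as equal
#' to the early one, the PBDB convention); otherwise `stage_name` is empty.
#'
#' @param path CSV path (or a data.frame already in memory).
#' @param stage_table A `stage_table` used to recognize stage names.
#' @param column_map Named list mapping internal names to file columns; see
#'   `paleoCMR:::default_column_map()`.
#' @return A data.table of occurrence records with standardized columns
#'   `genus`, `subgenus`, `class_name`, `stage_name` (empty when
#'   unresolved), `stage_index` (NA when unresolved), `lng`, `lat`,
#'   `paleo_lng`, `paleo_lat`. A summary of unresolved rows is attached as
#'   attribute `"resolution_log"` and reported via `message()`.
#' @export
read_occurrences <- function(path, stage_table, column_map = list()) {
  cm <- utils::modifyList(default_column_map(), column_map)
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path, colClasses = list(character = unlist(cm[c(
          "genus", "class_name", "early_interval", "late_interval")])))
  required <- c("genus", "class_name", "early_interval", "lng", "lat")
  for (key in required) {
    if (!cm[[key]] %in% names(dt)) {
      stop("required column not found in occurrence file: ", cm[[key]],
           " (mapped from '", key, "')")
    }
  }
  get_col <- function(key, default = NA) {
    if (cm[[key]] %in% names(dt)) dt[[cm[[key]]]] else rep(default, nrow(dt))
  }
  out <- data.table::data.table(
    genus = as.character(get_col("genus")),
    subgenus = as.character(get_col("subgenus", NA_character_)),
    class_name = as.character(get_col("class_name")),
    early_interval = as.character(get_col("early_interval")),
    late_interval = as.character(get_col("late_interval", NA_character_)),
    lng = as.numeric(get_col("lng")),
    lat = as.numeric(get_col("lat")),
    paleo_lng = as.numeric(get_col("paleo_lng", NA_real_)),
    paleo_lat = as.numeric(get_col("paleo_lat", NA_real_))
  )
  bad <- which(!is.na(out$lng) & (abs(out$lng) > 180 | abs(out$lat) > 90))
  if (length(bad)) stop("coordinates out of range in rows: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  late <- ifelse(is.na(out$late_interval) | out$late_interval == "",
                 out$early_interval, out$late_interval)
  resolved <- out$early_interval == late & out$early_interval %in% stage_table$name
  out$stage_name <- ifelse(resolved, out$early_interval, "")
  out$stage_index <- stage_table$index[match(out$stage_name, stage_table$name)]
  n_unres <- sum(!resolved)
  attr(out, "resolution_log") <- list(n_rows = nrow(out),
                                      n_resolved = sum(resolved),
                                      n_unresolved = n_unres)
  if (n_unres > 0) {
    message(n_unres, " of ", nrow(out),
            " occurrence(s) not resolved to a single stage of the table")
  }
  out[]
}

#' Elevate subgenera to genus level
#'
#' Where a subgenus is recorded -- either in a dedicated subgenus column or
#' as a `"Genus (Subgenus)"` pattern in the genus name -- the operating
#' genus name becomes the subgenus name. Distinct genera may merge under
#' elevation; merges are reported.
#'
#' @param records Occurrence records from [read_occurrences()].
#' @return Records with `genus` updated.
#' @export
elevate_subgenera <- function(records) {
  records <- data.table::copy(records)
  pat <- "^\\s*(\\S+)\\s+\\((\\S+)\\)\\s*$"
  from_name <- grepl(pat, records$genus)
  records[from_name, genus := sub(pat, "\\2", genus)]
  has_sub <- !is.na(records$subgenus) & records$subgenus != ""
  records[has_sub, genus := subgenus]
  n_elev <- sum(from_name | has_sub)
  if (n_elev) message(n_elev, " occurrence(s) elevated to subgenus name")
  records[]
}

#' Read a genus body-size trait table
#'
#' @param path CSV with header `genus,class,log10_volume_mm3` (or a
#'   data.frame).
#' @return data.table with columns `genus`, `class_name`, `log_size`.
#' @export
read_traits <- function(path) {
  dt <- if (is.data.frame(path)) data.table::as.data.table(path)
        else data.table::fread(path)
  need <- c("genus", "class", "log10_volume_mm3")
  if (!all(need %in% names(dt))) {
    stop("trait table needs columns: ", paste(need, collapse = ", "))
  }
  data.table::data.table(genus = as.character(dt$genus),
                         class_name = as.character(dt$class),
                         log_size = as.numeric(dt$log10_volume_mm3))
}

#' Apply the study's occurrence filters
#'
#' Keeps occurrences that (i) belong to a genus with a body-size trait
#' entry, (ii) are resolved to a single stage of the working stage table
#' (Cambrian occurrences predate the table and drop here), (iii) belong to
#' a genus retaining at least one stage-resolved occurrence, and (iv) belong
#' to a class whose surviving genus count reaches `min_genera` (applied
#' last, to the analysable set). Per-rule removal tallies are attached as
#' attribute `"filter_log"`.
#'
#' @param records Occurrence records (after [elevate_subgenera()]).
#' @param traits Trait table from [read_traits()].
#' @param stage_table The working `stage_table`.
#' @param min_genera Minimum genera per class (default 500, the study
#'   criterion; lower it for toy data).
#' @return Filtered records with a `filter_log` attribute.
#' @export
apply_study_filters <- function(records, traits, stage_table,
                                min_genera = 500L) {
  n0 <- nrow(records)
  trait_key <- paste(traits$genus, traits$class_name)
  has_trait <- paste(records$genus, records$class_name) %in% trait_key
  r1 <- records[has_trait]
  n_no_trait <- n0 - nrow(r1)

  resolved <- !is.na(r1$stage_index)
  r2 <- r1[resolved]
  n_unresolved <- nrow(r1) - nrow(r2)

  cls_counts <- r2[, list(n_gen = data.table::uniqueN(genus)), by = class_name]
  keep_cls <- cls_counts$class_name[cls_counts$n_gen >= min_genera]
  r3 <- r2[class_name %in% keep_cls]
  n_small_class <- nrow(r2) - nrow(r3)

  log <- list(n_input = n0, removed_no_trait = n_no_trait,
              removed_unresolved = n_unresolved,
              removed_small_class = n_small_class,
              n_kept = nrow(r3),
              classes_kept = sort(keep_cls))
  if (nrow(r3) == 0L) {
    stop("no occurrences survive the filters; review min_genera (",
         min_genera, "), the trait table and the stage table coverage")
  }
  attr(r3, "filter_log") <- log
  message(sprintf(
    "filters: %d input; removed %d (no trait), %d (not stage-resolved), %d (class < %d genera); %d kept",
    n0, n_no_trait, n_unresolved, n_small_class, min_genera, nrow(r3)))
  r3[]
}

#' Per-stage geographic ranges for every genus
#'
#' For every genus and every stage within its observed stage span (first to
#' last detected stage inclusive): the maximum great-circle distance among
#' the distinct occurrence points of that stage when at least two exist,
#' otherwise the 1 km convention (so `log_range = 0`). Coordinates are
#' palaeocoordinates when present (`coords = "paleo"`, default, falling
#' back to modern values where missing) or modern ones (`coords =
#' "modern"`).
#'
#' @param records Filtered occurrence records.
#' @param stage_table The working `stage_table` (unused beyond validation;
#'   spans are in stage indices already).
#' @param coords `"paleo"` or `"modern"`.
#' @return data.table with columns `class_name`, `genus`, `stage_index`,
#'   `n_occ`, `gcd_km`, `log_range`.
#' @export
build_stage_ranges <- function(records, stage_table, coords = c("paleo", "modern")) {
  coords <- match.arg(coords)
  dt <- data.table::copy(records)
  if (coords == "paleo") {
    dt[, `:=`(use_lng = ifelse(is.na(paleo_lng), lng, paleo_lng),
              use_lat = ifelse(is.na(paleo_lat), lat, paleo_lat))]
  } else {
    dt[, `:=`(use_lng = lng, use_lat = lat)]
  }
  per_stage <- dt[, {
    pts <- distinct_points(use_lng, use_lat)
    gcd <- if (nrow(pts) >= 2L) max_great_circle_km(pts) else 1.0
    list(n_occ = .N, gcd_km = gcd)
  }, by = list(class_name, genus, stage_index)]

  spans <- per_stage[, list(s0 = min(stage_index), s1 = max(stage_index)),
                     by = list(class_name, genus)]
  full <- spans[, list(stage_index = s0:s1), by = list(class_name, genus)]
  out <- merge(full, per_stage, by = c("class_name", "genus", "stage_index"),
               all.x = TRUE)
  out[is.na(n_occ), `:=`(n_occ = 0L, gcd_km = 1.0)]
  out[n_occ <= 1L, gcd_km := 1.0]   # single-occurrence stages: 1 km rule
  out[, log_range := log10(gcd_km)]
  out[]
}

#' Standardize body size and geographic range
#'
#' Standard scores (mean 0, sd 1, denominator n-1) computed per class for
#' body size over the analysed genus set and per class-by-stage for log10
#' geographic range over all genus-stage rows of that cell. Zero-variance
#' cells get `z = 0` (with a warning), keeping the covariate defined.
#'
#' @param traits Trait table restricted to the analysed genera.
#' @param ranges Output of [build_stage_ranges()].
#' @return List with `traits` (gains `z_size`), `ranges` (gains `z_range`),
#'   and `range_cells` (per class-by-stage mean/sd of `log_range`, used to
#'   transform out-of-span values downstream).
#' @export
standardize <- function(traits, ranges) {
  traits <- data.table::copy(traits)
  traits[, z_size := zscore(log_size), by = class_name]

  ranges <- data.table::copy(ranges)
  cells <- ranges[, list(cell_mean = mean(log_range),
                         cell_sd = if (.N > 1L) stats::sd(log_range) else 0),
                  by = list(class_name, stage_index)]
  n_degen <- sum(cells$cell_sd == 0 | !is.finite(cells$cell_sd))
  if (n_degen) {
    warning(n_degen, " class-by-stage cell(s) with zero range variance; z set to 0")
  }
  ranges <- merge(ranges, cells, by = c("class_name", "stage_index"))
  ranges[, z_range := ifelse(cell_sd > 0, (log_range - cell_mean) / cell_sd, 0)]
  ranges[, c("cell_mean", "cell_sd") := NULL]
  data.table::setorder(ranges, class_name, genus, stage_index)
  list(traits = traits, ranges = ranges, range_cells = cells)
}

#' Build per-class capture histories
#'
#' Detection is 1 iff the genus has at least one stage-resolved occurrence
#' in that stage. The time-varying range covariate is defined at every
#' occasion of the window: inside the genus's observed span it is the
#' standardized stage range; outside the span it is imputed, by default at
#' the class-by-stage mean (`z = 0`), which keeps the likelihood's
#' before-first and after-last tails neutral with respect to range.
#' `outside_span = "one_km"` instead extends the in-span 1 km convention
#' (the standardized transform of `log_range = 0`); this couples the
#' covariate with detection itself and can reverse the apparent
#' range-survival association, so it is not the default.
#'
#' @param records Filtered occurrence records.
#' @param std Output of [standardize()].
#' @param stage_table The working `stage_table`.
#' @param per_class_window Trim each class's occasion window to the stages
#'   its occurrences span (default `TRUE`); otherwise use the full table.
#' @param outside_span Out-of-span range imputation: `"cell_mean"`
#'   (default) or `"one_km"`.
#' @return Named list of `capture_history_set`, one per class.
#' @export
build_capture_histories <- function(records, std, stage_table,
                                    per_class_window = TRUE,
                                    outside_span = c("cell_mean", "one_km")) {
  outside_span <- match.arg(outside_span)
  traits <- std$traits
  ranges <- std$ranges
  cells <- std$range_cells
  out <- list()
  for (cls in sort(unique(records$class_name))) {
    rec_c <- records[class_name == cls]
    rng_c <- ranges[class_name == cls]
    window <- if (per_class_window) {
      seq(min(rec_c$stage_index), max(rec_c$stage_index))
    } else stage_table$index
    Tn <- length(window)
    genera <- sort(unique(rec_c$genus))
    n <- length(genera)

    det <- rec_c[, list(n_occ = .N), by = list(genus, stage_index)]
    ch <- matrix(0L, n, Tn, dimnames = list(genera, stage_table$name[window]))
    ch[cbind(match(det$genus, genera), match(det$stage_index, window))] <- 1L

    z0 <- rep(0, Tn)
    if (outside_span == "one_km") {
      ## standardized transform of log_range = 0 per class-by-stage cell
      cell_c <- cells[class_name == cls]
      m <- match(window, cell_c$stage_index)
      ok <- !is.na(m) & cell_c$cell_sd[m] > 0
      z0[ok] <- (0 - cell_c$cell_mean[m[ok]]) / cell_c$cell_sd[m[ok]]
    }
    zr <- matrix(rep(z0, each = n), n, Tn)
    in_span <- rng_c[stage_index %in% window]
    zr[cbind(match(in_span$genus, genera),
             match(in_span$stage_index, window))] <- in_span$z_range

    zs <- traits[class_name == cls]
    zsv <- zs$z_size[match(genera, zs$genus)]

    out[[cls]] <- capture_history_set(ch, zsv, zr, genera, cls,
                                      stage_table, window)
  }
  out
}

#' Run the full occurrence-preparation pipeline
#'
#' Convenience wrapper: read, elevate subgenera, filter, build stage ranges,
#' standardize, and build per-class capture histories.
#'
#' @param occurrences Path or data.frame (PBDB dialect).
#' @param traits Path or data.frame (`genus,class,log10_volume_mm3`).
#' @param stage_table A `stage_table` (default: packaged table).
#' @param min_genera Class-size threshold (default 500).
#' @param coords Coordinate mode for ranges (`"paleo"` or `"modern"`).
#' @param per_class_window,outside_span See [build_capture_histories()].
#' @param column_map Passed to [read_occurrences()].
#' @return List with `histories` (per class), `traits`, `ranges`,
#'   `filter_log`.
#' @export
prepare_occurrences <- function(occurrences, traits,
                                stage_table = load_stage_table(),
                                min_genera = 500L, coords = "paleo",
                                per_class_window = TRUE,
                                outside_span = "cell_mean",
                                column_map = list()) {
  recs <- read_occurrences(occurrences, stage_table, column_map)
  recs <- elevate_subgenera(recs)
  tr <- read_traits(traits)
  recs <- apply_study_filters(recs, tr, stage_table, min_genera)
  tr_used <- tr[paste(genus, class_name) %in%
                  unique(paste(recs$genus, recs$class_name))]
  rng <- build_stage_ranges(recs, stage_table, coords)
  std <- standardize(tr_used, rng)
  hists <- build_capture_histories(recs, std, stage_table, per_class_window,
                                   outside_span)
  list(histories = hists, traits = std$traits, ranges = std$ranges,
       filter_log = attr(recs, "filter_log"))
}
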