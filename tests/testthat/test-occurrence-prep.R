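toy_stage_table <- function() make_stage_table(8L, 5L)

toy_records <- function() {
  data.frame(
    genus = c("Aa", "Aa", "Bb", "Cc", "Acila (Truncacila)"),
    class = "Bivalvia",
    early_interval = c("S02", "S02", "Permian", "S03", "S04"),
    late_interval = c("S02", "", "Permian", "S05", "S04"),
    lng = c(0, 1, 2, 3, 4), lat = c(0, 0, 0, 0, 0),
    paleolng = c(0, 1, 2, 3, 4), paleolat = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

test_that("occurrence reader resolves stages per the PBDB conventions", {
  st <- toy_stage_table()
  recs <- quiet(read_occurrences(toy_records(), st))
  ## early == late naming a known stage resolves; empty late counts as equal
  expect_equal(recs$stage_name[1:2], c("S02", "S02"))
  ## a period name is not a stage of the table
  expect_equal(recs$stage_name[3], "")
  ## early != late spans several stages: unresolved
  expect_equal(recs$stage_name[4], "")
  log <- attr(recs, "resolution_log")
  expect_equal(log$n_rows, 5L)
  expect_equal(log$n_unresolved, 2L)
  expect_error(quiet(read_occurrences(toy_records()[, -1], st)),
               "required column")
})

test_that("subgenera are elevated from name pattern and column", {
  st <- toy_stage_table()
  recs <- quiet(read_occurrences(toy_records(), st))
  out <- quiet(elevate_subgenera(recs))
  expect_equal(out$genus[5], "Truncacila")
  expect_equal(out$genus[1], "Aa")           # no subgenus: unchanged
  recs$subgenus <- c("", "", "Sub", "", "")
  out2 <- quiet(elevate_subgenera(recs))
  expect_equal(out2$genus[3], "Sub")
})

test_that("study filters remove traitless, unresolved and small-class records", {
  st <- toy_stage_table()
  recs <- quiet(elevate_subgenera(read_occurrences(toy_records(), st)))
  traits <- data.table::data.table(
    genus = c("Aa", "Cc", "Truncacila"), class_name = "Bivalvia",
    log_size = c(1, 2, 3))
  out <- quiet(apply_study_filters(recs, traits, st, min_genera = 1L))
  ## Bb has no trait; Cc's only occurrence is not stage-resolved
  expect_setequal(unique(out$genus), c("Aa", "Truncacila"))
  log <- attr(out, "filter_log")
  expect_equal(log$removed_no_trait, 1L)
  expect_equal(log$removed_unresolved, 1L)

  ## class below the genus threshold disappears entirely
  expect_error(quiet(apply_study_filters(recs, traits, st, min_genera = 500L)),
               "min_genera")

  ## end state matches an independently computed record set
  keep_manual <- with(recs, {
    g <- ifelse(grepl("\\(", genus), sub(".*\\((.*)\\).*", "\\1", genus), genus)
    g %in% traits$genus & !is.na(stage_index)
  })
  expect_equal(nrow(out), sum(keep_manual))
})

test_that("stage ranges follow the observed span and the 1 km rule", {
  st <- toy_stage_table()
  recs <- data.table::data.table(
    genus = "Gg", class_name = "X",
    stage_index = c(3L, 3L, 6L),
    lng = c(0, 0, 10), lat = c(0, 1, 0),
    paleo_lng = c(0, 0, 10), paleo_lat = c(0, 1, 0))
  rng <- build_stage_ranges(recs, st)
  expect_equal(rng$stage_index, 3:6)
  ## two points 1 degree apart on a meridian at stage 3
  expect_equal(rng$gcd_km[1], 111.1949, tolerance = 1e-4)
  ## interior gap stages and the single-occurrence stage get 1 km
  expect_equal(rng$gcd_km[2:4], c(1, 1, 1))
  expect_equal(rng$log_range[2:4], c(0, 0, 0))
  ## duplicate coordinates collapse to one distinct point
  recs2 <- data.table::data.table(
    genus = "Hh", class_name = "X", stage_index = c(2L, 2L),
    lng = c(5, 5), lat = c(5, 5), paleo_lng = c(5, 5), paleo_lat = c(5, 5))
  rng2 <- build_stage_ranges(recs2, st)
  expect_equal(rng2$gcd_km, 1)
  ## invariants: n_occ <= 1 => 1 km; 1 km <=> log_range = 0
  both <- rbind(rng, rng2)
  expect_true(all(both$gcd_km[both$n_occ <= 1L] == 1))
  expect_equal(both$gcd_km == 1, both$log_range == 0)
})

test_that("standardization gives exact z-scores and handles degenerate cells", {
  traits <- data.table::data.table(genus = c("a", "b", "c"),
                                   class_name = "X", log_size = c(1, 2, 3))
  ranges <- data.table::data.table(
    class_name = "X", genus = c("a", "b", "c", "a"),
    stage_index = c(1L, 1L, 1L, 2L), n_occ = 2L,
    gcd_km = c(10, 100, 1000, 50), log_range = log10(c(10, 100, 1000, 50)))
  std <- quiet(standardize(traits, ranges))
  expect_equal(std$traits$z_size, c(-1, 0, 1))
  cell1 <- std$ranges[std$ranges$stage_index == 1L, ]
  expect_equal(mean(cell1$z_range), 0, tolerance = 1e-9)
  expect_equal(sd(cell1$z_range), 1, tolerance = 1e-9)
  ## single-genus cell: z = 0 with a warning
  expect_warning(standardize(traits, ranges), "zero range variance")
  expect_equal(std$ranges$z_range[std$ranges$stage_index == 2L], 0)
  ## standardization is reversible on non-degenerate cells
  cells <- std$range_cells[std$range_cells$stage_index == 1L, ]
  back <- cell1$z_range * cells$cell_sd + cells$cell_mean
  expect_equal(back, cell1$log_range, tolerance = 1e-9)
})

test_that("capture histories encode detections over the class window", {
  sim <- make_fixture("tiny", seed = 5)
  prep <- quiet(prepare_occurrences(sim$occurrences, sim$traits,
                                    stage_table = sim$config$stage_table,
                                    min_genera = 1L))
  h <- prep$histories[[1L]]
  ## histories = simulated genera with at least one sampled stage
  expect_equal(nrow(h$ch), sum(rowSums(sim$detected) > 0))
  expect_true(all(rowSums(h$ch) >= 1L))
  expect_equal(ncol(h$ch), length(h$window))
  ## detection matrix equals the simulator's sampling log on the window
  idx <- match(h$genus, sim$truth$genus)
  expect_equal(unname(h$ch), unname(sim$detected[idx, h$window] * 1L))
  ## full-table window on request
  prep2 <- quiet(prepare_occurrences(sim$occurrences, sim$traits,
                                     stage_table = sim$config$stage_table,
                                     min_genera = 1L,
                                     per_class_window = FALSE))
  expect_equal(ncol(prep2$histories[[1L]]$ch), nrow(sim$config$stage_table))
})

test_that("preparation is deterministic", {
  sim <- make_fixture("tiny", seed = 7)
  p1 <- quiet(prepare_occurrences(sim$occurrences, sim$traits,
                                  stage_table = sim$config$stage_table,
                                  min_genera = 1L))
  p2 <- quiet(prepare_occurrences(sim$occurrences, sim$traits,
                                  stage_table = sim$config$stage_table,
                                  min_genera = 1L))
  expect_identical(p1$histories[[1L]]$ch, p2$histories[[1L]]$ch)
  expect_identical(p1$histories[[1L]]$z_range, p2$histories[[1L]]$z_range)
})
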