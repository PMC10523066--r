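## timescale: ordered geologic stage bins with mass-extinction/recovery flags.
##
## A stage_table is a data.frame with columns
##   name, index, age_base, age_top, is_mass_extinction, is_recovery
## ordered from oldest (index 1) to youngest. The packaged default spans the
## base of the Ordovician (Tremadocian, 485.4 Ma) to the early Pleistocene
## (Gelasian, top 1.8 Ma): 86 stages, the canonical Big Five flagged.

#' Names of the Big Five mass-extinction stages
#'
#' Stage-level placements of the five canonical Phanerozoic mass extinctions:
#' End-Ordovician (Hirnantian), Late Devonian (Frasnian), End-Permian
#' (Changhsingian), End-Triassic (Rhaetian) and End-Cretaceous
#' (Maastrichtian). The Late Devonian event is sometimes placed at the
#' Famennian instead; pass your own vector to [flag_big_five()] for
#' alternative definitions.
#'
#' @return Character vector of five stage names.
#' @export
big_five_stages <- function() {
  c("Hirnantian", "Frasnian", "Changhsingian", "Rhaetian", "Maastrichtian")
}

#' Load and validate a geologic stage table
#'
#' Reads a stage table CSV (columns `name`, `age_base`, `age_top` and optional
#' 0/1 flag columns `is_mass_extinction`, `is_recovery`), orders it oldest
#' first, validates age contiguity, and derives recovery flags from the
#' mass-extinction flags. With no argument the packaged
#' Ordovician--Pleistocene table (86 stages, Big Five flagged) is returned.
#'
#' @param path Path to a stage-table CSV, or `NULL` for the packaged default.
#' @return A `stage_table` data.frame with columns `name`, `index`,
#'   `age_base`, `age_top`, `is_mass_extinction`, `is_recovery`.
#' @examples
#' st <- load_stage_table()
#' sum(st$is_mass_extinction)  # 5
#' @export
load_stage_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stage_table_default.csv",
                        package = "paleoCMR", mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "age_base", "age_top")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("stage table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$is_mass_extinction)) df$is_mass_extinction <- 0L
  if (is.null(df$is_recovery)) df$is_recovery <- 0L
  as_stage_table(df)
}

#' Construct a stage table from a data.frame
#'
#' @param df Data frame with columns `name`, `age_base`, `age_top` and
#'   optional flag columns.
#' @return A validated `stage_table`.
#' @export
as_stage_table <- function(df) {
  df <- df[order(-df$age_base), , drop = FALSE]
  df$index <- seq_len(nrow(df))
  df$is_mass_extinction <- as.logical(df$is_mass_extinction %||% FALSE)
  df$is_recovery <- as.logical(df$is_recovery %||% FALSE)
  df <- df[, c("name", "index", "age_base", "age_top",
               "is_mass_extinction", "is_recovery")]
  rownames(df) <- NULL
  class(df) <- c("stage_table", "data.frame")
  validate_stage_table(df)
  derive_recovery_flags(df)
}

validate_stage_table <- function(st) {
  bad <- which(st$age_base <= st$age_top)
  if (length(bad)) {
    stop("stage(s) with age_base <= age_top: ",
         paste(st$name[bad], collapse = ", "))
  }
  if (nrow(st) > 1L) {
    gaps <- which(abs(st$age_top[-nrow(st)] - st$age_base[-1L]) > 1e-6)
    if (length(gaps)) {
      stop("non-contiguous or overlapping stages at: ",
           paste(sprintf("%s/%s", st$name[gaps], st$name[gaps + 1L]),
                 collapse = ", "))
    }
  }
  if (anyDuplicated(st$name)) {
    stop("duplicated stage names: ",
         paste(unique(st$name[duplicated(st$name)]), collapse = ", "))
  }
  invisible(st)
}

#' Flag the Big Five mass-extinction stages
#'
#' Sets `is_mass_extinction` to `TRUE` for exactly the named stages and
#' `FALSE` everywhere else, then re-derives recovery flags. Idempotent.
#'
#' @param st A `stage_table`.
#' @param stages Character vector of stage names to flag; defaults to
#'   [big_five_stages()]. Supply e.g. `"Famennian"` in place of `"Frasnian"`
#'   for the alternative Late Devonian placement, or any other set for
#'   sensitivity analyses.
#' @return The stage table with updated flags.
#' @export
flag_big_five <- function(st, stages = big_five_stages()) {
  stopifnot(inherits(st, "stage_table"))
  absent <- setdiff(stages, st$name)
  if (length(absent)) {
    stop("stage(s) not present in table: ", paste(absent, collapse = ", "))
  }
  st$is_mass_extinction <- st$name %in% stages
  derive_recovery_flags(st)
}

#' Derive recovery flags from mass-extinction flags
#'
#' A recovery stage is the stage immediately following a mass-extinction
#' stage. Recomputes `is_recovery` as a pure function of
#' `is_mass_extinction`; re-deriving is idempotent.
#'
#' @param st A `stage_table` with mass-extinction flags set.
#' @return The stage table with `is_recovery` updated.
#' @export
derive_recovery_flags <- function(st) {
  stopifnot(inherits(st, "stage_table"))
  n <- nrow(st)
  rec <- rep(FALSE, n)
  me <- which(st$is_mass_extinction)
  if (length(me) && n %in% me) {
    warning("mass-extinction flag on the final stage: no recovery stage exists")
  }
  succ <- me[me < n] + 1L
  rec[succ] <- TRUE
  st$is_recovery <- rec
  st
}

#' @export
print.stage_table <- function(x, ...) {
  cat(sprintf("<stage_table> %d stages, %.1f-%.1f Ma; %d mass-extinction, %d recovery\n",
              nrow(x), max(x$age_base), min(x$age_top),
              sum(x$is_mass_extinction), sum(x$is_recovery)))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Build a synthetic stage table of contiguous 1-Myr bins
#'
#' Convenience constructor used by the simulator and tests: `n` contiguous
#' stages named `S01, S02, ...`, optionally flagging mass-extinction stages
#' by index.
#'
#' @param n Number of stages.
#' @param me_stages Integer indices (oldest = 1) to flag as mass extinctions.
#' @return A `stage_table`.
#' @export
make_stage_table <- function(n, me_stages = integer(0)) {
  stopifnot(n >= 1L, all(me_stages >= 1L & me_stages <= n))
  df <- data.frame(
    name = sprintf("S%02d", seq_len(n)),
    age_base = seq(n, 1),
    age_top = seq(n - 1, 0),
    is_mass_extinction = seq_len(n) %in% me_stages,
    is_recovery = FALSE
  )
  as_stage_table(df)
}
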