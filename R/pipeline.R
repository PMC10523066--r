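## Pipeline orchestration: prepare -> fit -> select -> report, and the
## simulate -> recover experiment harness. Functions are the primary
## interface; a thin command-line wrapper ships in inst/cli/paleocmr.R.

pkg_version <- function() as.character(utils::packageVersion("paleoCMR"))

config_hash <- function(config) {
  x <- config
  x$stage_table <- NULL
  substr(digest_chr(paste(deparse(x), collapse = "")), 1L, 12L)
}

## small stable string hash (FNV-1a); avoids a digest dependency
digest_chr <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x%08x", h %/% 65536, (h * 2654435761) %% 4294967296 %/% 65536)
}

output_header <- function(seed, config) {
  sprintf("# paleoCMR %s | seed=%s | config=%s", pkg_version(),
          seed %||% "NA", config_hash(config))
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [run_prepare()] and
#'   [run_fit_select()] (`occurrences`, `traits`, `stage_table`,
#'   `out_dir`, `min_genera`, `coords`, `me_stages`, `ess_rule`,
#'   `min_weight`, `model_set`, `starts`, `seed`, `tol`).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("occurrences", "traits")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("configured file does not exist: ", cfg[[key]], " (", key, ")")
    }
  }
  cfg
}

#' Prepare capture histories from configured inputs
#'
#' Reads occurrences and traits, applies the treatment rules, and writes a
#' per-class capture-history bundle: `capture_histories_<class>.csv`
#' (`class,genus,detections` with detections as a 0/1 string), `z_size_<class>.csv`,
#' `z_range_<class>.csv` (genus x stage matrix), and `filter_tally.json`.
#'
#' @param config Named list (see [read_run_config()]); requires
#'   `occurrences` and `traits`, honors `stage_table` (path), `me_stages`
#'   (stage names to flag), `min_genera`, `coords`, `per_class_window`,
#'   `out_dir`, `seed`.
#' @return The prepared bundle (list as from [prepare_occurrences()]),
#'   invisibly when `out_dir` is set.
#' @export
run_prepare <- function(config) {
  st <- if (is.null(config$stage_table)) load_stage_table()
        else load_stage_table(config$stage_table)
  if (!is.null(config$me_stages)) st <- flag_big_five(st, config$me_stages)
  prep <- prepare_occurrences(
    config$occurrences, config$traits, stage_table = st,
    min_genera = config$min_genera %||% 500L,
    coords = config$coords %||% "paleo",
    per_class_window = config$per_class_window %||% TRUE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- output_header(config$seed, config)
    for (cls in names(prep$histories)) {
      h <- prep$histories[[cls]]
      ch_df <- data.frame(class = cls, genus = h$genus,
                          detections = apply(h$ch, 1L, paste, collapse = ""))
      write_with_header(ch_df,
        file.path(config$out_dir, paste0("capture_histories_", cls, ".csv")), hdr)
      write_with_header(data.frame(genus = h$genus, z_size = h$z_size),
        file.path(config$out_dir, paste0("z_size_", cls, ".csv")), hdr)
      zr <- data.frame(genus = h$genus, h$z_range)
      names(zr) <- c("genus", h$stage_table$name[h$window])
      write_with_header(zr,
        file.path(config$out_dir, paste0("z_range_", cls, ".csv")), hdr)
    }
    jsonlite::write_json(prep$filter_log,
                         file.path(config$out_dir, "filter_tally.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(prep))
  }
  prep
}

resolve_model_set <- function(model_set) {
  if (is.list(model_set)) return(model_set)
  switch(model_set %||% "canonical_121",
         canonical_121 = enumerate_model_set(),
         reduced_8 = reduced_model_set(),
         stop("unknown model set: ", model_set))
}

#' Fit a model set per class and select
#'
#' Fits the configured candidate set (canonical 121 by default) to each
#' class's capture histories, ranks by AICc, and averages coefficients.
#' Fits are cached per (class, model id, config hash) under
#' `out_dir/cache/` so a rerun touches only missing fits. A class whose
#' models all fail is reported and skipped; other classes proceed.
#'
#' @param prep Bundle from [run_prepare()] / [prepare_occurrences()] (or a
#'   named list of `capture_history_set`).
#' @param config Named list: `model_set` (`"canonical_121"`,
#'   `"reduced_8"`, or a list of `model_spec`), `ess_rule`, `min_weight`,
#'   `starts`, `seed`, `tol`, `out_dir`.
#' @return List per class with `fits`, `table` (model_table) and
#'   `selectivity`; writes `model_table_<class>.csv` and
#'   `selectivity.csv` when `out_dir` is set.
#' @export
run_fit_select <- function(prep, config = list()) {
  hists <- if (!is.null(prep$histories)) prep$histories else prep
  specs <- resolve_model_set(config$model_set)
  out <- list()
  cache_dir <- if (!is.null(config$out_dir)) {
    d <- file.path(config$out_dir, "cache"); dir.create(d, recursive = TRUE,
                                                        showWarnings = FALSE); d
  } else NULL
  chash <- config_hash(config)
  for (cls in names(hists)) {
    h <- hists[[cls]]
    fits <- lapply(specs, function(sp) {
      cache_file <- if (!is.null(cache_dir))
        file.path(cache_dir, sprintf("%s_%s_%s.rds", cls, sp$id, chash))
      if (!is.null(cache_dir) && file.exists(cache_file)) {
        return(readRDS(cache_file))
      }
      f <- fit_model(sp, h,
                     starts = config$starts %||% 3L,
                     seed = config$seed %||% 1L,
                     tol = config$tol %||% 1e-8,
                     range_lag = config$range_lag %||% "current")
      if (!is.null(cache_dir)) saveRDS(f, cache_file)
      f
    })
    res <- tryCatch({
      tab <- rank_models(fits, ess_rule = config$ess_rule %||% "histories",
                         hist = h)
      sel <- average_coefficients(tab,
                                  min_weight = config$min_weight %||% 0.01,
                                  class_name = cls)
      list(fits = fits, table = tab, selectivity = sel)
    }, error = function(e) {
      message("class ", cls, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[cls]] <- res
  }
  if (!is.null(config$out_dir)) {
    hdr <- output_header(config$seed, config)
    for (cls in names(out)) {
      tab <- out[[cls]]$table
      write_with_header(
        data.frame(rank = seq_len(nrow(tab)),
                   as.data.frame(tab)[, c("model_id", "phi", "gamma", "p",
                                          "loglik", "k", "AICc", "dAICc",
                                          "weight")]),
        file.path(config$out_dir, paste0("model_table_", cls, ".csv")), hdr)
    }
    sel_all <- do.call(rbind, lapply(out, `[[`, "selectivity"))
    if (!is.null(sel_all)) {
      write_with_header(sel_all, file.path(config$out_dir, "selectivity.csv"),
                        hdr)
    }
  }
  out
}

#' Simulate-and-recover experiment
#'
#' Repeatedly simulates a fossil record from a known configuration, runs
#' the full preparation pipeline (or fits on the truth log directly), fits
#' a model set, and compares estimates with the generating coefficients.
#'
#' @param sim_cfg A [sim_config()]; its seed is re-derived per replicate.
#' @param n_seeds Number of replicates.
#' @param model_set As in [run_fit_select()]; default `"reduced_8"`.
#' @param use_pipeline Run occurrence-table preparation per replicate
#'   (default `TRUE`); `FALSE` fits on truth-log histories.
#' @param min_weight,ess_rule,starts,tol Selection/fit options.
#' @param base_seed Base seed; replicate r uses `base_seed + r`.
#' @return A `recovery_report` list: per-replicate table (top-model regime,
#'   background and ME range/size coefficients) and summary proportions.
#' @export
run_recover <- function(sim_cfg, n_seeds = 50L, model_set = "reduced_8",
                        use_pipeline = TRUE, min_weight = 0.01,
                        ess_rule = "histories", starts = 1L, tol = 1e-8,
                        base_seed = 1000L) {
  specs <- resolve_model_set(model_set)
  rows <- vector("list", n_seeds)
  prev_fits <- vector("list", length(specs))
  for (r in seq_len(n_seeds)) {
    cfg_r <- sim_cfg
    cfg_r$seed <- as.integer(base_seed + r)
    sim <- simulate_fossil_record(cfg_r, emit_occurrences = use_pipeline)
    h <- if (use_pipeline) {
      prep <- prepare_occurrences(sim$occurrences, sim$traits,
                                  stage_table = cfg_r$stage_table,
                                  min_genera = 1L)
      prep$histories[[1L]]
    } else truth_histories(sim)
    ## warm-start each model from the same model's previous-replicate
    ## solution (first replicate: from the simplest model's fit); SEs are
    ## computed only for models that enter the average
    fits <- vector("list", length(specs))
    for (m in seq_along(specs)) {
      init_m <- if (!is.null(prev_fits[[m]])) prev_fits[[m]]
                else if (m > 1L) fits[[1L]]$coefficients
      fits[[m]] <- fit_model(specs[[m]], h, starts = starts,
                             seed = cfg_r$seed, tol = tol, hessian = FALSE,
                             init = init_m)
      if (isTRUE(fits[[m]]$converged)) prev_fits[[m]] <- fits[[m]]$coefficients
    }
    tab <- rank_models(fits, ess_rule = ess_rule, hist = h)
    need <- tab$model_id[tab$weight >= min_weight]
    fits_att <- attr(tab, "fits")
    for (id in need) fits_att[[id]] <- refit_hessian(fits_att[[id]], h)
    attr(tab, "fits") <- fits_att
    sel <- average_coefficients(tab, min_weight = min_weight,
                                class_name = sim$class_name)
    gr <- function(trait, regime)
      sel$coefficient[sel$trait == trait & sel$regime == regime]
    rows[[r]] <- data.frame(
      seed = cfg_r$seed,
      top_two_regime = tab$two_regime[1L],
      weight_two_regime = sum(tab$weight[tab$two_regime]),
      bg_range = gr("range", "background"),
      me_range = gr("range", "mass_extinction"),
      bg_size = gr("size", "background"),
      me_size = gr("size", "mass_extinction"))
  }
  reps <- do.call(rbind, rows)
  ## generating truth on the extinction scale (negated survival scale)
  truth_bg_range <- -sim_cfg$beta_range_bg
  summary <- list(
    n_seeds = n_seeds,
    prop_top_two_regime = mean(reps$top_two_regime),
    prop_me_range_attenuated = mean(abs(reps$me_range) < abs(reps$bg_range)),
    prop_bg_range_sign_correct =
      if (truth_bg_range != 0) mean(sign(reps$bg_range) == sign(truth_bg_range))
      else NA_real_,
    mean_bg_range = mean(reps$bg_range),
    mean_me_range = mean(reps$me_range))
  structure(list(replicates = reps, summary = summary, config = sim_cfg),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery_report> %d replicates\n", s$n_seeds))
  cat(sprintf("  top model two-regime:      %.0f%%\n", 100 * s$prop_top_two_regime))
  cat(sprintf("  ME range coef attenuated:  %.0f%%\n", 100 * s$prop_me_range_attenuated))
  if (!is.na(s$prop_bg_range_sign_correct))
    cat(sprintf("  background range sign ok:  %.0f%%\n",
                100 * s$prop_bg_range_sign_correct))
  cat(sprintf("  mean background range coef: %+.3f | mean ME range coef: %+.3f\n",
              s$mean_bg_range, s$mean_me_range))
  invisible(x)
}
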