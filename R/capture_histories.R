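## CaptureHistory container: per-genus detection vectors over a shared stage
## window, with the static standardized body-size covariate and the
## time-varying standardized geographic-range covariate.

#' Construct a set of capture histories
#'
#' Bundles the per-genus detection matrix with its covariates and the stage
#' window it is defined on. All downstream likelihood code operates on this
#' container.
#'
#' @param ch Integer 0/1 matrix, genera x occasions; every row must contain
#'   at least one detection.
#' @param z_size Numeric vector (one standardized body size per genus).
#' @param z_range Numeric matrix, genera x occasions (standardized log10
#'   geographic range, defined at every occasion).
#' @param genus Character vector of genus names.
#' @param class_name Single class name for the set.
#' @param stage_table The `stage_table` the window indexes into.
#' @param window Integer vector of stage indices (temporal order) the
#'   occasions correspond to.
#' @return A `capture_history_set`.
#' @export
capture_history_set <- function(ch, z_size, z_range, genus, class_name,
                                stage_table, window) {
  ch <- as.matrix(ch)
  storage.mode(ch) <- "integer"
  z_range <- as.matrix(z_range)
  stopifnot(
    nrow(ch) == length(z_size), nrow(ch) == length(genus),
    all(dim(ch) == dim(z_range)),
    length(window) == ncol(ch),
    inherits(stage_table, "stage_table"),
    all(window %in% stage_table$index)
  )
  if (any(rowSums(ch) < 1L)) {
    stop("capture histories must have at least one detection per genus")
  }
  structure(
    list(ch = ch, z_size = as.numeric(z_size), z_range = z_range,
         genus = as.character(genus), class_name = class_name,
         stage_table = stage_table, window = as.integer(window)),
    class = "capture_history_set"
  )
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat(sprintf("<capture_history_set> %s: %d genera x %d occasions (stages %s-%s)\n",
              x$class_name, nrow(x$ch), ncol(x$ch),
              x$stage_table$name[x$window[1L]],
              x$stage_table$name[x$window[length(x$window)]]))
  invisible(x)
}

#' Number of genera in a capture-history set
#' @param x A `capture_history_set`.
#' @return Integer count.
#' @export
n_histories <- function(x) nrow(x$ch)

first_last <- function(ch) {
  det <- ch > 0L
  list(first = apply(det, 1L, function(r) which(r)[1L]),
       last = apply(det, 1L, function(r) max(which(r))))
}

#' Reverse a capture-history set in time
#'
#' Used by the time-reversal diagnostic: detection vectors and the
#' time-varying covariate are reversed occasion-wise.
#'
#' @param x A `capture_history_set`.
#' @return A `capture_history_set` on the reversed occasion order.
#' @export
reverse_histories <- function(x) {
  Tn <- ncol(x$ch)
  idx <- Tn:1L
  capture_history_set(x$ch[, idx, drop = FALSE], x$z_size,
                      x$z_range[, idx, drop = FALSE], x$genus, x$class_name,
                      x$stage_table, rev(x$window))
}
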