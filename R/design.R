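#' Build a block task design of alternating rest and movement periods
#'
#' Constructs the block design used in both recording modalities: periods of
#' rest interleaved with periods of finger movement, starting with rest. The
#' default study protocol uses 30 s blocks, with 4 movement / 5 rest blocks
#' in the scanner and 5 movement / 5 rest blocks during the ECoG recording.
#'
#' @param n_movement_blocks Number of movement blocks (>= 1).
#' @param n_rest_blocks Number of rest blocks; must equal
#'   `n_movement_blocks` or exceed it by one so that strict alternation
#'   starting with rest is possible.
#' @param block_s Duration of every block in seconds.
#'
#' @return A `task_design`: a data frame with columns `onset`, `duration`
#'   (seconds) and `trial_type` (`"rest"` or `"movement"`), blocks sorted,
#'   contiguous and non-overlapping, with attribute `total_duration`.
#'
#' @examples
#' d <- make_design(4, 5, 30)   # 4 min 30 s fMRI protocol
#' attr(d, "total_duration")    # 270
#' @export
make_design <- function(n_movement_blocks, n_rest_blocks, block_s = 30) {
  n_mov <- check_count(n_movement_blocks, "n_movement_blocks")
  n_rest <- check_count(n_rest_blocks, "n_rest_blocks")
  check_scalar(block_s, "block_s")
  if (!(n_rest - n_mov) %in% c(0L, 1L))
    stop("alternation starting with rest requires n_rest_blocks - n_movement_blocks to be 0 or 1",
         call. = FALSE)
  n <- n_mov + n_rest
  trial_type <- rep(c("rest", "movement"), length.out = n)
  onset <- (seq_len(n) - 1) * block_s
  design <- data.frame(
    onset = onset,
    duration = rep(block_s, n),
    trial_type = trial_type,
    stringsAsFactors = FALSE
  )
  attr(design, "total_duration") <- n * block_s
  class(design) <- c("task_design", "data.frame")
  design
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Block task design: %d blocks, %g s total\n",
              nrow(x), attr(x, "total_duration")))
  print.data.frame(x, ...)
  invisible(x)
}

# Coerce a plain events table (onset, duration, trial_type) to task_design.
as_task_design <- function(events) {
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(events)))
  events <- events[order(events$onset), , drop = FALSE]
  if (any(events$duration <= 0))
    stop("all block durations must be > 0", call. = FALSE)
  attr(events, "total_duration") <- max(events$onset + events$duration)
  class(events) <- c("task_design", "data.frame")
  events
}

design_total_duration <- function(design) {
  td <- attr(design, "total_duration")
  if (is.null(td)) td <- max(design$onset + design$duration)
  td
}
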