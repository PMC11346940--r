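#' Create an empty cascade trace
#'
#' A cascade trace records, for an ordered sequence of filtering stages, the
#' number of surviving items and one drop reason per item removed at each
#' stage. It mirrors the stage-count boxes of the target- and
#' payload-identification workflow diagrams.
#'
#' @return An object of class `cascade_trace`.
#' @export
new_trace <- function() {
  structure(
    list(
      stages = tibble::tibble(stage = character(), n = integer()),
      drops = list()
    ),
    class = "cascade_trace"
  )
}

#' Record one stage in a cascade trace
#'
#' @param trace A `cascade_trace`.
#' @param stage Stage name (unique within the trace).
#' @param survivors Character vector (or count) of surviving items.
#' @param dropped Tibble with columns `item`, `reason` for items removed at
#'   this stage (one reason per item), or NULL.
#' @return The updated trace.
#' @export
trace_record <- function(trace, stage, survivors, dropped = NULL) {
  stopifnot(inherits(trace, "cascade_trace"))
  if (stage %in% trace$stages$stage) {
    stop("stage '", stage, "' already recorded", call. = FALSE)
  }
  n <- if (is.numeric(survivors)) as.integer(survivors) else length(survivors)
  if (!is.null(dropped) && nrow(dropped) > 0) {
    stopifnot(all(c("item", "reason") %in% names(dropped)))
    if (anyDuplicated(dropped$item)) {
      stop("multiple drop reasons recorded for one item at stage '", stage,
           "'", call. = FALSE)
    }
    trace$drops[[stage]] <- tibble::as_tibble(dropped[c("item", "reason")])
  }
  trace$stages <- dplyr::bind_rows(
    trace$stages,
    tibble::tibble(stage = stage, n = n)
  )
  trace
}

#' Check that trace counts are non-increasing along a stage chain
#'
#' @param trace A `cascade_trace`.
#' @param stages Optional character vector naming the chain to check, in
#'   order; defaults to all recorded stages in recording order.
#' @return TRUE invisibly; errors if a later stage has more survivors.
#' @export
trace_check_monotone <- function(trace, stages = NULL) {
  tab <- trace$stages
  if (!is.null(stages)) tab <- tab[match(stages, tab$stage), , drop = FALSE]
  if (any(diff(tab$n) > 0)) {
    stop("trace counts increase along the stage chain", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cascade_trace <- function(x, ...) {
  cat("<cascade_trace> ", nrow(x$stages), " stages\n", sep = "")
  print(x$stages, n = Inf)
  invisible(x)
}

#' All drop records of a trace as one table
#'
#' @param trace A `cascade_trace`.
#' @return Tibble with columns `stage`, `item`, `reason`.
#' @export
trace_drops <- function(trace) {
  if (length(trace$drops) == 0) {
    return(tibble::tibble(stage = character(), item = character(),
                          reason = character()))
  }
  dplyr::bind_rows(trace$drops, .id = "stage")
}
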