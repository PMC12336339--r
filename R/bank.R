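#' Stressor item bank
#'
#' The registry of dichotomisable workplace/pandemic stressor items and, per
#' assessment wave, the subset of items actually administered (the survey
#' battery varied between waves). The full battery holds exactly 17 items.
#'
#' @param availability Named list mapping wave ("1", "2", "3") to a character
#'   vector of item ids administered at that wave. Default: all 17 items at
#'   every wave.
#' @param labels Optional character vector of 17 item labels, named by item id.
#'
#' @return An object of class `stressor_bank` with elements `items` (ids),
#'   `labels`, and `availability`.
#' @export
#' @examples
#' bank <- stressor_bank()
#' bank$availability[["2"]]
stressor_bank <- function(availability = NULL, labels = NULL) {
  items <- sprintf("s%02d", 1:17)
  default_labels <- c(
    "Shortage of personal protective equipment",
    "Fear of becoming infected at work",
    "Fear of transmitting the infection to family",
    "Involvement in triage or rationing decisions",
    "Redeployment to an unfamiliar unit",
    "Substantially increased workload",
    "Understaffing on the ward or team",
    "Death of patients under one's care",
    "Colleagues infected or quarantined",
    "Insufficient training for assigned tasks",
    "Conflicting or rapidly changing protocols",
    "Lack of rest breaks during shifts",
    "Separation or isolation from family",
    "Stigmatisation as a potential infection source",
    "Childcare or caregiving difficulties",
    "Job or income insecurity",
    "Witnessing severe suffering of patients"
  )
  if (is.null(labels)) {
    labels <- stats::setNames(default_labels, items)
  } else {
    if (length(labels) != 17L) stop("labels must have length 17", call. = FALSE)
    if (is.null(names(labels))) names(labels) <- items
  }
  if (is.null(availability)) {
    availability <- list(`1` = items, `2` = items, `3` = items)
  }
  if (!all(names(availability) %in% c("1", "2", "3"))) {
    stop("availability wave indices must be in {1, 2, 3}", call. = FALSE)
  }
  for (w in names(availability)) {
    sub <- availability[[w]]
    if (length(sub) == 0L) {
      stop("availability subset for wave ", w, " is empty", call. = FALSE)
    }
    if (!all(sub %in% items)) {
      stop("availability for wave ", w, " names items outside the 17-item bank",
           call. = FALSE)
    }
  }
  structure(
    list(items = items, labels = labels, availability = availability),
    class = "stressor_bank"
  )
}

#' Items administered at a wave
#'
#' @param bank A [stressor_bank()].
#' @param wave Wave index (1, 2 or 3).
#' @return Character vector of administered item ids.
#' @export
administered_items <- function(bank, wave) {
  stopifnot(inherits(bank, "stressor_bank"))
  key <- as.character(as.integer(wave))
  sub <- bank$availability[[key]]
  if (is.null(sub)) stop("wave ", wave, " not present in bank availability", call. = FALSE)
  sub
}

#' @export
print.stressor_bank <- function(x, ...) {
  cat("Stressor item bank: 17 items\n")
  for (w in names(x$availability)) {
    cat(sprintf("  wave %s: %d items administered\n", w, length(x$availability[[w]])))
  }
  invisible(x)
}
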