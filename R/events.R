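# Closed vocabulary for event histories.  The biogeographic and
# cophylogenetic readings of the same process are kept as paired labels
# where the analogy applies.
event_types <- c(
  "vicariance/cospeciation",
  "dispersal/host-switch",
  "duplication",
  "extinction/loss",
  "sharing",
  "cospeciation",
  "host-switch",
  "lineage-loss"
)

#' Create an event history
#'
#' An event history is a typed log of cladogenetic and anagenetic events:
#' vicariance/cospeciation and duplication anchor at internal nodes;
#' dispersal/host-switch and extinction/loss anchor along branches (the
#' anchor is the child node of the branch).
#'
#' @param type Character vector of event types (closed vocabulary:
#'   `vicariance/cospeciation`, `dispersal/host-switch`, `duplication`,
#'   `extinction/loss`, `sharing`, and the cophylogenetic aliases
#'   `cospeciation`, `host-switch`, `lineage-loss`).
#' @param node Integer vector: the anchoring node (parent node for
#'   cladogenetic events, child end of the branch for anagenetic ones).
#' @param child_left,child_right Integer: child nodes for cladogenetic
#'   events (`NA` for anagenetic events).
#' @param gained,lost Character: area/host gained or lost (`NA` when not
#'   applicable).
#' @param age Numeric: event age in Ma (for branch events, the upper end
#'   of the age interval when the exact time is not resolved).
#' @return A data frame of class `event_history`.
#' @export
event_history <- function(type = character(), node = integer(),
                          child_left = NA_integer_, child_right = NA_integer_,
                          gained = NA_character_, lost = NA_character_,
                          age = NA_real_) {
  n <- length(type)
  fill <- function(x, proto) {
    if (length(x) == n) x else rep(proto(x), length.out = max(n, 0))
  }
  h <- data.frame(type = as.character(type),
                  node = fill(node, as.integer),
                  child_left = fill(child_left, as.integer),
                  child_right = fill(child_right, as.integer),
                  gained = fill(gained, as.character),
                  lost = fill(lost, as.character),
                  age = fill(age, as.numeric), stringsAsFactors = FALSE)
  validate_event_history(h)
}

validate_event_history <- function(history) {
  stopifnot(is.data.frame(history))
  required <- c("type", "node", "child_left", "child_right",
                "gained", "lost", "age")
  missing_cols <- setdiff(required, names(history))
  if (length(missing_cols)) {
    stop("event history is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- !history$type %in% event_types
  if (any(bad)) {
    stop("unknown event type(s): ",
         paste(unique(history$type[bad]), collapse = ", "), call. = FALSE)
  }
  history <- history[, required]
  class(history) <- c("event_history", "data.frame")
  history
}

#' Write / read an event history as TSV
#'
#' One row per event with columns type, node, child_left, child_right,
#' gained, lost, age (Ma).  A `#`-prefixed header line records the
#' producing package version and seed.  `read_events()` round-trips
#' exactly what `write_events()` wrote.
#'
#' @param history An `event_history` (see [event_history()]).
#' @param path Output (input) file path.
#' @param seed Optional seed recorded in the file header.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns an `event_history`.
#' @export
write_events <- function(history, path, seed = NULL) {
  history <- validate_event_history(history)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(artifact_header(seed), con)
  utils::write.table(history, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         fileEncoding = "UTF-8",
                         colClasses = c(type = "character",
                                        node = "integer",
                                        child_left = "integer",
                                        child_right = "integer",
                                        gained = "character",
                                        lost = "character",
                                        age = "numeric"))
  validate_event_history(h)
}

artifact_header <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("decophy"))
  if (is.null(seed)) {
    sprintf("# decophy %s", ver)
  } else {
    sprintf("# decophy %s seed=%s", ver, format(seed))
  }
}
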