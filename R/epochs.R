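#' Time-stratified dispersal configuration
#'
#' A DEC analysis may divide time into epochs with different dispersal
#' multiplier matrices, e.g. elevated dispersal among palaeolake areas
#' during the Pleistocene.  Epoch `k` spans ages `[boundaries[k],
#' boundaries[k-1])` with `boundaries[0] = Inf`; boundaries are lower
#' epoch edges in Ma, strictly decreasing and ending at 0.
#'
#' @param boundaries Numeric vector of lower epoch edges in Ma,
#'   strictly decreasing, last element 0.  A single epoch is
#'   `boundaries = 0`.
#' @param multipliers List of N x N non-negative matrices, one per epoch
#'   (oldest first), scaling the dispersal rate per source-target area
#'   pair.  Default: unit multipliers.
#' @param n_areas Number of areas (used to build default multipliers).
#' @return An object of class `epoch_config`.
#' @examples
#' # one uniform epoch over 4 areas
#' epoch_config(0, n_areas = 4)
#' @export
epoch_config <- function(boundaries = 0, multipliers = NULL, n_areas = NULL) {
  boundaries <- as.numeric(boundaries)
  k <- length(boundaries)
  if (k < 1 || utils::tail(boundaries, 1) != 0) {
    stop("epoch boundaries must end at 0", call. = FALSE)
  }
  if (k > 1 && any(diff(boundaries) >= 0)) {
    stop("epoch boundaries must be strictly decreasing", call. = FALSE)
  }
  if (is.null(multipliers)) {
    if (is.null(n_areas)) {
      stop("supply multipliers or n_areas", call. = FALSE)
    }
    multipliers <- replicate(k, matrix(1, n_areas, n_areas),
                             simplify = FALSE)
  }
  if (!is.list(multipliers)) multipliers <- list(multipliers)
  if (length(multipliers) != k) {
    stop("need one multiplier matrix per epoch", call. = FALSE)
  }
  n <- nrow(multipliers[[1]])
  for (m in multipliers) {
    m <- as.matrix(m)
    if (!all(dim(m) == n)) {
      stop("multiplier matrices must share dimensions", call. = FALSE)
    }
    if (any(m < 0)) stop("multipliers must be >= 0", call. = FALSE)
  }
  structure(list(boundaries = boundaries,
                 multipliers = lapply(multipliers, as.matrix),
                 n_epochs = k),
            class = "epoch_config")
}

#' Read an epoch configuration from a YAML file
#'
#' Expected fields: `areas` (labels), `max_range_size`, `adjacency`
#' (list of rows, optional), `epoch_boundaries` (Ma, descending, ending
#' at 0), `multipliers` (list of matrices as lists of rows, one per
#' epoch, optional).
#'
#' @param path YAML file path.
#' @return List with `areas`, `max_range_size`, `adjacency`, and an
#'   `epoch_config`.
#' @export
read_epoch_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$areas)) stop("config must list areas", call. = FALSE)
  n <- length(cfg$areas)
  adjacency <- if (is.null(cfg$adjacency)) {
    matrix(1, n, n)
  } else {
    do.call(rbind, cfg$adjacency)
  }
  boundaries <- if (is.null(cfg$epoch_boundaries)) 0 else cfg$epoch_boundaries
  multipliers <- if (is.null(cfg$multipliers)) {
    NULL
  } else {
    lapply(cfg$multipliers, function(m) do.call(rbind, m))
  }
  list(
    areas = as.character(cfg$areas),
    max_range_size = if (is.null(cfg$max_range_size)) 2L
                     else as.integer(cfg$max_range_size),
    adjacency = adjacency,
    epochs = epoch_config(boundaries, multipliers, n_areas = n)
  )
}

# epoch index for an age (epoch k spans [boundaries[k], boundaries[k-1]))
epoch_of_age <- function(epochs, age) {
  k <- which(epochs$boundaries <= age)[1]
  if (is.na(k)) epochs$n_epochs else k
}

# split a branch spanning ages [age_child, age_parent] into epoch
# segments, oldest first: data.frame(epoch, dt)
epoch_segments <- function(epochs, age_parent, age_child) {
  b <- epochs$boundaries
  cuts <- b[b < age_parent & b > age_child]
  pts <- c(age_parent, cuts, age_child)
  k <- vapply(pts[-length(pts)], function(a) {
    # epoch containing the segment just below age a
    which(b < a)[1]
  }, integer(1))
  k[is.na(k)] <- epochs$n_epochs  # segment within the youngest epoch
  data.frame(epoch = k, dt = -diff(pts))
}

#' DEC model parameters
#'
#' @param d Dispersal (range-expansion) rate per source-target area pair
#'   per Ma, scaled by the epoch multiplier for that pair.
#' @param e Extinction (range-contraction) rate per occupied area per Ma.
#' @param epochs An [epoch_config()]; default a single epoch with unit
#'   multipliers (requires `n_areas`).
#' @param n_areas Number of areas, used only to build default epochs.
#' @return Object of class `dec_params`.
#' @export
dec_params <- function(d, e, epochs = NULL, n_areas = NULL) {
  if (!is.finite(d) || !is.finite(e) || d < 0 || e < 0) {
    stop("rates d and e must be finite and >= 0", call. = FALSE)
  }
  if (is.null(epochs)) {
    if (is.null(n_areas)) stop("supply epochs or n_areas", call. = FALSE)
    epochs <- epoch_config(0, n_areas = n_areas)
  }
  structure(list(d = d, e = e, epochs = epochs), class = "dec_params")
}
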