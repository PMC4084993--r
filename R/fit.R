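#' Maximum-likelihood estimation of DEC dispersal and extinction rates
#'
#' Maximises [tree_likelihood()] over `(d, e)` inside the box
#' `[lower, upper]^2` with a derivative-free Nelder-Mead search on the
#' log-rate scale, restarted from a fixed grid of starting points
#' (optionally jittered under `seed`).  The reported optimum is the best
#' across starts.
#'
#' @inheritParams tree_likelihood
#' @param epochs Optional [epoch_config()]; default one uniform epoch.
#' @param n_starts Number of multistarts (default 5).
#' @param lower,upper Box bounds for both rates (default `1e-9` and 10).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param seed Optional integer; jitters the start grid reproducibly.
#' @return An object of class `dec_fit`: list with `d`, `e`, `loglik`,
#'   `converged` (logical), `starts` (per-start data frame), and the
#'   inputs needed to resume (`space`, `epochs`).
#' @examples
#' \donttest{
#' tr <- read_newick("((t1:1,t2:1):1,t3:2);")
#' sp <- build_state_space(c("A", "B"), 2)
#' fit_dec(tr, c(t1 = "A", t2 = "B", t3 = "A"), sp)
#' }
#' @export
fit_dec <- function(tree, tip_ranges, space, epochs = NULL,
                    n_starts = 5, lower = 1e-9, upper = 10,
                    reltol = 1e-8, seed = NULL) {
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips", call. = FALSE)
  ctx <- prepare_likelihood(tree, tip_ranges, space, epochs)
  clamp <- function(x) pmin(pmax(exp(x), lower), upper)
  negll <- function(theta) {
    p <- clamp(theta)
    ll <- prune_loglik(ctx, p[1], p[2])$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  base_grid <- log(rbind(
    c(0.01, 0.01),
    c(0.10, 0.01),
    c(0.01, 0.10),
    c(1.00, 0.10),
    c(0.10, 1.00)
  ))
  if (n_starts > nrow(base_grid)) {
    extra <- n_starts - nrow(base_grid)
    base_grid <- rbind(base_grid,
                       matrix(log(0.05), extra, 2) +
                         matrix(seq_len(extra), extra, 2))
  }
  starts <- base_grid[seq_len(n_starts), , drop = FALSE]
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    starts <- starts + matrix(stats::runif(2 * n_starts, -0.5, 0.5),
                              n_starts, 2)
  }
  res <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    res[[i]] <- stats::optim(starts[i, ], negll, method = "Nelder-Mead",
                             control = list(reltol = reltol, maxit = 1000))
  }
  values <- vapply(res, function(r) r$value, numeric(1))
  best <- which.min(values)
  conv <- vapply(res, function(r) r$convergence == 0, logical(1))
  if (!any(conv)) {
    warning("optimizer did not converge from any start; ",
            "returning best point found", call. = FALSE)
  }
  par <- clamp(res[[best]]$par)
  start_tab <- data.frame(
    start_d = clamp(starts[, 1]),
    start_e = clamp(starts[, 2]),
    d = vapply(res, function(r) clamp(r$par)[1], numeric(1)),
    e = vapply(res, function(r) clamp(r$par)[2], numeric(1)),
    loglik = -values,
    converged = conv
  )
  structure(
    list(d = par[1], e = par[2], loglik = -values[best],
         converged = any(conv), starts = start_tab,
         space = space, epochs = ctx$epochs),
    class = "dec_fit"
  )
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC maximum-likelihood fit\n  d = %.6g  e = %.6g  logL = %.6f%s\n",
              x$d, x$e, x$loglik,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}
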