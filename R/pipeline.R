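#' Run the simulate -> fit -> ancestors -> combine -> events -> congruence
#' pipeline
#'
#' Wires the package's stages end to end on simulated data: simulates a
#' Yule host tree and a codiversification history, encodes the surviving
#' associations, fits the DEC model to a forward-simulated range history
#' on the parasite tree under two maximum range sizes, combines the two
#' ancestral reconstructions, translates the consensus into
#' cophylogenetic events, and tests host-parasite congruence.  Every
#' stage writes its artifact with a stable filename and a header naming
#' the package version and seed; the same seed yields byte-identical
#' outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (mandatory; drives every stochastic stage).
#' @param n_hosts Number of host tips to simulate.
#' @param lambda Host speciation rate per Ma.
#' @param p_c,lambda_s,lambda_d,mu Codiversification parameters, see
#'   [simulate_cophylo()].
#' @param areas Area labels for the range-history stage.
#' @param d,e True DEC rates for the forward range simulation.
#' @param max_range_sizes Two (or more) maximum range sizes defining the
#'   model runs to combine.
#' @param accept_threshold,moderate_threshold Consensus thresholds
#'   (defaults 0.7 and 0.5).
#' @param n_perm Permutations for the congruence test.
#' @return Invisibly, a list with the in-memory stage results and
#'   `files`, the artifact paths written.
#' @export
run_pipeline <- function(out_dir, seed,
                         n_hosts = 12, lambda = 1,
                         p_c = 0.8, lambda_s = 0.2, lambda_d = 0.1,
                         mu = 0.05,
                         areas = c("A", "B", "C", "D"),
                         d = 0.1, e = 0.03,
                         max_range_sizes = c(2, 3),
                         accept_threshold = 0.7,
                         moderate_threshold = 0.5,
                         n_perm = 499) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required", call. = FALSE)
  }
  if (accept_threshold <= 0 || accept_threshold > 1 ||
      moderate_threshold <= 0 || moderate_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(name) {
    files[[name]] <<- file.path(out_dir, name)
    files[[name]]
  }
  write_tsv <- function(df, path, seed) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(artifact_header(seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }

  # stage 1: codiversification simulation (retry seeds derived from the
  # master seed until at least 3 parasites survive)
  sim <- NULL
  for (k in 0:20) {
    cand <- simulate_cophylo(
      simulate_host_tree(lambda, n_hosts, seed = seed + k),
      p_c = p_c, lambda_s = lambda_s, lambda_d = lambda_d, mu = mu)
    if (!is.null(cand$parasite) && cand$n_parasites >= 3) {
      sim <- cand
      break
    }
  }
  if (is.null(sim)) {
    stop("no simulation with >= 3 surviving parasites in 21 attempts; ",
         "lower the loss rate", call. = FALSE)
  }
  write_newick(sim$host, put("host_tree.nwk"))
  write_newick(sim$parasite, put("parasite_tree.nwk"))
  write_tsv(data.frame(parasite_tip = names(sim$association),
                       host_tip = unname(sim$association)),
            put("associations.tsv"), seed)
  write_events(sim$events, put("true_events.tsv"), seed = seed)

  # stage 2: forward DEC history on the parasite tree + ML refit
  space_sim <- build_state_space(areas, max_range_size = 2)
  params_true <- dec_params(d, e, n_areas = length(areas))
  hist <- simulate_dec_history(sim$parasite, space_sim, params_true,
                               root_range = areas[1], seed = seed)
  keep <- names(hist$tip_ranges)[!hist$extinct]
  tree_fit <- sim$parasite
  if (length(keep) < ape::Ntip(sim$parasite)) {
    tree_fit <- ape::drop.tip(sim$parasite,
                              setdiff(sim$parasite$tip.label, keep))
  }
  if (is.null(tree_fit) || ape::Ntip(tree_fit) < 2) {
    stop("range history left fewer than 2 extant tips", call. = FALSE)
  }
  tip_ranges <- hist$tip_ranges[tree_fit$tip.label]
  write_tsv(data.frame(tip = names(tip_ranges),
                       range = vapply(tip_ranges, paste, character(1),
                                      collapse = ",")),
            put("tip_ranges.tsv"), seed)
  fit <- fit_dec(tree_fit, tip_ranges, space_sim, seed = seed)

  # stage 3: ancestral scenarios under each model run, then consensus
  runs <- lapply(max_range_sizes, function(mrs) {
    sp <- build_state_space(areas, max_range_size = mrs)
    f <- fit_dec(tree_fit, tip_ranges, sp, seed = seed)
    ancestral_scenarios(tree_fit, tip_ranges, sp,
                        dec_params(f$d, f$e, n_areas = length(areas)))
  })
  write_tsv(as.data.frame(runs[[1]]), put("scenarios.tsv"), seed)
  comb <- combine_runs(runs, threshold = accept_threshold,
                       moderate_threshold = moderate_threshold)
  write_tsv(comb$areas, put("combined_areas.tsv"), seed)

  # stage 4: cophylogenetic reading of the top scenarios
  top <- do.call(rbind, lapply(split(as.data.frame(runs[[1]]),
                                     runs[[1]]$node),
                               function(b) b[1, ]))
  node_ev <- classify_node_events(top, ages = node_ages(tree_fit))
  branch_ev <- classify_branch_events(tree_fit, top, tip_ranges)
  write_events(rbind(node_ev, branch_ev), put("events.tsv"), seed = seed)

  # stage 5: congruence test
  cong <- permutation_congruence_test(sim$host, sim$parasite,
                                      sim$association,
                                      n_perm = n_perm, seed = seed)
  summary <- list(
    seed = seed,
    version = as.character(utils::packageVersion("decophy")),
    n_hosts = n_hosts, n_parasites = sim$n_parasites,
    dec_fit = list(d = fit$d, e = fit$e, loglik = fit$loglik),
    congruence = list(observed = cong$observed, p_value = cong$p_value,
                      null_ci = cong$null_ci)
  )
  jsonlite::write_json(summary, put("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(sim = sim, history = hist, fit = fit, runs = runs,
                 combined = comb, node_events = node_ev,
                 branch_events = branch_ev, congruence = cong,
                 files = files))
}
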