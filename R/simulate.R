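# Seeded Monte-Carlo simulation of the evolutionary random walk: in the full
# sequence space (any peak landscape, incremental distance bookkeeping) and in
# the projected 1-D chain. Every proposed point mutation counts as one event.

walk_result_tbl <- function(res) {
  tibble::tibble(hit = res$hit, steps = res$steps,
                 final_distance = res$final_distance)
}

land_fit_by_d <- function(land) {
  L <- land$space$L
  if (inherits(land, "multiplicative_peak")) {
    (1 + land$sigma)^(L - (0:L))
  } else {
    ifelse(0:L <= land$w, land$advantage, 1)
  }
}

#' Simulate evolutionary random walks in the full sequence space
#'
#' Iterates uniform point-mutation proposals from the start sequence(s);
#' each proposal is accepted with probability `min(1, N * rho)` where `rho` is
#' the Moran fixation probability at the proposal's fitness ratio (on a flat
#' landscape every proposal is accepted). Every proposal counts as one event.
#' A walk stops at target membership or when the step budget is exhausted
#' (censored). Under the default discovery convention, proposing a target
#' sequence ends the walk whether or not the mutant would have fixed.
#'
#' @param land A peak landscape ([broad_peak()], [multi_peak()] or
#'   [multiplicative_peak()]).
#' @param start Character vector of start sequences (recycled to `n_runs` if
#'   length 1).
#' @param budget Step budget per walk (> 0, or 0 for an immediate check).
#' @param n_runs Number of independent walks.
#' @param N Population size for the acceptance weighting.
#' @param discovery `"proposal"` or `"fixation"`; see [selection_chain()].
#' @param seed Optional integer; if given, [set.seed()] is called first.
#' @return Tibble with one row per run: `hit`, `steps`, `final_distance`
#'   (minimal Hamming distance to a center at termination). Censored runs
#'   have `steps == budget` and `hit == FALSE`.
#' @export
simulate_walk <- function(land, start, budget, n_runs = length(start), N = 1,
                          discovery = c("proposal", "fixation"), seed = NULL) {
  discovery <- match.arg(discovery)
  stopifnot(inherits(land, "pw_landscape"), budget >= 0, n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  space <- land$space
  if (length(start) == 1) start <- rep(start, n_runs)
  stopifnot(length(start) == n_runs)
  starts <- t(vapply(start, seq_encode, integer(space$L), space = space)) - 1L
  dim(starts) <- c(n_runs, space$L)
  centers <- t(vapply(land$centers, seq_encode, integer(space$L),
                      space = space)) - 1L
  dim(centers) <- c(length(land$centers), space$L)
  res <- walk_full_batch_cpp(starts, centers, space$A, land$w,
                             land_fit_by_d(land), N, budget,
                             discovery == "proposal")
  walk_result_tbl(res)
}

#' Simulate the projected distance chain directly
#'
#' Samples the 1-D birth-death chain; for a broad-peak landscape this is
#' distributionally identical to [simulate_walk()] by permutation symmetry,
#' and far cheaper.
#'
#' @param chain A [bd_chain()].
#' @param start Starting distance state (scalar or one per run).
#' @param budget Step budget per walk.
#' @param n_runs Number of independent walks.
#' @param seed Optional integer seed.
#' @return Tibble as in [simulate_walk()]; `final_distance` is the chain state.
#' @export
simulate_projected <- function(chain, start, budget, n_runs = 1, seed = NULL) {
  stopifnot(inherits(chain, "bd_chain"), budget >= 0, n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(start >= 0), all(start <= chain_L(chain)))
  res <- chain_sim_batch_cpp(chain$p_down, chain$p_stay, chain$p_up,
                             chain_w(chain), as.integer(start),
                             budget, as.integer(n_runs))
  walk_result_tbl(res)
}

#' Summarize a batch of walks
#'
#' Success probability within the budget, and mean/standard error of the
#' hitting time among successful runs.
#'
#' @param runs A tibble from [simulate_walk()] or [simulate_projected()].
#' @param seed The master seed used (recorded, not applied).
#' @return One-row tibble: `n_runs`, `n_hits`, `success_prob`, `mean_steps`,
#'   `se_steps`, `seed`.
#' @export
summarize_walks <- function(runs, seed = NA_integer_) {
  hits <- runs$steps[runs$hit]
  tibble::tibble(
    n_runs = nrow(runs),
    n_hits = length(hits),
    success_prob = length(hits) / nrow(runs),
    mean_steps = if (length(hits)) mean(hits) else NA_real_,
    se_steps = if (length(hits) > 1) stats::sd(hits) / sqrt(length(hits))
               else NA_real_,
    seed = seed
  )
}

#' Run a seeded batch experiment on a landscape
#'
#' Convenience wrapper: seeds the RNG, simulates `n_runs` independent walks,
#' and returns the summary (the per-run table is attached as
#' `attr(, "runs")`).
#'
#' @inheritParams simulate_walk
#' @param seed Master seed for the whole batch.
#' @return One-row summary tibble as in [summarize_walks()].
#' @export
batch_walks <- function(land, start, budget, n_runs, N = 1, seed = 1L,
                        discovery = c("proposal", "fixation")) {
  discovery <- match.arg(discovery)
  runs <- simulate_walk(land, start, budget, n_runs = n_runs, N = N,
                        discovery = discovery, seed = seed)
  out <- summarize_walks(runs, seed = seed)
  attr(out, "runs") <- runs
  out
}
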