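# The three headline experiments: parallel independent searches, uniformly
# random multi-peak discovery, and the regeneration process that breaks the
# exponential barrier.

#' Ensemble success probability of independent searches
#'
#' The probability that at least one of `t` independent searches succeeds,
#' given per-search success probability `p`: since the searches are
#' independent, the probability that all fail is the product of the
#' per-search failure probabilities, so the ensemble success is
#' `1 - (1 - p)^t`. Computed stably for tiny `p` (log1p/expm1), where the
#' value is approximately `t * p`.
#'
#' @param p Per-search success probability (vectorized).
#' @param t Number of independent searches (>= 1).
#' @return Ensemble success probability.
#' @examples
#' parallel_success(0.5, 2)      # 0.75
#' parallel_success(1e-12, 1e6)  # ~1e-6
#' @export
parallel_success <- function(p, t) {
  stopifnot(all(p >= 0), all(p <= 1), all(t >= 1))
  -expm1(t * log1p(-p))
}

#' Parallel-search experiment
#'
#' Demonstrates the product law numerically: for each ensemble size `t`,
#' simulates `n_meta` replicates of `t` independent budgeted walks on the
#' projected chain and compares the empirical ensemble success frequency
#' against the exact `1 - (1 - p)^t`, with `p = success_within(chain, start,
#' T_budget)` computed by dynamic programming. The moral: when a single
#' search's discovery time is exponential in `L`, `p` is exponentially small
#' and polynomially many parallel searches still fail — the ensemble success
#' is at most `t * p`.
#'
#' @param chain A [bd_chain()].
#' @param start Start state.
#' @param t_values Ensemble sizes to test.
#' @param T_budget Per-search step budget.
#' @param n_meta Replicates per ensemble size.
#' @param seed Master seed.
#' @return Tibble with one row per `t`: `t`, `p_single` (exact), `exact`
#'   (product law), `empirical`, `n_meta`, and the 99% binomial CI of the
#'   empirical frequency.
#' @export
parallel_experiment <- function(chain, start, t_values, T_budget,
                                n_meta = 2000, seed = 1L) {
  stopifnot(all(t_values >= 1), n_meta >= 1)
  set.seed(seed)
  p_single <- success_within(chain, start, T_budget)
  purrr::map_dfr(sort(t_values), function(t) {
    runs <- simulate_projected(chain, start, T_budget, n_runs = t * n_meta)
    ens <- matrix(runs$hit, nrow = t)
    emp <- mean(colSums(ens) > 0)
    exact <- parallel_success(p_single, t)
    ci <- stats::qnorm(0.995) * sqrt(exact * (1 - exact) / n_meta)
    tibble::tibble(t = t, p_single = p_single, exact = exact,
                   empirical = emp, n_meta = n_meta,
                   ci_lo = pmax(0, exact - ci), ci_hi = pmin(1, exact + ci))
  })
}

#' Probability of reaching one boundary before another
#'
#' Gambler's-ruin primitive for a birth-death chain: the probability that a
#' walk started at `start` reaches state `low` before state `high`, by the
#' standard ratio-product closed form (evaluated in log space). Self-loops do
#' not affect the answer.
#'
#' @param chain A [bd_chain()].
#' @param start Start state, `low < start < high` (endpoints return 1 / 0).
#' @param low,high Absorbing boundary states.
#' @return Probability of hitting `low` first.
#' @export
absorption_before <- function(chain, start, low, high) {
  L <- chain_L(chain)
  stopifnot(low >= 0, high <= L, low < high, start >= low, start <= high)
  if (start == low) return(1)
  if (start == high) return(0)
  ks <- (low + 1):(high - 1)
  pd <- chain$p_down[ks + 1]
  pu <- chain$p_up[ks + 1]
  if (any(pd <= 0) || any(pu <= 0))
    stop("interior states must have positive up and down probabilities")
  # log of prod_{i=low+1}^{j} (p_down_i / p_up_i), j = low..high-1
  lr <- c(0, cumsum(log(pd) - log(pu)))
  m <- max(lr)
  num <- sum(exp(lr[(start - low + 1):length(lr)] - m))
  den <- sum(exp(lr - m))
  num / den
}

#' Exact stationary-mass discovery-time estimate for random targets
#'
#' Under neutrality the walk mixes fast (order `L log L` events) and its
#' stationary distribution is uniform over the `A^L` sequences, so once mixed,
#' epochs behave like uniform draws; with `m` uniformly placed peaks of radius
#' `w`, the expected number of epochs until a draw lands in the target is the
#' inverse stationary target mass, `A^L / (m * ball_volume(L, w, A))`. The
#' mixing-time polynomial factor is reported as an annotation, not folded in.
#'
#' @param L Sequence length.
#' @param A Alphabet size.
#' @param m Number of target centers.
#' @param w Peak radius.
#' @return Object of class `stationary_estimate`: exact big-integer
#'   `numerator` (`A^L`) and `denominator` (`m * ball`), double `value`,
#'   `log_value`, the mixing annotation and a `degenerate` flag (target
#'   covers the whole space).
#' @export
stationary_time_estimate <- function(L, A = 4, m = 1, w = 0) {
  stopifnot(L >= 1, A >= 2, m >= 1, w >= 0, w <= L)
  num <- bi_pow_small(A, L)
  ball <- ball_volume(L, w, A)
  den <- bi_mul_small(ball, m)
  degenerate <- bi_cmp(den, num) >= 0
  log_value <- L * log(A) - log(m) - ball_volume_log(L, w, A)
  structure(list(numerator = num, denominator = den,
                 value = exp(log_value), log_value = log_value,
                 degenerate = degenerate,
                 mixing_note = sprintf(
                   "multiply by the O(L log L) ~ %.0f-event mixing time per epoch",
                   L * log(L))),
            class = "stationary_estimate")
}

#' @export
print.stationary_estimate <- function(x, ...) {
  cat("<stationary-mass estimate> ", format(x$numerator), " / ",
      format(x$denominator), " ~ ", signif(x$value, 6),
      if (x$degenerate) "  [degenerate: target covers the space]", "\n",
      sep = "")
  cat("  ", x$mixing_note, "\n", sep = "")
  invisible(x)
}

#' @export
as.double.stationary_estimate <- function(x, ...) x$value

#' Uniformly random multi-peak discovery experiment
#'
#' Samples `m` target centers uniformly at random, draws start sequences
#' uniformly among non-target sequences (by rejection; the experiment refuses
#' degenerate regimes where targets cover more than half the space), runs
#' `n_runs` independent budgeted walks in the full sequence space, and
#' compares the mean discovery time against the stationary-mass estimate
#' `A^L / (m * ball_volume)`.
#'
#' @param L Sequence length.
#' @param A Alphabet size.
#' @param m Number of peaks.
#' @param w Peak radius.
#' @param budget Step budget per walk.
#' @param n_runs Number of walks.
#' @param seed Master seed.
#' @return One-row tibble: `L`, `A`, `m`, `w`, `n_runs`, `success_prob`,
#'   `mean_steps`, `se_steps`, `stationary_estimate`, `ratio` (mean over
#'   estimate). Per-run results in `attr(, "runs")`.
#' @export
multi_target_experiment <- function(L, A = 4, m, w, budget, n_runs = 200,
                                    seed = 1L) {
  stopifnot(m >= 1, n_runs >= 1, budget > 0)
  set.seed(seed)
  est <- stationary_time_estimate(L, A, m, w)
  # refuse when targets cover too much of the space for rejection sampling
  frac <- exp(log(m) + ball_volume_log(L, w, A) - L * log(A))
  if (frac > 0.5)
    stop("degenerate regime: targets cover ", signif(100 * frac, 3),
         "% of the space")
  space <- seq_space(L, A)
  centers <- random_sequence(space, m)
  land <- multi_peak(space, centers, w)
  starts <- character(n_runs)
  filled <- 0L
  while (filled < n_runs) {
    cand <- random_sequence(space, n_runs - filled)
    keep <- cand[!is_target(land, cand)]
    if (length(keep)) {
      starts[(filled + 1):(filled + length(keep))] <- keep
      filled <- filled + length(keep)
    }
  }
  runs <- simulate_walk(land, starts, budget, n_runs = n_runs)
  s <- summarize_walks(runs, seed = seed)
  out <- tibble::tibble(L = L, A = A, m = m, w = w,
                        n_runs = n_runs,
                        success_prob = s$success_prob,
                        mean_steps = s$mean_steps,
                        se_steps = s$se_steps,
                        stationary_estimate = est$value,
                        ratio = s$mean_steps / est$value)
  attr(out, "runs") <- runs
  out
}

#' Regeneration-process experiment
#'
#' The mechanism that breaks the exponential barrier: some process (gene
#' duplication, genome rearrangement) repeatedly generates fresh starting
#' sequences a *constant* number `k0` of mutations from the target — constant
#' meaning independent of `L`. Each attempt is a budgeted neutral walk from
#' distance `k0`; most attempts drift away and fail, but the per-attempt
#' success probability within a polynomial budget decays only polynomially in
#' `L` (roughly like `L^-k0`), so polynomially many regenerated attempts find
#' the target with high probability — even though the expected time of any
#' single search from a random start is exponential in `L`.
#'
#' Attempts are simulated on the projected chain (exact for a centered ball
#' target); the exact per-attempt probability is also computed by dynamic
#' programming and used for the meta-replicate ensemble stage, where
#' `ceiling(3 / p_hat)` searches per replicate give expected ensemble success
#' `>= 1 - exp(-3) ~ 0.95`.
#'
#' @param L_grid Sequence lengths to scan (>= 2 values for the slope fit).
#' @param A Alphabet size.
#' @param k0 Start distance from the target center (constant across `L`).
#' @param w Target radius (default 0, the hardest case).
#' @param budget_fun Function of `L` giving the per-attempt step budget;
#'   default `20 * L^2` (polynomial in `L`).
#' @param n_attempts Simulated attempts per `L`.
#' @param n_meta Meta-replicates for the ensemble-success stage.
#' @param seed Master seed.
#' @return Object of class `regeneration_report`: `data` (per-`L` tibble with
#'   `p_hat`, `p_exact`, `n_star = ceiling(3 / p_hat)`, `ensemble_success`
#'   frequency over meta-replicates), `slope` of `log p_hat ~ log L`, and the
#'   underlying `lm` fit.
#' @export
regeneration_experiment <- function(L_grid, A = 4, k0 = 2, w = 0,
                                    budget_fun = function(L) 20 * L^2,
                                    n_attempts = 1e4, n_meta = 100,
                                    seed = 1L) {
  stopifnot(k0 >= 0, all(L_grid >= 1), n_attempts >= 1)
  if (any(k0 + w >= L_grid)) stop("require k0 + w < L for every L in the grid")
  set.seed(seed)
  rows <- purrr::map_dfr(sort(L_grid), function(L) {
    if (k0 == 0) {
      return(tibble::tibble(L = L, budget = 0, p_hat = 1, p_exact = 1,
                            n_star = 1, ensemble_success = 1))
    }
    ch <- neutral_chain(L, A, w)
    Tb <- budget_fun(L)
    start <- w + k0
    runs <- simulate_projected(ch, start, Tb, n_runs = n_attempts)
    p_hat <- mean(runs$hit)
    p_exact <- success_within(ch, start, Tb)
    n_star <- if (p_hat > 0) ceiling(3 / p_hat) else NA_integer_
    ens <- if (!is.na(n_star))
      mean(stats::rbinom(n_meta, n_star, p_exact) > 0) else NA_real_
    tibble::tibble(L = L, budget = Tb, p_hat = p_hat, p_exact = p_exact,
                   n_star = n_star, ensemble_success = ens)
  })
  fit <- if (nrow(rows) >= 2 && all(rows$p_hat > 0) && k0 > 0)
    stats::lm(log(p_hat) ~ log(L), data = rows) else NULL
  slope <- if (!is.null(fit)) unname(stats::coef(fit)[2]) else NA_real_
  structure(list(data = rows, k0 = k0, w = w, A = A, slope = slope,
                 fit = fit, n_attempts = n_attempts, seed = seed),
            class = "regeneration_report")
}

#' @export
print.regeneration_report <- function(x, ...) {
  cat("<regeneration report> k0 = ", x$k0, ", w = ", x$w,
      ", attempts per L = ", x$n_attempts, "\n", sep = "")
  print(x$data)
  cat("slope of log p_hat ~ log L: ", signif(x$slope, 4),
      "  (polynomial decay ~ L^slope)\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy regeneration_report
tidy.regeneration_report <- function(x, ...) x$data

#' @export
#' @method glance regeneration_report
glance.regeneration_report <- function(x, ...) {
  tibble::tibble(k0 = x$k0, w = x$w, A = x$A, slope = x$slope,
                 n_attempts = x$n_attempts,
                 min_ensemble_success = min(x$data$ensemble_success))
}

#' @export
#' @method autoplot regeneration_report
autoplot.regeneration_report <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = log(.data$L),
                                            y = log(.data$p_hat))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log L", y = "log per-attempt success",
                  title = sprintf("Regeneration process, k0 = %d (slope %.2f)",
                                  object$k0, object$slope)) +
    ggplot2::theme_minimal()
}
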