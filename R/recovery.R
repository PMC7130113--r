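#' Simulation-based parameter recovery for the PSS/JND estimator
#'
#' Quantifies how well the probit pipeline recovers known generative
#' parameters under the experiment's own design. For every condition in the
#' grid, `n_sims` observers are simulated over the standard schedule (or one
#' with `reps_per_soa` repetitions of each SOA per posture), the full fit is
#' run per posture, and bias and RMSE of the PSS and of the JND magnitude
#' are reported against their generative values (`pss_true` and
#' `0.675 * sigma`, scaled by the crossed factor for the crossed posture).
#'
#' @param pss_grid Numeric vector of true PSS values to simulate.
#' @param sigma True psychometric spread in ms.
#' @param crossed_sigma_factor Crossed-posture spread multiplier.
#' @param lapse Lapse rate of the simulated observers.
#' @param reps_per_soa Repetitions of each SOA per posture (default 12, the
#'   standard design: 2 blocks x 6 repetitions).
#' @param n_sims Simulated subjects per condition.
#' @param seed Master seed; subject streams derive from it.
#' @param posture Which posture's estimates to score (default uncrossed).
#' @return Data frame of class `toj_recovery` with one row per condition:
#'   `pss_true`, `sigma`, `n_sims`, `reps_per_soa`, `pss_mean_est`,
#'   `pss_bias`, `pss_rmse`, `pss_mc_se`, `jnd_true`, `jnd_mean_est`,
#'   `jnd_bias`, `jnd_rmse`.
#' @export
#' @examples
#' recovery_experiment(pss_grid = c(0, 50), n_sims = 20, seed = 1)
recovery_experiment <- function(pss_grid = c(-50, 0, 50), sigma = 100,
                                crossed_sigma_factor = 1, lapse = 0,
                                reps_per_soa = 12L, n_sims = 100L, seed = 1L,
                                posture = c("uncrossed", "crossed")) {
  posture <- match.arg(posture)
  if (n_sims < 1L) stop("`n_sims` must be >= 1", call. = FALSE)
  soas <- soa_levels()
  sigma_p <- sigma * if (posture == "crossed") crossed_sigma_factor else 1
  jnd_true <- 0.675 * sigma_p

  rows <- lapply(seq_along(pss_grid), function(ci) {
    pss_true <- pss_grid[ci]
    obs <- observer(pss_true, sigma, max(1, crossed_sigma_factor), lapse,
                    affected_side = "left")
    u_all <- rep(soas, each = reps_per_soa)   # affected side left: u = soa
    p_aff <- response_probability(obs, u_all, posture)
    pss_est <- numeric(n_sims)
    jnd_est <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      aff_first <- with_local_seed(seed + (ci - 1L) * n_sims + s,
                                   stats::runif(length(u_all)) < p_aff)
      k <- tapply(as.integer(aff_first), u_all, sum)
      tab <- data.frame(posture = posture, u = as.numeric(names(k)),
                        n_trials = reps_per_soa, n_affected_first = as.vector(k),
                        stringsAsFactors = FALSE)
      tab$p <- tab$n_affected_first / tab$n_trials
      tab <- probit_transform(tab, "half_count")
      fit <- fit_probit_line(tab)
      pss_est[s] <- compute_pss(fit)
      jnd_est[s] <- compute_jnd(fit)$jnd_magnitude
    }
    data.frame(
      pss_true = pss_true, sigma = sigma, n_sims = n_sims,
      reps_per_soa = reps_per_soa,
      pss_mean_est = mean(pss_est),
      pss_bias = mean(pss_est) - pss_true,
      pss_rmse = sqrt(mean((pss_est - pss_true)^2)),
      pss_mc_se = stats::sd(pss_est) / sqrt(n_sims),
      jnd_true = jnd_true,
      jnd_mean_est = mean(jnd_est),
      jnd_bias = mean(jnd_est) - jnd_true,
      jnd_rmse = sqrt(mean((jnd_est - jnd_true)^2)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("toj_recovery", "data.frame")
  out
}
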