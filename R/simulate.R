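#' Simulation scenario
#'
#' Parameters of the tiered benchmark: `p_per_visit` biomarkers measured
#' at `n_visits` visits plus one binary outcome at the final tier,
#' `n_obs` subjects, within-biomarker autoregressive noise correlation
#' `rho` (the study varied it over 0.5-0.7) with marginal noise variance
#' `sigma2 = 1`, edge inclusion probability `edge_prob`, and structural
#' weights drawn uniformly from `weight_range` with random sign.
#'
#' @param p_per_visit biomarkers per visit.
#' @param n_visits number of visits (tiers); the study explored 3 to 6.
#' @param n_obs subjects per simulated dataset (50 to 1000 in the study).
#' @param rho within-biomarker AR(1) noise correlation in \[0, 1).
#' @param sigma2 noise variance.
#' @param alpha CI-test cut-off used by the learners.
#' @param edge_prob probability that a tier-respecting candidate edge
#'   enters the DAG.
#' @param weight_range absolute structural weight interval.
#' @param outcome_intercept intercept of the logistic outcome model
#'   (0 gives ~50% prevalence since covariates are centred).
#' @param n_replicates replicates per scenario.
#' @param fixed_dag reuse one DAG across replicates (TRUE) or redraw each
#'   replicate (FALSE, default).
#' @param seed integer seed.
#' @return a list of class `sim_scenario`.
#' @export
sim_scenario <- function(p_per_visit = 10L, n_visits = 4L, n_obs = 1000L,
                         rho = 0.6, sigma2 = 1, alpha = 0.02,
                         edge_prob = 0.1, weight_range = c(0.5, 1.5),
                         outcome_intercept = 0, n_replicates = 50L,
                         fixed_dag = FALSE, seed = 1L) {
  stopifnot(p_per_visit >= 1, n_visits >= 1, n_obs >= 10,
            rho >= 0, rho < 1, sigma2 > 0, alpha > 0, alpha < 1,
            edge_prob >= 0, edge_prob <= 1, length(weight_range) == 2,
            weight_range[1] <= weight_range[2], n_replicates >= 1)
  structure(as.list(environment()), class = "sim_scenario")
}

#' Tiered variable set of a scenario
#'
#' Nodes `bm<i>@V<v>` for biomarker i at visit v, plus outcome `Y` at tier
#' `n_visits + 1`.
#'
#' @param scn a [sim_scenario].
#' @export
scenario_vars <- function(scn) {
  covs <- as.vector(outer(seq_len(scn$p_per_visit), seq_len(scn$n_visits),
                          function(i, v) sprintf("bm%d@V%d", i, v)))
  tier <- rep(seq_len(scn$n_visits), each = scn$p_per_visit)
  tiered_vars(c(covs, "Y"),
              c(stats::setNames(tier, covs), Y = scn$n_visits + 1L),
              outcome = "Y")
}

#' Random weighted tiered DAG
#'
#' Every tier-respecting candidate edge (tail tier <= head tier; within a
#' tier only the lower-index to higher-index direction, which keeps the
#' graph acyclic by construction) — including the same-biomarker
#' chain edges and all covariate-to-outcome edges — enters independently
#' with probability `edge_prob`.  Weights are uniform on `weight_range`
#' with random sign.
#'
#' @param scn a [sim_scenario].
#' @return a `mixed_graph` (directed only) with extra element `weight`
#'   (matrix, `weight[i, j]` for edge i -> j).
#' @export
generate_tiered_dag <- function(scn) {
  vars <- scenario_vars(scn)
  nodes <- vars$names
  tr <- vars$tier[nodes]
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  wt <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      ok <- tr[i] < tr[j] || (tr[i] == tr[j] && i < j)
      if (!ok) next
      if (stats::runif(1) < scn$edge_prob) {
        amat[i, j] <- 1L
        wt[i, j] <- stats::runif(1, scn$weight_range[1], scn$weight_range[2]) *
          sample(c(-1, 1), 1)
      }
    }
  }
  g <- new_mixed_graph(amat, vars)
  g$weight <- wt
  g
}

#' Autoregressive noise covariance of one biomarker across visits
#'
#' `Sigma[a, b] = rho^|a - b| * sigma2` — the repeated-measures
#' correlation model driving the simulated collinearity.
#'
#' @param n_visits number of visits.
#' @param rho AR(1) correlation.
#' @param sigma2 marginal variance.
#' @export
ar_covariance <- function(n_visits, rho, sigma2 = 1) {
  d <- abs(outer(seq_len(n_visits), seq_len(n_visits), `-`))
  rho^d * sigma2
}

#' Simulate a dataset from a weighted tiered DAG
#'
#' Covariates follow the linear structural equations of the DAG; each
#' biomarker's noise vector across visits is multivariate normal with the
#' [ar_covariance()] matrix (independent across biomarkers), so that with
#' no structural edges the same-biomarker cross-visit correlation is
#' exactly `rho^|dv|` and marginal variances equal `sigma2`.  The binary
#' outcome is Bernoulli-logistic with linear predictor
#' `outcome_intercept + sum(weights * parents)`.
#'
#' @param dag a weighted DAG from [generate_tiered_dag()].
#' @param scn the [sim_scenario] it came from.
#' @param n_obs number of rows (default `scn$n_obs`).
#' @return numeric matrix with columns `dag$nodes` (outcome 0/1 in `Y`).
#' @export
simulate_dataset <- function(dag, scn, n_obs = scn$n_obs) {
  vars <- dag$vars
  nodes <- dag$nodes
  covs <- covariates_of(vars)
  Sig <- ar_covariance(scn$n_visits, scn$rho, scn$sigma2)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("non-positive-definite AR covariance")
  L <- chol(Sig)
  eps <- matrix(0, n_obs, length(covs), dimnames = list(NULL, covs))
  for (b in seq_len(scn$p_per_visit)) {
    cols <- sprintf("bm%d@V%d", b, seq_len(scn$n_visits))
    eps[, cols] <- matrix(stats::rnorm(n_obs * scn$n_visits), n_obs) %*% L
  }
  X <- matrix(0, n_obs, length(nodes), dimnames = list(NULL, nodes))
  tr <- vars$tier[nodes]
  ord <- order(tr, seq_along(nodes))  # topological: tiers, then index
  wt <- dag$weight
  for (j in ord) {
    nj <- nodes[j]
    if (nj == "Y") next
    pa <- which(dag$amat[, j] == 1L)
    X[, j] <- eps[, nj] +
      if (length(pa)) X[, pa, drop = FALSE] %*% wt[pa, j] else 0
  }
  pa_y <- which(dag$amat[, "Y"] == 1L)
  lp <- scn$outcome_intercept +
    if (length(pa_y)) drop(X[, pa_y, drop = FALSE] %*% wt[pa_y, "Y"]) else 0
  X[, "Y"] <- stats::rbinom(n_obs, 1, stats::plogis(lp))
  X
}

#' Large-sample true adjusted effects of every covariate on the outcome
#'
#' Monte-Carlo reference values for benchmarking: one large seeded draw
#' from the generating model, then for each covariate the adjusted effect
#' on the outcome controlling for its true parents, on the same scale as
#' [estimate_effect()].  Covariates with no directed path to the outcome
#' have effect ~ 0.
#'
#' @param dag a weighted DAG from [generate_tiered_dag()].
#' @param scn its [sim_scenario].
#' @param scale effect scale, see [estimate_effect()].
#' @param n_mc Monte-Carlo sample size (default 1e5).
#' @param seed seed for the draw.
#' @return named numeric vector over the covariates.
#' @export
true_effects <- function(dag, scn, scale = "log-odds", n_mc = 1e5,
                         seed = 1L) {
  set.seed(seed)
  big <- simulate_dataset(dag, scn, n_obs = n_mc)
  covs <- covariates_of(dag$vars)
  vapply(covs, function(x) {
    pa <- setdiff(parents_of(dag, x), "Y")
    estimate_effect(big, x, "Y", pa, scale)
  }, numeric(1))
}

#' Run a simulation scenario: PC-stable vs COPC-stable
#'
#' Per replicate: draw a DAG (or reuse the fixed one), simulate a dataset,
#' run both learners at `scn$alpha`, and score each against the true
#' CPDAG ([dag_to_cpdag()] of the generating DAG) via
#' [structure_metrics()].  With `effects = TRUE`, additionally compute the
#' IDA lower bounds per covariate on each estimated CPDAG and their mean
#' squared error against [true_effects()].
#'
#' @param scn a [sim_scenario].
#' @param effects also benchmark effect estimation (slower).
#' @param n_mc Monte-Carlo size for the reference effects.
#' @return object of class `sim_report`: `metrics` (data.frame with mean,
#'   sd and se of Se/Sp/SHD and non-chronological count per method),
#'   `per_replicate` (raw metrics), `mse` (data.frame per method, or
#'   NULL), `n_failed`.
#' @export
run_scenario <- function(scn, effects = FALSE, n_mc = 1e5) {
  set.seed(scn$seed)
  vars <- scenario_vars(scn)
  cfg_pc <- learn_config(alpha = scn$alpha)
  cfg_co <- learn_config(alpha = scn$alpha, tiered = TRUE)
  dag0 <- if (scn$fixed_dag) generate_tiered_dag(scn) else NULL
  truth0 <- if (scn$fixed_dag) dag_to_cpdag(dag0) else NULL
  te0 <- if (scn$fixed_dag && effects)
    true_effects(dag0, scn, n_mc = n_mc, seed = scn$seed) else NULL
  rows <- list()
  mse_rows <- list()
  n_failed <- 0L
  for (r in seq_len(scn$n_replicates)) {
    res <- tryCatch({
      dag <- if (scn$fixed_dag) dag0 else generate_tiered_dag(scn)
      truth <- if (scn$fixed_dag) truth0 else dag_to_cpdag(dag)
      dat <- simulate_dataset(dag, scn)
      g_pc <- pc_stable(dat, cfg_pc, vars = vars)
      g_co <- copc_stable(dat, vars, cfg_co)
      m_pc <- structure_metrics(g_pc, truth, vars)
      m_co <- structure_metrics(g_co, truth, vars)
      out <- list(
        data.frame(replicate = r, method = c("pc_stable", "copc_stable"),
                   sensitivity = c(m_pc$sensitivity, m_co$sensitivity),
                   specificity = c(m_pc$specificity, m_co$specificity),
                   shd = c(m_pc$shd, m_co$shd),
                   n_nonchronological = c(m_pc$n_nonchronological,
                                          m_co$n_nonchronological),
                   n_tests = c(attr(g_pc, "n_tests"), attr(g_co, "n_tests")),
                   stringsAsFactors = FALSE))
      if (effects) {
        te <- if (scn$fixed_dag) te0 else
          true_effects(dag, scn, n_mc = n_mc, seed = scn$seed + r)
        for (meth in c("pc_stable", "copc_stable")) {
          g <- if (meth == "pc_stable") g_pc else g_co
          eff <- ida_all_effects(g, dat, vars)
          est <- stats::setNames(eff$lower_bound, eff$covariate)[names(te)]
          out$mse <- rbind(out$mse,
            data.frame(replicate = r, method = meth,
                       mse = mean((abs(est) - abs(te))^2),
                       stringsAsFactors = FALSE))
        }
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
      next
    }
    rows[[length(rows) + 1L]] <- res[[1]]
    if (!is.null(res$mse)) mse_rows[[length(mse_rows) + 1L]] <- res$mse
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$method), function(d) {
    summarise <- function(x) c(mean = mean(x), sd = stats::sd(x),
                               se = stats::sd(x) / sqrt(length(x)))
    data.frame(method = d$method[1],
               t(c(sensitivity = summarise(d$sensitivity),
                   specificity = summarise(d$specificity),
                   shd = summarise(d$shd),
                   nonchrono = summarise(d$n_nonchronological))),
               n_replicates = nrow(d),
               stringsAsFactors = FALSE)
  }))
  mse <- if (length(mse_rows)) {
    md <- do.call(rbind, mse_rows)
    do.call(rbind, lapply(split(md, md$method), function(d)
      data.frame(method = d$method[1], mse_mean = mean(d$mse),
                 mse_sd = stats::sd(d$mse), stringsAsFactors = FALSE)))
  } else NULL
  structure(list(scenario = scn, metrics = agg, per_replicate = per,
                 mse = mse, n_failed = n_failed),
            class = "sim_report")
}

#' @export
print.sim_report <- function(x, ...) {
  cat(sprintf("Simulation report: %d visits x %d biomarkers, n = %d, alpha = %g, %d replicates (%d failed)\n",
              x$scenario$n_visits, x$scenario$p_per_visit, x$scenario$n_obs,
              x$scenario$alpha, x$scenario$n_replicates, x$n_failed))
  print(x$metrics, row.names = FALSE, digits = 3)
  if (!is.null(x$mse)) print(x$mse, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a simulation report as CSV
#'
#' One row per method with mean/sd/se of sensitivity, specificity and SHD
#' (mirroring the benchmark table layout); MSE columns appended when
#' available.
#'
#' @param x a `sim_report`.
#' @param path output CSV path.
#' @export
write_sim_report_csv <- function(x, path) {
  out <- x$metrics
  if (!is.null(x$mse)) out <- merge(out, x$mse, by = "method")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
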