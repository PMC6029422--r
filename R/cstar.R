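#' Per-comparison error rate bound
#'
#' PCER bound for a covariate appearing among the top `q` of `p`
#' covariates with relative frequency `pi_hat` over subsample runs:
#' `q^2 / (p^2 * (2 * pi_hat - 1))`; infinite when `pi_hat <= 0.5` (no
#' control below majority frequency).
#'
#' @param pi_hat top-q relative frequency in \[0, 1\].
#' @param q size of the top list.
#' @param p number of covariates.
#' @return positive numeric (possibly `Inf`); vectorised over `pi_hat`.
#' @examples
#' pcer(1, 10, 100)     # 0.01
#' pcer(0.75, 10, 100)  # 0.02
#' @export
pcer <- function(pi_hat, q, p) {
  stopifnot(all(pi_hat >= 0), all(pi_hat <= 1), q >= 1, q <= p)
  ifelse(pi_hat > 0.5, (q^2 / p^2) / (2 * pi_hat - 1), Inf)
}

#' Causal stability ranking (CStaR) over random subsamples
#'
#' Runs COPC-stable (or PC-stable) followed by local IDA on `B` random
#' subsamples of size `m` drawn without replacement, ranks covariates by
#' their causal-effect lower bound in every run, and summarises how often
#' each covariate lands in the top `q` (the frequency `pi_hat`, its PCER
#' bound, and the median lower bound across runs).
#'
#' @param data numeric matrix / data.frame with columns `vars$names`.
#' @param vars a [tiered_vars] with an outcome.
#' @param cfg a [learn_config]; `cfg$tiered` selects COPC-stable (TRUE,
#'   default) or plain PC-stable.
#' @param B number of subsample runs (the application used 300).
#' @param m subsample size (default `floor(n / 2)`; the application used
#'   30).
#' @param q top-list size (default `max(1, ceiling(0.1 * p))`).
#' @param seed integer seed making the whole run reproducible.
#' @param scale effect scale, see [estimate_effect()].
#' @param keep_graphs store the per-run CPDAGs (for [aggregate_cpdags()]).
#' @return object of class `stability_ranking`: `ranking` (data.frame
#'   `covariate`, `pi_hat`, `pcer`, `median_effect`, `rank`), `q`, `B`
#'   (requested), `B_effective` (successful runs), `m`, `graphs`
#'   (list or NULL), `failures` (character log).
#' @export
cstar <- function(data, vars, cfg = learn_config(tiered = TRUE),
                  B = 100L, m = floor(nrow(data) / 2), q = NULL,
                  seed = 1L, scale = "log-odds", keep_graphs = TRUE) {
  data <- as.matrix(data)[, vars$names, drop = FALSE]
  n <- nrow(data)
  stopifnot(m <= n, B >= 1)
  covs <- covariates_of(vars)
  p <- length(covs)
  if (is.null(q)) q <- max(1L, ceiling(0.1 * p))
  stopifnot(q <= p)
  outc <- outcome_of(vars)
  if (is.null(outc)) stop("stability selection needs an outcome variable")

  set.seed(seed)
  top_count <- stats::setNames(rep(0L, p), covs)
  bounds_mat <- matrix(NA_real_, p, B, dimnames = list(covs, NULL))
  graphs <- if (keep_graphs) vector("list", B) else NULL
  failures <- character()
  for (b in seq_len(B)) {
    idx <- sample.int(n, m)
    res <- tryCatch({
      sub <- data[idx, , drop = FALSE]
      g <- if (cfg$tiered) copc_stable(sub, vars, cfg)
           else pc_stable(sub, cfg, vars = vars)
      eff <- ida_all_effects(g, sub, vars, scale = scale)
      list(g = g, eff = eff)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("run %d: %s", b, conditionMessage(res)))
      next
    }
    bb <- stats::setNames(res$eff$lower_bound, res$eff$covariate)[covs]
    bounds_mat[, b] <- bb
    top <- rank_effects(bb)[seq_len(q)]
    top_count[top] <- top_count[top] + 1L
    if (keep_graphs) graphs[[b]] <- res$g
  }
  B_eff <- B - length(failures)
  if (B_eff == 0L) stop("all subsample runs failed")
  pi_hat <- top_count / B_eff
  med <- apply(bounds_mat, 1, stats::median, na.rm = TRUE)
  ord <- order(-pi_hat, -med, covs)
  ranking <- data.frame(covariate = covs[ord],
                        pi_hat = unname(pi_hat[ord]),
                        pcer = unname(pcer(pi_hat[ord], q, p)),
                        median_effect = unname(med[ord]),
                        rank = seq_len(p),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, q = q, B = B, B_effective = B_eff,
                 m = m, seed = seed, alpha = cfg$alpha, scale = scale,
                 graphs = if (keep_graphs) Filter(Negate(is.null), graphs),
                 failures = failures),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("CStaR ranking: %d covariates, q = %d, B = %d (%d successful), m = %d\n",
              nrow(x$ranking), x$q, x$B, x$B_effective, x$m))
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Select biomarkers at a PCER threshold
#'
#' Covariates whose PCER bound is at most `threshold` (the application
#' used 0.5%), sorted by PCER ascending then median effect descending.
#'
#' @param ranking a `stability_ranking` from [cstar()] (or its `$ranking`
#'   data.frame).
#' @param threshold PCER cut-off (default 0.005).
#' @return data.frame subset of the ranking, re-sorted.
#' @export
select_biomarkers <- function(ranking, threshold = 0.005) {
  df <- if (inherits(ranking, "stability_ranking")) ranking$ranking else ranking
  sel <- df[df$pcer <= threshold, , drop = FALSE]
  sel[order(sel$pcer, -sel$median_effect, sel$covariate), , drop = FALSE]
}

#' Write a stability ranking as CSV
#'
#' Columns `covariate,pi_hat,pcer,median_effect,rank`; run metadata (seed,
#' alpha, q, B, m) goes to a JSON sidecar `<path>.meta.json`.
#'
#' @param x a `stability_ranking`.
#' @param path output CSV path.
#' @export
write_ranking_csv <- function(x, path) {
  utils::write.csv(x$ranking, path, row.names = FALSE, quote = FALSE)
  meta <- list(q = x$q, B = x$B, B_effective = x$B_effective, m = x$m,
               seed = x$seed, alpha = x$alpha, scale = x$scale,
               version = as.character(utils::packageVersion("copcida")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
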