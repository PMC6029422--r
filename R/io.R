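#' Load a wide-format repeated-measures dataset
#'
#' Reads a delimited table of subjects x biomarker measurements plus one
#' binary outcome column, assigns each covariate column to a visit tier
#' (by the `name@V<k>` suffix convention or an explicit map), and
#' validates the bundle.  Missing cells are rejected: imputation (the
#' application used MICE) belongs upstream of structure learning.
#'
#' @param path delimited file with a header row.
#' @param outcome name of the binary outcome column ({0,1} or two-level
#'   strings).
#' @param tier_config optional path to a YAML file mapping column names to
#'   visit indices, or a named list/vector doing the same.
#' @param sep field separator (default `","`).
#' @return object of class `dataset_bundle`: `data` (numeric matrix,
#'   outcome coerced to 0/1), `vars` ([tiered_vars]), `provenance` (path,
#'   options, md5).
#' @export
load_dataset <- function(path, outcome, tier_config = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!outcome %in% names(df))
    stop("outcome column not found: ", outcome)
  na_idx <- which(is.na(df), arr.ind = TRUE)
  if (nrow(na_idx))
    stop(sprintf(paste0("missing cell at row %d, column '%s'; impute ",
                        "upstream (e.g. MICE) before loading"),
                 na_idx[1, 1], names(df)[na_idx[1, 2]]))
  y <- df[[outcome]]
  if (!is.numeric(y)) {
    lev <- sort(unique(y))
    if (length(lev) != 2L)
      stop("outcome must have exactly two levels, found: ",
           paste(lev, collapse = ", "))
    y <- as.integer(y == lev[2])
  }
  if (!all(y %in% c(0, 1)))
    stop("outcome column must be binary 0/1")
  df[[outcome]] <- y
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("non-numeric covariate column(s): ",
         paste(names(df)[!vapply(df, is.numeric, TRUE)], collapse = ", "))
  tier_map <- NULL
  if (!is.null(tier_config)) {
    tier_map <- if (is.character(tier_config) && length(tier_config) == 1L &&
                    file.exists(tier_config))
      yaml::read_yaml(tier_config) else tier_config
  }
  vars <- tiers_from_names(names(df), outcome = outcome, tier_map = tier_map)
  const <- names(df)[vapply(df, function(c) stats::var(c) == 0, TRUE)]
  if (length(const))
    warning("constant column(s): ", paste(const, collapse = ", "))
  structure(list(data = as.matrix(df), vars = vars,
                 provenance = list(path = normalizePath(path),
                                   sep = sep, outcome = outcome,
                                   md5 = unname(tools::md5sum(path)))),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("dataset_bundle: %d subjects x %d columns, outcome '%s', tiers {%s}\n",
              nrow(x$data), ncol(x$data), outcome_of(x$vars),
              paste(sort(unique(x$vars$tier[covariates_of(x$vars)])),
                    collapse = ", ")))
  invisible(x)
}

#' Write a dataset bundle back to CSV
#' @param bundle a `dataset_bundle` (or plain matrix).
#' @param path output path.
#' @export
write_dataset_csv <- function(bundle, path) {
  m <- if (inherits(bundle, "dataset_bundle")) bundle$data else bundle
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded synthetic demo dataset
#'
#' Draws a small tiered biomarker panel from the simulation generator and
#' returns it as a `dataset_bundle`-shaped list (and optionally writes the
#' CSV) — used for demos, tests and the CLI `fixtures` subcommand.
#'
#' @param p_per_visit,n_visits,n_obs,rho,edge_prob,seed generator
#'   settings, see [sim_scenario()].
#' @param path optional CSV output path.
#' @return list `data`, `vars`, `dag` (the generating weighted DAG),
#'   `scenario`.
#' @export
synthetic_biomarker_dataset <- function(p_per_visit = 5L, n_visits = 3L,
                                        n_obs = 100L, rho = 0.6,
                                        edge_prob = 0.15, seed = 1L,
                                        path = NULL) {
  scn <- sim_scenario(p_per_visit = p_per_visit, n_visits = n_visits,
                      n_obs = n_obs, rho = rho, edge_prob = edge_prob,
                      seed = seed)
  set.seed(seed)
  dag <- generate_tiered_dag(scn)
  dat <- simulate_dataset(dag, scn)
  if (!is.null(path)) write_dataset_csv(dat, path)
  list(data = dat, vars = dag$vars, dag = dag, scenario = scn)
}
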