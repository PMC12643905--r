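# Data ingestion, configuration and the simulate/detect/evaluate pipeline
# behind the mnlfa-anchor command-line interface (inst/cli/mnlfa-anchor).

#' Read a response/covariate dataset from CSV
#'
#' Responses are one column per item (header = item ids, integer cells);
#' covariates one column per covariate. Category codes are normalized to
#' `0..m-1`: by default the minimum observed code is subtracted (so `1..4`
#' becomes `0..3`), or pass an explicit `response_offset`.
#'
#' @param responses_path path to the responses CSV.
#' @param covariates_path path to the covariates CSV.
#' @param response_offset integer subtracted from every response cell
#'   (default: the minimum observed code).
#' @param covariate_kinds optional character vector (`"binary"` /
#'   `"continuous"`) per covariate; auto-detected when omitted.
#' @return list with `y` (integer matrix), `X` (numeric matrix), `m`,
#'   `kinds`.
#' @export
read_dataset <- function(responses_path, covariates_path,
                         response_offset = NULL, covariate_kinds = NULL) {
  y <- as.matrix(utils::read.csv(responses_path, check.names = FALSE))
  X <- as.matrix(utils::read.csv(covariates_path, check.names = FALSE))
  if (any(is.na(y))) stop("missing cells in responses")
  if (any(is.na(X))) stop("missing cells in covariates")
  if (!is.numeric(y) || any(y != round(y)))
    stop("non-integer responses in ", responses_path)
  if (nrow(y) != nrow(X))
    stop("row mismatch: ", nrow(y), " response rows vs ", nrow(X),
         " covariate rows")
  if (is.null(response_offset)) response_offset <- min(y)
  y <- y - as.integer(response_offset)
  if (min(y) < 0)
    stop("out-of-range categories after applying offset ", response_offset)
  storage.mode(y) <- "integer"
  if (is.null(covariate_kinds))
    covariate_kinds <- unname(ifelse(apply(X, 2, function(c) all(c %in% 0:1)),
                                     "binary", "continuous"))
  if (any(!is.finite(X))) stop("non-finite covariate values")
  list(y = y, X = X, m = max(y) + 1L, kinds = covariate_kinds)
}

#' Read (and validate) a run configuration
#'
#' JSON file with any of the fields of [mnlfa_control()] plus pipeline
#' fields (`mode`, `N`, `J`, `anchor_prop`, `scenario`, `reps`, `seed`,
#' `workers`, `out`, `responses`, `covariates`, `archive`,
#' `response_offset`). Unknown keys raise an error naming the key.
#'
#' @param path JSON config file path.
#' @param overrides named list merged over the file contents.
#' @return validated named list with an `mnlfa_control` in `$control`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else list()
  cfg[names(overrides)] <- overrides
  known <- c("mode", "N", "J", "anchor_prop", "scenario", "reps", "seed",
             "workers", "out", "responses", "covariates", "archive",
             "response_offset", "quad_points", "iter_max", "rel_tol",
             "gtol", "z_threshold", "alpha", "wic_grid")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  ctrl_keys <- intersect(names(cfg), names(formals(mnlfa_control)))
  cfg$control <- do.call(mnlfa_control, cfg[ctrl_keys])
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$workers)) cfg$workers <- 1L
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Flat parameter table of a fit
#'
#' @param fit an `mnlfa_fit`.
#' @return data frame with `parameter`, `estimate`, `se`.
#' @export
param_table <- function(fit) {
  spec <- fit$spec
  est <- .pack(fit$params, spec, natural = TRUE)
  se <- if (!is.null(fit$se)) fit$se$vector else rep(NA_real_, length(est))
  data.frame(parameter = fit$labels, estimate = est, se = unname(se))
}

#' Write a model report (JSON + flat CSV parameter table)
#'
#' @param fit an `mnlfa_fit`.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the report list.
#' @export
write_fit_report <- function(fit, json_path = NULL, csv_path = NULL) {
  tab <- param_table(fit)
  rep <- list(loglik = fit$loglik, k = fit$k, n = fit$n,
              converged = fit$converged, AIC = fit$AIC, BIC = fit$BIC,
              estimates = tab)
  if (!is.null(json_path)) .write_json(rep, json_path)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(rep)
}

.screening_trace <- function(rounds) {
  do.call(rbind, lapply(seq_along(rounds), function(i) {
    r <- rounds[[i]]
    data.frame(round = i, criterion = r$criterion,
               wic_lambda = if (is.null(r$wic_lambda) || is.na(r$wic_lambda))
                 NA_real_ else r$wic_lambda,
               item = r$tested_items, delta_ic = r$delta_ic,
               robust_se = r$robust_se, z = r$z,
               flagged = r$tested_items %in% r$flagged)
  }))
}

.run_simulate <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  cond <- sim_condition(cfg$N, cfg$J, cfg$anchor_prop, cfg$scenario,
                        cfg$reps, cfg$seed)
  seeds <- .derive_seeds(cond$seed, cond$reps + 1L)
  gen <- gen_true_params(cond$J, cond$anchor_prop, cond$scenario,
                         seed = seeds[1])
  rep_dirs <- character(cond$reps)
  for (r in seq_len(cond$reps)) {
    set.seed(seeds[r + 1L])
    X <- gen_covariates(cond$N)
    y <- gen_responses(X, gen$params)
    d <- file.path(cfg$out, sprintf("rep_%03d", r))
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(y, file.path(d, "y.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(X), file.path(d, "x.csv"),
                     row.names = FALSE)
    utils::write.csv(gen$truth$table, file.path(d, "truth.csv"),
                     row.names = FALSE)
    rep_dirs[r] <- basename(d)
  }
  .write_json(list(condition = unclass(cond)[c("N", "J", "anchor_prop",
                                               "scenario", "reps", "seed")],
                   anchor = gen$truth$anchor, reps = rep_dirs),
              file.path(cfg$out, "archive_index.json"))
  invisible(cfg$out)
}

.run_detect <- function(cfg) {
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(cfg$responses, cfg$covariates,
                     response_offset = cfg$response_offset)
  res <- run_refined(ds$y, ds$X, cfg$control)
  ar <- res$anchor_report
  .write_json(list(step1_candidates = ar$step1_candidates,
                   wic_lambda_used = ar$wic_lambda_used,
                   anchors = ar$anchors, dif_items = ar$dif_items,
                   converged = res$final_report$converged),
              file.path(cfg$out, "anchor_report.json"))
  utils::write.csv(res$final_report$effects,
                   file.path(cfg$out, "final_dif.csv"), row.names = FALSE)
  utils::write.csv(.screening_trace(ar$rounds),
                   file.path(cfg$out, "screening_trace.csv"),
                   row.names = FALSE)
  write_fit_report(res$final_report$fit,
                   json_path = file.path(cfg$out, "final_model.json"))
  writeLines(c(sprintf("mnlfa-anchor detect log"),
               sprintf("n = %d, J = %d, p = %d", nrow(ds$y), ncol(ds$y),
                       ncol(ds$X)),
               sprintf("final logLik = %.6f, k = %d, AIC = %.4f, BIC = %.4f",
                       res$final_report$fit$loglik, res$final_report$fit$k,
                       res$final_report$fit$AIC, res$final_report$fit$BIC),
               sprintf("anchors: %s", paste(ar$anchors, collapse = ", "))),
             file.path(cfg$out, "run.log"))
  invisible(res)
}

# rebuild a sim_archive from an archive directory whose replication
# subdirectories contain truth.csv plus detect outputs
.archive_from_dir <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "archive_index.json"),
                             simplifyVector = TRUE)
  truth_tab <- utils::read.csv(file.path(dir, idx$reps[1], "truth.csv"))
  J <- max(truth_tab$item); p <- max(truth_tab$covariate)
  B <- matrix(0, J, p); G <- matrix(0, J, p)
  B[cbind(truth_tab$item, truth_tab$covariate)] <- truth_tab$uniform
  G[cbind(truth_tab$item, truth_tab$covariate)] <- truth_tab$nonuniform
  reps <- lapply(idx$reps, function(rd) {
    ap <- file.path(dir, rd, "anchor_report.json")
    fp <- file.path(dir, rd, "final_dif.csv")
    if (!file.exists(ap) || !file.exists(fp))
      return(list(ok = FALSE, error = "missing detect output"))
    ar <- jsonlite::read_json(ap, simplifyVector = TRUE)
    ef <- utils::read.csv(fp)
    list(ok = TRUE,
         anchor_report = list(anchors = as.integer(ar$anchors),
                              dif_items = as.integer(ar$dif_items),
                              step1_candidates = as.integer(ar$step1_candidates)),
         final_report = list(effects = ef))
  })
  structure(list(condition = idx$condition,
                 truth = list(B = B, Gamma = G,
                              anchor = rowSums(B != 0) + rowSums(G != 0) == 0,
                              table = truth_tab),
                 reps = reps),
            class = "sim_archive")
}

.run_evaluate <- function(cfg) {
  archive <- .archive_from_dir(cfg$archive)
  m <- metrics_report(archive)
  vals <- unlist(m[c("hit_rate", "type2_uniform", "type2_nonuniform",
                     "type1", "power_uniform", "power_nonuniform",
                     "rel_bias_uniform", "rel_bias_nonuniform")])
  out_csv <- if (!is.null(cfg$out)) cfg$out else
    file.path(cfg$archive, "metrics.csv")
  utils::write.csv(data.frame(metric = names(vals), value = unname(vals)),
                   out_csv, row.names = FALSE)
  .write_json(c(as.list(vals), list(n_reps = m$n_reps, n_ok = m$n_ok)),
              sub("\\.csv$", ".json", out_csv))
  invisible(m)
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches the `simulate`, `detect` or `evaluate` stage named by
#' `config$mode`. `simulate` writes per-replication `y.csv`, `x.csv`,
#' `truth.csv` and an `archive_index.json`; `detect` runs the refined
#' procedure on one dataset and writes `anchor_report.json`,
#' `final_dif.csv`, `screening_trace.csv`, `final_model.json` and a run
#' log; `evaluate` scores an archive directory (after `detect` has been run
#' on each replication) and writes `metrics.csv`/`metrics.json`.
#'
#' @param config list from [read_run_config()] (or equivalent).
#' @return invisibly, the stage result.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$mode))
    stop("config must name a mode: simulate, detect or evaluate")
  switch(config$mode,
         simulate = .run_simulate(config),
         detect = .run_detect(config),
         evaluate = .run_evaluate(config),
         stop("unknown mode: ", config$mode))
}
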