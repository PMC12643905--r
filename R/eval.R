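# Confusion-matrix metrics scoring detection output against the generating
# truth. Rates aggregate as the mean of per-replication rates; relative bias
# averages each true effect's estimate over the replications in which it was
# estimated (the item reached the final model) before comparing to truth.

.ok_reps <- function(archive) Filter(function(r) isTRUE(r$ok), archive$reps)

.truth_items <- function(truth, effect_type) {
  has <- switch(effect_type,
                uniform = rowSums(truth$B != 0) > 0,
                nonuniform = rowSums(truth$Gamma != 0) > 0,
                any = rowSums(truth$B != 0) + rowSums(truth$Gamma != 0) > 0)
  which(has)
}

# long table of true effects: item, covariate, type, true value
.true_effects <- function(truth, effect_type = c("uniform", "nonuniform")) {
  out <- lapply(intersect(effect_type, c("uniform", "nonuniform")),
                function(ty) {
    M <- if (ty == "uniform") truth$B else truth$Gamma
    idx <- which(M != 0)
    if (!length(idx)) return(NULL)
    rc <- arrayInd(idx, dim(M))
    data.frame(item = rc[, 1], covariate = rc[, 2], type = ty,
               true = M[idx])
  })
  do.call(rbind, out)
}

#' Hit rate: truly DIF-free items confirmed as pure anchors
#'
#' Per replication, the proportion of truly DIF-free items that end up in
#' the confirmed anchor set; averaged over replications. Undefined (returned
#' as `NA`) when the design has no DIF-free items.
#'
#' @param archive a `sim_archive` from [run_condition()].
#' @return scalar rate in `[0, 1]` (or `NA`).
#' @export
hit_rate <- function(archive) {
  free_items <- which(archive$truth$anchor)
  if (!length(free_items)) return(NA_real_)
  reps <- .ok_reps(archive)
  mean(vapply(reps, function(r)
    mean(free_items %in% r$anchor_report$anchors), numeric(1)))
}

#' Type II error: true DIF items mistakenly confirmed as anchors
#'
#' Per replication, the proportion of items truly carrying the given DIF
#' effect type that end up in the anchor set (and are therefore excluded
#' from the final model); averaged over replications.
#'
#' @param archive a `sim_archive`.
#' @param effect_type `"uniform"`, `"nonuniform"` or `"any"`.
#' @return scalar rate in `[0, 1]` (`NA` if no item carries the type).
#' @export
type2_error <- function(archive, effect_type = c("uniform", "nonuniform", "any")) {
  effect_type <- match.arg(effect_type)
  items <- .truth_items(archive$truth, effect_type)
  if (!length(items)) return(NA_real_)
  reps <- .ok_reps(archive)
  mean(vapply(reps, function(r)
    mean(items %in% r$anchor_report$anchors), numeric(1)))
}

#' Type I error: truly DIF-free effects flagged as significant
#'
#' The denominator is every truly DIF-free item x covariate x type effect
#' (2 J p minus the number of true effects), including both DIF-free effects
#' within DIF items tested in the final model and effects on items
#' designated pure anchors — the latter were excluded from the final model
#' and therefore count as unflagged. The numerator is the number of DIF-free
#' effects with Wald `p < alpha` in the final model. Averaged over
#' replications.
#'
#' @param archive a `sim_archive`.
#' @return scalar rate in `[0, 1]`.
#' @export
type1_error <- function(archive) {
  truth <- archive$truth
  J <- nrow(truth$B); p <- ncol(truth$B)
  n_true <- sum(truth$B != 0) + sum(truth$Gamma != 0)
  denom <- 2 * J * p - n_true
  if (denom == 0) return(NA_real_)
  reps <- .ok_reps(archive)
  mean(vapply(reps, function(r) {
    ef <- r$final_report$effects
    if (!nrow(ef)) return(0)
    tr <- ifelse(ef$type == "uniform",
                 truth$B[cbind(ef$item, ef$covariate)],
                 truth$Gamma[cbind(ef$item, ef$covariate)])
    sum(ef$flagged & tr == 0) / denom
  }, numeric(1)))
}

#' Power: true DIF effects detected in the final model
#'
#' A true effect counts as detected iff its item reached the final model
#' (was not anchored away in steps 1-2) and the matching Wald test is
#' significant; effects on items anchored early are misses. Averaged over
#' replications.
#'
#' @param archive a `sim_archive`.
#' @param effect_type `"uniform"` or `"nonuniform"`.
#' @return scalar rate in `[0, 1]` (`NA` if there are no such true effects).
#' @export
power_rate <- function(archive, effect_type = c("uniform", "nonuniform")) {
  effect_type <- match.arg(effect_type)
  eff <- .true_effects(archive$truth, effect_type)
  if (is.null(eff) || !nrow(eff)) return(NA_real_)
  reps <- .ok_reps(archive)
  mean(vapply(reps, function(r) {
    ef <- r$final_report$effects
    hit <- vapply(seq_len(nrow(eff)), function(i) {
      row <- ef[ef$item == eff$item[i] & ef$covariate == eff$covariate[i] &
                  ef$type == eff$type[i], , drop = FALSE]
      nrow(row) == 1 && isTRUE(row$flagged)
    }, logical(1))
    mean(hit)
  }, numeric(1)))
}

#' Absolute relative bias of estimated DIF effects
#'
#' For each true effect, the estimate is averaged over the replications in
#' which the effect was estimated (its item reached the final model), then
#' compared to the truth: `|mean(estimate) - true| / |true|`. The returned
#' value is the mean over true effects of the given type. Effects never
#' estimated in any replication are reported as missing.
#'
#' @param archive a `sim_archive`.
#' @param effect_type `"uniform"` or `"nonuniform"`.
#' @return list with `bias` (scalar), `per_effect` (data frame with the
#'   per-effect mean estimate, bias, and the number of replications in which
#'   the effect was estimated).
#' @export
relative_bias <- function(archive, effect_type = c("uniform", "nonuniform")) {
  effect_type <- match.arg(effect_type)
  eff <- .true_effects(archive$truth, effect_type)
  if (is.null(eff) || !nrow(eff))
    return(list(bias = NA_real_, per_effect = NULL))
  reps <- .ok_reps(archive)
  per <- lapply(seq_len(nrow(eff)), function(i) {
    est <- unlist(lapply(reps, function(r) {
      ef <- r$final_report$effects
      row <- ef[ef$item == eff$item[i] & ef$covariate == eff$covariate[i] &
                  ef$type == eff$type[i], , drop = FALSE]
      if (nrow(row) == 1) row$estimate else NULL
    }))
    data.frame(item = eff$item[i], covariate = eff$covariate[i],
               type = eff$type[i], true = eff$true[i],
               n_est = length(est),
               mean_est = if (length(est)) mean(est) else NA_real_)
  })
  per <- do.call(rbind, per)
  per$bias <- abs(per$mean_est - per$true) / abs(per$true)
  b <- mean(per$bias, na.rm = TRUE)  # never-estimated effects stay NA in detail
  list(bias = if (is.nan(b)) NA_real_ else b, per_effect = per)
}

#' Full metrics report for a simulation archive
#'
#' @param archive a `sim_archive`.
#' @return list of class `metrics_report` with hit rate, Type II error per
#'   effect type, Type I error, power per effect type, absolute relative
#'   bias per effect type, and replication counts.
#' @export
metrics_report <- function(archive) {
  reps <- archive$reps
  ok <- vapply(reps, function(r) isTRUE(r$ok), logical(1))
  rb_u <- relative_bias(archive, "uniform")
  rb_n <- relative_bias(archive, "nonuniform")
  structure(list(
    hit_rate = hit_rate(archive),
    type2_uniform = type2_error(archive, "uniform"),
    type2_nonuniform = type2_error(archive, "nonuniform"),
    type1 = type1_error(archive),
    power_uniform = power_rate(archive, "uniform"),
    power_nonuniform = power_rate(archive, "nonuniform"),
    rel_bias_uniform = rb_u$bias,
    rel_bias_nonuniform = rb_n$bias,
    bias_detail = list(uniform = rb_u$per_effect,
                       nonuniform = rb_n$per_effect),
    n_reps = length(reps), n_ok = sum(ok),
    failures = vapply(reps[!ok], function(r) r$error, character(1))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Detection metrics over", x$n_ok, "of", x$n_reps, "replications\n")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat("  hit rate:           ", fmt(x$hit_rate), "\n",
      " Type II (uniform):   ", fmt(x$type2_uniform), "\n",
      " Type II (nonuniform):", fmt(x$type2_nonuniform), "\n",
      " Type I:              ", fmt(x$type1), "\n",
      " power (uniform):     ", fmt(x$power_uniform), "\n",
      " power (nonuniform):  ", fmt(x$power_nonuniform), "\n",
      " |rel bias| (uniform):   ", fmt(x$rel_bias_uniform), "\n",
      " |rel bias| (nonuniform):", fmt(x$rel_bias_nonuniform), "\n")
  invisible(x)
}
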