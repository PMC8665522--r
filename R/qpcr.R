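# Relative quantification of qPCR plates by the 2^-ddCt method.

#' 2^-ddCt relative expression from a well table
#'
#' Replicate Ct values are averaged arithmetically per (sample, target).
#' For each sample, `delta_ct = mean Ct(target) - mean Ct(reference)`;
#' the calibrator is the mean delta-Ct of the `calibratorGroup` for that
#' target, so the calibrator group's mean ddCt is exactly 0 and its
#' geometric-mean fold is 1. `fold = 2^-ddCt` (amplification efficiency
#' fixed at 2).
#'
#' @param wells data.frame with `sample_id`, `group`, `target`,
#'   `replicate`, `ct` (see [simulateQPCR()] / [readWells()]).
#' @param referenceGene id of the endogenous control gene; must be
#'   present for every sample.
#' @param calibratorGroup group whose mean delta-Ct calibrates each
#'   target (default `"control"`).
#' @return data.frame with `sample_id`, `group`, `target`,
#'   `mean_ct_target`, `mean_ct_reference`, `delta_ct`,
#'   `delta_delta_ct`, `fold`.
#' @export
relativeExpression <- function(wells, referenceGene,
                               calibratorGroup = "control") {
  need <- c("sample_id", "group", "target", "replicate", "ct")
  stopifnot(all(need %in% colnames(wells)))
  if (!referenceGene %in% wells$target)
    stop("reference gene '", referenceGene, "' has no wells")
  if (!calibratorGroup %in% wells$group)
    stop("calibrator group '", calibratorGroup, "' has no wells")
  mean_ct <- stats::aggregate(ct ~ sample_id + group + target,
                              data = wells, FUN = mean)
  ref <- mean_ct[mean_ct$target == referenceGene, ]
  ref_by_sample <- stats::setNames(ref$ct, ref$sample_id)
  tg <- mean_ct[mean_ct$target != referenceGene, ]
  missing_ref <- setdiff(tg$sample_id, names(ref_by_sample))
  if (length(missing_ref))
    stop("sample(s) without reference wells: ",
         paste(unique(missing_ref), collapse = ", "))
  tg$mean_ct_reference <- unname(ref_by_sample[tg$sample_id])
  tg$delta_ct <- tg$ct - tg$mean_ct_reference
  calib <- stats::aggregate(
    delta_ct ~ target, FUN = mean,
    data = tg[tg$group == calibratorGroup, , drop = FALSE])
  calib_by_target <- stats::setNames(calib$delta_ct, calib$target)
  if (!all(tg$target %in% names(calib_by_target)))
    stop("target(s) absent from the calibrator group: ",
         paste(setdiff(unique(tg$target), names(calib_by_target)),
               collapse = ", "))
  tg$delta_delta_ct <- tg$delta_ct - unname(calib_by_target[tg$target])
  tg$fold <- 2^(-tg$delta_delta_ct)
  out <- data.frame(sample_id = tg$sample_id, group = tg$group,
                    target = tg$target, mean_ct_target = tg$ct,
                    mean_ct_reference = tg$mean_ct_reference,
                    delta_ct = tg$delta_ct,
                    delta_delta_ct = tg$delta_delta_ct,
                    fold = tg$fold, stringsAsFactors = FALSE)
  out <- out[order(out$target, out$group, out$sample_id), ]
  rownames(out) <- NULL
  out
}

#' Group comparison of relative expression for one target
#'
#' Two-sided Student's t-test on the per-sample delta-Ct values
#' (equivalently on `log2(fold)`, since the two differ only by sign and
#' a per-target constant). The fold ratio reported is the geometric-mean
#' fold of the case group over the calibrator group,
#' `2^-(mean ddCt_case - mean ddCt_control)`.
#'
#' @param rel output of [relativeExpression()].
#' @param target target gene id.
#' @param groups the two group labels (case first); default
#'   `c("tumor", "control")`.
#' @return list with `target`, `fold_ratio`, `p_value`, `t`, `df`,
#'   `group_means` (mean delta-Ct per group).
#' @export
compareGroups <- function(rel, target, groups = c("tumor", "control")) {
  d <- rel[rel$target == target & rel$group %in% groups, ]
  if (nrow(d) == 0) stop("no rows for target ", target)
  x <- d$delta_ct[d$group == groups[1]]
  y <- d$delta_ct[d$group == groups[2]]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 samples")
  if (stats::var(x) + stats::var(y) == 0) {
    # degenerate plates: equal constant groups are a certain null,
    # unequal constant groups a certain difference
    tt <- list(p.value = as.numeric(mean(x) == mean(y)), statistic = NA,
               parameter = length(x) + length(y) - 2)
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  list(target = target,
       fold_ratio = 2^(-(mean(x) - mean(y))),
       p_value = unname(tt$p.value),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       group_means = stats::setNames(c(mean(x), mean(y)), groups))
}
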