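#' Relative expression by the 2^(-ddCt) method
#'
#' Per replicate, `dCt = ct_target - ct_reference`. Per (gene, condition),
#' `ddCt = mean dCt(condition) - mean dCt(control)` and the fold change is
#' `2^(-ddCt)` (so the control condition has fold 1 by construction). The
#' mean and standard deviation of replicate-level folds
#' `2^-(dCt_rep - mean dCt(control))` are reported alongside.
#'
#' @param ct A data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference` (cycle numbers).
#' @param controlCondition Label of the calibrator condition; must be
#'   present for every gene.
#' @param mode `"meanDelta"` (default: fold from mean dCt) or
#'   `"perReplicate"` (fold = mean of replicate-level folds).
#' @return A data.frame: `gene`, `condition`, `fold`, `fold_mean`,
#'   `fold_sd`, `n` (replicates), ordered by gene then condition with the
#'   control first.
#' @export
relativeExpression <- function(ct, controlCondition,
                               mode = c("meanDelta", "perReplicate")) {
  mode <- match.arg(mode)
  need <- c("gene", "condition", "replicate", "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0)
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(ct$ct_target) || !is.numeric(ct$ct_reference))
    stop("non-numeric Ct values")
  if (anyNA(ct$ct_target) || anyNA(ct$ct_reference))
    stop("missing Ct values")
  ct$dct <- ct$ct_target - ct$ct_reference
  rows <- list()
  for (g in unique(ct$gene)) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    if (!controlCondition %in% sub$condition)
      stop(sprintf("gene '%s' has no control condition '%s'", g,
                   controlCondition))
    ctrl_mean <- mean(sub$dct[sub$condition == controlCondition])
    conds <- unique(sub$condition)
    conds <- c(controlCondition, setdiff(conds, controlCondition))
    for (cond in conds) {
      dcts <- sub$dct[sub$condition == cond]
      rep_folds <- 2^(-(dcts - ctrl_mean))
      fold <- switch(mode,
                     meanDelta = 2^(-(mean(dcts) - ctrl_mean)),
                     perReplicate = mean(rep_folds))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, fold = fold,
        fold_mean = mean(rep_folds),
        fold_sd = if (length(rep_folds) > 1) sd(rep_folds) else NA_real_,
        n = length(rep_folds), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a Ct table from TSV
#'
#' @param path TSV file with one header row and columns `gene`, `condition`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return A data.frame.
#' @export
readCtTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Heatmap transform: log2(FPKM + pseudo) with per-row z-scaling
#'
#' Applies `log2(FPKM + pseudo)` elementwise and then scales each row to
#' mean 0 and standard deviation 1 ("row scale"). Rows with zero variance
#' map to all zeros, with a warning.
#'
#' @param mat Non-negative numeric matrix of FPKM values (genes x
#'   conditions), with dimnames.
#' @param pseudo Pseudo-count added before the log. Default 0.01.
#' @return A matrix of the same shape and dimnames.
#' @export
heatmapTransform <- function(mat, pseudo = 0.01) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("matrix must be numeric")
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  lg <- log2(mat + pseudo)
  mu <- rowMeans(lg)
  sdv <- apply(lg, 1, sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat))
    warning("constant row(s) mapped to zero: ",
            paste(rownames(mat)[flat], collapse = ", "))
  out <- (lg - mu) / ifelse(flat, 1, sdv)
  out[flat, ] <- 0
  out
}

#' Read an FPKM matrix from TSV
#'
#' First column = gene ids (row names), remaining columns = conditions.
#'
#' @param path TSV file with one header row.
#' @return A numeric matrix.
#' @export
readFpkmMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
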