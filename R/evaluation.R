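#' Pearson correlation between two flexibility profiles
#'
#' The accuracy metric used throughout: the Pearson product-moment
#' correlation between predicted and actual B factors over the residues of
#' one protein. Because Pearson correlation is invariant under positive
#' affine maps, scores computed on Z-scored and raw-scale values agree,
#' which is what makes the normalized and un-normalized modes comparable.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3L) stop("need at least 3 points for a meaningful PCC")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: constant input vector")
  cor(x, y)
}

#' Evaluate a trained predictor over a dataset
#'
#' Computes one Pearson correlation per protein on its full sequence and
#' the unweighted mean over proteins. A protein on which the model emits a
#' constant profile has no defined correlation; it is excluded from the
#' mean and reported with its failure reason rather than silently scored
#' as zero.
#'
#' @param model A trained `bf_predictor`.
#' @param encodings List of encodings (same mask and target mode as used
#'   in training).
#' @return List with `per_protein` (data.frame: protein_id, n, pcc),
#'   `average_pcc`, `n_failed`, and `failed` (data.frame with reasons).
#' @export
evaluate_dataset <- function(model, encodings) {
  rows <- list(); fails <- list()
  for (e in encodings) {
    pred <- predict_protein(model, e)
    if (sd(pred) == 0 || sd(e$y) == 0) {
      fails[[length(fails) + 1L]] <-
        data.frame(protein_id = e$protein_id,
                   reason = if (sd(pred) == 0) "constant_prediction"
                            else "constant_target",
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(protein_id = e$protein_id, n = nrow(e$X),
                 pcc = pearson_cc(pred, e$y), stringsAsFactors = FALSE)
  }
  per_protein <- if (length(rows)) do.call(rbind, rows)
    else data.frame(protein_id = character(0), n = integer(0),
                    pcc = numeric(0))
  failed <- if (length(fails)) do.call(rbind, fails)
    else data.frame(protein_id = character(0), reason = character(0))
  list(per_protein = per_protein,
       average_pcc = if (nrow(per_protein)) mean(per_protein$pcc) else NA_real_,
       n_failed = nrow(failed), failed = failed)
}

#' Write an evaluation report as delimited text
#'
#' One row per protein (protein_id, N, PCC) and a footer with the
#' unweighted average and the failed-protein count.
#'
#' @param report Output of [evaluate_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tn\tpcc", con)
  p <- report$per_protein
  if (nrow(p))
    writeLines(sprintf("%s\t%d\t%.6f", p$protein_id, p$n, p$pcc), con)
  writeLines(sprintf("# average_pcc\t%.6f\tfailed\t%d",
                     report$average_pcc, report$n_failed), con)
  invisible(path)
}
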