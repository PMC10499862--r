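# Interpretability analyses: how far along the sequence (window size Ws)
# and how far in Euclidean space (cutoff radius Rcut) does information
# travel before a trained model's prediction stops improving?

site_distances <- function(record) {
  xyz <- as.matrix(record$sites[, c("x", "y", "z")])
  as.matrix(stats::dist(xyz))
}

#' Predict one residue from a sequence window
#'
#' Runs the model on the contiguous block of ws + 1 rows around residue i
#' (ws is the sequence distance between the first and last residue of the
#' window) and returns the prediction at i's position inside the block.
#' The window is centered on i with the extra residue on the left when ws
#' is odd, and is shifted to stay inside the sequence near the termini, so
#' any `ws >= N - 1` reproduces the full-sequence prediction exactly.
#' Chain flags are taken as encoded — they are not recomputed for the crop.
#'
#' @param model A trained `bf_predictor`.
#' @param features Encoding list or bare feature matrix.
#' @param i Residue index, 1-based.
#' @param ws Window size in sequence-distance units, >= 0 (`ws = 0` means
#'   prediction from residue i's features alone).
#' @return Scalar prediction at residue i (model scale).
#' @export
window_predict <- function(model, features, i, ws) {
  X <- if (is.list(features)) features$X else features
  n <- nrow(X)
  if (i < 1L || i > n) stop("residue index out of range")
  if (ws < 0) stop("ws must be >= 0")
  span <- min(ws + 1L, n)
  lo <- i - ceiling(ws / 2)
  lo <- max(1L, min(lo, n - span + 1L))
  pred <- predict_protein(model, X[lo:(lo + span - 1L), , drop = FALSE])
  pred[i - lo + 1L]
}

#' Sweep the sequence-window size and locate the PCC plateau
#'
#' For each window size in `ws_grid`, every residue is re-predicted from
#' its ws-window alone and the Pearson correlation with the actual profile
#' is recorded. The critical window size is the smallest ws whose PCC is
#' within `plateau_tol` of the plateau (the PCC at the largest ws): beyond
#' it, widening the window no longer helps.
#'
#' @param model A trained `bf_predictor`.
#' @param features Encoding list (its `y` provides the actual profile).
#' @param ws_grid Ascending integer grid of window sizes.
#' @param plateau_tol PCC tolerance defining the plateau (default 0.02).
#' @return List with `sweep` (data.frame ws, pcc, defined), `wsc_estimate`,
#'   and `plateau_pcc`.
#' @export
window_sweep <- function(model, features, ws_grid = c(0, 2, 4, 8, 16, 32, 64),
                         plateau_tol = 0.02) {
  if (is.unsorted(ws_grid, strictly = TRUE)) stop("ws_grid must be ascending")
  n <- nrow(features$X)
  actual <- features$y
  pccs <- rep(NA_real_, length(ws_grid))
  for (k in seq_along(ws_grid)) {
    pred <- vapply(seq_len(n), function(i)
      window_predict(model, features, i, ws_grid[k]), numeric(1))
    if (sd(pred) > 0) pccs[k] <- pearson_cc(pred, actual)
  }
  defined <- !is.na(pccs)
  plateau <- pccs[max(which(defined))]
  ok <- which(defined & pccs >= plateau - plateau_tol)
  list(sweep = data.frame(ws = ws_grid, pcc = pccs, defined = defined),
       wsc_estimate = ws_grid[min(ok)], plateau_pcc = plateau)
}

#' Predict one residue considering only atoms within a cutoff radius
#'
#' Implements the cutoff-radius probe: every residue whose C-alpha lies
#' farther than `rcut` (raw Angstrom coordinates, never the Z-scored ones)
#' from residue i is replaced by a null token. Under the default `"zero"`
#' convention all 28 feature slots of out-of-radius rows are zeroed while
#' the rows stay in place, so sequence distances are undisturbed; the
#' `"delete"` convention removes the rows instead (offered for
#' comparison, but it corrupts sequence distances). Residue i itself is
#' never masked.
#'
#' @param model A trained `bf_predictor`.
#' @param record The `protein_record` supplying raw coordinates.
#' @param features Encoding list or feature matrix for the record.
#' @param i Residue index.
#' @param rcut Cutoff radius in Angstrom, >= 0 (`Inf` masks nothing).
#' @param convention `"zero"` (default) or `"delete"`.
#' @param dist_mat Optional precomputed distance matrix.
#' @return Scalar prediction at residue i (model scale).
#' @export
masked_predict_rcut <- function(model, record, features, i, rcut,
                                convention = c("zero", "delete"),
                                dist_mat = NULL) {
  convention <- match.arg(convention)
  if (rcut < 0) stop("rcut must be >= 0")
  X <- if (is.list(features)) features$X else features
  if (is.null(dist_mat)) dist_mat <- site_distances(record)
  far <- dist_mat[i, ] > rcut
  far[i] <- FALSE
  if (convention == "zero") {
    Xm <- X
    Xm[far, ] <- 0
    predict_protein(model, Xm)[i]
  } else {
    keep <- which(!far)
    predict_protein(model, X[keep, , drop = FALSE])[match(i, keep)]
  }
}

#' Sweep the Euclidean cutoff radius over a set of proteins
#'
#' For each cutoff in `rcut_grid`, every residue of every record is
#' re-predicted with [masked_predict_rcut()]; the pooled Pearson
#' correlation against the actual profiles is reported as is and as a
#' ratio to the unmasked pooled PCC. `atoms_considered` counts the
#' ordered neighbor pairs (i, j), j != i, with distance <= rcut — the
#' information admitted at that cutoff; it grows with the cube of the
#' cutoff in the bulk regime of a dense globule.
#'
#' @param model A trained `bf_predictor`.
#' @param records List of `protein_record`s.
#' @param encodings Matching list of encodings.
#' @param rcut_grid Ascending numeric grid of cutoffs (Angstrom).
#' @param convention Masking convention, see [masked_predict_rcut()].
#' @return List with `sweep` (data.frame rcut, pcc, pcc_ratio,
#'   atoms_considered) and `pcc_all`.
#' @export
rcut_sweep <- function(model, records, encodings, rcut_grid,
                       convention = "zero") {
  if (is.unsorted(rcut_grid, strictly = TRUE))
    stop("rcut_grid must be ascending")
  dmats <- lapply(records, site_distances)
  actual <- unlist(lapply(encodings, `[[`, "y"))
  full <- unlist(lapply(encodings, function(e) predict_protein(model, e)))
  pcc_all <- pearson_cc(full, actual)
  pcc <- atoms <- numeric(length(rcut_grid))
  for (k in seq_along(rcut_grid)) {
    rc <- rcut_grid[k]
    preds <- unlist(lapply(seq_along(records), function(p) {
      n <- nrow(encodings[[p]]$X)
      vapply(seq_len(n), function(i)
        masked_predict_rcut(model, records[[p]], encodings[[p]], i, rc,
                            convention = convention, dist_mat = dmats[[p]]),
        numeric(1))
    }))
    pcc[k] <- pearson_cc(preds, actual)
    atoms[k] <- sum(vapply(dmats, function(d)
      sum(d <= rc) - nrow(d), numeric(1)))
  }
  list(sweep = data.frame(rcut = rcut_grid, pcc = pcc,
                          pcc_ratio = pcc / pcc_all,
                          atoms_considered = atoms),
       pcc_all = pcc_all)
}

#' Marginal contribution to PCC per admitted atom
#'
#' Differences a cutoff sweep: for consecutive grid points the change in
#' PCC is divided by the change in admitted neighbor pairs and reported at
#' the midpoint distance. Grid steps that admit no new pairs are skipped
#' and flagged. The stepwise PCC changes telescope to
#' PCC(last) - PCC(first) by construction.
#'
#' @param sweep Output of [rcut_sweep()].
#' @return `data.frame` with `deuc` (midpoint, Angstrom), `delta_pcc`,
#'   `delta_atoms`, `ratio`; skipped steps attached as the
#'   `skipped` attribute.
#' @export
delta_pcc_per_atom <- function(sweep) {
  s <- sweep$sweep
  if (nrow(s) < 2L) stop("need at least 2 grid points")
  d_pcc <- diff(s$pcc)
  d_atoms <- diff(s$atoms_considered)
  mid <- (s$rcut[-1] + s$rcut[-nrow(s)]) / 2
  keep <- d_atoms != 0
  if (!any(keep)) stop("no grid step admits any new atom pair")
  out <- data.frame(deuc = mid[keep], delta_pcc = d_pcc[keep],
                    delta_atoms = d_atoms[keep],
                    ratio = d_pcc[keep] / d_atoms[keep])
  attr(out, "skipped") <- mid[!keep]
  out
}

#' Normalized neighbor count
#'
#' For each residue, n_i counts the other C-alpha atoms within `rcut`
#' (raw coordinates), optionally restricted to sequence distance
#' `|i - j| <= ws`. The mean over residues, n_bar, is normalized by N - 1
#' to give n_hat in \[0, 1\]: 0 below the minimum pairwise distance, 1 once
#' the cutoff covers the whole protein (without a window restriction).
#'
#' @param record A `protein_record` with at least 2 residues.
#' @param rcut Cutoff radius, Angstrom.
#' @param ws Optional sequence-window restriction.
#' @return List with `rcut`, `ws`, `n_i`, `n_bar`, `n_hat`.
#' @export
nhat <- function(record, rcut, ws = NULL) {
  n <- n_residues(record)
  if (n < 2L) stop("need at least 2 residues")
  d <- site_distances(record)
  within <- d <= rcut
  diag(within) <- FALSE
  if (!is.null(ws)) {
    seq_d <- abs(outer(seq_len(n), seq_len(n), "-"))
    within <- within & seq_d <= ws
  }
  n_i <- unname(rowSums(within))
  n_bar <- mean(n_i)
  list(rcut = rcut, ws = ws, n_i = n_i, n_bar = n_bar,
       n_hat = n_bar / (n - 1))
}

#' Correlate neighbor-count growth with prediction-quality growth
#'
#' The cutoff-radius recovery analysis: for a candidate radius, the curve
#' n_hat(Ws; rcut) describes how quickly spatial neighbors are captured as
#' the sequence window widens; PCC(Ws) describes how quickly prediction
#' quality saturates. Their Pearson correlation, PCC_n, peaks (averaged
#' over proteins) near the radius within which atoms actually inform the
#' B factor.
#'
#' @param pcc_curves List (one per protein) of window-sweep results or
#'   data.frames with columns `ws` and `pcc`.
#' @param records Matching list of `protein_record`s.
#' @param rcut_grid Candidate cutoff radii, Angstrom.
#' @param ws_grid Window sizes the PCC curves were computed on (>= 2
#'   points).
#' @return List with `curve` (data.frame rcut, pccn_mean, n_proteins,
#'   n_excluded) and `peak_rcut` (argmax of the mean curve).
#' @export
pccn_vs_rcut <- function(pcc_curves, records, rcut_grid, ws_grid) {
  if (length(ws_grid) < 2L) stop("need at least 2 window sizes")
  curves <- lapply(pcc_curves, function(cv) {
    df <- if (is.data.frame(cv)) cv else cv$sweep
    df$pcc[match(ws_grid, df$ws)]
  })
  rows <- lapply(rcut_grid, function(rc) {
    vals <- c(); excluded <- 0L
    for (p in seq_along(records)) {
      nh <- vapply(ws_grid, function(w)
        nhat(records[[p]], rc, ws = w)$n_hat, numeric(1))
      pc <- curves[[p]]
      if (anyNA(pc) || sd(nh) == 0 || sd(pc) == 0) {
        excluded <- excluded + 1L
        next
      }
      vals <- c(vals, pearson_cc(nh, pc))
    }
    data.frame(rcut = rc,
               pccn_mean = if (length(vals)) mean(vals) else NA_real_,
               n_proteins = length(vals), n_excluded = excluded)
  })
  curve <- do.call(rbind, rows)
  ok <- which(!is.na(curve$pccn_mean))
  list(curve = curve,
       peak_rcut = curve$rcut[ok[which.max(curve$pccn_mean[ok])]])
}

#' Summarize normalized B factors by residue type or secondary structure
#'
#' Pools all residues of all records and reports, per group, the mean and
#' population SD of the actual and predicted Z-scored B factors, with
#' counts. Groups without members are omitted (listed in the `omitted`
#' attribute).
#'
#' @param records List of `protein_record`s.
#' @param encodings Matching encodings in normalized mode.
#' @param predictions Optional list of prediction vectors; computed from
#'   `model` if missing.
#' @param model Predictor used when `predictions` is missing.
#' @param group_by `"amino_acid"` or `"ss_class"`.
#' @return `data.frame` with `group`, `count`, `mean_actual`, `sd_actual`,
#'   `mean_predicted`, `sd_predicted`.
#' @export
group_summary <- function(records, encodings, predictions = NULL,
                          model = NULL,
                          group_by = c("amino_acid", "ss_class")) {
  group_by <- match.arg(group_by)
  if (any(vapply(encodings, `[[`, character(1), "b_mode") != "normalized"))
    stop("group summaries are defined on normalized B factors")
  if (is.null(predictions)) {
    if (is.null(model)) stop("provide predictions or a model")
    predictions <- lapply(encodings, function(e) predict_protein(model, e))
  }
  key <- unlist(lapply(records, function(r)
    if (group_by == "amino_acid") r$sites$aa_code else r$sites$ss_label))
  actual <- unlist(lapply(encodings, `[[`, "y"))
  pred <- unlist(predictions)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  groups <- sort(unique(key))
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- key == g
    data.frame(group = g, count = sum(sel),
               mean_actual = mean(actual[sel]), sd_actual = pop_sd(actual[sel]),
               mean_predicted = mean(pred[sel]),
               sd_predicted = pop_sd(pred[sel]), stringsAsFactors = FALSE)
  }))
  universe <- if (group_by == "amino_acid") unique(c(AA20, groups)) else SS3
  attr(out, "omitted") <- setdiff(universe, groups)
  out
}
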