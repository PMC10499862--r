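# Fixed slot layout of the 28-element per-residue feature vector:
#   1-21  amino-acid one-hot (20 canonical residues ordered alphabetically
#         by one-letter code, slot 21 = any other residue code)
#   22-24 secondary-structure one-hot in the order (sheet, helix, coil)
#   25-27 per-protein Z-scored x, y, z coordinates
#   28    chain start/end flag (1 at the first and last residue of a chain)

# canonical 20, alphabetical by one-letter code: A C D E F G H I K L M N P Q R S T V W Y
AA20 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS",
          "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL",
          "TRP", "TYR")
SS3 <- c("sheet", "helix", "coil")

#' Feature-group mask for ablation studies
#'
#' Selects which of the four feature groups are encoded: primary sequence
#' (PS, the amino-acid one-hot), secondary structure (SS), coordinate
#' information (CoI), and chain start/end information (ChI). Disabled
#' groups are written as zeros so the feature width stays 28 and one
#' architecture serves every ablation.
#'
#' @param use_ps,use_ss,use_coi,use_chi Logical flags; at least one must
#'   be `TRUE`.
#' @return A `feature_mask` object.
#' @export
feature_mask <- function(use_ps = TRUE, use_ss = TRUE, use_coi = TRUE,
                         use_chi = TRUE) {
  if (!any(use_ps, use_ss, use_coi, use_chi))
    stop("at least one feature group must be enabled")
  structure(list(use_ps = use_ps, use_ss = use_ss, use_coi = use_coi,
                 use_chi = use_chi), class = "feature_mask")
}

#' Per-protein normalization statistics
#'
#' Means and population standard deviations (divisor N, matching the
#' normalization formulas) of the B factors and of each coordinate axis,
#' computed over the record's own sites only.
#'
#' @param record A curated `protein_record`.
#' @return List with `mu_b`, `sigma_b`, `mu_x`, `mu_y`, `mu_z`, `sigma_x`,
#'   `sigma_y`, `sigma_z`.
#' @export
compute_norm_stats <- function(record) {
  s <- record$sites
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  st <- list(mu_b = mean(s$b_factor), sigma_b = pop_sd(s$b_factor),
             mu_x = mean(s$x), mu_y = mean(s$y), mu_z = mean(s$z),
             sigma_x = pop_sd(s$x), sigma_y = pop_sd(s$y),
             sigma_z = pop_sd(s$z))
  if (st$sigma_b == 0 || st$sigma_x == 0 || st$sigma_y == 0 ||
      st$sigma_z == 0)
    stop("degenerate protein: zero variance in B factors or a coordinate axis")
  st
}

#' Z-score normalize B factors within one protein
#'
#' B_hat_i = (B_i - mu_B) / sigma_B with the per-protein mean and
#' population SD, making flexibility profiles comparable across proteins
#' solved at different resolutions.
#'
#' @param record A `protein_record`.
#' @param stats Output of [compute_norm_stats()]; computed if missing.
#' @return Numeric vector of normalized (unitless) B factors.
#' @export
normalize_bfactors <- function(record, stats = compute_norm_stats(record)) {
  (record$sites$b_factor - stats$mu_b) / stats$sigma_b
}

#' Z-score normalize coordinates within one protein, per axis
#'
#' Each axis is centered and scaled by its own per-protein mean and
#' population SD. Scaling is anisotropic: raw Angstrom distances are not
#' preserved, which is why all Euclidean-distance analyses in this package
#' use raw coordinates.
#'
#' @inheritParams normalize_bfactors
#' @return N x 3 matrix of normalized coordinates.
#' @export
normalize_coordinates <- function(record, stats = compute_norm_stats(record)) {
  s <- record$sites
  cbind(x = (s$x - stats$mu_x) / stats$sigma_x,
        y = (s$y - stats$mu_y) / stats$sigma_y,
        z = (s$z - stats$mu_z) / stats$sigma_z)
}

#' Encode a protein as an N x 28 feature matrix plus regression targets
#'
#' Row i encodes residue i: a 21-slot amino-acid one-hot (slot 21 catches
#' non-canonical codes such as MSE), a 3-slot secondary-structure one-hot,
#' the three Z-scored coordinates, and the chain start/end flag. Feature
#' groups disabled in `mask` are identically zero. Targets are the
#' per-protein Z-scored B factors (`b_mode = "normalized"`) or the raw
#' deposited values divided by `raw_scale` for conditioning
#' (`b_mode = "unnormalized"`; undo with [denormalize_predictions()]).
#'
#' @param record A curated `protein_record`; secondary structure must be
#'   assigned when `mask$use_ss` is `TRUE`.
#' @param mask A [feature_mask()].
#' @param b_mode `"normalized"` or `"unnormalized"`.
#' @param raw_scale Fixed divisor applied to raw targets in unnormalized
#'   mode; defaults to 80, the curation ceiling, so targets stay in (0, 1].
#' @return List with `X` (N x 28 matrix), `y` (targets), `mask`, `b_mode`,
#'   `raw_scale`, `stats`, and `protein_id`.
#' @export
encode_protein <- function(record, mask = feature_mask(),
                           b_mode = c("normalized", "unnormalized"),
                           raw_scale = 80) {
  b_mode <- match.arg(b_mode)
  s <- record$sites
  n <- nrow(s)
  stats <- compute_norm_stats(record)
  X <- matrix(0, nrow = n, ncol = 28)
  if (mask$use_ps) {
    slot <- match(s$aa_code, AA20)
    slot[is.na(slot)] <- 21L
    X[cbind(seq_len(n), slot)] <- 1
  }
  if (mask$use_ss) {
    if (any(s$ss_label == "unassigned"))
      stop("secondary structure must be assigned before encoding with use_ss")
    X[cbind(seq_len(n), 21L + match(s$ss_label, SS3))] <- 1
  }
  if (mask$use_coi) X[, 25:27] <- normalize_coordinates(record, stats)
  if (mask$use_chi) {
    ends <- cumsum(rle(as.character(s$chain_id))$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    X[unique(c(starts, ends)), 28] <- 1
  }
  y <- if (b_mode == "normalized") normalize_bfactors(record, stats)
       else s$b_factor / raw_scale
  list(X = X, y = y, mask = mask, b_mode = b_mode, raw_scale = raw_scale,
       stats = stats, protein_id = record$protein_id)
}

#' Map model outputs back to the raw B-factor scale
#'
#' Inverts the target transform of [encode_protein()]: multiplies by
#' sigma_B and adds mu_B in normalized mode, or multiplies by `raw_scale`
#' in unnormalized mode. Pearson correlation is unaffected by this affine
#' map; the function exists for reporting predictions in Angstrom^2.
#'
#' @param pred Numeric vector of model outputs.
#' @param encoded The encoding (list) the protein was predicted from.
#' @return Numeric vector on the deposited B-factor scale.
#' @export
denormalize_predictions <- function(pred, encoded) {
  if (encoded$b_mode == "normalized")
    pred * encoded$stats$sigma_b + encoded$stats$mu_b
  else pred * encoded$raw_scale
}

#' Encode a list of records into a training manifest
#'
#' @param records List of curated `protein_record`s.
#' @param mask A [feature_mask()].
#' @param b_mode Target mode, see [encode_protein()].
#' @return List of encodings (one per record).
#' @export
encode_dataset <- function(records, mask = feature_mask(),
                           b_mode = "normalized") {
  lapply(records, encode_protein, mask = mask, b_mode = b_mode)
}

#' Serialize encodings as one JSON record per line
#'
#' @param encodings Output of [encode_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(encodings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (e in encodings) {
    rec <- list(protein_id = e$protein_id, n = nrow(e$X),
                mask = unclass(e$mask), b_mode = e$b_mode,
                values = as.vector(t(e$X)), targets = e$y)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path Manifest file path.
#' @return List of encodings with `X`, `y`, `mask`, `b_mode`, `protein_id`.
#' @export
read_manifest <- function(path) {
  lapply(readLines(path), function(ln) {
    rec <- jsonlite::fromJSON(ln)
    list(X = matrix(rec$values, nrow = rec$n, byrow = TRUE),
         y = rec$targets,
         mask = do.call(feature_mask, as.list(rec$mask)),
         b_mode = rec$b_mode, protein_id = rec$protein_id)
  })
}
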