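#' Construct a protein record of C-alpha residue sites
#'
#' A protein record is the package's central container: an ordered list of
#' C-alpha residue sites (one per residue, chains concatenated in file
#' order). Order matters — the sequence position of a site is its row index.
#'
#' @param protein_id Opaque identifier string.
#' @param sites `data.frame` with columns `aa_code` (three-letter residue
#'   name), `x`, `y`, `z` (C-alpha coordinates, Angstrom), `b_factor`
#'   (Angstrom^2, as deposited), `chain_id`, and `ss_label` (one of
#'   `"helix"`, `"sheet"`, `"coil"`, `"unassigned"`).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sites) {
  required <- c("aa_code", "x", "y", "z", "b_factor", "chain_id", "ss_label")
  if (!is.data.frame(sites) || !all(required %in% names(sites)))
    stop("sites must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  if (nrow(sites) < 1L) stop("a protein record needs at least one site")
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (!all(sites$ss_label %in% c("helix", "sheet", "coil", "unassigned")))
    stop("invalid ss_label")
  # sites of one chain must be contiguous
  r <- rle(as.character(sites$chain_id))$values
  if (anyDuplicated(r)) stop("sites of the same chain must be contiguous")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(protein_id = as.character(protein_id), sites = sites),
            class = "protein_record")
}

#' Number of residues in a protein record
#' @param record A `protein_record`.
#' @return Integer residue count N.
#' @export
n_residues <- function(record) nrow(record$sites)

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues, %d chain(s)\n",
              x$protein_id, n_residues(x),
              length(unique(x$sites$chain_id))))
  invisible(x)
}

#' Read C-alpha residue sites from a PDB file
#'
#' Extracts one site per C-alpha ATOM record, in file order. HETATM records
#' are ignored, only the first MODEL of a multi-model (NMR) file is read,
#' and alternate locations are resolved to the first-listed altloc of each
#' residue. B factors come from the fixed-column B-factor field and the
#' secondary-structure label is initialized to `"unassigned"` (see
#' [assign_secondary_structure()]).
#'
#' @param path Path to a PDB file.
#' @param protein_id Identifier to store; defaults to the file name without
#'   extension.
#' @return A [protein_record()].
#' @export
read_structure <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (is.null(protein_id))
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type == "ATOM" & a$elety == "CA", , drop = FALSE]
  if (nrow(a) == 0L) stop("no C-alpha ATOM records in ", path)
  # first-listed altloc per residue
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert))
  a <- a[!duplicated(key), , drop = FALSE]
  sites <- data.frame(
    aa_code  = as.character(a$resid),
    x = a$x, y = a$y, z = a$z,
    b_factor = a$b,
    chain_id = ifelse(is.na(a$chain), " ", as.character(a$chain)),
    ss_label = "unassigned",
    stringsAsFactors = FALSE)
  protein_record(protein_id, sites)
}

#' Write a protein record as a C-alpha-only PDB file
#'
#' Serializes one ATOM line per site in the standard fixed-column layout
#' (coordinates at 3 decimals, B factor at 2 decimals — the precision of
#' the format), with TER records between chains. Used by the synthetic
#' generator and as the round-trip partner of [read_structure()].
#'
#' @param record A `protein_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(record, path) {
  s <- record$sites
  lines <- character(0)
  serial <- 0L
  chains <- rle(as.character(s$chain_id))
  idx <- 1L
  for (ci in seq_along(chains$values)) {
    for (k in seq_len(chains$lengths[ci])) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, substr(s$aa_code[idx], 1, 3), substr(s$chain_id[idx], 1, 1),
        ((idx - 1L) %% 9999L) + 1L,
        s$x[idx], s$y[idx], s$z[idx], 1.00, s$b_factor[idx]))
      idx <- idx + 1L
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Curate a protein record with the standard rejection filters
#'
#' A protein is rejected when any C-alpha B factor exceeds `max_b`
#' (extreme values indicate experimental error), when any B factor is
#' non-positive (unphysical), when all B factors are exactly identical
#' (also unphysical), or when the protein is longer than `max_len`
#' residues. Every violated rule is reported, not just the first.
#'
#' Equality for the constant-B rule is exact: the deposited PDB field is
#' already quantized to 2 decimals, so no tolerance is applied.
#'
#' @param record A `protein_record`.
#' @param max_b Maximum allowed B factor, Angstrom^2. Default 80.
#' @param max_len Maximum allowed residue count. Default 500.
#' @return A list with `accepted` (logical) and `reasons` (character vector
#'   drawn from `b_above_max`, `b_nonpositive`, `b_constant`, `too_long`).
#' @export
curate_protein <- function(record, max_b = 80, max_len = 500) {
  b <- record$sites$b_factor
  reasons <- character(0)
  if (any(b > max_b)) reasons <- c(reasons, "b_above_max")
  if (any(b <= 0)) reasons <- c(reasons, "b_nonpositive")
  if (length(b) >= 1L && all(b == b[1L])) reasons <- c(reasons, "b_constant")
  if (n_residues(record) > max_len) reasons <- c(reasons, "too_long")
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Write a curation audit table
#'
#' @param records List of `protein_record`s.
#' @param path Output path for the tab-delimited audit
#'   (protein_id, accepted, reasons).
#' @param ... Passed to [curate_protein()].
#' @return The audit `data.frame`, invisibly.
#' @export
write_curation_report <- function(records, path, ...) {
  rows <- lapply(records, function(r) {
    d <- curate_protein(r, ...)
    data.frame(protein_id = r$protein_id, accepted = d$accepted,
               reasons = paste(d$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, rows)
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(audit)
}

#' Split protein ids into train / validation / test sets
#'
#' Deterministic for a fixed seed. Validation and test sizes are the
#' rounded fractions of the total; the remainder goes to train.
#'
#' @param ids Character vector of protein ids.
#' @param fractions Numeric length-3 vector (train, validation, test),
#'   nonnegative, summing to 1 within 1e-9.
#' @param seed Integer seed controlling the shuffle.
#' @return List with `train`, `validation`, `test`, and `seed`.
#' @export
split_dataset <- function(ids, fractions = c(0.92, 0.04, 0.04), seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 nonnegative numbers summing to 1")
  n <- length(ids)
  if (n < sum(fractions > 0))
    stop("fewer ids than nonzero partitions")
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  perm <- with_seed(seed, function() sample(ids))
  test <- perm[seq_len(n_test)]
  val <- perm[n_test + seq_len(n_val)]
  train <- perm[-seq_len(n_test + n_val)]
  if (n_test + n_val == 0) train <- perm
  list(train = train, validation = val, test = test, seed = as.integer(seed))
}
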