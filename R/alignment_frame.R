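#' Read a master (gapped) multiple sequence alignment from FASTA
#'
#' The master alignment places every superfamily member in one common
#' column frame; columns are 1-based.  All rows must have equal length;
#' the gap character is `"-"`.
#'
#' @param path Aligned FASTA file, one row per entry, names matching
#'   manifest `entry_id`s.
#' @return A `master_alignment` list: `rows` (named character vector of
#'   gapped sequences) and `n_columns`.
#' @export
read_master_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(aln),
                          sub("\\s.*$", "", names(aln)))
  master_alignment(rows)
}

#' Construct a master alignment from gapped sequences
#' @param rows Named character vector of equal-length gapped sequences.
#' @return A `master_alignment`.
#' @export
master_alignment <- function(rows) {
  if (length(rows) == 0L) stop("empty alignment")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by entry_id")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths")
  if (anyDuplicated(names(rows))) stop("duplicate entry_id rows")
  structure(list(rows = rows, n_columns = unname(widths[1])),
            class = "master_alignment")
}

#' @export
print.master_alignment <- function(x, ...) {
  cat(sprintf("<master_alignment> %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

# identity-style substitution matrix over amino-acid letters (incl. X):
# a sequence is reconciled against its own alignment row, so match/mismatch
# scoring suffices and no substitution matrix is warranted
.identity_submat <- function(match = 2L, mismatch = -1L) {
  letters26 <- LETTERS
  m <- matrix(mismatch, 26L, 26L, dimnames = list(letters26, letters26))
  diag(m) <- match
  m
}

#' Map a chain model's residues to master-alignment columns
#'
#' Reconciles the observed (built) sequence against the entry's own
#' alignment row: the observed sequence is globally aligned (match +2,
#' mismatch -1, gap open -5, gap extend -1) to the ungapped row sequence,
#' and the resulting residue-to-row-position map is composed with the
#' row-position-to-column map.  Because a structure's observed sequence
#' should essentially be a substring pattern of its own row, percent
#' identity over the aligned region must be at least `min_identity`
#' (default 95%) — failures signal a manifest/row mismatch.
#'
#' @param model A [chain_model()] (or a plain one-letter sequence string,
#'   in which case residue keys are 1..n with empty insertion codes).
#' @param row The entry's gapped alignment row.
#' @param min_identity Identity gate over the aligned region, in `[0,1]`.
#' @return A `column_map` data frame with columns `resno`, `icode`,
#'   `column` (1-based alignment column; `NA` where unmapped), carrying
#'   the `entry_id` as an attribute.  Mapped columns are strictly
#'   increasing and used at most once.
#' @export
map_to_alignment <- function(model, row, min_identity = 0.95) {
  if (is.character(model) && length(model) == 1L) {
    observed <- model
    keys <- data.frame(resno = seq_len(nchar(model)), icode = "",
                       stringsAsFactors = FALSE)
    entry_id <- NA_character_
  } else {
    observed <- extract_sequence(model)
    keys <- model$residues[, c("resno", "icode")]
    entry_id <- model$entry_id
  }
  row_chars <- strsplit(row, "", fixed = TRUE)[[1]]
  ungapped_pos <- which(row_chars != "-")
  ungapped <- paste(row_chars[ungapped_pos], collapse = "")
  if (nchar(ungapped) == 0L) stop("alignment row is all gaps")

  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(observed),
    subject = Biostrings::AAString(ungapped),
    type = "global",
    substitutionMatrix = .identity_submat(),
    gapOpening = 5, gapExtension = 1)

  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  asub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & asub != "-"
  if (!any(both)) stop("no aligned residues between sequence and row")
  ident <- sum(ap[both] == asub[both]) / sum(both)
  if (ident < min_identity)
    stop(sprintf(
      "sequence/alignment-row identity %.1f%% below %.1f%% for entry '%s': manifest row mismatch?",
      100 * ident, 100 * min_identity, entry_id))

  # walk the alignment once, composing residue -> row position -> column
  pi_ <- cumsum(ap != "-")    # observed residue index at each alignment pos
  si_ <- cumsum(asub != "-")  # ungapped-row index at each alignment pos
  column <- rep(NA_integer_, nchar(observed))
  column[pi_[both]] <- ungapped_pos[si_[both]]

  cm <- data.frame(resno = keys$resno, icode = keys$icode, column = column,
                   stringsAsFactors = FALSE)
  attr(cm, "entry_id") <- entry_id
  attr(cm, "identity") <- ident
  class(cm) <- c("column_map", "data.frame")
  cm
}

#' Write column maps as TSV
#' @param maps A list of `column_map`s (named by entry_id) or one map.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_column_maps <- function(maps, path) {
  if (inherits(maps, "column_map")) maps <- list(maps)
  tab <- do.call(rbind, lapply(maps, function(m) {
    data.frame(entry_id = attr(m, "entry_id"), resno = m$resno,
               icode = m$icode, column = m$column)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an ensemble coordinate tensor
#'
#' @param entry_ids Character vector of entry identifiers.
#' @param coords entries x columns x 3 array (Angstrom).
#' @param mask entries x columns logical occupancy matrix; `TRUE` exactly
#'   where a mapped residue with a C-alpha exists.
#' @return An `ensemble_matrix`.
#' @export
ensemble_matrix <- function(entry_ids, coords, mask) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L,
            is.matrix(mask), nrow(mask) == length(entry_ids),
            dim(coords)[1] == length(entry_ids),
            dim(coords)[2] == ncol(mask))
  if (anyDuplicated(entry_ids)) stop("duplicate entry ids")
  mask3 <- array(mask, dim = dim(coords))  # recycled along the xyz slab
  if (any(mask3 & !is.finite(coords)))
    stop("non-finite coordinates at occupied positions")
  structure(list(entry_ids = as.character(entry_ids), coords = coords,
                 mask = mask),
            class = "ensemble_matrix")
}

#' @export
print.ensemble_matrix <- function(x, ...) {
  cat(sprintf("<ensemble_matrix> %d entries x %d columns (%.1f%% occupied)\n",
              length(x$entry_ids), ncol(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Assemble the ensemble coordinate tensor from mapped chain models
#'
#' `coords[e, c, ]` holds the C-alpha of the residue of entry `e` mapped
#' to alignment column `c`; the occupancy mask is `TRUE` exactly there.
#'
#' @param models List of [chain_model()]s.
#' @param maps List of `column_map`s, one per model, in the same order.
#' @param aln The [master_alignment()] defining the column frame.
#' @return An [ensemble_matrix()].
#' @export
build_ensemble <- function(models, maps, aln) {
  if (length(models) == 0L) stop("empty model list")
  if (length(maps) != length(models))
    stop("need exactly one column map per model")
  n <- length(models)
  L <- aln$n_columns
  ids <- vapply(models, function(m) m$entry_id, character(1))
  arr <- array(NA_real_, dim = c(n, L, 3))
  mask <- matrix(FALSE, n, L)
  for (e in seq_len(n)) {
    cm <- maps[[e]]
    mapped <- !is.na(cm$column)
    cols <- cm$column[mapped]
    if (anyDuplicated(cols))
      stop("duplicate column claims for entry '", ids[e], "'")
    if (length(cols) && max(cols) > L)
      stop("column map exceeds alignment width for entry '", ids[e], "'")
    xyz <- coords(models[[e]])[mapped, , drop = FALSE]
    arr[e, cols, ] <- xyz
    mask[e, cols] <- TRUE
  }
  ensemble_matrix(ids, arr, mask)
}

#' Columns occupied by every entry
#'
#' The strict intersection (occupancy 1.0) mirrors "ungapped positions
#' across all representatives"; a relaxed threshold is available but
#' columns below full occupancy cannot enter fitting or PCA, which
#' require complete data.
#'
#' @param ens An [ensemble_matrix()].
#' @param occupancy Minimum fraction of entries occupying a column.
#' @return Ascending integer vector of columns.
#' @export
complete_columns <- function(ens, occupancy = 1.0) {
  if (length(ens$entry_ids) == 0L) stop("empty ensemble")
  frac <- colMeans(ens$mask)
  cols <- which(frac >= occupancy)
  if (length(cols) == 0L)
    stop("no common frame: no column reaches occupancy ", occupancy)
  cols
}

#' Subset an ensemble matrix to a set of entries
#' @param ens An [ensemble_matrix()].
#' @param entries Entry ids or integer indices to keep.
#' @return An [ensemble_matrix()] with the selected entries, in the
#'   requested order.
#' @export
subset_entries <- function(ens, entries) {
  idx <- if (is.character(entries)) match(entries, ens$entry_ids)
         else as.integer(entries)
  if (anyNA(idx)) stop("unknown entries requested")
  ensemble_matrix(ens$entry_ids[idx],
                  ens$coords[idx, , , drop = FALSE],
                  ens$mask[idx, , drop = FALSE])
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL per entry, residues numbered by alignment column, restricted
#' to columns every written entry occupies.
#'
#' @param ens An [ensemble_matrix()] (typically core-fitted).
#' @param path Output PDB path.
#' @param columns Columns to write; default the complete columns.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path, columns = NULL) {
  if (is.null(columns)) columns <- complete_columns(ens)
  .require_occupied(ens, columns)
  n <- length(ens$entry_ids)
  xyz <- t(vapply(seq_len(n), function(e)
    as.vector(t(ens$coords[e, columns, ])), numeric(3 * length(columns))))
  L <- length(columns)
  bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                   resno = columns, resid = rep("ALA", L),
                   elety = rep("CA", L), chain = rep("A", L))
  invisible(path)
}
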