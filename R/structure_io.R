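# Closed vocabularies used throughout the annotation layer.
.nucleotide_states <- c("NTP", "NTPa", "NDP", "apo", "other")
.assembly_states   <- c("polymerized", "unpolymerized", "special")

# One-letter codes for the 20 standard amino acids.
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa1to3 <- stats::setNames(names(.aa3to1), unname(.aa3to1))

#' Construct a per-chain C-alpha model
#'
#' A `chain_model` holds one subunit's ordered residues with their C-alpha
#' coordinates, keyed by author residue number plus insertion code (no
#' renumbering, so every position remains traceable to the deposition).
#'
#' @param entry_id Entry identifier (e.g. a PDB accession).
#' @param chain_id Chain identifier within the entry.
#' @param residues Data frame with columns `resno` (integer), `icode`
#'   (single character, `""` if absent), `resid` (three-letter residue
#'   name), `aa` (one-letter code) and `x`, `y`, `z` (Angstrom).
#' @param resolution Resolution in Angstrom, or `NA` if not applicable.
#' @param method One of `"x-ray"`, `"cryo-EM"`, `"NMR"`, `"other"`.
#' @return An object of class `chain_model`.
#' @export
chain_model <- function(entry_id, chain_id, residues,
                        resolution = NA_real_, method = "other") {
  stopifnot(is.character(entry_id), length(entry_id) == 1L,
            is.character(chain_id), length(chain_id) == 1L,
            is.data.frame(residues))
  need <- c("resno", "icode", "resid", "aa", "x", "y", "z")
  if (!all(need %in% names(residues)))
    stop("residues must have columns: ", paste(need, collapse = ", "))
  keys <- paste(residues$resno, residues$icode)
  if (anyDuplicated(keys))
    stop("duplicate residue keys (resno, icode) in '", entry_id, "'")
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (nrow(residues) > 0L && !all(is.finite(xyz)))
    stop("non-finite C-alpha coordinates in '", entry_id, "'")
  method <- match.arg(method, c("x-ray", "cryo-EM", "NMR", "other"))
  structure(
    list(entry_id = entry_id, chain_id = chain_id,
         residues = residues, resolution = as.numeric(resolution),
         method = method),
    class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("<chain_model> %s chain %s: %d residues",
              x$entry_id, x$chain_id, nrow(x$residues)))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A", x$resolution))
  cat(sprintf(" [%s]\n", x$method))
  invisible(x)
}

#' Number of residues in a chain model
#' @param x A `chain_model`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) nrow(x$residues)

#' C-alpha coordinates of a chain model
#' @param x A `chain_model`.
#' @return Numeric matrix, one row per residue, columns x/y/z (Angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x$residues[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Read one chain of a coordinate file into a C-alpha model
#'
#' Parses a PDB or mmCIF file (dispatched on extension: `.cif`/`.mmcif`
#' use the mmCIF reader, everything else the PDB reader) and extracts the
#' ordered C-alpha trace of one chain.  For multi-model (e.g. NMR) files
#' only the first model is kept; for alternate locations the highest
#' occupancy wins, ties broken by alphabetically first altloc identifier;
#' residues lacking a C-alpha atom are skipped.  Calcium ions (element Ca,
#' atom name "CA") are excluded.
#'
#' @param path Path to a PDB or mmCIF coordinate file.
#' @param entry_id Entry identifier to record.
#' @param chain_id Chain to extract.
#' @inheritParams chain_model
#' @return A [chain_model()].
#' @export
read_structure <- function(path, entry_id, chain_id,
                           resolution = NA_real_, method = "other") {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  chains <- sort(unique(at$chain))
  if (!chain_id %in% chains)
    stop("chain '", chain_id, "' not found in ", path,
         "; available chains: {", paste(chains, collapse = ", "), "}")
  at <- at[at$chain == chain_id & at$elety == "CA", , drop = FALSE]
  # drop calcium ions: element symbol CA (atom-name CA on residue CA)
  if (nrow(at) > 0L && "elesy" %in% names(at)) {
    ion <- !is.na(at$elesy) & toupper(trimws(at$elesy)) == "CA"
    at <- at[!ion, , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop("no C-alpha atoms for chain '", chain_id, "' in ", path)

  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$resno, at$icode)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(idx) {
    sub <- at[idx, , drop = FALSE]
    # highest occupancy; ties -> alphabetically first altloc id
    idx[order(-sub$o, sub$alt)][1L]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]

  residues <- data.frame(
    resno = at$resno,
    icode = at$icode,
    resid = at$resid,
    aa = unname(ifelse(at$resid %in% names(.aa3to1), .aa3to1[at$resid], "X")),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  chain_model(entry_id, chain_id, residues,
              resolution = resolution, method = method)
}

#' Write a chain model as a PDB file
#'
#' C-alpha-only PDB output; coordinates round-trip through the fixed-width
#' format to 1e-3 Angstrom.
#'
#' @param model A [chain_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(model, path) {
  r <- model$residues
  if (nrow(r) == 0L) stop("empty model")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(as.matrix(r[, c("x", "y", "z")]))),
    resno = r$resno,
    insert = ifelse(r$icode == "", NA, r$icode),
    resid = r$resid,
    elety = rep("CA", nrow(r)),
    chain = rep(model$chain_id, nrow(r)))
  invisible(path)
}

#' Extract the one-letter sequence of a chain model
#'
#' Nonstandard residues map to `"X"` by default; the mapping is
#' configurable (e.g. `c(MSE = "M")` to treat selenomethionine as Met).
#'
#' @param model A [chain_model()].
#' @param mapping Named character vector of extra three-letter to
#'   one-letter mappings, applied on top of the 20 standard residues.
#' @return Single string, one letter per residue in model order.
#' @export
extract_sequence <- function(model, mapping = NULL) {
  if (n_residues(model) == 0L) stop("empty model: no sequence to extract")
  tab <- .aa3to1
  if (!is.null(mapping)) tab[names(mapping)] <- unname(mapping)
  paste(unname(ifelse(model$residues$resid %in% names(tab),
                      tab[model$residues$resid], "X")),
        collapse = "")
}

#' Default ligand-code to nucleotide-state mapping
#'
#' ATP/GTP count as hydrolyzable triphosphate (`NTP`); the common
#' less/nonhydrolyzable analogs (AMPPNP, ATP-gamma-S, GMPPNP, GMPCPP,
#' GMPPCP as deposited code GCP, GTP-gamma-S, AMPPCP) as `NTPa`; ADP/GDP
#' as `NDP`.  Edit or extend to match local deposition conventions.
#'
#' @return Named character vector mapping three-letter component codes to
#'   nucleotide-state labels.
#' @export
nucleotide_code_table <- function() {
  c(ATP = "NTP", GTP = "NTP",
    ANP = "NTPa", AGS = "NTPa", GNP = "NTPa", GCP = "NTPa",
    GSP = "NTPa", ACP = "NTPa",
    ADP = "NDP", GDP = "NDP")
}

#' Classify the nucleotide state of an entry from its ligand codes
#'
#' Pure function of the code set (permutation-invariant, deterministic).
#' If codes from multiple classes are present the precedence is
#' NTP > NTPa > NDP.  An empty set is `apo`; codes absent from the table
#' fall through to `other`.
#'
#' @param ligand_codes Character vector of three-letter component codes
#'   (may be empty).
#' @param table Mapping of codes to states; see [nucleotide_code_table()].
#' @return One of `"NTP"`, `"NTPa"`, `"NDP"`, `"apo"`, `"other"`.
#' @export
classify_nucleotide <- function(ligand_codes, table = nucleotide_code_table()) {
  ligand_codes <- unique(toupper(trimws(ligand_codes)))
  ligand_codes <- ligand_codes[nzchar(ligand_codes)]
  if (length(ligand_codes) == 0L) return("apo")
  states <- unname(table[ligand_codes[ligand_codes %in% names(table)]])
  for (s in c("NTP", "NTPa", "NDP")) if (s %in% states) return(s)
  "other"
}

#' Classify the assembly (polymerization) state of an entry
#'
#' A state declared in the manifest always wins.  Without a declaration a
#' heuristic mirrors semiautomatic assignment from experimental technique:
#' entries whose method string indicates a filament reconstruction
#' (matching "filament" or "helical") are `polymerized`, everything else
#' `unpolymerized`.  The provenance of the call (declared vs heuristic) is
#' returned alongside the state so it can be logged and audited.
#'
#' @param declared Declared assembly state from the manifest, or `NA`.
#' @param method Experimental method string (free text), used only when no
#'   state is declared.
#' @return List with elements `state` (one of `"polymerized"`,
#'   `"unpolymerized"`, `"special"`) and `provenance` (`"declared"` or
#'   `"heuristic"`).
#' @export
classify_assembly <- function(declared = NA, method = NA) {
  if (!is.na(declared) && nzchar(trimws(declared))) {
    declared <- trimws(declared)
    if (!declared %in% .assembly_states)
      stop("assembly state '", declared, "' not in vocabulary {",
           paste(.assembly_states, collapse = ", "), "}")
    return(list(state = declared, provenance = "declared"))
  }
  state <- if (!is.na(method) &&
               grepl("filament|helical", method, ignore.case = TRUE))
    "polymerized" else "unpolymerized"
  list(state = state, provenance = "heuristic")
}

#' Read the entry manifest
#'
#' Tab-separated with header columns `entry_id`, `path`, `chain`,
#' `subfamily`, `ligands` (comma-separated three-letter codes, may be
#' empty), optional `nucleotide_state`, optional `assembly_state`,
#' `organism`, `resolution`, and optional `method`.  Relative structure
#' paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest TSV.
#' @return Data frame with one row per entry plus derived columns
#'   `nucleotide_state` (declared or classified from `ligands`),
#'   `assembly_state` and `assembly_provenance`.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("entry_id", "path", "chain", "subfamily", "ligands",
            "organism", "resolution")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$entry_id))
    stop("duplicate entry_id in manifest")
  if (!"nucleotide_state" %in% names(man)) man$nucleotide_state <- NA_character_
  if (!"assembly_state" %in% names(man)) man$assembly_state <- NA_character_
  if (!"method" %in% names(man)) man$method <- NA_character_
  man$resolution <- suppressWarnings(as.numeric(man$resolution))

  base <- dirname(path)
  abs <- grepl("^(/|[A-Za-z]:)", man$path)
  man$path[!abs] <- file.path(base, man$path[!abs])

  man$nucleotide_state <- vapply(seq_len(nrow(man)), function(i) {
    declared <- man$nucleotide_state[i]
    if (!is.na(declared) && nzchar(trimws(declared))) {
      declared <- trimws(declared)
      if (!declared %in% .nucleotide_states)
        stop("nucleotide state '", declared, "' not in vocabulary for entry ",
             man$entry_id[i])
      declared
    } else {
      codes <- strsplit(man$ligands[i], ",", fixed = TRUE)[[1]]
      classify_nucleotide(codes)
    }
  }, character(1))

  asm <- lapply(seq_len(nrow(man)), function(i)
    classify_assembly(man$assembly_state[i], man$method[i]))
  man$assembly_state <- vapply(asm, `[[`, character(1), "state")
  man$assembly_provenance <- vapply(asm, `[[`, character(1), "provenance")
  man
}
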