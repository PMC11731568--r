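# Structure reading and atom selection.
#
# Structures are parsed with bio3d (PDB and mmCIF) and normalised to a flat
# atom table; all downstream key generation consumes ordered selections
# extracted from that table.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a flat atom table.  All ATOM and HETATM
#' records are retained; waters are kept but flagged; alternate locations
#' are resolved to the highest-occupancy conformer (ties broken by the
#' alphabetically first altloc code).  Multi-model files use model 1 only.
#'
#' @param source A file path, or (for `format = "pdb"`) a character string
#'   containing PDB-format text.
#' @param format `"pdb"` or `"cif"`.
#' @param source_id Identifier stored in provenance; defaults to the file
#'   base name.
#' @return An object of class `tsr_structure`: a list with `atoms` (one
#'   row per atom: `serial`, `atom_name`, `element`, `res_name`,
#'   `res_seq`, `chain_id`, `x`, `y`, `z`, `altloc`, `occupancy`, `het`,
#'   `is_water`) and `source_id`.
#' @export
read_structure <- function(source, format = c("pdb", "cif"),
                           source_id = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1)
  is_path <- !grepl("\n", source) && file.exists(source)
  if (!is_path && format == "cif") {
    stop("mmCIF input must be given as a file path", call. = FALSE)
  }
  if (is_path) {
    path <- source
    if (is.null(source_id)) {
      source_id <- toupper(sub("\\.(pdb|ent|cif)$", "",
                               basename(path), ignore.case = TRUE))
    }
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
    if (is.null(source_id)) source_id <- "inline"
  }
  if (format == "pdb") validate_pdb_lines(path)
  parsed <- if (format == "pdb") {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  }
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("empty model: no ATOM/HETATM records in ", source_id,
         call. = FALSE)
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = normalize_element(at$elesy, at$elety, at$type),
    res_name = trimws(at$resid),
    res_seq = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", source_id, call. = FALSE)
  }
  atoms$is_water <- atoms$res_name %in% WATER_RESNAMES
  atoms <- resolve_altloc(atoms)
  structure(list(atoms = atoms, source_id = source_id),
            class = "tsr_structure")
}

# Fail early, naming the offending line, when a coordinate record cannot
# carry numeric coordinates (bio3d would silently coerce to NA).
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed coordinate line ", i, ": too short", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed coordinate line ", i,
           ": non-numeric coordinates", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Element symbol from the PDB element column when present, otherwise from
# the atom name: strip digits/primes, recognise common two-letter metal
# symbols on HETATM records, else take the first letter.
normalize_element <- function(elesy, elety, type) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  need <- el == ""
  if (any(need)) {
    nm <- toupper(gsub("[0-9']", "", trimws(elety[need])))
    two <- c("MG", "FE", "MN", "ZN", "CU", "NI", "CO", "NA", "CL", "BR", "SE")
    guess <- ifelse(type[need] == "HETATM" & nm %in% two,
                    nm, substr(nm, 1, 1))
    el[need] <- guess
  }
  el
}

# Keep the highest-occupancy conformer per (chain, res_seq, atom_name);
# ties go to the alphabetically first altloc code.  File order of the
# surviving atoms is preserved.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$res_name,
               atoms$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep_first <- !duplicated(key[ord])
  keep <- sort(seq_len(nrow(atoms))[ord][keep_first])
  atoms[keep, , drop = FALSE]
}

is_hydrogen <- function(atoms) atoms$element %in% c("H", "D")

new_selection <- function(atoms, mode, provenance) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, mode = mode, provenance = provenance),
            class = "tsr_selection")
}

#' @export
print.tsr_selection <- function(x, ...) {
  cat("tsr_selection [", x$mode, "] ", nrow(x$atoms), " atoms  (",
      paste(unlist(x$provenance), collapse = " "), ")\n", sep = "")
  invisible(x)
}

#' Number of atoms in a selection
#' @param x A `tsr_selection`.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Select the C-alpha trace of a chain
#'
#' One CA atom per standard residue, ordered by residue number.  Residues
#' lacking a CA atom are skipped with a warning.
#'
#' @param model A `tsr_structure`.
#' @param chain Chain identifier.
#' @param role Optional role tag stored in provenance (e.g. `"PsaA"`).
#' @return A `tsr_selection` with `mode = "CA"`.
#' @export
select_calpha <- function(model, chain, role = NULL) {
  at <- model$atoms
  prot <- at[!at$het & !at$is_water & at$chain_id == chain &
               at$res_name %in% STANDARD_AA, , drop = FALSE]
  if (nrow(prot) == 0) {
    stop("no standard protein residues in chain ", chain, call. = FALSE)
  }
  ca <- prot[prot$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) {
    stop("no CA atoms in chain ", chain, call. = FALSE)
  }
  missing <- setdiff(unique(prot$res_seq), ca$res_seq)
  if (length(missing) > 0) {
    warning(length(missing), " residue(s) without a CA atom skipped in ",
            "chain ", chain, call. = FALSE)
  }
  ca <- ca[order(ca$res_seq), , drop = FALSE]
  new_selection(ca, "CA", list(
    source_id = model$source_id, chain = chain,
    span = paste0(min(ca$res_seq), "-", max(ca$res_seq)),
    role = if (is.null(role)) paste0("chain_", chain) else role))
}

#' Select all heavy atoms of an annotated cofactor
#'
#' @param model A `tsr_structure`.
#' @param annotation One row of the cofactor annotation table (see
#'   [cofactor_annotations()]), or any list with `pdb_id`, `role`,
#'   `chain`, `res_seq`, `res_name`.
#' @return A `tsr_selection` with `mode = "COFACTOR"`; provenance carries
#'   the role tag.
#' @export
select_cofactor <- function(model, annotation) {
  ann <- as.list(annotation)
  at <- model$atoms
  hit <- at$chain_id == ann$chain & at$res_seq == ann$res_seq &
    !at$is_water
  if (!any(hit)) {
    stop("annotation row [", ann$pdb_id, " ", ann$role, " chain ",
         ann$chain, " ", ann$res_name, " ", ann$res_seq,
         "]: ligand not found in model", call. = FALSE)
  }
  lig <- at[hit, , drop = FALSE]
  if (!all(lig$res_name == ann$res_name)) {
    stop("annotation row [", ann$pdb_id, " ", ann$role, "]: residue ",
         ann$res_seq, " on chain ", ann$chain, " is ",
         unique(lig$res_name)[1], ", expected ", ann$res_name,
         call. = FALSE)
  }
  lig <- lig[!is_hydrogen(lig), , drop = FALSE]
  new_selection(lig, "COFACTOR", list(
    source_id = model$source_id, chain = ann$chain,
    span = paste0(ann$res_name, ann$res_seq), role = ann$role))
}

#' Select the heavy atoms of a single amino-acid residue
#'
#' @param model A `tsr_structure`.
#' @param chain Chain identifier.
#' @param res_seq Residue number.
#' @param role Optional role tag stored in provenance.
#' @return A `tsr_selection` with `mode = "AA"`.
#' @export
select_residue <- function(model, chain, res_seq, role = NULL) {
  at <- model$atoms
  hit <- at$chain_id == chain & at$res_seq == res_seq & !at$is_water
  if (!any(hit)) {
    stop("residue ", res_seq, " not found in chain ", chain, call. = FALSE)
  }
  res <- at[hit, , drop = FALSE]
  rn <- unique(res$res_name)[1]
  if (!rn %in% STANDARD_AA) {
    stop("residue ", chain, "/", res_seq, " (", rn, ") is not a standard ",
         "amino acid; use select_cofactor() for hetero ligands",
         call. = FALSE)
  }
  res <- res[!is_hydrogen(res), , drop = FALSE]
  new_selection(res, "AA", list(
    source_id = model$source_id, chain = chain,
    span = paste0(rn, res_seq),
    role = if (is.null(role)) paste0(rn, res_seq) else role))
}

#' Remove atoms by name from a selection
#'
#' Atom order is otherwise preserved; the operation is idempotent for a
#' fixed name set.  The packaged `"phytol_tail"` preset
#' ([atom_filter_preset()]) removes chlorophyll tail carbons C6..C20 so
#' that keys describe only the chlorin ring.
#'
#' @param selection A `tsr_selection`.
#' @param excluded_names Character vector of atom names to drop.
#' @return The filtered `tsr_selection`.
#' @export
filter_atoms <- function(selection, excluded_names) {
  keep <- !selection$atoms$atom_name %in% excluded_names
  if (!any(keep)) {
    stop("atom filter removed every atom of the selection", call. = FALSE)
  }
  selection$atoms <- selection$atoms[keep, , drop = FALSE]
  rownames(selection$atoms) <- NULL
  selection
}

#' Packaged photosystem I cofactor annotation table
#'
#' The chlorophyll chains, residue numbers, residue names and axial
#' ligands of the special pair (P700), accessory (A_-1), primary acceptor
#' (A_0) and connecting (A_C) chlorophylls for nine photosystem I
#' structures (1JB0, 5OY0, 6HQB, 6JO6, 6KMW, 6KMX, 6PNJ, 7COY, 5ZJI).
#'
#' Columns: `pdb_id`, `role` (P700_A, P700_B, A_-1A, A_-1B, A_0A, A_0B,
#' A_CA, A_CB), `chain`, `res_seq`, `res_name`, `axial_chain`,
#' `axial_res`, `axial_aa`.
#'
#' @param pdb_id Optional filter by accession.
#' @param role Optional filter by cofactor role.
#' @return A data frame, one row per annotated cofactor.
#' @export
cofactor_annotations <- function(pdb_id = NULL, role = NULL) {
  path <- system.file("extdata", "cofactor_annotations.tsv",
                      package = "tsrkeys", mustWork = TRUE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!is.null(pdb_id)) ann <- ann[ann$pdb_id %in% toupper(pdb_id), ]
  if (!is.null(role)) ann <- ann[ann$role %in% role, ]
  rownames(ann) <- NULL
  ann
}

#' Write a selection as a minimal PDB fragment
#'
#' @param selection A `tsr_selection` or `tsr_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_pdb <- function(selection, path) {
  atoms <- selection$atoms
  if (is.null(atoms) || nrow(atoms) == 0) {
    stop("nothing to write", call. = FALSE)
  }
  if (is.null(atoms$het)) atoms$het <- FALSE
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    pdb_atom_line(if (isTRUE(a$het)) "HETATM" else "ATOM",
                  a$serial, a$atom_name, a$res_name, a$chain_id,
                  a$res_seq, a$x, a$y, a$z,
                  if (is.null(a$occupancy)) 1 else a$occupancy,
                  a$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Fixed-column PDB coordinate record.
pdb_atom_line <- function(rec, serial, name, resn, chain, resno,
                          x, y, z, occ = 1, element = "") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, as.integer(serial), nm, resn, chain, as.integer(resno),
          x, y, z, occ, 0, element)
}
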