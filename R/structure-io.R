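#' Read a macromolecular structure from a PDB file
#'
#' Parses `ATOM` records of a PDB file into a tidy atom table, one row per
#' atom. `HETATM` records (waters, ligands, ions) are dropped, only the first
#' `MODEL` block of multi-model files is kept, and author residue numbering is
#' preserved verbatim — residue numbers are the coordinate system used by
#' site-definition tables, so `E1213` in an annotation refers to author residue
#' 1213, never to a sequential index.
#'
#' @param path Path to a PDB file containing at least one `ATOM` record.
#' @param altloc_policy How to resolve alternate-location conformers:
#'   `"first"` (default) keeps the first conformer encountered for each atom,
#'   `"highest_occupancy"` keeps the conformer with the largest occupancy.
#' @param id Structure label; defaults to the file name without extension.
#'
#' @return A tibble of class `dicer_structure` with one row per atom and
#'   columns `chain`, `resno` (author residue number), `ins` (insertion code,
#'   `""` when absent), `aa` (one-letter amino-acid code, `"X"` for
#'   non-standard residues), `atom` (atom name, e.g. `"CA"`), `elem`, `x`,
#'   `y`, `z` (Å), `o` (occupancy) and `b` (B-factor, Å²). The structure id
#'   and source path are carried in attributes `id` and `source`.
#'
#' @examples
#' pdb <- system.file("extdata", "scaffold_dmel_synthetic.pdb",
#'                    package = "dicerruler")
#' str <- read_structure(pdb)
#' dplyr::count(str, chain)
#' @export
read_structure <- function(path, altloc_policy = c("first", "highest_occupancy"),
                           id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    stop_dicer(paste0("cannot read PDB file: '", path, "' does not exist"), "io")
  }
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^ATOM  ", lines)
  if (length(atom_idx) == 0L) {
    stop_dicer(paste0("no ATOM records in '", path, "'"), "empty_structure")
  }
  check_atom_records(lines, atom_idx)

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop_dicer(
      paste0("failed to parse '", path, "': ", conditionMessage(e)), "parse")
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(at, .data$type == "ATOM")
  if (nrow(at) == 0L) {
    stop_dicer(paste0("no ATOM records in '", path, "'"), "empty_structure")
  }

  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)

  # altloc resolution: one conformer per (chain, resno, ins, atom name)
  at <- dplyr::group_by(at, .data$chain, .data$resno, .data$insert, .data$elety)
  at <- if (altloc_policy == "first") {
    dplyr::slice_head(at, n = 1L)
  } else {
    dplyr::slice_max(at, .data$o, n = 1L, with_ties = FALSE)
  }
  at <- dplyr::arrange(dplyr::ungroup(at), .data$eleno)

  out <- tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    ins   = at$insert,
    aa    = aa3_to1(at$resid),
    atom  = at$elety,
    elem  = ifelse(is.na(at$elesy), "", at$elesy),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b)
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    bad <- which(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))[1]
    stop_dicer(paste0("non-finite coordinates in '", path, "' (atom ", bad, ")"),
               "parse")
  }
  new_structure(out, id = id %||% sub("\\.[^.]*$", "", basename(path)),
                source = path)
}

# Coordinate fields must be fixed-width parseable; report the offending line.
check_atom_records <- function(lines, atom_idx) {
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop_dicer(paste0("malformed ATOM record at line ", i,
                        ": record shorter than coordinate fields"), "parse")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop_dicer(paste0("malformed ATOM record at line ", i,
                        ": non-numeric coordinate field"), "parse")
    }
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26))))) {
      stop_dicer(paste0("malformed ATOM record at line ", i,
                        ": non-integer residue number"), "parse")
    }
  }
  invisible(TRUE)
}

new_structure <- function(tbl, id = "structure", source = NA_character_) {
  tbl <- as_tibble(tbl)
  structure(tbl,
            class = c("dicer_structure", class(tbl)),
            id = id, source = source)
}

#' @export
print.dicer_structure <- function(x, ...) {
  cat("<dicer_structure> id:", attr(x, "id") %||% "?",
      "|", nrow(x), "atoms,",
      nrow(dplyr::distinct(as_tibble(x), .data$chain, .data$resno, .data$ins)),
      "residues\n")
  NextMethod()
}

structure_id <- function(s) attr(s, "id") %||% "structure"

aa3_to1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !(out %in% AA1)] <- "X"
  out
}

aa1_to3 <- function(aa) {
  out <- suppressWarnings(bio3d::aa123(aa))
  out[is.na(out) | aa == "X"] <- "UNK"
  out
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width `ATOM` records (coordinates to 3 decimals, author residue
#' numbering preserved) terminated by `END`. Round-tripping through
#' [read_structure()] preserves chain IDs, residue numbers, atom names and
#' coordinates to 3 decimal places.
#'
#' @param structure A `dicer_structure` atom table (see [read_structure()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0L) {
    stop_dicer("cannot write an empty structure", "empty_structure")
  }
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_dicer(paste0("cannot write to '", path, "'"), "io")
  xyz <- as.numeric(t(as.matrix(structure[, c("x", "y", "z")])))
  tryCatch(
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                     resno = structure$resno,
                     chain = ifelse(structure$chain == "", " ", structure$chain),
                     insert = ifelse(structure$ins == "", "", structure$ins),
                     resid = aa1_to3(structure$aa),
                     elety = structure$atom,
                     elesy = ifelse(structure$elem == "",
                                    substr(structure$atom, 1, 1),
                                    structure$elem),
                     o = structure$o, b = structure$b),
    error = function(e) stop_dicer(
      paste0("cannot write to '", path, "': ", conditionMessage(e)), "io")
  )
  invisible(path)
}

#' Select named atoms as a coordinate set
#'
#' Extracts atoms by name — by default the alpha carbons (`"CA"`) on which all
#' superposition and centroid geometry operates — optionally restricted to a
#' set of residues. Order follows structure (file) order.
#'
#' @param structure A `dicer_structure` atom table.
#' @param atom_name Atom name to select (default `"CA"`).
#' @param residues Optional data frame with columns `chain` and `resno`
#'   restricting the selection to those residues.
#' @return A tibble with columns `chain`, `resno`, `ins`, `atom`, `x`, `y`,
#'   `z` — a labelled N×3 coordinate set.
#' @export
select_atoms <- function(structure, atom_name = "CA", residues = NULL) {
  if (nrow(structure) == 0L) {
    stop_dicer("structure is empty", "empty_structure")
  }
  out <- dplyr::filter(as_tibble(structure), .data$atom == atom_name)
  if (!is.null(residues)) {
    keys <- dplyr::distinct(as_tibble(residues)[, c("chain", "resno")])
    out <- dplyr::semi_join(out, keys, by = c("chain", "resno"))
  }
  if (nrow(out) == 0L) {
    stop_dicer(paste0("no atoms named '", atom_name, "' match the selection"),
               "empty_selection")
  }
  out[, c("chain", "resno", "ins", "atom", "x", "y", "z")]
}

coords_matrix <- function(coordset) {
  unname(as.matrix(coordset[, c("x", "y", "z")]))
}
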