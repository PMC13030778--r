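#' Read a functional-site definition table
#'
#' Site tables give, per structure, the residues defining the four caliper
#' sites of Dicer-2: the two RNase III catalytic centers (`RIII_A`, `RIII_B`)
#' and the PAZ 3'/5' terminal-nucleotide binding pockets (`pocket_3prime`,
#' `pocket_5prime`). The file is TSV with columns `structure_id`, `site_name`,
#' `chain_id`, `residue_number`, `expected_aa`; a `"?"` in `residue_number`
#' marks an entry that could not be assigned in the ortholog alignment and is
#' excluded from geometry. Lines starting with `#` are comments.
#'
#' The packaged fixture `table1_sites.tsv` transcribes the published
#' catalytic/pocket residue assignments for five insect Dicer-2 orthologs
#' (D. melanogaster reference plus T. castaneum, B. terrestris, L. migratoria,
#' T. ni), unresolved entries included.
#'
#' @param path Path to a TSV site file.
#' @return A tibble of class `site_map` with columns `structure_id`, `site`
#'   (one of the four canonical names), `chain`, `resno` (integer, `NA` when
#'   unresolved), `expected_aa` and `resolved` (logical).
#' @examples
#' sites <- read_sites(system.file("extdata", "table1_sites.tsv",
#'                                 package = "dicerruler"))
#' dplyr::count(sites, structure_id, site)
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) {
    stop_dicer(paste0("site file '", path, "' does not exist"), "io")
  }
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c("structure_id", "site_name", "chain_id", "residue_number",
              "expected_aa")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_dicer(paste0("site file missing column(s): ",
                      paste(missing_cols, collapse = ", ")), "parse")
  }
  bad <- setdiff(unique(raw$site_name), RULER_SITES)
  if (length(bad) > 0) {
    stop_dicer(paste0("unknown site_name: ", paste(bad, collapse = ", "),
                      " (expected ", paste(RULER_SITES, collapse = ", "), ")"),
               "parse")
  }
  resno <- suppressWarnings(as.integer(raw$residue_number))
  unresolved <- raw$residue_number == "?"
  if (any(is.na(resno) & !unresolved)) {
    stop_dicer("residue_number must be an integer or '?'", "parse")
  }
  out <- new_site_map(tibble(
    structure_id = raw$structure_id,
    site = raw$site_name,
    chain = raw$chain_id,
    resno = ifelse(unresolved, NA_integer_, resno),
    expected_aa = raw$expected_aa,
    resolved = !unresolved
  ))
  dup <- dplyr::count(dplyr::filter(out, .data$resolved),
                      .data$structure_id, .data$site, .data$chain, .data$resno)
  if (any(dup$n > 1)) {
    d <- dup[dup$n > 1, ][1, ]
    stop_dicer(paste0("duplicate site entry: ", d$structure_id, " ", d$site,
                      " ", d$chain, d$resno), "parse")
  }
  out
}

new_site_map <- function(tbl) {
  tbl <- as_tibble(tbl)
  class(tbl) <- unique(c("site_map", class(tbl)))
  tbl
}

#' Write a site table to TSV
#'
#' Inverse of [read_sites()]; unresolved entries are written back as `"?"`.
#'
#' @param sites A `site_map` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  out <- tibble(
    structure_id = sites$structure_id,
    site_name = sites$site,
    chain_id = sites$chain,
    residue_number = ifelse(sites$resolved, as.character(sites$resno), "?"),
    expected_aa = sites$expected_aa
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Packaged site and distance fixtures
#'
#' Convenience accessors for the packaged reference tables: the Dicer-2
#' catalytic/pocket residue assignments (`dicer2_sites()`) and the published
#' per-species caliper distances with reported means and siRNA length classes
#' (`dicer2_distances()`).
#'
#' @return `dicer2_sites()`: a `site_map` tibble (see [read_sites()]).
#'   `dicer2_distances()`: a tibble with columns `structure_id`, `species`,
#'   `d_3p_riiia`, `d_5p_riiib` (Å), `reported_mean` (Å) and `reported_nt`.
#' @export
dicer2_sites <- function() {
  read_sites(system.file("extdata", "table1_sites.tsv", package = "dicerruler"))
}

#' @rdname dicer2_sites
#' @export
dicer2_distances <- function() {
  readr::read_tsv(system.file("extdata", "table2_distances.tsv",
                              package = "dicerruler"),
                  comment = "#",
                  col_types = readr::cols(
                    structure_id = readr::col_character(),
                    species = readr::col_character(),
                    .default = readr::col_double()))
}

#' Check a site table against a structure
#'
#' Reports, without raising, every resolved site entry whose residue is absent
#' from the structure or whose amino acid differs from the expected one-letter
#' code. An empty result means the annotation and the structure agree.
#'
#' @param sites A `site_map` tibble (one structure's rows).
#' @param structure A `dicer_structure` atom table.
#' @return A tibble with columns `site`, `chain`, `resno`, `expected_aa`,
#'   `found_aa` and `problem` (`"absent_residue"` or `"identity_mismatch"`);
#'   zero rows when fully consistent.
#' @export
validate_map <- function(sites, structure) {
  res <- dplyr::distinct(as_tibble(structure),
                         .data$chain, .data$resno, .data$aa)
  entries <- dplyr::filter(as_tibble(sites), .data$resolved)
  checked <- dplyr::left_join(entries, res, by = c("chain", "resno"))
  out <- dplyr::mutate(
    checked,
    found_aa = .data$aa,
    problem = dplyr::case_when(
      is.na(.data$aa) ~ "absent_residue",
      .data$expected_aa != "?" & .data$aa != .data$expected_aa ~
        "identity_mismatch",
      TRUE ~ NA_character_
    )
  )
  out <- dplyr::filter(out, !is.na(.data$problem))
  out[, c("site", "chain", "resno", "expected_aa", "found_aa", "problem")]
}

# All four caliper sites need >=1 resolved entry for the ruler to run.
check_ruler_sites <- function(sites) {
  have <- unique(sites$site[sites$resolved])
  missing <- setdiff(RULER_SITES, have)
  if (length(missing) > 0) {
    stop_dicer(paste0("site(s) without resolved entries: ",
                      paste(missing, collapse = ", ")), "missing_site")
  }
  invisible(TRUE)
}
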