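#' Pair corresponding alpha-carbon atoms of two structures
#'
#' Builds two equally sized, order-matched Cα coordinate sets for
#' superposition. By default residues are matched on `(chain, resno, ins)`;
#' an explicit correspondence table (e.g. from [site_pairs()] or an
#' alignment's [tidy()] output joined to author numbering) overrides this for
#' structures that do not share numbering. Residues missing the selected atom
#' in either structure are dropped from both sets.
#'
#' @param ref,tgt `dicer_structure` atom tables.
#' @param pairs Optional correspondence tibble with columns `ref_chain`,
#'   `ref_resno`, `tgt_chain`, `tgt_resno`.
#' @param atom_name Atom to pair (default `"CA"`).
#' @return A list with order-matched coordinate-set tibbles `ref` and `tgt`
#'   (see [select_atoms()]).
#' @export
pair_common_calpha <- function(ref, tgt, pairs = NULL, atom_name = "CA") {
  ref_ca <- dplyr::filter(as_tibble(ref), .data$atom == atom_name)
  tgt_ca <- dplyr::filter(as_tibble(tgt), .data$atom == atom_name)
  if (is.null(pairs)) {
    joined <- dplyr::inner_join(
      ref_ca, tgt_ca,
      by = c("chain", "resno", "ins"), suffix = c("_ref", "_tgt"))
    if (nrow(joined) < 3) {
      stop_dicer("fewer than 3 paired C-alpha atoms between structures",
                 "too_few_pairs")
    }
    ref_set <- tibble(chain = joined$chain, resno = joined$resno,
                      ins = joined$ins, atom = atom_name,
                      x = joined$x_ref, y = joined$y_ref, z = joined$z_ref)
    tgt_set <- tibble(chain = joined$chain, resno = joined$resno,
                      ins = joined$ins, atom = atom_name,
                      x = joined$x_tgt, y = joined$y_tgt, z = joined$z_tgt)
    return(list(ref = ref_set, tgt = tgt_set))
  }
  pairs <- as_tibble(pairs)
  a <- dplyr::inner_join(pairs, ref_ca,
                         by = c(ref_chain = "chain", ref_resno = "resno"))
  a <- dplyr::rename(a, x_ref = "x", y_ref = "y", z_ref = "z")
  a <- dplyr::inner_join(a, tgt_ca,
                         by = c(tgt_chain = "chain", tgt_resno = "resno"))
  if (nrow(a) < 3) {
    stop_dicer("fewer than 3 paired C-alpha atoms between structures",
               "too_few_pairs")
  }
  list(
    ref = tibble(chain = a$ref_chain, resno = a$ref_resno, ins = "",
                 atom = atom_name, x = a$x_ref, y = a$y_ref, z = a$z_ref),
    tgt = tibble(chain = a$tgt_chain, resno = a$tgt_resno, ins = "",
                 atom = atom_name, x = a$x, y = a$y, z = a$z)
  )
}

#' Residue correspondence implied by two site maps
#'
#' Order-pairs the resolved entries of each caliper site between a reference
#' and a target annotation, giving a Cα correspondence usable by
#' [pair_common_calpha()] for ortholog structures whose author numbering
#' differs.
#'
#' @param ref_sites,tgt_sites `site_map` tibbles for the two structures.
#' @return A tibble with columns `site`, `ref_chain`, `ref_resno`,
#'   `tgt_chain`, `tgt_resno`.
#' @export
site_pairs <- function(ref_sites, tgt_sites) {
  pick <- function(s) {
    s <- dplyr::filter(as_tibble(s), .data$resolved)
    s <- dplyr::group_by(s, .data$site)
    s <- dplyr::mutate(s, k = dplyr::row_number())
    dplyr::ungroup(s)
  }
  r <- pick(ref_sites)
  t <- pick(tgt_sites)
  j <- dplyr::inner_join(r, t, by = c("site", "k"), suffix = c("_ref", "_tgt"))
  tibble(site = j$site,
         ref_chain = j$chain_ref, ref_resno = j$resno_ref,
         tgt_chain = j$chain_tgt, tgt_resno = j$resno_tgt)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the mobile
#' set `Q` onto the reference set `P`, by the closed-form SVD solution with
#' determinant correction (reflections are never returned, even for
#' chirality-breaking inputs).
#'
#' @param P,Q Coordinate-set tibbles (see [select_atoms()]) or N×3 matrices,
#'   equally sized with N ≥ 3 non-collinear points, row i of `P`
#'   corresponding to row i of `Q`.
#' @return An object of class `superposition`: list with `rotation` (3×3,
#'   det +1), `translation` (length 3), `rmsd` (Å, the minimized value),
#'   `n_atoms`, and `per_domain` (`NULL` unless filled by
#'   [superpose_structures()]). The fitted map is `q %*% t(rotation) +
#'   translation`, applied by [apply_transform()].
#' @export
kabsch <- function(P, Q) {
  Pm <- if (is.matrix(P)) P else coords_matrix(P)
  Qm <- if (is.matrix(Q)) Q else coords_matrix(Q)
  if (nrow(Pm) != nrow(Qm)) {
    stop_dicer("coordinate sets differ in size", "size_mismatch")
  }
  n <- nrow(Pm)
  if (n < 3) stop_dicer("need at least 3 paired atoms", "too_few_pairs")
  pbar <- colMeans(Pm)
  qbar <- colMeans(Qm)
  Pc <- sweep(Pm, 2, pbar)
  Qc <- sweep(Qm, 2, qbar)
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(pbar - R %*% qbar)
  resid <- Pc - Qc %*% t(R)
  out <- list(rotation = R, translation = tr,
              rmsd = sqrt(mean(rowSums(resid^2))),
              n_atoms = n, per_domain = NULL)
  class(out) <- "superposition"
  out
}

#' Apply a fitted rigid transform
#'
#' @param x A `dicer_structure` or coordinate-set tibble with `x`, `y`, `z`.
#' @param fit A `superposition` object from [kabsch()].
#' @return `x` with transformed coordinates.
#' @export
apply_transform <- function(x, fit) {
  m <- as.matrix(as_tibble(x)[, c("x", "y", "z")])
  m2 <- sweep(m %*% t(fit$rotation), 2, fit$translation, `+`)
  x$x <- m2[, 1]
  x$y <- m2[, 2]
  x$z <- m2[, 3]
  x
}

#' RMSD of a residue subset under the global transform
#'
#' Computes the RMSD of the selected atoms under the *global* superposition
#' (no refit), so that per-domain values decompose the global fit rather than
#' re-optimizing each domain.
#'
#' @param P,Q Order-matched coordinate-set tibbles (as produced by
#'   [pair_common_calpha()]); subsetting uses the labels of `P`.
#' @param fit The global `superposition` from [kabsch()].
#' @param span A one-row data frame (or list) with `chain`, `start`, `end`
#'   selecting residues `start..end` of `chain` in `P`'s labelling, or `NULL`
#'   for all atoms.
#' @return RMSD in Å.
#' @export
rmsd_subset <- function(P, Q, fit, span = NULL) {
  idx <- if (is.null(span)) {
    seq_len(nrow(P))
  } else {
    which(P$chain == span$chain & P$resno >= span$start & P$resno <= span$end)
  }
  if (length(idx) == 0) {
    stop_dicer("domain span selects no paired atoms", "empty_selection")
  }
  Qt <- apply_transform(Q[idx, , drop = FALSE], fit)
  d2 <- (P$x[idx] - Qt$x)^2 + (P$y[idx] - Qt$y)^2 + (P$z[idx] - Qt$z)^2
  sqrt(mean(d2))
}

#' Read domain spans from TSV
#'
#' Columns: `name`, `chain`, `start`, `end` (author numbering, inclusive),
#' one row per contiguous range; a domain may span several rows.
#'
#' @param path TSV file path.
#' @return A tibble of domain spans.
#' @export
read_domains <- function(path) {
  d <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    name = readr::col_character(), chain = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer()))
  if (any(d$start > d$end)) {
    stop_dicer("domain span with start > end", "parse")
  }
  d
}

#' Superpose two structures with optional per-domain RMSD
#'
#' One-call wrapper: pairs common Cα atoms, runs [kabsch()], and — when domain
#' spans are given — decomposes the global fit into per-domain RMSDs (helicase,
#' PAZ, RNase III regions in the Dicer-2 analysis).
#'
#' @inheritParams pair_common_calpha
#' @param domains Optional domain-span tibble (see [read_domains()]).
#' @return A `superposition` object whose `per_domain` slot is a tibble
#'   `(name, n_atoms, rmsd)` when `domains` is given.
#' @export
superpose_structures <- function(ref, tgt, pairs = NULL, domains = NULL,
                                 atom_name = "CA") {
  sets <- pair_common_calpha(ref, tgt, pairs = pairs, atom_name = atom_name)
  fit <- kabsch(sets$ref, sets$tgt)
  if (!is.null(domains)) {
    per <- purrr::map(split(as_tibble(domains), domains$name), function(dd) {
      idx <- integer(0)
      for (i in seq_len(nrow(dd))) {
        idx <- union(idx, which(sets$ref$chain == dd$chain[i] &
                                  sets$ref$resno >= dd$start[i] &
                                  sets$ref$resno <= dd$end[i]))
      }
      if (length(idx) == 0) {
        return(tibble(n_atoms = 0L, rmsd = NA_real_))
      }
      Qt <- apply_transform(sets$tgt[idx, , drop = FALSE], fit)
      d2 <- (sets$ref$x[idx] - Qt$x)^2 + (sets$ref$y[idx] - Qt$y)^2 +
        (sets$ref$z[idx] - Qt$z)^2
      tibble(n_atoms = length(idx), rmsd = sqrt(mean(d2)))
    })
    fit$per_domain <- dplyr::bind_rows(per, .id = "name")
  }
  fit
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd:", format(x$rmsd, digits = 4), "A over",
      x$n_atoms, "atoms\n")
  if (!is.null(x$per_domain)) print(x$per_domain)
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  global <- tibble(name = "global", n_atoms = x$n_atoms, rmsd = x$rmsd)
  if (is.null(x$per_domain)) global else dplyr::bind_rows(global, x$per_domain)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
         det_rotation = det(x$rotation))
}

#' Write a rigid transform as a homogeneous matrix JSON
#'
#' @param fit A `superposition` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(fit, path) {
  m <- rbind(cbind(fit$rotation, fit$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = m, rmsd = fit$rmsd, n_atoms = fit$n_atoms),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
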