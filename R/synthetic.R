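# Seeded random proper rotation: QR of a Gaussian matrix, det-corrected.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Generate a two-domain caliper scaffold with known ruler distances
#'
#' Builds a poly-alanine-style ground-truth structure for the ruler analysis:
#' four labelled residue clusters (the two RNase III catalytic centers and the
#' two PAZ pockets) whose Cα centroids sit at exactly the requested pairwise
#' distances before noise, plus decoy residues as realistic bulk for parsers
#' and selectors. Gaussian coordinate noise (the stand-in for rotamer and
#' modeling variability) and a random rigid placement are then applied, both
#' seeded. Because Euclidean distances are rigid-invariant, the random
#' placement never changes the measured ruler.
#'
#' @param structure_id Label for the generated structure.
#' @param d_3p_riiia Target 3' pocket ↔ RNase III A centroid distance (Å).
#' @param d_5p_riiib Target 5' pocket ↔ RNase III B centroid distance (Å).
#' @param residues_per_site Residues per site cluster (≥ 1, default 4).
#' @param site_cluster_radius Cluster radius in Å (default 2.0); targets must
#'   exceed twice this radius for a feasible geometry.
#' @param noise_sigma Gaussian noise SD per coordinate in Å (default 0).
#' @param decoy_residues Number of filler residues (default 50, < 700 so decoy
#'   numbering cannot collide with site numbering).
#' @param seed Integer seed; the generator never touches the global RNG state.
#' @return A list with `structure` (a `dicer_structure`), `sites` (the
#'   matching `site_map`) and `truth` (a one-row tibble of the exact pre-noise
#'   distances).
#' @examples
#' sc <- generate_scaffold("dmel_like", 61.0, 59.6, seed = 7)
#' measure_ruler(sc$structure, sc$sites)
#' @export
generate_scaffold <- function(structure_id, d_3p_riiia, d_5p_riiib,
                              residues_per_site = 4, site_cluster_radius = 2.0,
                              noise_sigma = 0, decoy_residues = 50, seed = 1) {
  if (noise_sigma < 0) stop_dicer("noise_sigma must be >= 0", "domain")
  if (residues_per_site < 1) stop_dicer("residues_per_site must be >= 1", "domain")
  if (decoy_residues < 0 || decoy_residues >= 700) {
    stop_dicer("decoy_residues must be in [0, 700)", "domain")
  }
  for (d in c(d_3p_riiia, d_5p_riiib)) {
    if (!is.finite(d) || d <= 2 * site_cluster_radius) {
      stop_dicer(paste0("infeasible scaffold: target distance ", d,
                        " must exceed twice the cluster radius (",
                        2 * site_cluster_radius, ")"), "infeasible")
    }
  }

  centroids <- list(
    RIII_A        = c(0, 0, 0),
    pocket_3prime = c(d_3p_riiia, 0, 0),
    RIII_B        = c(0, 30, 0),
    pocket_5prime = c(d_5p_riiib, 30, 0)
  )
  base_resno <- c(RIII_A = 1201L, RIII_B = 1401L,
                  pocket_3prime = 801L, pocket_5prime = 701L)
  site_aa <- c(RIII_A = "E", RIII_B = "D",
               pocket_3prime = "Y", pocket_5prime = "Y")

  withr::with_seed(seed, {
    site_rows <- purrr::imap(centroids, function(cen, nm) {
      k <- residues_per_site
      off <- if (k == 1) {
        matrix(0, 1, 3)
      } else {
        # uniform in a ball, then recentered so the centroid is exact
        o <- matrix(rnorm(3 * k), k, 3)
        o <- o / sqrt(rowSums(o^2)) * runif(k)^(1 / 3) * site_cluster_radius
        sweep(o, 2, colMeans(o))
      }
      pts <- sweep(off, 2, cen, `+`)
      tibble(chain = "A",
             resno = base_resno[[nm]] + seq_len(k) - 1L,
             ins = "", aa = site_aa[[nm]], atom = "CA", elem = "C",
             x = pts[, 1], y = pts[, 2], z = pts[, 3], o = 1, b = 0,
             site = nm)
    })
    decoys <- if (decoy_residues > 0) {
      span <- max(d_3p_riiia, d_5p_riiib)
      tibble(chain = "A", resno = seq_len(decoy_residues), ins = "",
             aa = "A", atom = "CA", elem = "C",
             x = runif(decoy_residues, -20, span + 20),
             y = runif(decoy_residues, -20, 50),
             z = runif(decoy_residues, -40, -10),
             o = 1, b = 0, site = NA_character_)
    } else {
      NULL
    }
    atoms <- dplyr::bind_rows(c(site_rows, list(decoys)))
    atoms <- dplyr::arrange(atoms, .data$resno)

    if (noise_sigma > 0) {
      atoms$x <- atoms$x + rnorm(nrow(atoms), sd = noise_sigma)
      atoms$y <- atoms$y + rnorm(nrow(atoms), sd = noise_sigma)
      atoms$z <- atoms$z + rnorm(nrow(atoms), sd = noise_sigma)
    }
    R <- random_rotation()
    tr <- runif(3, -50, 50)
    m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    atoms$x <- m[, 1] + tr[1]
    atoms$y <- m[, 2] + tr[2]
    atoms$z <- m[, 3] + tr[3]
  })

  sites <- new_site_map(tibble(
    structure_id = structure_id,
    site = dplyr::filter(atoms, !is.na(.data$site))$site,
    chain = "A",
    resno = dplyr::filter(atoms, !is.na(.data$site))$resno,
    expected_aa = dplyr::filter(atoms, !is.na(.data$site))$aa,
    resolved = TRUE
  ))
  list(
    structure = new_structure(dplyr::select(atoms, -"site"),
                              id = structure_id, source = "synthetic"),
    sites = sites,
    truth = tibble(structure_id = structure_id,
                   d_3p_riiia = d_3p_riiia, d_5p_riiib = d_5p_riiib,
                   noise_sigma = noise_sigma, seed = seed)
  )
}

#' Generate an ideal A-form dsRNA duplex of pseudo-atoms
#'
#' Two antiparallel strands of phosphate-proxy pseudo-atoms on a regular
#' helix, one atom per nucleotide, residues numbered 5'→3' within each strand.
#' With the default A-form rise (2.81 Å per base pair), the axial extent of an
#' n-bp duplex is exactly `(n-1) * rise` — the geometric content of the
#' distance-to-length conversion: one extra nucleotide adds one rise.
#'
#' @param n_bp Number of base pairs (≥ 2).
#' @param rise Axial rise per base pair in Å (default 2.81, A-form).
#' @param twist Helical twist per base pair in degrees (default 32.7).
#' @param radius Backbone radius in Å (default 9.0).
#' @param seed Optional integer seed; when given, the duplex is placed at a
#'   seeded random rigid orientation instead of the canonical z-axis frame.
#' @param structure_id Label for the structure.
#' @return A `dicer_structure`: chain `A` residues 1..n and chain `B`
#'   residues 1..n (5'→3'), atom name `"P"`.
#' @export
generate_duplex <- function(n_bp, rise = 2.81, twist = 32.7, radius = 9.0,
                            seed = NULL, structure_id = "duplex") {
  if (n_bp < 2) stop_dicer("n_bp must be >= 2", "domain")
  if (rise <= 0) stop_dicer("rise must be > 0", "domain")
  if (twist <= 0 || twist >= 360) stop_dicer("twist must be in (0, 360)", "domain")
  i <- seq_len(n_bp)
  theta <- deg2rad(twist * (i - 1))
  a <- tibble(chain = "A", resno = as.integer(i), ins = "", aa = "X",
              atom = "P", elem = "P",
              x = radius * cos(theta), y = radius * sin(theta),
              z = rise * (i - 1), o = 1, b = 0)
  # strand B: residue j pairs with strand A residue n+1-j (antiparallel);
  # pseudo-atoms of a pair sit diametrically opposite across the helix axis,
  # so pair midpoints lie exactly on the axis
  j <- seq_len(n_bp)
  theta_b <- deg2rad(twist * (n_bp - j)) + pi
  b <- tibble(chain = "B", resno = as.integer(j), ins = "", aa = "X",
              atom = "P", elem = "P",
              x = radius * cos(theta_b), y = radius * sin(theta_b),
              z = rise * (n_bp - j), o = 1, b = 0)
  atoms <- dplyr::bind_rows(a, b)
  if (!is.null(seed)) {
    withr::with_seed(seed, {
      R <- random_rotation()
      tr <- runif(3, -50, 50)
    })
    m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
    atoms$x <- m[, 1] + tr[1]
    atoms$y <- m[, 2] + tr[2]
    atoms$z <- m[, 3] + tr[3]
  }
  new_structure(atoms, id = structure_id, source = "synthetic")
}

#' Axial extent of a duplex
#'
#' Length of a [generate_duplex()] structure along its helix axis: the axis is
#' recovered from the base-pair midpoints (which lie exactly on it, strand
#' pseudo-atoms being placed diametrically opposite), and the extent is the
#' max − min projection of all atoms onto that axis. Invariant under rigid
#' placement; equals `(n_bp − 1) * rise` by construction.
#'
#' @param structure A duplex `dicer_structure` with paired chains `A` and `B`.
#' @return Extent in Å.
#' @export
axial_extent <- function(structure) {
  tb <- as_tibble(structure)
  a <- dplyr::arrange(dplyr::filter(tb, .data$chain == "A"), .data$resno)
  b <- dplyr::arrange(dplyr::filter(tb, .data$chain == "B"), .data$resno)
  if (nrow(a) < 2 || nrow(a) != nrow(b)) {
    stop_dicer("axial_extent needs a duplex with equally sized chains A and B",
               "domain")
  }
  am <- as.matrix(a[, c("x", "y", "z")])
  bm <- as.matrix(b[nrow(b):1, c("x", "y", "z")])  # partner of A residue i
  mid <- (am + bm) / 2
  mc <- sweep(mid, 2, colMeans(mid))
  v <- svd(mc, nu = 0, nv = 1)$v[, 1]
  p <- rbind(am, bm) %*% v
  max(p) - min(p)
}

#' Add Gaussian coordinate noise to a structure
#'
#' Adds i.i.d. Gaussian noise to every atom coordinate — a simple model of the
#' side-chain/rotamer variability that perturbs pocket geometry between
#' independent modeling runs. Seeded and reproducible; the global RNG state is
#' untouched.
#'
#' @param structure A `dicer_structure` atom table.
#' @param sigma Noise SD per coordinate in Å (≥ 0).
#' @param seed Integer seed.
#' @return The perturbed structure.
#' @export
perturb <- function(structure, sigma, seed = 1) {
  if (sigma < 0) stop_dicer("sigma must be >= 0", "domain")
  if (sigma == 0) return(structure)
  n <- nrow(structure)
  withr::with_seed(seed, {
    noise <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  })
  structure$x <- structure$x + noise[, 1]
  structure$y <- structure$y + noise[, 2]
  structure$z <- structure$z + noise[, 3]
  structure
}
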