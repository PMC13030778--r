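#' Centroid of a functional site
#'
#' The "center" of a pocket or catalytic site is the unweighted mean position
#' of the selected atoms over the site's resolved residues. The default
#' `"calpha"` policy uses one Cα per residue, keeping the measure independent
#' of side-chain rotamers; `"all_heavy"` averages every non-hydrogen atom for
#' sensitivity checks. Unresolved (`"?"`) entries are skipped and counted.
#'
#' @param structure A `dicer_structure` atom table.
#' @param sites A `site_map` tibble.
#' @param site Site name: one of `"RIII_A"`, `"RIII_B"`, `"pocket_3prime"`,
#'   `"pocket_5prime"`.
#' @param atom_policy `"calpha"` (default) or `"all_heavy"`.
#' @return Numeric length-3 centroid (Å) with attributes `n_residues` (used)
#'   and `n_skipped` (unresolved entries).
#' @export
site_centroid <- function(structure, sites, site,
                          atom_policy = c("calpha", "all_heavy")) {
  atom_policy <- match.arg(atom_policy)
  entries <- dplyr::filter(as_tibble(sites), .data$site == !!site)
  if (nrow(entries) == 0) {
    stop_dicer(paste0("site '", site, "' has no entries"), "missing_site")
  }
  resolved <- dplyr::filter(entries, .data$resolved)
  atoms <- as_tibble(structure)
  if (atom_policy == "calpha") {
    atoms <- dplyr::filter(atoms, .data$atom == "CA")
  } else {
    elem <- ifelse(atoms$elem == "", substr(atoms$atom, 1, 1), atoms$elem)
    atoms <- atoms[!(elem %in% c("H", "D")), , drop = FALSE]
  }
  sel <- dplyr::semi_join(atoms, resolved, by = c("chain", "resno"))
  if (nrow(sel) == 0) {
    stop_dicer(paste0("site '", site,
                      "' has no resolved residues present in structure '",
                      structure_id(structure), "'"), "missing_site")
  }
  n_res <- nrow(dplyr::distinct(sel, .data$chain, .data$resno))
  out <- c(mean(sel$x), mean(sel$y), mean(sel$z))
  attr(out, "n_residues") <- n_res
  attr(out, "n_skipped") <- sum(!entries$resolved)
  out
}

#' Measure the molecular-ruler distances of a structure
#'
#' The caliper statistic: Euclidean distances between the PAZ 3' pocket and
#' the RNase III A catalytic center, and between the PAZ 5' pocket and the
#' RNase III B center, plus their arithmetic mean. All four sites must have at
#' least one resolved residue present in the structure. Values are kept at
#' full precision; rounding to 0.1 Å happens only when a report is serialized.
#'
#' @inheritParams site_centroid
#' @return A one-row tibble with columns `structure_id`, `d_3p_riiia`,
#'   `d_5p_riiib`, `mean_distance` (Å), `sd` (0 for a single run) and
#'   `n_replicates` (1). Attribute `provenance` records residues used and
#'   skipped per site.
#' @examples
#' sc <- generate_scaffold("demo", d_3p_riiia = 61, d_5p_riiib = 59.6, seed = 1)
#' measure_ruler(sc$structure, sc$sites)
#' @export
measure_ruler <- function(structure, sites,
                          atom_policy = c("calpha", "all_heavy")) {
  atom_policy <- match.arg(atom_policy)
  check_ruler_sites(sites)
  cents <- lapply(RULER_SITES, function(s) {
    site_centroid(structure, sites, s, atom_policy = atom_policy)
  })
  names(cents) <- RULER_SITES
  d1 <- sqrt(sum((cents$pocket_3prime - cents$RIII_A)^2))
  d2 <- sqrt(sum((cents$pocket_5prime - cents$RIII_B)^2))
  out <- tibble(
    structure_id = structure_id(structure),
    d_3p_riiia = d1,
    d_5p_riiib = d2,
    mean_distance = (d1 + d2) / 2,
    sd = 0,
    n_replicates = 1L
  )
  attr(out, "provenance") <- purrr::imap(cents, function(v, nm) {
    list(n_residues = attr(v, "n_residues"), n_skipped = attr(v, "n_skipped"))
  })
  out
}

#' Replicate statistics of ruler measurements
#'
#' Mean and sample standard deviation (n−1 denominator; 0 for a single run)
#' of the per-replicate mean caliper distances, the summary reported per
#' species over independent modeling runs.
#'
#' @param measurements A data frame of stacked [measure_ruler()] rows (or any
#'   tibble with a `mean_distance` column).
#' @return A one-row tibble with `n`, `mean` and `sd` (Å).
#' @export
replicate_stats <- function(measurements) {
  m <- as_tibble(measurements)
  if (nrow(m) == 0) {
    stop_dicer("no measurements to summarise", "empty_input")
  }
  x <- m$mean_distance
  tibble(n = length(x), mean = mean(x),
         sd = if (length(x) == 1L) 0 else stats::sd(x))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Anchored distance-to-length calibration
#'
#' Converts a caliper distance into an siRNA length class relative to a
#' reference enzyme: `L_ref + round((d - d_ref)/rise)` with nearest-integer
#' rounding (ties away from zero). The default rise of 2.0 Å per nucleotide is
#' the spacing the comparative distance data themselves imply between adjacent
#' length classes; the crystallographic A-form helical rise (2.81 Å/nt) can be
#' set instead.
#'
#' @param d_ref Reference mean caliper distance (Å).
#' @param l_ref Reference siRNA length (nt, within the canonical 18–24 range).
#' @param rise Å per nucleotide (> 0).
#' @return A `ruler_calibration` object (mode `"anchored_rounding"`).
#' @examples
#' model <- calibration_anchored(d_ref = 60.3, l_ref = 21, rise = 2.0)
#' predict_length(dicer2_distances()[, c("structure_id", "reported_mean")] |>
#'                  dplyr::rename(mean_distance = reported_mean), model)
#' @export
calibration_anchored <- function(d_ref, l_ref = 21, rise = 2.0) {
  if (rise <= 0) stop_dicer("rise must be > 0", "calibration")
  if (l_ref < 18 || l_ref > 24) {
    stop_dicer("l_ref must lie in the canonical 18-24 nt range", "calibration")
  }
  out <- list(mode = "anchored_rounding", d_ref = d_ref, l_ref = l_ref,
              rise = rise, slope = NULL, intercept = NULL, data = NULL)
  class(out) <- "ruler_calibration"
  out
}

#' Least-squares distance-to-length calibration
#'
#' Ordinary least squares of known siRNA length (nt) on mean caliper distance
#' (Å): `length = slope * distance + intercept`. The implied rise is
#' `1/slope` Å per nucleotide.
#'
#' @param data A data frame with the calibration points.
#' @param distance,length Column names (strings) holding mean distance (Å) and
#'   known siRNA length (nt). Defaults `"mean_distance"`, `"length_nt"`.
#' @param d_ref,l_ref Optional anchor used for `delta_vs_ref` in predictions;
#'   defaults to the mean distance of the calibration points and its fitted
#'   length.
#' @return A `ruler_calibration` object (mode `"linear_fit"`) wrapping the
#'   [stats::lm] fit; `tidy()` and `glance()` summarise it.
#' @export
fit_calibration <- function(data, distance = "mean_distance",
                            length = "length_nt", d_ref = NULL, l_ref = NULL) {
  df <- as_tibble(data)
  x <- df[[distance]]
  y <- df[[length]]
  if (length(x) < 2) stop_dicer("need at least 2 calibration points", "calibration")
  if (length(unique(x)) < 2) {
    stop_dicer("degenerate calibration: all distances identical", "calibration")
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope <= 0) {
    warn("calibration slope is not positive; longer distances should give longer siRNAs")
  }
  d_ref <- d_ref %||% mean(x)
  out <- list(mode = "linear_fit", d_ref = d_ref,
              l_ref = l_ref %||% (slope * d_ref + intercept),
              rise = 1 / slope, slope = slope, intercept = intercept,
              data = tibble(mean_distance = x, length_nt = y), fit = fit)
  class(out) <- "ruler_calibration"
  out
}

#' @export
print.ruler_calibration <- function(x, ...) {
  if (x$mode == "anchored_rounding") {
    cat("<ruler_calibration> anchored: d_ref", x$d_ref, "A =", x$l_ref,
        "nt, rise", x$rise, "A/nt\n")
  } else {
    cat("<ruler_calibration> linear fit: length =",
        format(x$slope, digits = 4), "* d +", format(x$intercept, digits = 4),
        " (rise", format(x$rise, digits = 4), "A/nt)\n")
  }
  invisible(x)
}

#' @export
tidy.ruler_calibration <- function(x, ...) {
  if (x$mode == "anchored_rounding") {
    tibble(term = c("d_ref", "l_ref", "rise"),
           estimate = c(x$d_ref, x$l_ref, x$rise))
  } else {
    tibble(term = c("intercept", "slope", "rise"),
           estimate = c(x$intercept, x$slope, x$rise))
  }
}

#' @export
glance.ruler_calibration <- function(x, ...) {
  if (x$mode == "anchored_rounding") {
    tibble(mode = x$mode, d_ref = x$d_ref, l_ref = x$l_ref, rise = x$rise,
           n = NA_integer_, r.squared = NA_real_)
  } else {
    tibble(mode = x$mode, d_ref = x$d_ref, l_ref = x$l_ref, rise = x$rise,
           n = nrow(x$data), r.squared = summary(x$fit)$r.squared)
  }
}

#' Predict siRNA length class from caliper distance
#'
#' Applies a calibration model to mean caliper distances. Predictions outside
#' the canonical 18–24 nt range are flagged (`out_of_range`) with a warning
#' but still returned. `delta_vs_ref` is the distance shift from the model's
#' reference, and `significant` applies the biological-relevance threshold
#' (strictly exceeding `threshold` Å, default 0.5) via [relevance_flag()].
#'
#' @param data A data frame with a `mean_distance` column (Å) — e.g.
#'   [measure_ruler()] output — or a bare numeric vector of distances.
#' @param model A `ruler_calibration` object.
#' @param threshold Relevance threshold in Å (> 0).
#' @return The input tibble with columns `predicted_nt` (integer),
#'   `delta_vs_ref` (Å), `significant` and `out_of_range` appended.
#' @export
predict_length <- function(data, model, threshold = 0.5) {
  if (is.numeric(data)) data <- tibble(mean_distance = data)
  df <- as_tibble(data)
  d <- df$mean_distance
  if (any(d <= 0)) stop_dicer("mean_distance must be positive", "domain")
  nt <- if (model$mode == "anchored_rounding") {
    model$l_ref + round_half_away((d - model$d_ref) / model$rise)
  } else {
    round_half_away(model$slope * d + model$intercept)
  }
  oor <- nt < 18 | nt > 24
  if (any(oor)) {
    warn(paste0(sum(oor), " prediction(s) outside the canonical 18-24 nt range"))
  }
  delta <- d - model$d_ref
  dplyr::mutate(df,
                predicted_nt = as.integer(nt),
                delta_vs_ref = delta,
                significant = relevance_flag(delta, threshold),
                out_of_range = oor)
}

#' Biological-relevance flag for a distance shift
#'
#' A structural variation in active-site spacing is flagged as biologically
#' relevant when it strictly exceeds the threshold (default 0.5 Å) in absolute
#' value; a shift of exactly the threshold is not flagged.
#'
#' @param delta Distance shift(s) in Å.
#' @param threshold Positive threshold in Å.
#' @return Logical vector.
#' @export
relevance_flag <- function(delta, threshold = 0.5) {
  if (threshold <= 0) stop_dicer("threshold must be > 0", "domain")
  abs(delta) > threshold
}

#' Check reported means against recomputed ones
#'
#' Recomputes the arithmetic mean of the two per-pocket distances and flags
#' rows whose reported mean differs beyond printing precision (default
#' tolerance 0.05 Å, half of the last printed digit). The recomputed mean is
#' first rounded at coordinate precision (3 decimals, what a PDB file
#' carries), so that sub-millivangstrom noise from coordinate serialization
#' never trips the flag; a value sitting exactly on the printing boundary
#' (e.g. a true mean of 58.35 reported as 58.3) is treated as consistent.
#'
#' @param data A data frame with columns `d_3p_riiia`, `d_5p_riiib` and
#'   `reported_mean`.
#' @param tol Absolute tolerance in Å.
#' @return The input with `computed_mean` (full precision) and logical
#'   `discrepancy` appended.
#' @examples
#' check_reported_means(dicer2_distances())
#' @export
check_reported_means <- function(data, tol = 0.05) {
  df <- as_tibble(data)
  dplyr::mutate(df,
                computed_mean = (.data$d_3p_riiia + .data$d_5p_riiib) / 2,
                discrepancy = abs(round(.data$computed_mean, 3) -
                                    .data$reported_mean) > tol + 1e-9)
}
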