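pipeline_defaults <- list(
  rise = 2.0,
  calibration_mode = "anchored_rounding",
  n_replicates = 3L,
  perturb_sigma = 0,
  relevance_threshold = 0.5,
  atom_policy = "calpha",
  seed = 1L,
  output_dir = NULL,
  domains = NULL
)

#' Read a pipeline configuration file
#'
#' The configuration is a single YAML file. Required keys: `reference`
#' (with `id`, `structure`, `sites` and `length_nt`) and `targets` (a list of
#' entries with `id`, `structure`, and either `sites` or `fasta` — the latter
#' triggers annotation transfer by alignment against `reference$fasta`).
#' Optional keys with defaults: `rise` (2.0 Å/nt), `calibration_mode`
#' (`"anchored_rounding"` or `"linear_fit"`), `n_replicates` (3),
#' `perturb_sigma` (0 Å), `relevance_threshold` (0.5 Å), `atom_policy`
#' (`"calpha"`), `seed` (1), `domains` (domain-span TSV), `output_dir`.
#' Targets may carry `expected_mean` (Å), a published value to check the
#' recomputed mean against.
#'
#' @param path Path to a YAML configuration file.
#' @return A named list of class `ruler_config` with defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_dicer(paste0("config file '", path, "' does not exist"), "io")
  }
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_dicer(
                    paste0("cannot parse config: ", conditionMessage(e)),
                    "parse"))
  as_ruler_config(cfg, base_dir = dirname(path))
}

as_ruler_config <- function(cfg, base_dir = ".") {
  for (k in names(pipeline_defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- pipeline_defaults[[k]]
  }
  cfg$base_dir <- base_dir
  class(cfg) <- c("ruler_config", "list")
  cfg
}

resolve_path <- function(p, base_dir) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) p else file.path(base_dir, p)
}

#' Statically validate a pipeline configuration
#'
#' Checks paths, enum values and numeric ranges without reading any structure
#' content. Validation reports problems; it never raises on content.
#'
#' @param config A `ruler_config` list, a plain list, or a YAML file path.
#' @return A tibble with columns `field` and `problem`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) read_config(config)
         else as_ruler_config(config, base_dir = config$base_dir %||% ".")
  problems <- list()
  note <- function(field, problem) {
    problems[[length(problems) + 1]] <<- tibble(field = field, problem = problem)
  }

  if (is.null(cfg$reference)) {
    note("reference", "missing")
  } else {
    for (k in c("id", "structure", "sites")) {
      if (is.null(cfg$reference[[k]])) note(paste0("reference.", k), "missing")
    }
    for (k in c("structure", "sites", "fasta")) {
      p <- cfg$reference[[k]]
      if (!is.null(p) && is.null(resolve_path_checked(p, cfg$base_dir))) {
        note(paste0("reference.", k), paste0("file not found: ", p))
      }
    }
    lr <- cfg$reference$length_nt
    if (is.null(lr) || lr < 18 || lr > 24) {
      note("reference.length_nt", "must be in 18-24")
    }
  }
  if (is.null(cfg$targets) || length(cfg$targets) == 0) {
    note("targets", "at least one target required")
  } else {
    for (i in seq_along(cfg$targets)) {
      tg <- cfg$targets[[i]]
      pre <- paste0("targets[", i, "]")
      if (is.null(tg$id)) note(paste0(pre, ".id"), "missing")
      if (is.null(tg$structure)) note(paste0(pre, ".structure"), "missing")
      if (is.null(tg$sites) && is.null(tg$fasta)) {
        note(pre, "needs either sites or fasta")
      }
      for (k in c("structure", "sites", "fasta")) {
        p <- tg[[k]]
        if (!is.null(p) && is.null(resolve_path_checked(p, cfg$base_dir))) {
          note(paste0(pre, ".", k), paste0("file not found: ", p))
        }
      }
    }
  }
  if (!cfg$calibration_mode %in% c("anchored_rounding", "linear_fit")) {
    note("calibration_mode",
         "must be 'anchored_rounding' or 'linear_fit'")
  }
  if (!cfg$atom_policy %in% c("calpha", "all_heavy")) {
    note("atom_policy", "must be 'calpha' or 'all_heavy'")
  }
  if (cfg$n_replicates < 1) note("n_replicates", "must be >= 1")
  if (cfg$relevance_threshold <= 0) note("relevance_threshold", "must be > 0")
  if (cfg$rise <= 0) note("rise", "must be > 0")
  if (cfg$perturb_sigma < 0) note("perturb_sigma", "must be >= 0")
  if (length(problems) == 0) {
    tibble(field = character(), problem = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

resolve_path_checked <- function(p, base_dir) {
  full <- resolve_path(p, base_dir)
  if (!is.null(full) && file.exists(full)) full else NULL
}

log_line <- function(level, msg) {
  message(sprintf("[%s] %s", level, msg))
}

measure_with_replicates <- function(structure, sites, n_replicates, sigma,
                                    seed_base, atom_policy) {
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    s <- if (sigma > 0) perturb(structure, sigma, seed = seed_base + r)
         else structure
    measure_ruler(s, sites, atom_policy = atom_policy)
  })
  all_reps <- dplyr::bind_rows(reps)
  st <- replicate_stats(all_reps)
  tibble(
    structure_id = structure_id(structure),
    d_3p_riiia = mean(all_reps$d_3p_riiia),
    d_5p_riiib = mean(all_reps$d_5p_riiib),
    mean_distance = st$mean,
    sd = st$sd,
    n_replicates = st$n
  )
}

# Site rows for one structure id; a site file may bundle several structures.
sites_for <- function(sites, id) {
  sub <- dplyr::filter(as_tibble(sites), .data$structure_id == id)
  if (nrow(sub) == 0) sites else new_site_map(sub)
}

#' Run the full molecular-ruler pipeline
#'
#' Orchestrates the whole analysis: load the reference structure and its site
#' annotation, measure its caliper distances over replicates, build the
#' distance-to-length calibration anchored at the reference, then for every
#' target establish the site map (from a file, or transferred through a
#' global sequence alignment when a FASTA is given), superpose onto the
#' reference through the site correspondence, measure ruler distances over
#' replicates, predict the siRNA length class and flag biologically relevant
#' shifts. Replicates differ only when `perturb_sigma > 0`; otherwise their
#' SD is 0 by construction and logged as such. The run is deterministic under
#' a fixed seed.
#'
#' @param config A `ruler_config` list ([read_config()]), a plain list with
#'   the same fields, or a YAML file path.
#' @return An object of class `ruler_report`: list with `results` (one row
#'   per structure: distances, mean ± sd, predicted length, relevance and
#'   superposition summary), `notes` (structured warnings such as reported-
#'   mean discrepancies or unresolved sites), and run metadata. `tidy()`
#'   returns the results tibble. When `output_dir` is set, `report.tsv`
#'   (distances rounded to 0.1 Å) and `report.json` (full precision) are
#'   written there.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_config(config)
         else as_ruler_config(config, base_dir = config$base_dir %||% ".")
  problems <- validate_config(cfg)
  if (nrow(problems) > 0) {
    stop_dicer(paste0("invalid configuration:\n", paste0(
      "  - ", problems$field, ": ", problems$problem, collapse = "\n")),
      "config")
  }
  notes <- list()
  note <- function(id, level, msg) {
    notes[[length(notes) + 1]] <<- tibble(structure_id = id, level = level,
                                          note = msg)
    log_line(level, paste0(id, ": ", msg))
  }

  ref_id <- cfg$reference$id
  log_line("info", paste0("loading reference '", ref_id, "'"))
  ref_structure <- read_structure(resolve_path(cfg$reference$structure,
                                               cfg$base_dir), id = ref_id)
  ref_sites <- sites_for(read_sites(resolve_path(cfg$reference$sites,
                                                 cfg$base_dir)), ref_id)
  disc <- validate_map(ref_sites, ref_structure)
  if (nrow(disc) > 0) {
    note(ref_id, "warning", paste0(nrow(disc),
                                   " site/structure discrepancies on reference"))
  }
  if (cfg$perturb_sigma == 0 && cfg$n_replicates > 1) {
    log_line("info", "replicates without perturbation: SD will be 0 by construction")
  }
  ref_meas <- measure_with_replicates(ref_structure, ref_sites,
                                      cfg$n_replicates, cfg$perturb_sigma,
                                      seed_base = cfg$seed,
                                      atom_policy = cfg$atom_policy)

  model <- calibration_anchored(d_ref = ref_meas$mean_distance,
                                l_ref = cfg$reference$length_nt,
                                rise = cfg$rise)

  domains <- if (!is.null(cfg$domains)) {
    read_domains(resolve_path(cfg$domains, cfg$base_dir))
  } else NULL

  target_rows <- list()
  for (ti in seq_along(cfg$targets)) {
    tg <- cfg$targets[[ti]]
    log_line("info", paste0("processing target '", tg$id, "'"))
    tgt_structure <- read_structure(resolve_path(tg$structure, cfg$base_dir),
                                    id = tg$id)
    tgt_sites <- if (!is.null(tg$sites)) {
      sites_for(read_sites(resolve_path(tg$sites, cfg$base_dir)), tg$id)
    } else {
      ref_seq <- read_fasta(resolve_path(cfg$reference$fasta, cfg$base_dir))[[1]]
      tgt_seq <- read_fasta(resolve_path(tg$fasta, cfg$base_dir))[[1]]
      al <- align_global(ref_seq, tgt_seq)
      transfer_sites(ref_sites, al,
                     ref_numbering = seq_len(nchar(ref_seq)) +
                       (cfg$reference$numbering_offset %||% 0),
                     tgt_numbering = seq_len(nchar(tgt_seq)) +
                       (tg$numbering_offset %||% 0),
                     structure_id = tg$id)
    }
    n_unres <- sum(!tgt_sites$resolved)
    if (n_unres > 0) {
      note(tg$id, "warning", paste0(n_unres, " unresolved site entr",
                                    if (n_unres == 1) "y" else "ies",
                                    " skipped"))
    }
    disc <- validate_map(tgt_sites, tgt_structure)
    if (nrow(disc) > 0) {
      note(tg$id, "warning",
           paste0(nrow(disc), " site/structure discrepancies"))
    }

    sup <- tryCatch({
      superpose_structures(ref_structure, tgt_structure,
                           pairs = site_pairs(ref_sites, tgt_sites),
                           domains = domains)
    }, dicerruler_error = function(e) {
      note(tg$id, "warning",
           paste0("superposition skipped: ", conditionMessage(e)))
      NULL
    })

    meas <- measure_with_replicates(tgt_structure, tgt_sites,
                                    cfg$n_replicates, cfg$perturb_sigma,
                                    seed_base = cfg$seed + 100 * ti,
                                    atom_policy = cfg$atom_policy)
    if (!is.null(tg$expected_mean)) {
      chk <- check_reported_means(dplyr::mutate(meas,
                                                reported_mean = tg$expected_mean))
      if (chk$discrepancy) {
        note(tg$id, "warning", sprintf(
          "recomputed mean %.1f differs from reported mean %.1f",
          round(chk$computed_mean, 1), tg$expected_mean))
      }
    }
    target_rows[[ti]] <- dplyr::mutate(
      meas,
      rmsd_to_ref = if (is.null(sup)) NA_real_ else sup$rmsd,
      n_atoms_fit = if (is.null(sup)) NA_integer_ else sup$n_atoms
    )
  }

  ref_row <- dplyr::mutate(ref_meas, rmsd_to_ref = 0,
                           n_atoms_fit = NA_integer_)
  results <- dplyr::bind_rows(ref_row, dplyr::bind_rows(target_rows))
  results <- predict_length(results, model,
                            threshold = cfg$relevance_threshold)

  report <- structure(list(
    results = results,
    notes = if (length(notes) == 0) {
      tibble(structure_id = character(), level = character(),
             note = character())
    } else dplyr::bind_rows(notes),
    model = model,
    seed = cfg$seed,
    n_replicates = cfg$n_replicates,
    perturb_sigma = cfg$perturb_sigma,
    version = as.character(utils::packageVersion("dicerruler")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "ruler_report")

  if (!is.null(cfg$output_dir)) {
    write_report(report, cfg$output_dir)
  }
  report
}

#' @export
print.ruler_report <- function(x, ...) {
  cat("<ruler_report>", nrow(x$results), "structures, seed", x$seed, "\n")
  print(report_table(x))
  if (nrow(x$notes) > 0) {
    cat("notes:\n")
    for (i in seq_len(nrow(x$notes))) {
      cat(" -", x$notes$structure_id[i], paste0("[", x$notes$level[i], "]"),
          x$notes$note[i], "\n")
    }
  }
  invisible(x)
}

#' @export
tidy.ruler_report <- function(x, ...) x$results

#' @export
glance.ruler_report <- function(x, ...) {
  tibble(n_structures = nrow(x$results), n_notes = nrow(x$notes),
         d_ref = x$model$d_ref, l_ref = x$model$l_ref, rise = x$model$rise,
         seed = x$seed, n_replicates = x$n_replicates)
}

# Serialized table: distances rounded to 0.1 A only here, never upstream.
report_table <- function(report) {
  dplyr::mutate(report$results,
                dplyr::across(c("d_3p_riiia", "d_5p_riiib", "mean_distance",
                                "sd", "delta_vs_ref"), ~ round(.x, 1)),
                rmsd_to_ref = round(.data$rmsd_to_ref, 3))
}

#' Write a pipeline report to disk
#'
#' Writes `report.tsv` (the per-structure table with Å values rounded to one
#' decimal, mirroring the published table layout) and `report.json` (full
#' precision, with notes and run metadata).
#'
#' @param report A `ruler_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(report_table(report), file.path(dir, "report.tsv"))
  jsonlite::write_json(
    list(results = report$results, notes = report$notes,
         model = glance(report$model), seed = report$seed,
         n_replicates = report$n_replicates,
         perturb_sigma = report$perturb_sigma,
         version = report$version, timestamp = report$timestamp),
    file.path(dir, "report.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' Read back a JSON pipeline report
#'
#' Reconstructs a `ruler_report` (results, notes, metadata) from the JSON
#' written by [write_report()], losslessly for all numeric fields.
#'
#' @param path Path to `report.json`.
#' @return A `ruler_report` object (without the calibration closure; the
#'   model summary is kept as a tibble in `$model_summary`).
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    results = as_tibble(j$results),
    notes = as_tibble(j$notes),
    model_summary = as_tibble(j$model),
    seed = j$seed, n_replicates = j$n_replicates,
    perturb_sigma = j$perturb_sigma,
    version = j$version, timestamp = j$timestamp
  ), class = "ruler_report")
}
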