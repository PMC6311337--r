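# Batch orchestration: measure a subject, simulate a cohort, report cohort
# tables, audit printed tables.  These functions back the command-line
# front end in inst/cli/pubicorridor.

config_from_list <- function(x) {
  if (inherits(x, "corridor_config")) return(x)
  if (is.null(x)) return(corridor_config())
  plate_args <- x$plate
  x$plate <- NULL
  args <- x[names(x) %in% names(formals(corridor_config))]
  if (!is.null(plate_args)) {
    args$plate <- do.call(plate_spec, plate_args)
  }
  do.call(corridor_config, args)
}

#' Read a pipeline configuration file (JSON)
#'
#' Any subset of the [corridor_config()] fields may be given; `plate` is a
#' nested object with the [plate_spec()] fields.
#'
#' @param path JSON file; `NULL` for defaults.
#' @return a `corridor_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  if (is.null(path)) return(corridor_config())
  config_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Measure one subject from files
#'
#' Reads a mesh and landmark file, runs [analyze_hemipelvis()] and writes the
#' result as JSON and a one-row CSV next to `out_prefix`.
#'
#' @param mesh_path STL/PLY mesh file.
#' @param landmarks_path landmark JSON.
#' @param out_prefix output path prefix (writes `<prefix>.json`,
#'   `<prefix>.csv`).
#' @param config a [corridor_config()] or config file path.
#' @param units_scale coordinate rescale on load (1 = millimetres).
#' @return the `corridor_result`, invisibly.
#' @export
cmd_measure <- function(mesh_path, landmarks_path, out_prefix,
                        config = corridor_config(), units_scale = 1) {
  if (is.character(config)) config <- read_pipeline_config(config)
  mesh <- read_mesh(mesh_path, scale = units_scale)
  lm <- read_landmarks(landmarks_path, mesh = mesh)
  res <- analyze_hemipelvis(mesh, lm, config)
  df <- as.data.frame(res)
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  jsonlite::write_json(as.list(df), paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(df, paste0(out_prefix, ".csv"), row.names = FALSE)
  invisible(res)
}

#' Simulate a phantom cohort to disk
#'
#' Samples a cohort, writes one mesh (STL) + landmark JSON per subject and a
#' manifest CSV.
#'
#' @param cohort a [cohort_spec()] or path to a JSON cohort spec with fields
#'   `n_male`, `n_female`, `seed`.
#' @param out_dir output directory.
#' @param n_u,n_v phantom mesh resolution.
#' @return the manifest data frame, invisibly.
#' @export
cmd_simulate <- function(cohort, out_dir, n_u = 84, n_v = 7) {
  if (is.character(cohort)) {
    cj <- jsonlite::fromJSON(cohort)
    cohort <- cohort_spec(n_male = cj$n_male, n_female = cj$n_female,
                          seed = if (is.null(cj$seed)) 1 else cj$seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sample_cohort(cohort, n_u = n_u, n_v = n_v)
  for (sub in cs$subjects) {
    ph <- generate_pubis_phantom(sub$spec)
    write_mesh(ph$mesh, file.path(out_dir, paste0(sub$id, ".stl")))
    write_landmarks(ph$landmarks,
                    file.path(out_dir, paste0(sub$id, "_landmarks.json")))
  }
  write.csv(cs$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(cs$manifest)
}

#' Measure a simulated cohort in memory
#'
#' Generates and measures every subject of a cohort without touching disk;
#' the workhorse behind the cohort-level statistics.
#'
#' @param cohort a [cohort_spec()].
#' @param config a [corridor_config()]; restrict `config$measures` to the
#'   blocks needed to keep large replicate studies fast.
#' @param n_u,n_v phantom mesh resolution.
#' @return data frame with one row per subject (sex + measured parameters).
#' @export
measure_cohort <- function(cohort, config = corridor_config(), n_u = 84,
                           n_v = 7) {
  cs <- sample_cohort(cohort, n_u = n_u, n_v = n_v)
  rows <- lapply(cs$subjects, function(sub) {
    ph <- generate_pubis_phantom(sub$spec)
    res <- analyze_hemipelvis(ph$mesh, ph$landmarks, config)
    cbind(data.frame(subject_id = sub$id, sex = sub$sex,
                     stringsAsFactors = FALSE),
          as.data.frame(res))
  })
  do.call(rbind, rows)
}

#' Cohort report from per-subject result files
#'
#' Collects the per-subject CSV rows written by [cmd_measure()] (or a single
#' results CSV with a `sex` column), builds the three-table report and the
#' printed-table audit, and writes them to `out_dir`.
#'
#' @param results_dir directory of per-subject `*.csv` results plus a
#'   `manifest.csv` with `subject_id`, `sex`; or a single CSV with `sex`.
#' @param out_dir output directory.
#' @return the report data frame, invisibly.
#' @export
cmd_cohort_report <- function(results_dir, out_dir = results_dir) {
  if (dir.exists(results_dir)) {
    manifest <- read.csv(file.path(results_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(manifest)), function(i) {
      f <- file.path(results_dir, paste0(manifest$subject_id[i], ".csv"))
      cbind(manifest[i, c("subject_id", "sex")],
            read.csv(f, stringsAsFactors = FALSE))
    })
    results <- do.call(rbind, rows)
  } else {
    results <- read.csv(results_dir, stringsAsFactors = FALSE)
  }
  report <- make_tables(results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report, file.path(out_dir, "cohort_report.csv"),
            row.names = FALSE)
  writeLines(format_tables(report), file.path(out_dir, "cohort_report.txt"))
  invisible(report)
}

#' Audit the printed reference tables
#'
#' Recomputes every printed t from its own printed summaries and writes the
#' audit JSON (recomputed beside printed, consistency flags).
#'
#' @param out_path output JSON path, or `NULL` to skip writing.
#' @param tables printed summaries, see [audit_printed_tables()].
#' @return the audit data frame, invisibly.
#' @export
cmd_audit_tables <- function(out_path = NULL,
                             tables = printed_reference_tables()) {
  audit <- audit_printed_tables(tables)
  if (!is.null(out_path)) {
    dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(audit, out_path, digits = NA, pretty = TRUE)
  }
  invisible(audit)
}
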