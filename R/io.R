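# Validate the cohort contract: two rows per person (one per side), binary
# outcome, no missing values.
check_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame")
  needed <- c("person_id", "side", "outcome")
  missing_cols <- setdiff(needed, colnames(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(cohort)) stop("cohort contains missing values")
  if (!all(cohort$side %in% c(1L, 2L)))
    stop("side must be 1 (left) or 2 (right)")
  if (!is_binary01(cohort$outcome))
    stop("outcome column must be strictly binary (0/1)")
  sides_per_person <- table(cohort$person_id)
  if (any(sides_per_person != 2L))
    stop("every person must contribute exactly two rows (one per side)")
  if (anyDuplicated(cohort[, c("person_id", "side")]))
    stop("duplicate (person_id, side) rows")
  invisible(cohort)
}

#' Read a bilateral cohort from CSV
#'
#' Reads a knee-level CSV (one row per knee), standardises the identifier,
#' side and outcome column names, and applies the cohort inclusion rules:
#' rows with any missing value are dropped, and persons left without both
#' knees are dropped; both counts are reported via \code{message}.
#'
#' @param path CSV file with a header row.
#' @param id_col,side_col,outcome_col column names in the file.
#' @return A validated \code{"cohort"} data frame (columns \code{person_id},
#'   \code{side}, \code{outcome}, then covariates).
#' @export
read_cohort <- function(path, id_col = "person_id", side_col = "side",
                        outcome_col = "outcome") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(id_col, side_col, outcome_col))
    if (!col %in% colnames(raw))
      stop("input lacks required column: ", col)
  names(raw)[match(c(id_col, side_col, outcome_col), names(raw))] <-
    c("person_id", "side", "outcome")
  raw <- raw[, c("person_id", "side", "outcome",
                 setdiff(names(raw), c("person_id", "side", "outcome")))]

  complete <- stats::complete.cases(raw)
  if (any(!complete))
    message(sum(!complete), " row(s) with missing values excluded")
  raw <- raw[complete, , drop = FALSE]

  if (!all(raw$outcome %in% c(0, 1)))
    stop("column '", outcome_col, "' must be binary 0/1; found other values")
  if (!all(raw$side %in% c(1, 2)))
    stop("column '", side_col, "' must contain only 1 (left) and 2 (right)")
  if (anyDuplicated(raw[, c("person_id", "side")]))
    stop("duplicate (", id_col, ", ", side_col, ") rows in input")

  n_sides <- table(raw$person_id)
  incomplete_persons <- names(n_sides)[n_sides < 2L]
  if (length(incomplete_persons)) {
    message(length(incomplete_persons),
            " person(s) without both knees dropped")
    raw <- raw[!raw$person_id %in% incomplete_persons, , drop = FALSE]
  }
  if (nrow(raw) == 0L) stop("no complete bilateral persons left after filtering")
  raw$side <- as.integer(raw$side)
  raw$outcome <- as.integer(raw$outcome)
  rownames(raw) <- NULL
  class(raw) <- c("cohort", "data.frame")
  check_cohort(raw)
  raw
}

#' Write a cohort table to CSV
#'
#' Plain UTF-8 comma-separated output with a header row and no missing
#' cells; \code{\link{read_cohort}} round-trips it exactly.
#'
#' @param cohort a \code{"cohort"} table.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' AUC box plot across partitions
#'
#' Side-by-side box plot of per-partition test AUC for BiMM and the plain
#' forest, written as a PNG.
#'
#' @param experiment a \code{"bimm_experiment"}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
plot_auc_boxplot <- function(experiment, path) {
  stopifnot(inherits(experiment, "bimm_experiment"))
  grDevices::png(path, width = 600, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::boxplot(auc ~ method, data = experiment$metrics,
                    ylab = "Test AUC", xlab = "",
                    main = sprintf("AUC over %d person-level partitions",
                                   experiment$n_partitions))
  invisible(path)
}

#' Write all evaluation outputs with a checksum manifest
#'
#' Writes the per-partition metrics, the summary tables (CSV and a
#' human-readable text report), the AUC box plot, and optionally a
#' grid-search trace and BiMM trajectories, then a \code{manifest.csv}
#' listing every produced file with its MD5 checksum. All CSV contents are
#' deterministic given the experiment object.
#'
#' @param experiment a \code{"bimm_experiment"}.
#' @param outdir output directory (created if absent).
#' @param grid optional \code{"split_grid_search"} result.
#' @param models optional named list of \code{"bimm"} models whose
#'   trajectories are written.
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_outputs <- function(experiment, outdir, grid = NULL, models = NULL) {
  if (!inherits(experiment, "bimm_experiment") ||
      nrow(experiment$metrics) == 0L)
    stop("experiment is empty; nothing to write")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(outdir, "partition_metrics.csv")
  utils::write.csv(experiment$metrics, f, row.names = FALSE)
  files <- c(files, f)

  summ <- merge(experiment$summary$mean, experiment$summary$sd,
                by = "method", suffixes = c("_mean", "_sd"))
  f <- file.path(outdir, "summary.csv")
  utils::write.csv(summ, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(outdir, "summary.txt")
  utils::capture.output(print(experiment), file = f)
  files <- c(files, f)

  for (method in names(experiment$importance_summary)) {
    f <- file.path(outdir, paste0("importance_", tolower(method), ".csv"))
    utils::write.csv(experiment$importance_summary[[method]]$top_mean, f,
                     row.names = FALSE)
    files <- c(files, f)
  }

  f <- file.path(outdir, "auc_boxplot.png")
  plot_auc_boxplot(experiment, f)
  files <- c(files, f)

  if (!is.null(grid)) {
    f <- file.path(outdir, "grid_search_trace.csv")
    write_grid_trace(grid, f)
    files <- c(files, f)
  }
  for (nm in names(models)) {
    f <- file.path(outdir, paste0("trajectory_", nm, ".csv"))
    write_trajectory(models[[nm]], f)
    files <- c(files, f)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
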