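## Delimited-text formats. Headers are comment lines of the form
## "# key: value" preceding a tab-separated table; files are diff-able and
## round-trip to full double precision.

header_lines <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  kv
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write PMF profiles as TSV
#'
#' The format is a tab-separated table with columns `z`, `value`, `stderr`
#' preceded by header comment lines recording `temperature`, `species`,
#' `reference` and `units`. A legacy two-column (z, value) table without a
#' stderr column is accepted with `stderr = 0` and a warning.
#'
#' @param path file path.
#' @param profile a [pmf_profile].
#' @return `read_pmf_tsv` returns a [pmf_profile]; `write_pmf_tsv` returns
#'   `path` invisibly. Writing then reading reproduces the arrays exactly.
#' @export
read_pmf_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  kv <- header_lines(path)
  needed <- c("temperature", "species", "reference")
  miss <- setdiff(needed, names(kv))
  if (length(miss)) {
    stop("PMF file header is missing key(s): ", paste(miss, collapse = ", "))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("z", "value") %in% names(df))) {
    stop("PMF table needs at least z and value columns")
  }
  if (!"stderr" %in% names(df)) {
    warning("legacy 2-column PMF file: stderr set to 0")
    df$stderr <- 0
  }
  ref <- kv$reference
  if (identical(ref, "NA")) ref <- NA
  pmf_profile(df$z, df$value, df$stderr,
              temperature = as.numeric(kv$temperature),
              species = kv$species, reference = ref)
}

#' @rdname read_pmf_tsv
#' @export
write_pmf_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature: %s", fmt_num(profile$temperature)),
    sprintf("# species: %s", profile$species),
    sprintf("# reference: %s", if (is.na(profile$reference)) "NA" else profile$reference),
    "# units: z=Angstrom value=kcal/mol stderr=kcal/mol",
    paste("z", "value", "stderr", sep = "\t")), con)
  writeLines(paste(fmt_num(profile$z), fmt_num(profile$value),
                   fmt_num(profile$stderr), sep = "\t"), con)
  invisible(path)
}

#' Read and write trajectory ensembles as CSV
#'
#' Columns: `time_ns`, `particle_id`, `species`, `x`, `y`, `z` and any
#' optional columns (`mu_x`, `mu_y`, `mu_z`, `ring1_z`, `ring2_z`, ...). The
#' box is recorded in a `# box:` header line. Time must be monotone within
#' each particle; a violation is reported with its row number.
#'
#' @param path file path.
#' @param traj a [trajectory_ensemble].
#' @return `read_trajectory_csv` returns a [trajectory_ensemble];
#'   `write_trajectory_csv` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  kv <- header_lines(path)
  if (is.null(kv$box)) stop("trajectory file header is missing key(s): box")
  box <- as.numeric(strsplit(kv$box, "\\s+")[[1L]])
  df <- utils::read.csv(path, comment.char = "#")
  ## report the first non-monotone row, 1-based over data rows
  for (pid in unique(df$particle_id)) {
    rows <- which(df$particle_id == pid)
    tv <- df$time_ns[rows]
    bad <- which(diff(tv) < 0)
    if (length(bad)) {
      stop(sprintf("non-monotone time for particle %s at data row %d",
                   as.character(pid), rows[bad[1L] + 1L]))
    }
  }
  trajectory_ensemble(df, box)
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box: %s %s %s", fmt_num(traj$box[1L]),
                     fmt_num(traj$box[2L]), fmt_num(traj$box[3L])), con)
  utils::write.csv(traj$frames, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write umbrella window samples as TSV
#'
#' One row per sample (`window_id`, `z`); window centers and force constants
#' and the temperature are recorded in header lines.
#'
#' @param path file path.
#' @param wset an [umbrella_window_set].
#' @return `read_windows_tsv` returns an [umbrella_window_set];
#'   `write_windows_tsv` returns `path` invisibly.
#' @export
read_windows_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  kv <- header_lines(path)
  miss <- setdiff(c("temperature", "centers", "force_consts"), names(kv))
  if (length(miss)) {
    stop("window file header is missing key(s): ", paste(miss, collapse = ", "))
  }
  centers <- as.numeric(strsplit(kv$centers, "\\s+")[[1L]])
  ks <- as.numeric(strsplit(kv$force_consts, "\\s+")[[1L]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  windows <- lapply(seq_along(centers), function(i) {
    list(center = centers[i], force_const = ks[i],
         samples = df$z[df$window_id == i])
  })
  umbrella_window_set(windows, temperature = as.numeric(kv$temperature))
}

#' @rdname read_windows_tsv
#' @export
write_windows_tsv <- function(wset, path) {
  stopifnot(inherits(wset, "umbrella_window_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# temperature: %s", fmt_num(wset$temperature)),
    sprintf("# centers: %s", paste(fmt_num(vapply(wset$windows, `[[`, numeric(1), "center")), collapse = " ")),
    sprintf("# force_consts: %s", paste(fmt_num(vapply(wset$windows, `[[`, numeric(1), "force_const")), collapse = " ")),
    paste("window_id", "z", sep = "\t")), con)
  for (i in seq_along(wset$windows)) {
    writeLines(paste(i, fmt_num(wset$windows[[i]]$samples), sep = "\t"), con)
  }
  invisible(path)
}

#' Read and write analog descriptor tables as CSV
#'
#' Columns `id`, `sasa`, `dipole`, `logp` and optionally `true_group`.
#'
#' @param path file path.
#' @param records analog data.frame.
#' @return `read_analog_csv` returns the data.frame; `write_analog_csv`
#'   returns `path` invisibly.
#' @export
read_analog_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("id", "sasa", "dipole", "logp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("analog table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$sasa)) || any(df$sasa <= 0)) stop("sasa must be positive and finite")
  df
}

#' @rdname read_analog_csv
#' @export
write_analog_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
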