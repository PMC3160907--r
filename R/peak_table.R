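#' Construct a lipid peak table
#'
#' A peak table holds a lipids-by-samples matrix of raw MS intensities or
#' internal-standard-normalized concentrations, together with per-peak
#' metadata (parsed lipid name, retention time, identification flag).
#'
#' @param values Numeric matrix, `n_peaks x n_samples`, finite and
#'   nonnegative.
#' @param peak_ids Character vector of unique peak identifiers (one per row).
#' @param sample_ids Character vector of unique sample identifiers (one per
#'   column).
#' @param names Optional character vector of lipid shorthand labels, parsed
#'   with [parse_lipid_name()]. Defaults to the peak ids (typically
#'   unparseable, hence unidentified).
#' @param retention_time Optional numeric vector of retention times in
#'   seconds (required for unidentified peaks if internal-standard
#'   normalization by retention time is to be applied).
#' @param unit `"raw_intensity"` or `"concentration"` (the study convention
#'   for concentrations is µmol/l lipid per mg/dl HDL protein).
#'
#' @return An object of class `peak_table`: a list with elements `values`
#'   (matrix with dimnames), `peaks` (data frame of peak metadata with a
#'   `parsed` list-column of `lipid_name` objects), `sample_ids`, `unit`.
#' @export
peak_table <- function(values, peak_ids, sample_ids, names = NULL,
                       retention_time = NULL,
                       unit = c("raw_intensity", "concentration")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(peak_ids)) {
    stop("dimension mismatch: ", nrow(values), " rows but ",
         length(peak_ids), " peak ids", call. = FALSE)
  }
  if (ncol(values) != length(sample_ids)) {
    stop("dimension mismatch: ", ncol(values), " columns but ",
         length(sample_ids), " sample ids", call. = FALSE)
  }
  dup <- peak_ids[duplicated(peak_ids)]
  if (length(dup)) {
    stop("duplicate peak_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite or negative value at peak '", peak_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "'", call. = FALSE)
  }
  if (is.null(names)) names <- peak_ids
  parsed <- lapply(names, parse_lipid_name)
  identified <- vapply(parsed, function(p) p$lipid_class != "unknown",
                       logical(1))
  if (is.null(retention_time)) retention_time <- rep(NA_real_, length(peak_ids))
  if (any(!is.na(retention_time) & retention_time < 0)) {
    stop("retention_time must be >= 0", call. = FALSE)
  }
  dimnames(values) <- list(peak_ids, sample_ids)
  peaks <- data.frame(peak_id = peak_ids, name = names,
                      retention_time = as.numeric(retention_time),
                      identified = identified, stringsAsFactors = FALSE)
  peaks$parsed <- parsed
  structure(list(values = values, peaks = peaks,
                 sample_ids = as.character(sample_ids), unit = unit),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$values), " peaks x ", ncol(x$values),
      " samples [", x$unit, "], ", sum(x$peaks$identified),
      " identified\n", sep = "")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$values)

#' Read / write a peak table as CSV or TSV
#'
#' The on-disk layout is one header row and one row per peak: a `peak_id`
#' column, optional `name` and `retention_time` columns, then one numeric
#' column per sample.  Values are written with full (17 significant digit)
#' precision so a write/read round trip is bit-exact.
#'
#' @param path File path.
#' @param format `"csv"` (comma) or `"tsv"` (tab).
#' @param unit Unit flag recorded on the returned table.
#' @return `read_peak_table()` returns a [peak_table()];
#'   `write_peak_table()` returns `path` invisibly.
#' @export
read_peak_table <- function(path, format = c("csv", "tsv"),
                            unit = c("raw_intensity", "concentration")) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!"peak_id" %in% names(df)) {
    stop("missing required column 'peak_id'", call. = FALSE)
  }
  meta_cols <- intersect(c("peak_id", "name", "retention_time"), names(df))
  sample_idx <- which(!names(df) %in% meta_cols)
  if (length(sample_idx) == 0L) stop("no sample columns found", call. = FALSE)
  vals <- as.matrix(df[sample_idx])
  colnames(vals) <- names(df)[sample_idx]  # preserve duplicates for validation
  peak_table(
    values = vals,
    peak_ids = as.character(df$peak_id),
    sample_ids = names(df)[sample_idx],
    names = if ("name" %in% names(df)) as.character(df$name) else NULL,
    retention_time = if ("retention_time" %in% names(df)) df$retention_time else NULL,
    unit = unit
  )
}

#' @rdname read_peak_table
#' @param table A [peak_table()].
#' @export
write_peak_table <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "peak_table"))
  sep <- if (format == "csv") "," else "\t"
  vals <- apply(table$values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(table$values))
  out <- data.frame(peak_id = table$peaks$peak_id,
                    name = table$peaks$name,
                    retention_time = sprintf("%.17g", table$peaks$retention_time),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$retention_time[is.na(table$peaks$retention_time)] <- "NA"
  colnames(vals) <- table$sample_ids
  out <- cbind(out, as.data.frame(vals, stringsAsFactors = FALSE,
                                  check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = which(names(out) %in% c("peak_id", "name")))
  invisible(path)
}

#' Construct a sample design table
#'
#' Maps samples to patients, treatment groups and time points for the
#' three-group fenofibrate/placebo design.  The high-Hcy placebo cell is
#' unrepresentable by construction of the group factor: placebo patients are
#' Hcy-matched to the low-Hcy fenofibrate group.
#'
#' @param sample_id,patient_id Character vectors.
#' @param group Character vector with values in `"feno_low_hcy"`,
#'   `"feno_high_hcy"`, `"placebo_low_hcy"`.
#' @param time Character vector with values in `"before"`, `"after"`.
#' @return A data frame of class `sample_design`.
#' @export
sample_design <- function(sample_id, patient_id, group, time) {
  groups <- c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy")
  times <- c("before", "after")
  sample_id <- as.character(sample_id)
  patient_id <- as.character(patient_id)
  group <- as.character(group)
  time <- as.character(time)
  n <- length(sample_id)
  stopifnot(length(patient_id) == n, length(group) == n, length(time) == n)
  if (!all(group %in% groups)) {
    stop("invalid group value(s): ",
         paste(unique(setdiff(group, groups)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(time %in% times)) {
    stop("invalid time value(s): ",
         paste(unique(setdiff(time, times)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  pt <- paste(patient_id, time, sep = "\r")
  if (anyDuplicated(pt)) {
    bad <- strsplit(pt[duplicated(pt)][1], "\r")[[1]]
    stop("patient '", bad[1], "' has more than one '", bad[2], "' sample",
         call. = FALSE)
  }
  gp <- tapply(group, patient_id, function(g) length(unique(g)))
  if (any(gp > 1)) {
    stop("patient '", names(gp)[which(gp > 1)[1]],
         "' assigned to more than one group", call. = FALSE)
  }
  structure(
    data.frame(sample_id = sample_id, patient_id = patient_id,
               group = group, time = time, stringsAsFactors = FALSE),
    class = c("sample_design", "data.frame")
  )
}

#' Read a sample design table from CSV
#'
#' @param path CSV file with exactly the columns `sample_id`, `patient_id`,
#'   `group`, `time`.
#' @return A [sample_design()].
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "group", "time")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_design(df$sample_id, df$patient_id, df$group, df$time)
}

#' @rdname read_sample_design
#' @param design A [sample_design()].
#' @export
write_sample_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[
    c("sample_id", "patient_id", "group", "time")], path, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a peak table against a sample design
#'
#' Produces a report listing samples present in only one of the two objects,
#' patients with missing time points, and per-group patient counts.  The
#' check passes iff every sample column of the table appears in the design.
#' Placebo patients without a baseline sample are reported but do not fail
#' validation (the study's placebo arm was sampled at close-out only).
#'
#' @param design A [sample_design()].
#' @param table A [peak_table()].
#' @return A list of class `validation_report` with elements `valid`,
#'   `samples_only_in_table`, `samples_only_in_design`, `unpaired_patients`
#'   (data frame patient/group/missing time), `group_sizes` (patients per
#'   group).  Serialize with [write_validation_report()].
#' @export
validate_design <- function(design, table) {
  stopifnot(inherits(design, "sample_design"), inherits(table, "peak_table"))
  only_tab <- setdiff(table$sample_ids, design$sample_id)
  only_des <- setdiff(design$sample_id, table$sample_ids)
  pat <- unique(design[c("patient_id", "group")])
  have <- base::table(factor(design$patient_id, levels = pat$patient_id),
                      factor(design$time, levels = c("before", "after")))
  missing_before <- pat$patient_id[have[pat$patient_id, "before"] == 0]
  missing_after <- pat$patient_id[have[pat$patient_id, "after"] == 0]
  unpaired <- rbind(
    data.frame(patient_id = missing_before,
               group = pat$group[match(missing_before, pat$patient_id)],
               missing_time = rep("before", length(missing_before)),
               stringsAsFactors = FALSE),
    data.frame(patient_id = missing_after,
               group = pat$group[match(missing_after, pat$patient_id)],
               missing_time = rep("after", length(missing_after)),
               stringsAsFactors = FALSE)
  )
  group_sizes <- as.list(base::table(factor(
    pat$group, levels = c("feno_low_hcy", "feno_high_hcy", "placebo_low_hcy"))))
  structure(
    list(valid = length(only_tab) == 0L,
         samples_only_in_table = only_tab,
         samples_only_in_design = only_des,
         unpaired_patients = unpaired,
         group_sizes = group_sizes),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$valid) "VALID" else "INVALID", "\n",
      sep = "")
  cat("  patients per group: ",
      paste(names(x$group_sizes), unlist(x$group_sizes), sep = "=",
            collapse = ", "), "\n", sep = "")
  if (length(x$samples_only_in_table)) {
    cat("  samples missing from design: ",
        paste(x$samples_only_in_table, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$unpaired_patients)) {
    cat("  unpaired patients: ", nrow(x$unpaired_patients), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname validate_design
#' @param report A `validation_report`.
#' @param path Output JSON path.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
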