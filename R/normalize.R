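#' Internal-standard map
#'
#' Describes which internal standard normalizes which lipid peak, and at what
#' spiked concentration.  Identified peaks are dispatched by structural rule
#' tag; unidentified peaks are dispatched by retention time.  The rule set is
#' the UPLC-MS lipidomics convention used throughout this package:
#'
#' * `monoacyl` (all monoacyl lipids except cholesteryl esters, e.g. lysoPC,
#'   lysoPE) -> `PC(17:0/0:0)`
#' * `diacyl` (all diacyl lipids except ethanolamine phospholipids; also
#'   two-chain choline sphingolipids, i.e. SM, and ether-linked PC) ->
#'   `PC(17:0/17:0)`
#' * `ceramide` -> `Cer(d18:1/17:0)`
#' * `ethanolamine` (diacyl, ether and plasmalogen PE) -> `PE(17:0/17:0)`
#' * `tg_sterol` (TG, cholesteryl esters, free cholesterol) ->
#'   `TG(17:0/17:0/17:0)`
#'
#' Unknown peaks: retention time in `[0, 300)` s -> `PC(17:0/0:0)`;
#' `[300, 410]` s -> `PC(17:0/17:0)`; `(410, Inf)` s -> `TG(17:0/17:0/17:0)`.
#'
#' @param concentrations Named numeric vector of spiked standard
#'   concentrations (per sample), names being standard ids.  Defaults to 1
#'   for each of the five standards; actual spike levels are
#'   instrument-protocol configuration.
#' @return A list of class `standard_map` with elements `standards` (data
#'   frame standard_id/concentration/rule), `rt_rules` (data frame
#'   rt_upper/standard_id covering `[0, Inf)`).
#' @export
default_standard_map <- function(concentrations = NULL) {
  std <- data.frame(
    rule = c("monoacyl", "diacyl", "ceramide", "ethanolamine", "tg_sterol"),
    standard_id = c("PC(17:0/0:0)", "PC(17:0/17:0)", "Cer(d18:1/17:0)",
                    "PE(17:0/17:0)", "TG(17:0/17:0/17:0)"),
    concentration = 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(concentrations)) {
    idx <- match(names(concentrations), std$standard_id)
    if (anyNA(idx)) {
      stop("unknown standard id: ",
           paste(names(concentrations)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    std$concentration[idx] <- as.numeric(concentrations)
  }
  rt <- data.frame(
    rt_upper = c(300, 410, Inf),
    standard_id = c("PC(17:0/0:0)", "PC(17:0/17:0)", "TG(17:0/17:0/17:0)"),
    # upper bound inclusive? [0,300) / [300,410] / (410,Inf)
    inclusive = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  validate_standard_map(structure(list(standards = std, rt_rules = rt),
                                  class = "standard_map"))
}

validate_standard_map <- function(map) {
  stopifnot(inherits(map, "standard_map"))
  if (anyDuplicated(map$standards$rule)) {
    stop("each rule tag must map to exactly one standard", call. = FALSE)
  }
  if (any(map$standards$concentration <= 0)) {
    stop("standard concentrations must be > 0", call. = FALSE)
  }
  rt <- map$rt_rules
  if (is.unsorted(rt$rt_upper) || !is.infinite(rt$rt_upper[nrow(rt)])) {
    stop("rt_rules must be sorted and end at Inf (cover [0, Inf))",
         call. = FALSE)
  }
  map
}

#' Read a standard map from a YAML config file
#'
#' Expected layout: a `standards` mapping of rule tag to
#' `{standard_id, concentration}` and an `rt_rules` list of
#' `{rt_upper, standard_id, inclusive}` entries in increasing order of
#' `rt_upper` (use `.inf` for the last).
#'
#' @param path YAML file path.
#' @return A `standard_map`.
#' @export
read_standard_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  std <- data.frame(
    rule = names(cfg$standards),
    standard_id = vapply(cfg$standards, function(s) s$standard_id, character(1)),
    concentration = vapply(cfg$standards, function(s) as.numeric(s$concentration),
                           numeric(1)),
    stringsAsFactors = FALSE
  )
  rt <- data.frame(
    rt_upper = vapply(cfg$rt_rules, function(r) as.numeric(r$rt_upper), numeric(1)),
    standard_id = vapply(cfg$rt_rules, function(r) r$standard_id, character(1)),
    inclusive = vapply(cfg$rt_rules, function(r) isTRUE(r$inclusive), logical(1)),
    stringsAsFactors = FALSE
  )
  validate_standard_map(structure(list(standards = std, rt_rules = rt),
                                  class = "standard_map"))
}

standard_rule_for_class <- function(name) {
  cls <- name$lipid_class
  if (cls == "unknown") return(NA_character_)
  if (cls == "Cer") return("ceramide")
  if (cls %in% c("TG", "ChoE", "FCho")) return("tg_sterol")
  if (name$is_monoacyl || cls %in% c("lysoPC", "lysoPE")) return("monoacyl")
  if (cls %in% c("PE", "PE_plasmalogen")) return("ethanolamine")
  # remaining two-chain choline lipids: diacyl PC, ether PC, SM
  "diacyl"
}

#' Assign an internal standard to a peak
#'
#' Deterministically maps one peak to the single internal standard that
#' normalizes it, by structural rule for identified peaks and by retention
#' time for unidentified peaks (see [default_standard_map()] for the rules).
#'
#' @param name A `lipid_name` (from [parse_lipid_name()]) or a character
#'   label, or a one-row slice of `peak_table$peaks`.
#' @param map A `standard_map`.
#' @param retention_time Retention time in seconds; required when the peak is
#'   unidentified.
#' @return The standard id (character scalar).
#' @examples
#' m <- default_standard_map()
#' assign_standard("Cer(d18:1/24:0)", m)            # Cer(d18:1/17:0)
#' assign_standard("ChoE(18:2)", m)                 # TG(17:0/17:0/17:0)
#' assign_standard("peak_0042", m, retention_time = 250)  # PC(17:0/0:0)
#' @export
assign_standard <- function(name, map, retention_time = NA_real_) {
  stopifnot(inherits(map, "standard_map"))
  if (is.character(name)) name <- parse_lipid_name(name)
  if (is.data.frame(name)) {
    retention_time <- name$retention_time[1]
    name <- name$parsed[[1]]
  }
  stopifnot(inherits(name, "lipid_name"))
  rule <- standard_rule_for_class(name)
  if (!is.na(rule)) {
    i <- match(rule, map$standards$rule)
    if (is.na(i)) stop("standard map has no rule '", rule, "'", call. = FALSE)
    return(map$standards$standard_id[i])
  }
  if (is.na(retention_time)) {
    stop("unidentified peak '", name$raw_label,
         "' has no retention time; cannot dispatch to a standard",
         call. = FALSE)
  }
  rt <- map$rt_rules
  for (i in seq_len(nrow(rt))) {
    if (retention_time < rt$rt_upper[i] ||
        (rt$inclusive[i] && retention_time == rt$rt_upper[i])) {
      return(rt$standard_id[i])
    }
  }
  rt$standard_id[nrow(rt)]
}

#' Normalize peak intensities by internal standards
#'
#' Converts raw MS intensities to concentrations: each peak's intensity is
#' divided by the intensity of its assigned internal standard in the same
#' sample and multiplied by the standard's spiked concentration,
#' `out[d, s] = in[d, s] / in[std(d), s] * conc(std(d))`.  The ratio cancels
#' any per-sample global intensity scaling (instrument drift), which is the
#' property the spiked standards exist to provide.  Standard rows are
#' dropped from the output and the unit flag is set to `"concentration"`.
#'
#' @param table A [peak_table()] with `unit = "raw_intensity"`.
#' @param map A `standard_map`.
#' @param standard_rows Named character vector mapping standard id to the
#'   `peak_id` of that standard's row in `table`.  Defaults to matching the
#'   standard ids against the peak names.
#' @return A [peak_table()] of concentrations.
#' @export
normalize_peaks <- function(table, map = default_standard_map(),
                            standard_rows = NULL) {
  stopifnot(inherits(table, "peak_table"))
  if (table$unit != "raw_intensity") {
    stop("table is already in concentration units", call. = FALSE)
  }
  std_ids <- map$standards$standard_id
  if (is.null(standard_rows)) {
    canon <- function(x) gsub("∶", ":", x)
    idx <- match(canon(std_ids), canon(table$peaks$name))
    if (anyNA(idx)) {
      stop("standard(s) not found among peak names: ",
           paste(std_ids[is.na(idx)], collapse = ", "),
           "; supply `standard_rows` explicitly", call. = FALSE)
    }
    standard_rows <- structure(table$peaks$peak_id[idx], names = std_ids)
  }
  miss <- setdiff(std_ids, names(standard_rows))
  if (length(miss)) {
    stop("standard_rows missing entries for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  row_of <- match(standard_rows[std_ids], table$peaks$peak_id)
  if (anyNA(row_of)) {
    stop("standard peak_id not in table: ",
         paste(standard_rows[std_ids][is.na(row_of)], collapse = ", "),
         call. = FALSE)
  }
  std_mat <- table$values[row_of, , drop = FALSE]
  rownames(std_mat) <- std_ids
  bad <- which(std_mat <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("standard '", std_ids[bad[1, 1]], "' has nonpositive intensity in ",
         "sample '", table$sample_ids[bad[1, 2]], "'", call. = FALSE)
  }

  keep <- setdiff(seq_len(nrow(table$values)), row_of)
  assigned <- vapply(keep, function(i) {
    assign_standard(table$peaks$parsed[[i]], map,
                    table$peaks$retention_time[i])
  }, character(1))
  conc <- map$standards$concentration[match(assigned, std_ids)]
  out <- table$values[keep, , drop = FALSE] / std_mat[assigned, , drop = FALSE] *
    conc
  peak_table(out,
             peak_ids = table$peaks$peak_id[keep],
             sample_ids = table$sample_ids,
             names = table$peaks$name[keep],
             retention_time = table$peaks$retention_time[keep],
             unit = "concentration")
}
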