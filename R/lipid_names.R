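#' Parse a lipid shorthand name
#'
#' Parses shorthand lipid nomenclature as used in UPLC-MS lipidomics, e.g.
#' `"PC(36:5)"` (sum composition), `"PE(P-16:0/20:5)"` (plasmalogen with
#' resolved chains), `"SM(d18:1/16:1)"` (sphingolipid with sphingoid base),
#' `"TG(54:3)"`, `"ChoE(18:2)"` or `"LysoPC(22:0)"`.  Both `":"` and the
#' unicode ratio character `"∶"` are accepted as carbon/double-bond
#' separators and normalized to `":"` internally.
#'
#' Parsing is total: any label that does not match a known pattern (for
#' example an unidentified peak code) is returned with `lipid_class =
#' "unknown"` and the raw label preserved; no error is raised except for an
#' empty label.
#'
#' @param label A single non-empty character string.
#'
#' @return An object of class `lipid_name`, a list with fields
#'   `raw_label`, `lipid_class` (one of `r paste0('"', lipid_classes(), '"', collapse = ", ")`),
#'   `total_carbons`, `total_double_bonds`, `chains` (list of
#'   `(carbons, double_bonds, prefix)` or `NULL` for sum compositions),
#'   `sphingoid_prefix` (e.g. `"d18:1"` or `NA`), and the logical flags
#'   `is_monoacyl`, `is_diacyl`, `is_ether`, `is_plasmalogen`.
#'
#' @examples
#' parse_lipid_name("PC(36:5)")
#' parse_lipid_name("PE(P-16:0/20:5)")
#' parse_lipid_name("SM(d18:1/16:1)")
#' parse_lipid_name("XYZ_peak_0042")$lipid_class
#'
#' @export
parse_lipid_name <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label)) {
    stop("`label` must be a single non-empty string", call. = FALSE)
  }
  lab <- gsub("∶", ":", label)
  lab <- gsub("\\s+", " ", trimws(lab))
  # drop space between head group and parenthesis, e.g. "ChoE (18:2)"
  lab <- sub("^([A-Za-z]+) \\(", "\\1(", lab)

  unknown <- new_lipid_name(raw_label = label)

  # free cholesterol carries no chain shorthand
  if (tolower(lab) == "fcho") {
    return(new_lipid_name(raw_label = label, lipid_class = "FCho"))
  }

  m <- regmatches(lab, regexec("^([A-Za-z]+)\\((.*)\\)$", lab))[[1]]
  if (length(m) != 3L) return(unknown)
  head_raw <- m[2]
  body <- m[3]

  cls <- switch(tolower(head_raw),
    "pc" = "PC", "lysopc" = "lysoPC", "pe" = "PE", "lysope" = "lysoPE",
    "sm" = "SM", "cer" = "Cer", "tg" = "TG", "choe" = "ChoE", "fcho" = "FCho",
    NA_character_
  )
  if (is.na(cls)) return(unknown)

  segs <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(segs) == 0L || !all(nzchar(segs))) return(unknown)

  parse_seg <- function(s) {
    mm <- regmatches(s, regexec("^(P-|O-|d|t)?([0-9]+):([0-9]+)(e)?$", s))[[1]]
    if (length(mm) != 5L) return(NULL)
    list(prefix = mm[2], carbons = as.integer(mm[3]),
         double_bonds = as.integer(mm[4]), ether_suffix = nzchar(mm[5]))
  }
  parsed <- lapply(segs, parse_seg)
  if (any(vapply(parsed, is.null, logical(1)))) return(unknown)

  sphingoid <- NA_character_
  if (parsed[[1]]$prefix %in% c("d", "t")) {
    sphingoid <- paste0(parsed[[1]]$prefix, parsed[[1]]$carbons, ":",
                        parsed[[1]]$double_bonds)
  }

  has_plasm <- any(vapply(parsed, function(p) identical(p$prefix, "P-"), logical(1)))
  has_alkyl <- any(vapply(parsed, function(p) identical(p$prefix, "O-"), logical(1)))
  has_e     <- any(vapply(parsed, function(p) p$ether_suffix, logical(1)))
  is_ether  <- has_plasm || has_alkyl || has_e
  is_plasm  <- has_plasm

  total_c  <- sum(vapply(parsed, function(p) p$carbons, integer(1)))
  total_db <- sum(vapply(parsed, function(p) p$double_bonds, integer(1)))

  # chain-resolved only when more than one segment (or a sphingoid base given);
  # a single segment is a sum composition
  chains <- NULL
  if (length(parsed) > 1L) {
    chains <- lapply(parsed, function(p) {
      list(carbons = p$carbons, double_bonds = p$double_bonds,
           prefix = if (nzchar(p$prefix)) p$prefix else NA_character_)
    })
  }

  # radyl chain count: segments with carbons > 0, excluding the sphingoid base
  n_radyl <- if (length(parsed) > 1L) {
    sum(vapply(parsed, function(p) p$carbons > 0L, logical(1))) -
      (!is.na(sphingoid))
  } else NA_integer_

  # class refinement from structure
  if (cls == "PC" && is_ether && !is_plasm) cls <- "PC_ether"
  if (cls == "PE" && is_plasm) cls <- "PE_plasmalogen"
  if (cls == "PC" && !is.na(n_radyl) && n_radyl == 1L) cls <- "lysoPC"
  if (cls == "PE" && !is.na(n_radyl) && n_radyl == 1L && !is_ether) cls <- "lysoPE"

  lyso <- cls %in% c("lysoPC", "lysoPE")
  is_mono <- lyso || (!is.na(n_radyl) && n_radyl == 1L &&
                        cls %in% c("PC", "PE", "PC_ether"))
  # two-chain glycerolipids / glycerophospholipids with plain acyl chains
  diacyl_classes <- c("PC", "PE")
  is_di <- cls %in% diacyl_classes && !is_ether &&
    (is.na(n_radyl) || n_radyl == 2L) && length(parsed) <= 2L
  if (cls %in% c("TG", "ChoE", "SM", "Cer", "FCho", "PC_ether",
                 "PE_plasmalogen")) {
    is_di <- FALSE
  }
  if (lyso) is_di <- FALSE

  new_lipid_name(
    raw_label = label, lipid_class = cls,
    total_carbons = total_c, total_double_bonds = total_db,
    chains = chains, sphingoid_prefix = sphingoid,
    is_monoacyl = is_mono, is_diacyl = is_di,
    is_ether = is_ether, is_plasmalogen = is_plasm
  )
}

#' Lipid classes recognised by the parser
#'
#' @return Character vector of class codes, including `"unknown"`.
#' @export
lipid_classes <- function() {
  c("PC", "lysoPC", "PE", "lysoPE", "PE_plasmalogen", "PC_ether",
    "SM", "Cer", "TG", "ChoE", "FCho", "unknown")
}

new_lipid_name <- function(raw_label,
                           lipid_class = "unknown",
                           total_carbons = NA_integer_,
                           total_double_bonds = NA_integer_,
                           chains = NULL,
                           sphingoid_prefix = NA_character_,
                           is_monoacyl = FALSE,
                           is_diacyl = FALSE,
                           is_ether = FALSE,
                           is_plasmalogen = FALSE) {
  stopifnot(lipid_class %in% lipid_classes())
  structure(
    list(raw_label = raw_label, lipid_class = lipid_class,
         total_carbons = total_carbons, total_double_bonds = total_double_bonds,
         chains = chains, sphingoid_prefix = sphingoid_prefix,
         is_monoacyl = is_monoacyl, is_diacyl = is_diacyl,
         is_ether = is_ether, is_plasmalogen = is_plasmalogen),
    class = "lipid_name"
  )
}

#' Format a parsed lipid name back to shorthand
#'
#' Produces a canonical shorthand label (ASCII `":"` separators) from a
#' `lipid_name` descriptor.  `format(parse_lipid_name(x))` parses back to an
#' equal descriptor for any recognised label; unknown descriptors return the
#' preserved raw label.
#'
#' @param x A `lipid_name` object.
#' @param ... Unused.
#' @return A character string.
#' @export
format.lipid_name <- function(x, ...) {
  if (x$lipid_class == "unknown") return(x$raw_label)
  if (x$lipid_class == "FCho" && is.na(x$total_carbons)) return("FCho")
  head_grp <- switch(x$lipid_class,
    PC = "PC", PC_ether = "PC", lysoPC = "LysoPC",
    PE = "PE", PE_plasmalogen = "PE", lysoPE = "LysoPE",
    SM = "SM", Cer = "Cer", TG = "TG", ChoE = "ChoE", FCho = "FCho"
  )
  if (is.null(x$chains)) {
    body <- paste0(x$total_carbons, ":", x$total_double_bonds,
                   if (x$is_ether && !x$is_plasmalogen) "e" else "")
  } else {
    segs <- vapply(x$chains, function(ch) {
      paste0(if (!is.na(ch$prefix)) ch$prefix else "",
             ch$carbons, ":", ch$double_bonds)
    }, character(1))
    body <- paste(segs, collapse = "/")
  }
  # lyso classes written with the head group of their parent class
  if (x$lipid_class == "lysoPC" && !is.null(x$chains)) head_grp <- "PC"
  if (x$lipid_class == "lysoPE" && !is.null(x$chains)) head_grp <- "PE"
  paste0(head_grp, "(", body, ")")
}

#' @export
print.lipid_name <- function(x, ...) {
  cat("<lipid_name> ", format(x), "\n", sep = "")
  cat("  class: ", x$lipid_class,
      if (x$is_monoacyl) " [monoacyl]" else "",
      if (x$is_diacyl) " [diacyl]" else "",
      if (x$is_plasmalogen) " [plasmalogen]"
      else if (x$is_ether) " [ether]" else "",
      "\n", sep = "")
  if (!is.na(x$total_carbons)) {
    cat("  composition: ", x$total_carbons, ":", x$total_double_bonds, "\n",
        sep = "")
  }
  invisible(x)
}
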