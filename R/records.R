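#' Construct a table of raw kinetic-parameter records
#'
#' A `kinetic_records` table holds one measurement per row in the schema of
#' BRENDA/SABIO-RK exports: enzyme identity (EC number, wild-type or mutant,
#' substitution codes, amino-acid sequence), substrate (name and SMILES),
#' assay conditions (organism, pH, temperature) and a single kinetic value
#' (`param_kind` either `"kcat"` or `"km"`) with its raw unit.
#'
#' Missing fields are representable (`NA`) because dropping incomplete rows
#' is the job of [curate_pipeline()], not of the constructor. Mutant rows
#' carry the wild-type sequence plus `mutation_codes` (semicolon-separated
#' substitution codes such as `"A123V"`); the curation pipeline applies them.
#'
#' @param df data.frame with (a subset of) the columns
#'   `id, ec_number, enzyme_type, mutation_codes, sequence, substrate_name,
#'   substrate_smiles, organism, ph, temperature, param_kind, value, unit,
#'   source`. Absent columns are added as `NA`.
#' @return A data.frame of class `kinetic_records`.
#' @seealso [curate_pipeline()], [gen_dataset()]
#' @export
kinetic_records <- function(df) {
  stopifnot(is.data.frame(df))
  cols <- c("id", "ec_number", "enzyme_type", "mutation_codes", "sequence",
            "substrate_name", "substrate_smiles", "organism", "ph",
            "temperature", "param_kind", "value", "unit", "source")
  for (cl in setdiff(cols, names(df))) df[[cl]] <- rep(NA, nrow(df))
  df <- df[cols]
  if (anyNA(df$id)) df$id[is.na(df$id)] <- paste0("r", which(is.na(df$id)))
  df$id <- as.character(df$id)
  df$ph <- as.numeric(df$ph)
  df$temperature <- as.numeric(df$temperature)
  df$value <- as.numeric(df$value)
  bad <- !(df$param_kind %in% c("kcat", "km"))
  if (any(bad)) {
    stopf("param_kind must be 'kcat' or 'km' (row %d has '%s')",
          which(bad)[1], df$param_kind[which(bad)[1]])
  }
  wt <- !is.na(df$enzyme_type) & df$enzyme_type == "wild_type" &
    !is.na(df$mutation_codes) & nzchar(df$mutation_codes)
  if (any(wt)) {
    stopf("wild_type records must have empty mutation_codes (row %d)",
          which(wt)[1])
  }
  class(df) <- c("kinetic_records", "data.frame")
  df
}

#' Unit conversion table for kinetic parameters
#'
#' Canonical units are s^-1 for kcat and mM for Km (the units in which
#' medians and predictions are reported throughout). The table is closed:
#' values in any unit not listed here are rejected during curation rather
#' than guessed at. Conversion is an exact rational scaling.
#'
#' @return data.frame with columns `param_kind`, `unit`, `factor` where
#'   `canonical_value = value * factor`.
#' @export
unit_conversion_table <- function() {
  data.frame(
    param_kind = c(rep("kcat", 7), rep("km", 5)),
    unit = c("s^-1", "1/s", "min^-1", "1/min", "h^-1", "1/h", "hr^-1",
             "M", "mM", "uM", "µM", "nM"),
    factor = c(1, 1, 1 / 60, 1 / 60, 1 / 3600, 1 / 3600, 1 / 3600,
               1000, 1, 1e-3, 1e-3, 1e-6),
    stringsAsFactors = FALSE
  )
}

# vectorized lookup; NA for unknown units
unit_factor <- function(unit, param_kind) {
  tab <- unit_conversion_table()
  key <- paste(param_kind, unit, sep = "\r")
  tk <- paste(tab$param_kind, tab$unit, sep = "\r")
  tab$factor[match(key, tk)]
}

#' Convert a kinetic value to its canonical unit
#'
#' kcat values are expressed in s^-1, Km values in mM. Only units in
#' [unit_conversion_table()] are accepted.
#'
#' @param value numeric vector of raw values.
#' @param unit character vector of unit strings.
#' @param param_kind `"kcat"` or `"km"` (recycled).
#' @return Numeric vector in the canonical unit.
#' @examples
#' normalize_unit(120, "min^-1", "kcat")  # 2 s^-1
#' normalize_unit(500, "uM", "km")        # 0.5 mM
#' @export
normalize_unit <- function(value, unit, param_kind) {
  f <- unit_factor(unit, param_kind)
  if (anyNA(f)) {
    i <- which(is.na(f))[1]
    stopf("unknown unit '%s' for %s", unit[min(i, length(unit))],
          param_kind[min(i, length(param_kind))])
  }
  value * f
}

#' Log10-transform a positive kinetic value
#'
#' Model labels and all reported metrics live on the log10 scale.
#' Non-positive values must have been filtered out upstream and are an
#' error here.
#'
#' @param value numeric vector, strictly positive.
#' @return `log10(value)`.
#' @export
log_transform <- function(value) {
  if (any(!is.finite(value) | value <= 0)) {
    stopf("log_transform requires strictly positive finite values")
  }
  log10(value)
}

#' Label-pattern accounting for a curated dataset
#'
#' Counts entries by which labels they carry: both kcat and Km, kcat only,
#' or Km only. The identities
#' `n_kcat_total = n_both + n_kcat_only`,
#' `n_km_total = n_both + n_km_only` and
#' `n_union = n_both + n_kcat_only + n_km_only` hold by construction.
#'
#' @param entries a `curated_entries` data.frame (or any data.frame with
#'   `log10_kcat` / `log10_km` columns where `NA` marks a missing label).
#' @return Object of class `dataset_accounting`: a list with fields
#'   `n_both`, `n_kcat_only`, `n_km_only`, `n_kcat_total`, `n_km_total`,
#'   `n_union`.
#' @export
accounting <- function(entries) {
  has_kcat <- !is.na(entries$log10_kcat)
  has_km <- !is.na(entries$log10_km)
  if (any(!has_kcat & !has_km)) {
    stopf("curated entries must carry at least one label")
  }
  out <- list(
    n_both = sum(has_kcat & has_km),
    n_kcat_only = sum(has_kcat & !has_km),
    n_km_only = sum(!has_kcat & has_km)
  )
  out$n_kcat_total <- out$n_both + out$n_kcat_only
  out$n_km_total <- out$n_both + out$n_km_only
  out$n_union <- out$n_both + out$n_kcat_only + out$n_km_only
  structure(out, class = "dataset_accounting")
}

#' @export
print.dataset_accounting <- function(x, ...) {
  cat("Dataset accounting\n")
  cat(sprintf("  both labels : %d\n", x$n_both))
  cat(sprintf("  kcat only   : %d\n", x$n_kcat_only))
  cat(sprintf("  Km only     : %d\n", x$n_km_only))
  cat(sprintf("  kcat total  : %d\n", x$n_kcat_total))
  cat(sprintf("  Km total    : %d\n", x$n_km_total))
  cat(sprintf("  union       : %d\n", x$n_union))
  invisible(x)
}

#' Label pattern of each curated entry
#'
#' @param entries curated entries.
#' @return character vector in `{"both","kcat_only","km_only"}`.
#' @export
label_pattern <- function(entries) {
  has_kcat <- !is.na(entries$log10_kcat)
  has_km <- !is.na(entries$log10_km)
  ifelse(has_kcat & has_km, "both", ifelse(has_kcat, "kcat_only", "km_only"))
}

#' Read kinetic records from CSV/TSV, optionally resolving sequences from FASTA
#'
#' The delimiter is inferred from the file extension (`.tsv` uses tab).
#' If `fasta` is given, rows whose `sequence` is empty are filled by looking
#' up their `id` among the FASTA headers (first whitespace-delimited token).
#'
#' @param path CSV/TSV file in the [kinetic_records()] column schema.
#' @param fasta optional FASTA file keyed by record id.
#' @return A `kinetic_records` data.frame.
#' @export
read_kinetic_records <- function(path, fasta = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          quote = "\"", comment.char = "")
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    need <- is.na(df$sequence) | !nzchar(df$sequence)
    hit <- match(df$id[need], names(seqs))
    df$sequence[need][!is.na(hit)] <- unname(seqs[hit[!is.na(hit)]])
  }
  kinetic_records(df)
}

# minimal FASTA reader (plain text, sequences joined across lines)
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stopf("no FASTA headers found in %s", path)
  grp <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- ids[as.integer(names(seqs))]
  seqs
}

#' @export
write_kinetic_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
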