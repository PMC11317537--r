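#' @name curation
#' @title Cleaning pipeline for raw kinetic records
#' @description
#' Multi-round cleaning of BRENDA/SABIO-RK style exports: completeness
#' filter, unit normalization, mutation application, SMILES
#' canonicalization, structural and value filters, duplicate aggregation
#' (maximum kcat, minimum Km per identical assay key), and the outer join
#' of the two tasks into joint multitask entries.
NULL

required_fields <- c("ec_number", "enzyme_type", "sequence",
                     "substrate_smiles", "organism", "ph", "temperature",
                     "value", "unit")

key_cols <- c("canonical_smiles", "sequence", "ph", "temperature", "organism")

field_missing <- function(x) {
  if (is.character(x)) is.na(x) | !nzchar(trimws(x)) else is.na(x)
}

#' Drop records with any required field missing
#'
#' Required: EC number, enzyme type, sequence, substrate SMILES, organism,
#' pH, temperature, value and unit. Empty strings count as missing.
#'
#' @param records `kinetic_records`.
#' @return list with elements `kept` and `dropped` (the latter gains a
#'   `reason` column).
#' @export
drop_incomplete <- function(records) {
  miss <- Reduce(`|`, lapply(required_fields, function(f) {
    field_missing(records[[f]])
  }))
  split_kept(records, !miss, "incomplete")
}

split_kept <- function(records, keep, reason) {
  dropped <- as.data.frame(records)[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Canonicalize SMILES strings
#'
#' Deterministic canonicalization through Open Babel, so that structurally
#' identical encodings (atom-order permutations, kekulized vs aromatic
#' rings) collapse to one string. Used to remove substrate-synonym
#' redundancy before duplicate aggregation.
#'
#' @param smiles character vector.
#' @param on_error `"error"` (default) aborts on the first unparseable
#'   string; `"na"` returns `NA` for it.
#' @return character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    idx <- which(ok)
    src <- paste(paste(smiles[idx], seq_along(idx)), collapse = "\n")
    res <- suppressMessages(suppressWarnings(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))
    ))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- regmatches(lines, regexpr("\\S+$", lines))
    can <- trimws(sub("\\s+\\S+$", "", lines))
    pos <- suppressWarnings(as.integer(parts))
    good <- !is.na(pos) & nzchar(can)
    out[idx[pos[good]]] <- can[good]
  }
  if (on_error == "error" && any(ok & is.na(out))) {
    stopf("unparseable SMILES: '%s'", smiles[which(ok & is.na(out))[1]])
  }
  out
}

#' Count heavy (non-hydrogen) atoms of SMILES strings
#'
#' @param smiles character vector.
#' @return integer vector; `NA` where the SMILES cannot be parsed.
#' @export
heavy_atom_count <- function(smiles) {
  out <- rep(NA_integer_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste(paste(smiles[idx], seq_along(idx)), collapse = "\n")
  sdf <- suppressMessages(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(src, "\n"))
  ))
  mols <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  for (m in mols) {
    lines <- strsplit(m, "\n", fixed = TRUE)[[1]]
    lines <- lines[cumsum(nzchar(lines)) > 0 | nzchar(lines)]
    # leading blank lines stripped; first non-empty line is the id
    first <- which(nzchar(trimws(lines)))[1]
    if (is.na(first)) next
    pos <- suppressWarnings(as.integer(trimws(lines[first])))
    cnt <- grep("V2000", lines)
    if (is.na(pos) || !length(cnt)) next
    natoms <- suppressWarnings(as.integer(substr(lines[cnt[1]], 1, 3)))
    if (is.na(natoms)) next
    atoms <- lines[(cnt[1] + 1):(cnt[1] + natoms)]
    sym <- trimws(substr(atoms, 32, 34))
    out[idx[pos]] <- sum(sym != "H" & sym != "D" & sym != "T")
  }
  out
}

#' Structural filter on substrates
#'
#' Keeps records whose substrate SMILES parses, contains no fragment dot,
#' and has a heavy-atom count h with 2 < h <= 128.
#'
#' @param records `kinetic_records`.
#' @return list `(kept, dropped)`; dropped rows carry reason codes
#'   `unparseable_smiles`, `fragment_smiles` or `heavy_atoms_out_of_range`.
#' @export
filter_structure <- function(records) {
  smi <- records$substrate_smiles
  frag <- grepl(".", smi, fixed = TRUE)
  h <- rep(NA_integer_, nrow(records))
  h[!frag] <- heavy_atom_count(smi[!frag])
  unparse <- !frag & is.na(h)
  bad_h <- !frag & !unparse & (h <= 2 | h > 128)
  keep <- !(frag | unparse | bad_h)
  dropped <- as.data.frame(records)[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(frag[!keep], "fragment_smiles",
                             ifelse(unparse[!keep], "unparseable_smiles",
                                    "heavy_atoms_out_of_range"))
  }
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Value filter
#'
#' Keeps records with strictly positive, finite kinetic values (a
#' non-positive value has no log10 and is always a data error).
#'
#' @param records `kinetic_records`.
#' @return list `(kept, dropped)` with reason `nonpositive_value`.
#' @export
filter_values <- function(records) {
  keep <- !is.na(records$value) & is.finite(records$value) &
    records$value > 0
  split_kept(records, keep, "nonpositive_value")
}

#' Apply point-mutation codes to a wild-type sequence
#'
#' Substitution codes use the standard `<ref><1-based position><new>`
#' notation, e.g. `"A123V"`. The reference residue is checked against the
#' wild-type sequence; mismatches and out-of-range positions are errors.
#' Only substitutions are supported.
#'
#' @param wild_sequence amino-acid string.
#' @param codes character vector of substitution codes (a single
#'   semicolon/comma-separated string is also accepted).
#' @return The mutated sequence (same length as input).
#' @examples
#' apply_mutations("MKT", c("M1V", "T3S"))  # "VKS"
#' @export
apply_mutations <- function(wild_sequence, codes) {
  if (length(codes) == 1L && grepl("[;,]", codes)) {
    codes <- strsplit(codes, "[;,]\\s*")[[1]]
  }
  codes <- codes[!is.na(codes) & nzchar(codes)]
  if (!length(codes)) return(wild_sequence)
  chars <- strsplit(wild_sequence, "")[[1]]
  for (code in codes) {
    m <- regmatches(code, regexec("^([A-Za-z])(\\d+)([A-Za-z])$", code))[[1]]
    if (!length(m)) stopf("malformed mutation code '%s'", code)
    pos <- as.integer(m[3])
    if (pos < 1L || pos > length(chars)) {
      stopf("mutation '%s': position %d out of range (length %d)",
            code, pos, length(chars))
    }
    if (toupper(chars[pos]) != toupper(m[2])) {
      stopf("mutation '%s': position %d holds %s, not %s",
            code, pos, chars[pos], toupper(m[2]))
    }
    chars[pos] <- toupper(m[4])
  }
  paste(chars, collapse = "")
}

# apply mutations across a record table; failures become dropped rows
apply_mutations_records <- function(records) {
  is_mut <- !is.na(records$enzyme_type) & records$enzyme_type == "mutant" &
    !is.na(records$mutation_codes) & nzchar(records$mutation_codes)
  err <- rep(NA_character_, nrow(records))
  seqs <- records$sequence
  for (i in which(is_mut)) {
    res <- tryCatch(apply_mutations(seqs[i], records$mutation_codes[i]),
                    error = function(e) e)
    if (inherits(res, "error")) err[i] <- conditionMessage(res) else
      seqs[i] <- res
  }
  records$sequence <- seqs
  keep <- is.na(err)
  dropped <- as.data.frame(records)[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- paste0("mutation_error: ", err[!keep])
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

# normalize units across a table; unknown units become dropped rows
normalize_units_records <- function(records) {
  f <- unit_factor(records$unit, records$param_kind)
  keep <- !is.na(f)
  records$value[keep] <- records$value[keep] * f[keep]
  records$unit[keep] <- ifelse(records$param_kind[keep] == "kcat",
                               "s^-1", "mM")
  split_kept(records, keep, "unknown_unit")
}

#' Collapse duplicates and aggregate repeated measurements
#'
#' Records sharing the full assay key (canonical SMILES, sequence, pH,
#' temperature, organism) are reduced to one value per parameter:
#' byte-identical repeats (same key and same value) collapse as duplicates;
#' groups with differing values keep the maximum kcat or the minimum Km.
#' Aggregation happens on the linear (canonical-unit) scale, before the
#' log10 transform.
#'
#' @param records unit-normalized records with a `canonical_smiles` column.
#' @return list with `entries` (one row per key and param_kind, value on
#'   the canonical linear scale), `n_duplicate` (byte-identical copies
#'   removed) and `n_aggregated` (distinct values merged away).
#' @export
dedup_and_aggregate <- function(records) {
  df <- as.data.frame(records)
  if (!nrow(df)) {
    return(list(entries = df, n_duplicate = 0L, n_aggregated = 0L))
  }
  gkey <- paste(df$canonical_smiles, df$sequence, df$ph, df$temperature,
                df$organism, df$param_kind, sep = "\r")
  dup <- duplicated(paste(gkey, df$value, sep = "\r"))
  n_duplicate <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  gkey <- gkey[!dup]
  groups <- split(seq_len(nrow(df)), gkey)
  pick <- vapply(groups, function(ix) {
    v <- df$value[ix]
    if (df$param_kind[ix[1]] == "kcat") ix[which.max(v)] else ix[which.min(v)]
  }, integer(1))
  n_aggregated <- nrow(df) - length(pick)
  entries <- df[sort(pick), , drop = FALSE]
  rownames(entries) <- NULL
  list(entries = entries, n_duplicate = n_duplicate,
       n_aggregated = n_aggregated)
}

#' Outer-join kcat and Km entries into joint multitask entries
#'
#' Entries sharing the assay key carry both labels; the rest carry one.
#'
#' @param kcat_entries,km_entries per-task tables from
#'   [dedup_and_aggregate()] with `log10_value` columns.
#' @return A `curated_entries` data.frame with `log10_kcat` / `log10_km`
#'   columns (`NA` where the label is absent).
#' @export
merge_tasks <- function(kcat_entries, km_entries) {
  carry <- c(key_cols, "ec_number", "enzyme_type", "mutation_codes")
  prep <- function(df, label) {
    if (!nrow(df)) {
      out <- data.frame(canonical_smiles = character(0),
                        sequence = character(0), ph = numeric(0),
                        temperature = numeric(0), organism = character(0),
                        ec_number = character(0), enzyme_type = character(0),
                        mutation_codes = character(0), v = numeric(0))
      names(out)[ncol(out)] <- label
      return(out)
    }
    out <- df[c(carry, "log10_value")]
    names(out)[ncol(out)] <- label
    out
  }
  a <- prep(kcat_entries, "log10_kcat")
  b <- prep(km_entries, "log10_km")
  joint <- merge(a, b, by = key_cols, all = TRUE, suffixes = c("", ".km"))
  # metadata columns: prefer the kcat side, fall back to the Km side
  for (f in c("ec_number", "enzyme_type", "mutation_codes")) {
    alt <- paste0(f, ".km")
    if (alt %in% names(joint)) {
      take <- is.na(joint[[f]])
      joint[[f]][take] <- joint[[alt]][take]
      joint[[alt]] <- NULL
    }
  }
  joint <- joint[c(key_cols, "ec_number", "enzyme_type", "mutation_codes",
                   "log10_kcat", "log10_km")]
  joint <- joint[order(joint$canonical_smiles, joint$sequence, joint$ph,
                       joint$temperature, joint$organism), , drop = FALSE]
  rownames(joint) <- NULL
  class(joint) <- c("curated_entries", "data.frame")
  joint
}

#' Run the full curation pipeline
#'
#' Stages, in order: completeness filter, unit normalization (canonical
#' s^-1 / mM), mutation application, SMILES canonicalization, structural
#' filter (parseable, no fragment dot, 2 < heavy atoms <= 128), value
#' filter (> 0), duplicate collapse and max-kcat/min-Km aggregation per
#' assay key, log10 transform, and the kcat/Km outer join. Per-record
#' failures are logged with reason codes, never aborting the batch.
#'
#' @param records `kinetic_records`.
#' @return list with `entries` (a `curated_entries` data.frame) and
#'   `report` (a `curation_report`).
#' @export
curate_pipeline <- function(records) {
  records <- kinetic_records(as.data.frame(records))
  n_input <- nrow(records)
  reasons <- data.frame(id = character(0), reason = character(0))
  log_drop <- function(dropped) {
    if (nrow(dropped)) {
      reasons <<- rbind(reasons,
                        data.frame(id = dropped$id, reason = dropped$reason))
    }
  }

  s1 <- drop_incomplete(records); log_drop(s1$dropped)
  s2 <- normalize_units_records(s1$kept); log_drop(s2$dropped)
  s3 <- apply_mutations_records(s2$kept); log_drop(s3$dropped)

  rec <- s3$kept
  rec$canonical_smiles <- canonicalize_smiles(rec$substrate_smiles,
                                              on_error = "na")
  s4a <- split_kept(rec, !is.na(rec$canonical_smiles), "unparseable_smiles")
  log_drop(s4a$dropped)
  s4 <- filter_structure(s4a$kept); log_drop(s4$dropped)
  s5 <- filter_values(s4$kept); log_drop(s5$dropped)

  rec <- s5$kept
  agg_kcat <- dedup_and_aggregate(rec[rec$param_kind == "kcat", , drop = FALSE])
  agg_km <- dedup_and_aggregate(rec[rec$param_kind == "km", , drop = FALSE])
  add_log <- function(df) {
    df$log10_value <- if (nrow(df)) log_transform(df$value) else numeric(0)
    df
  }
  entries <- merge_tasks(add_log(agg_kcat$entries), add_log(agg_km$entries))

  n_frag_or_nonpos <- nrow(s4a$dropped) +
    sum(s4$dropped$reason %in% c("fragment_smiles", "unparseable_smiles")) +
    nrow(s5$dropped)
  report <- structure(list(
    n_input = n_input,
    n_dropped_incomplete = nrow(s1$dropped),
    n_dropped_unknown_unit = nrow(s2$dropped),
    n_dropped_mutation = nrow(s3$dropped),
    n_dropped_heavy_atoms = sum(s4$dropped$reason == "heavy_atoms_out_of_range"),
    n_dropped_fragment_or_nonpositive = n_frag_or_nonpos,
    n_dropped_duplicate = agg_kcat$n_duplicate + agg_km$n_duplicate,
    n_aggregated = agg_kcat$n_aggregated + agg_km$n_aggregated,
    n_output = nrow(agg_kcat$entries) + nrow(agg_km$entries),
    n_joint = nrow(entries),
    reasons = reasons
  ), class = "curation_report")

  list(entries = entries, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input records              : %d\n", x$n_input))
  cat(sprintf("  dropped incomplete         : %d\n", x$n_dropped_incomplete))
  cat(sprintf("  dropped unknown unit       : %d\n", x$n_dropped_unknown_unit))
  cat(sprintf("  dropped mutation error     : %d\n", x$n_dropped_mutation))
  cat(sprintf("  dropped heavy-atom range   : %d\n", x$n_dropped_heavy_atoms))
  cat(sprintf("  dropped fragment/nonpos.   : %d\n",
              x$n_dropped_fragment_or_nonpositive))
  cat(sprintf("  duplicate copies removed   : %d\n", x$n_dropped_duplicate))
  cat(sprintf("  aggregated (max/min rule)  : %d\n", x$n_aggregated))
  cat(sprintf("  output measurements        : %d\n", x$n_output))
  cat(sprintf("  joint multitask entries    : %d\n", x$n_joint))
  invisible(x)
}

#' Convert curated entries back to per-measurement records
#'
#' One record per available label, in canonical units, with mutations
#' already applied (so `mutation_codes` is cleared). Running
#' [curate_pipeline()] on the result reproduces the same entries, which is
#' the pipeline's idempotence contract.
#'
#' @param entries `curated_entries`.
#' @return `kinetic_records`.
#' @export
entries_to_records <- function(entries) {
  rows <- list()
  for (kind in c("kcat", "km")) {
    col <- paste0("log10_", kind)
    sub <- entries[!is.na(entries[[col]]), , drop = FALSE]
    if (!nrow(sub)) next
    rows[[kind]] <- data.frame(
      ec_number = sub$ec_number, enzyme_type = sub$enzyme_type,
      mutation_codes = "", sequence = sub$sequence,
      substrate_name = NA_character_,
      substrate_smiles = sub$canonical_smiles, organism = sub$organism,
      ph = sub$ph, temperature = sub$temperature, param_kind = kind,
      value = 10^sub[[col]],
      unit = if (kind == "kcat") "s^-1" else "mM",
      source = "curated", stringsAsFactors = FALSE)
  }
  kinetic_records(do.call(rbind, rows))
}

#' @export
write_curated_entries <- function(entries, path) {
  utils::write.csv(as.data.frame(entries), path, row.names = FALSE)
  invisible(path)
}

#' @export
read_curated_entries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  class(df) <- c("curated_entries", "data.frame")
  df
}
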