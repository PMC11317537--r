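# fixtures built in code, shared across test files

# curated entries with a prescribed label pattern
make_pattern_entries <- function(n_both, n_kcat_only, n_km_only) {
  n <- n_both + n_kcat_only + n_km_only
  pattern <- rep(c("both", "kcat_only", "km_only"),
                 c(n_both, n_kcat_only, n_km_only))
  df <- data.frame(
    canonical_smiles = sprintf("C%d", seq_len(n)),
    sequence = sprintf("SEQ%d", seq_len(n)),
    ph = rep(7, n), temperature = rep(25, n), organism = rep("org", n),
    ec_number = rep("1.1.1.1", n), enzyme_type = rep("wild_type", n),
    mutation_codes = rep("", n),
    log10_kcat = ifelse(pattern != "km_only", 1, NA),
    log10_km = ifelse(pattern != "kcat_only", -1, NA),
    stringsAsFactors = FALSE)
  class(df) <- c("curated_entries", "data.frame")
  df
}

# one fully populated raw record, with overridable fields
make_record <- function(...) {
  base <- data.frame(
    ec_number = "1.1.1.1", enzyme_type = "wild_type", mutation_codes = "",
    sequence = "MKTAYIAKQR", substrate_name = "ethanol",
    substrate_smiles = "CCO", organism = "Escherichia coli",
    ph = 7.0, temperature = 25.0, param_kind = "kcat",
    value = 2.0, unit = "s^-1", source = "synthetic",
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

make_records <- function(...) {
  kinetic_records(do.call(rbind, list(...)))
}

# small featurized setup for model tests
small_setup <- function(n = 30, seed = 1, d_enz = 6, d_sub = 4, d_aux = 4) {
  withr::local_seed(seed)
  entries <- data.frame(
    canonical_smiles = replicate(n, paste(
      sample(c("C", "N", "O"), sample(3:8, 1), replace = TRUE),
      collapse = "")),
    sequence = kinetmoe::gen_sequences(n, c(8L, 15L), seed = seed + 1L),
    ph = round(runif(n, 5, 9), 2),
    temperature = round(runif(n, 20, 60), 1),
    organism = sample(paste0("org", 1:4), n, replace = TRUE),
    ec_number = "1.1.1.1",
    enzyme_type = sample(c("wild_type", "mutant"), n, replace = TRUE),
    mutation_codes = "",
    log10_kcat = rnorm(n), log10_km = rnorm(n),
    stringsAsFactors = FALSE)
  drop_kcat <- sample(n, round(n / 5))
  drop_km <- sample(setdiff(seq_len(n), drop_kcat), round(n / 5))
  entries$log10_kcat[drop_kcat] <- NA
  entries$log10_km[drop_km] <- NA
  class(entries) <- c("curated_entries", "data.frame")
  spec <- feature_spec(entries, hash_embedder(d_enz, salt = 1L),
                       hash_embedder(d_sub, salt = 2L), aux_dim = d_aux)
  list(entries = entries, spec = spec,
       fs = featurize_entries(entries, spec))
}

# flatten/restore nested parameter trees (for finite-difference checks)
flat_params <- function(p) unlist(p, use.names = FALSE)
unflat_params <- function(v, skeleton) utils::relist(v, skeleton)

# materialize the fused matrix of a feature set under given aux params
fused_of <- function(fs, aux) {
  kinetmoe:::fused_matrix(list(XB = fs$XB, R_ph = fs$R_ph,
                               R_temp = fs$R_temp, org_idx = fs$org_idx),
                          aux)
}
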