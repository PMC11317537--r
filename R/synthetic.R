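#' @name synthetic
#' @title Deterministic embedders and a seeded generative benchmark
#' @description
#' Stand-ins that make the whole pipeline testable offline: hash-based
#' embedders satisfying the embedding contract, generators for amino-acid
#' sequences and small toy SMILES (including deliberate filter
#' violators), a generative model with a controllable shared-signal
#' fraction between the kcat and Km tasks and a known Bayes-optimal R2,
#' and case-study constructors with an exact number of correctly
#' predicted efficiency directions.
NULL

amino_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Deterministic hash embedder
#'
#' Maps any string to a unit-norm vector of the requested dimension.
#' Two independent rolling hashes of (salt, text) seed a fixed
#' pseudo-random draw whose sum is L2-normalized, so the map is
#' deterministic, sensitive to single-character changes, and collisions
#' require both hashes to coincide. This is the shipped default for the
#' enzyme and substrate embedder slots; adapters around pretrained
#' language-model embeddings plug into the same [embedder()] contract.
#'
#' @param dim output dimension.
#' @param salt integer distinguishing embedder instances (use different
#'   salts for the enzyme and substrate embedders).
#' @param name identifier.
#' @return an [embedder()].
#' @export
hash_embedder <- function(dim, salt = 0L, name = sprintf("hash%d", salt)) {
  dim <- as.integer(dim)
  fn <- function(texts) {
    out <- matrix(0, length(texts), dim)
    for (i in seq_along(texts)) {
      h <- string_hashes(texts[i], salt = salt)
      v <- with_seed(h[1], stats::rnorm(dim)) +
        with_seed(h[2], stats::rnorm(dim))
      out[i, ] <- v / sqrt(sum(v^2))
    }
    out
  }
  embedder(name, dim, fn)
}

#' Generate random amino-acid sequences
#'
#' @param n number of sequences.
#' @param length_range `(min, max)` sequence length.
#' @param seed integer seed.
#' @return character vector over the 20-letter alphabet.
#' @export
gen_sequences <- function(n, length_range = c(12L, 30L), seed = 1L) {
  stopifnot(length_range[1] >= 1)
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(amino_alphabet, L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# one random acyclic C/N/O SMILES with exactly `heavy` heavy atoms;
# branches hang off chain carbons, heteroatoms stay in the chain interior
random_chain_smiles <- function(heavy) {
  if (heavy <= 2) return(strrep("C", heavy))
  atoms <- sample(c("C", "N", "O"), heavy, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  n_branch <- if (heavy >= 6) sample(0:min(2, heavy %/% 4), 1) else 0
  main <- heavy - n_branch
  s <- atoms[seq_len(main)]
  if (n_branch > 0) {
    cpos <- which(s == "C")
    cpos <- cpos[cpos > 1 & cpos < main]
    if (length(cpos)) {
      at <- cpos[sample.int(length(cpos), n_branch, replace = TRUE)]
      for (pos in at) s[pos] <- paste0(s[pos], "(C)")
    } else {
      s <- c(s, rep("C", n_branch))  # no interior carbon: extend the chain
    }
  }
  paste(s, collapse = "")
}

#' Generate toy substrate SMILES
#'
#' Acyclic chains over C/N/O with controllable heavy-atom counts, plus
#' on-demand violators of the structural filters.
#'
#' @param n number of SMILES.
#' @param seed integer seed.
#' @param heavy_range range of heavy-atom counts for valid substrates.
#' @param violator `NULL` for valid substrates, or one of `"tiny"`
#'   (<= 2 heavy atoms), `"huge"` (> 128), `"fragment"` (contains a dot),
#'   `"invalid"` (unparseable).
#' @return character vector of SMILES.
#' @export
gen_substrates <- function(n, seed = 1L, heavy_range = c(3L, 40L),
                           violator = NULL) {
  with_seed(seed, {
    if (is.null(violator)) {
      heavy <- sample(heavy_range[1]:heavy_range[2], n, replace = TRUE)
      return(vapply(heavy, random_chain_smiles, character(1)))
    }
    switch(violator,
      tiny = sample(c("O", "C", "N", "CC", "CO", "CN"), n, replace = TRUE),
      huge = vapply(sample(129:140, n, replace = TRUE), strrep,
                    character(1), x = "C"),
      fragment = vapply(seq_len(n), function(i) {
        paste0(random_chain_smiles(sample(3:10, 1)), ".",
               random_chain_smiles(sample(3:10, 1)))
      }, character(1)),
      invalid = rep("C(#Q", n),
      stopf("unknown violator mode '%s'", violator))
  })
}

#' Specification of a synthetic kinetic dataset
#'
#' Defaults emulate the shape of a curated BRENDA/SABIO-RK multitask
#' dataset at desk scale: label-pattern proportions matching the real
#' corpus (50.4% both, 12.9% kcat-only, 36.6% Km-only), a high shared
#' signal fraction between the two tasks (`rho = 0.9`), and Gaussian
#' label noise with `noise_sd = 0.5` relative to unit-variance signal,
#' i.e. a Bayes-optimal R2 of `1 / (1 + noise_sd^2) = 0.8`.
#'
#' @param n_entries number of joint entries.
#' @param seq_length_range enzyme sequence length range.
#' @param missing_props probabilities of (both, kcat_only, km_only).
#' @param rho shared-signal fraction in `[0, 1]`: the label of task t is
#'   `rho * u + (1 - rho) * v_t` (plus noise) with u common to both tasks.
#' @param noise_sd label noise standard deviation (signals are
#'   standardized to unit variance).
#' @param n_organisms size of the organism pool.
#' @param mutant_fraction fraction of entries that are mutants (wild
#'   sequence + substitution codes in the emitted records).
#' @param duplicate_rate fraction of measurements that get planted
#'   same-key duplicates (exercising max-kcat/min-Km aggregation).
#' @param planted_violations named counts of invalid records to append:
#'   any of `incomplete`, `tiny`, `huge`, `fragment`, `nonpositive`,
#'   `unknown_unit`, `bad_mutation`.
#' @param enzyme_dim,substrate_dim,aux_dim embedding dimensions of the
#'   generative features (desk-scale defaults).
#' @param seed integer seed.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_entries = 500L,
                       seq_length_range = c(12L, 30L),
                       missing_props = c(both = 0.504, kcat_only = 0.129,
                                         km_only = 0.367),
                       rho = 0.9,
                       noise_sd = 0.5,
                       n_organisms = 20L,
                       mutant_fraction = 0.35,
                       duplicate_rate = 0.1,
                       planted_violations = NULL,
                       enzyme_dim = 16L,
                       substrate_dim = 8L,
                       aux_dim = 8L,
                       seed = 1L) {
  stopifnot(abs(sum(missing_props) - 1) < 1e-8, rho >= 0, rho <= 1,
            noise_sd >= 0, mutant_fraction >= 0, mutant_fraction <= 1)
  structure(list(
    n_entries = as.integer(n_entries),
    seq_length_range = as.integer(seq_length_range),
    missing_props = missing_props,
    rho = rho, noise_sd = noise_sd,
    n_organisms = as.integer(n_organisms),
    mutant_fraction = mutant_fraction,
    duplicate_rate = duplicate_rate,
    planted_violations = planted_violations,
    enzyme_dim = as.integer(enzyme_dim),
    substrate_dim = as.integer(substrate_dim),
    aux_dim = as.integer(aux_dim),
    seed = as.integer(seed)
  ), class = "synth_spec")
}

# render a canonical-unit value in a randomly chosen legal raw unit
vary_unit <- function(value, param_kind) {
  if (param_kind == "kcat") {
    u <- sample(c("s^-1", "min^-1", "h^-1"), 1, prob = c(0.6, 0.3, 0.1))
    f <- c("s^-1" = 1, "min^-1" = 60, "h^-1" = 3600)[[u]]
  } else {
    u <- sample(c("mM", "uM", "M"), 1, prob = c(0.6, 0.3, 0.1))
    f <- c("mM" = 1, "uM" = 1000, "M" = 1e-3)[[u]]
  }
  list(value = value * f, unit = u)
}

#' Generate a schema-complete synthetic kinetic dataset
#'
#' Draws enzymes (a pool, so enzymes recur with several substrates),
#' substrates, organisms and assay conditions; computes fused generative
#' features from hash embedders plus fixed random projections of the RBF
#' expansions; generates correlated task labels
#' `label_t = rho u + (1 - rho) v_t + noise` with signals standardized to
#' unit variance (plus task-specific offsets so values land in realistic
#' decades); and emits raw records with unit variety, planted same-key
#' duplicate groups, mutants expressed as wild sequence + substitution
#' codes, and the requested filter violators. Fully deterministic under
#' the spec seed.
#'
#' @param spec [synth_spec()].
#' @return list with `records` (a `kinetic_records` table) and `truth`
#'   (generative coefficients, per-entry latent factors and noiseless
#'   labels, keyed by the mutated sequence and substrate).
#' @export
gen_dataset <- function(spec) {
  with_seed(spec$seed, {
    n <- spec$n_entries
    n_seq <- max(2L, ceiling(n / 3))
    n_sub <- max(2L, ceiling(n / 4))
    seq_pool <- gen_sequences(n_seq, spec$seq_length_range,
                              seed = spec$seed + 11L)
    sub_pool <- gen_substrates(n_sub, seed = spec$seed + 13L)
    organisms <- paste0("Organism_", seq_len(spec$n_organisms))

    wild_seq <- sample(seq_pool, n, replace = TRUE)
    smiles <- sample(sub_pool, n, replace = TRUE)
    organism <- sample(organisms, n, replace = TRUE)
    ph <- round(stats::runif(n, 5, 9), 2)
    temperature <- round(stats::runif(n, 20, 60), 1)
    ec <- paste0(sample(1:7, n, replace = TRUE), ".",
                 sample(1:20, n, replace = TRUE), ".",
                 sample(1:20, n, replace = TRUE), ".",
                 sample(1:99, n, replace = TRUE))

    is_mut <- stats::runif(n) < spec$mutant_fraction
    codes <- character(n)
    final_seq <- wild_seq
    for (i in which(is_mut)) {
      chars <- strsplit(wild_seq[i], "")[[1]]
      n_mut <- sample(1:2, 1)
      pos <- sample(seq_along(chars), n_mut)
      cds <- character(n_mut)
      for (j in seq_len(n_mut)) {
        new <- sample(setdiff(amino_alphabet, chars[pos[j]]), 1)
        cds[j] <- paste0(chars[pos[j]], pos[j], new)
        chars[pos[j]] <- new
      }
      codes[i] <- paste(cds, collapse = ";")
      final_seq[i] <- paste(chars, collapse = "")
    }

    # generative fused features: hash embeddings of the *mutated* sequence
    # and the substrate, plus fixed random projections of the rbf-encoded
    # conditions and a random organism table
    enz <- embed_strings(hash_embedder(spec$enzyme_dim, salt = 1L),
                         final_seq)
    sub <- embed_strings(hash_embedder(spec$substrate_dim, salt = 2L),
                         smiles)
    ph_centers <- build_rbf_centers(c(5, 9), stride = 0.1)
    t_centers <- build_rbf_centers(c(20, 60), stride = 0.1)
    W_ph <- matrix(stats::rnorm(length(ph_centers) * spec$aux_dim,
                                sd = 1 / sqrt(length(ph_centers))),
                   length(ph_centers), spec$aux_dim)
    W_t <- matrix(stats::rnorm(length(t_centers) * spec$aux_dim,
                               sd = 1 / sqrt(length(t_centers))),
                  length(t_centers), spec$aux_dim)
    E_org <- matrix(stats::rnorm(spec$n_organisms * spec$aux_dim,
                                 sd = 1 / sqrt(spec$aux_dim)),
                    spec$n_organisms, spec$aux_dim)
    aux <- rbf_expand(ph, ph_centers) %*% W_ph +
      rbf_expand(temperature, t_centers) %*% W_t +
      E_org[match(organism, organisms), , drop = FALSE]
    X <- cbind(enz, sub, aux)
    d <- ncol(X)

    a <- stats::rnorm(d); a <- a / sqrt(sum(a^2))
    b_kcat <- stats::rnorm(d); b_kcat <- b_kcat / sqrt(sum(b_kcat^2))
    b_km <- stats::rnorm(d); b_km <- b_km / sqrt(sum(b_km^2))
    u <- drop(X %*% a)
    v_kcat <- drop(X %*% b_kcat)
    v_km <- drop(X %*% b_km)
    std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
      else x
    sig_kcat <- std(spec$rho * u + (1 - spec$rho) * v_kcat)
    sig_km <- std(spec$rho * u + (1 - spec$rho) * v_km)
    # offsets place values in the decades typical of curated corpora
    log10_kcat <- 0.9 + sig_kcat + stats::rnorm(n, sd = spec$noise_sd)
    log10_km <- -0.9 + sig_km + stats::rnorm(n, sd = spec$noise_sd)

    pattern <- sample(c("both", "kcat_only", "km_only"), n, replace = TRUE,
                      prob = spec$missing_props)

    rows <- list()
    emit <- function(i, kind, value_canon) {
      vu <- vary_unit(value_canon, kind)
      rows[[length(rows) + 1]] <<- data.frame(
        ec_number = ec[i],
        enzyme_type = if (is_mut[i]) "mutant" else "wild_type",
        mutation_codes = codes[i], sequence = wild_seq[i],
        substrate_name = paste0("substrate_", match(smiles[i], sub_pool)),
        substrate_smiles = smiles[i], organism = organism[i],
        ph = ph[i], temperature = temperature[i], param_kind = kind,
        value = vu$value, unit = vu$unit, source = "synthetic",
        stringsAsFactors = FALSE)
      # planted same-key worse measurements: lower kcat / higher Km, so
      # max/min aggregation recovers the true label
      if (stats::runif(1) < spec$duplicate_rate) {
        worse <- if (kind == "kcat") value_canon * stats::runif(1, 0.2, 0.9)
          else value_canon / stats::runif(1, 0.2, 0.9)
        vw <- vary_unit(worse, kind)
        dup <- rows[[length(rows)]]
        dup$value <- vw$value
        dup$unit <- vw$unit
        rows[[length(rows) + 1]] <<- dup
      }
    }
    for (i in seq_len(n)) {
      if (pattern[i] != "km_only") emit(i, "kcat", 10^log10_kcat[i])
      if (pattern[i] != "kcat_only") emit(i, "km", 10^log10_km[i])
    }

    # planted filter violations
    pv <- spec$planted_violations
    if (!is.null(pv)) {
      base <- function() {
        i <- sample(n, 1)
        data.frame(ec_number = ec[i], enzyme_type = "wild_type",
                   mutation_codes = "", sequence = wild_seq[i],
                   substrate_name = "violator",
                   substrate_smiles = random_chain_smiles(sample(3:10, 1)),
                   organism = organism[i], ph = ph[i],
                   temperature = temperature[i], param_kind = "kcat",
                   value = stats::runif(1, 0.1, 10), unit = "s^-1",
                   source = "synthetic", stringsAsFactors = FALSE)
      }
      for (mode in names(pv)) {
        for (r in seq_len(pv[[mode]])) {
          rec <- base()
          if (mode == "incomplete") {
            rec[[sample(c("ec_number", "ph", "temperature", "organism"), 1)]] <- NA
          } else if (mode %in% c("tiny", "huge", "fragment", "invalid")) {
            rec$substrate_smiles <- gen_substrates(
              1, seed = spec$seed + 17L + r, violator = mode)
          } else if (mode == "nonpositive") {
            rec$value <- sample(c(0, -1), 1)
          } else if (mode == "unknown_unit") {
            rec$unit <- "furlongs"
          } else if (mode == "bad_mutation") {
            rec$enzyme_type <- "mutant"
            rec$mutation_codes <- "B1Z"  # malformed reference residue
          }
          rows[[length(rows) + 1]] <- rec
        }
      }
    }

    records <- do.call(rbind, rows)
    records$id <- sprintf("r%05d", seq_len(nrow(records)))
    truth <- list(
      coefficients = list(a = a, b_kcat = b_kcat, b_km = b_km),
      entries = data.frame(
        sequence = final_seq, substrate_smiles = smiles,
        organism = organism, ph = ph, temperature = temperature,
        u = u, v_kcat = v_kcat, v_km = v_km,
        signal_kcat = 0.9 + sig_kcat, signal_km = -0.9 + sig_km,
        log10_kcat = log10_kcat, log10_km = log10_km,
        pattern = pattern, stringsAsFactors = FALSE),
      spec = spec)
    list(records = kinetic_records(records), truth = truth)
  })
}

#' Construct a case study with a known number of correct directions
#'
#' Builds one reference enzyme plus `n_variants` variants with
#' experimental and predicted catalytic efficiencies (log10 kcat/Km) such
#' that exactly `n_correct` variants' predicted change direction matches
#' the experimental direction, as in hit-ratio evaluations of enzyme
#' mining and directed-evolution panels.
#'
#' @param n_variants number of non-reference variants.
#' @param n_correct number whose predicted direction matches.
#' @param seed integer seed (magnitudes only; correctness pattern is
#'   exact by construction).
#' @return data.frame with columns `id`, `role`, `exp_eff`, `pred_eff`.
#' @export
gen_casestudy <- function(n_variants, n_correct, seed = 1L) {
  stopifnot(n_correct >= 0, n_correct <= n_variants, n_variants >= 1)
  with_seed(seed, {
    ref_exp <- stats::runif(1, 1, 3)
    ref_pred <- ref_exp + stats::rnorm(1, sd = 0.2)
    dir_exp <- sample(c(1, -1), n_variants, replace = TRUE, prob = c(0.7, 0.3))
    mag_exp <- stats::runif(n_variants, 0.2, 1.5)
    correct <- seq_len(n_variants) %in% sample(n_variants, n_correct)
    mag_pred <- stats::runif(n_variants, 0.2, 1.5)
    dir_pred <- ifelse(correct, dir_exp, -dir_exp)
    data.frame(
      id = c("reference", sprintf("variant_%d", seq_len(n_variants))),
      role = c("reference", rep("variant", n_variants)),
      exp_eff = c(ref_exp, ref_exp + dir_exp * mag_exp),
      pred_eff = c(ref_pred, ref_pred + dir_pred * mag_pred),
      stringsAsFactors = FALSE)
  })
}
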