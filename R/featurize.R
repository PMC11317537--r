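#' @name featurize
#' @title Feature assembly: embedders, RBF covariate encoding, fusion
#' @description
#' A curated entry becomes one fused numeric vector
#' `[enzyme || substrate || auxiliary]`. Enzyme and substrate vectors come
#' from pluggable embedders (deterministic hash embedders by default, see
#' [hash_embedder()]; adapters for pretrained language-model embeddings
#' satisfy the same contract). pH and temperature are expanded over a grid
#' of Gaussian radial basis functions and mapped linearly to the auxiliary
#' dimension; the organism is looked up in a trainable embedding table;
#' the three auxiliary vectors are summed.
NULL

#' Construct an embedder satisfying the embedding contract
#'
#' An embedder maps a character vector to an `n x dim` numeric matrix,
#' deterministically: the same string always yields the same row.
#'
#' @param name short identifier.
#' @param dim output dimension.
#' @param fn function(character vector) -> numeric matrix with `dim` columns.
#' @return object of class `embedder`; call it via [embed_strings()].
#' @export
embedder <- function(name, dim, fn) {
  stopifnot(is.character(name), length(name) == 1L,
            is_scalar_number(dim), dim >= 1, is.function(fn))
  structure(list(name = name, dim = as.integer(dim), fn = fn),
            class = "embedder")
}

#' Apply an embedder to a character vector
#'
#' @param emb an [embedder()].
#' @param texts character vector.
#' @return numeric matrix, one row per string, `emb$dim` columns.
#' @export
embed_strings <- function(emb, texts) {
  stopifnot(inherits(emb, "embedder"))
  out <- emb$fn(texts)
  if (!is.matrix(out) || ncol(out) != emb$dim || nrow(out) != length(texts)) {
    stopf("embedder '%s' violated its contract (expected %d x %d)",
          emb$name, length(texts), emb$dim)
  }
  out
}

#' Build a radial-basis-function center grid
#'
#' Centers form an arithmetic progression starting at the minimum of the
#' observed values with the given stride, extended until the maximum is
#' covered (the last center is the first grid point >= max).
#'
#' @param values numeric vector of observed covariate values (training
#'   split only; `NA` ignored).
#' @param stride center spacing (default 0.1).
#' @return numeric vector of centers.
#' @export
build_rbf_centers <- function(values, stride = 0.1) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("build_rbf_centers: no values")
  stopifnot(stride > 0)
  lo <- min(values); hi <- max(values)
  n <- floor((hi - lo) / stride + 1e-9)
  centers <- lo + stride * (0:n)
  if (centers[length(centers)] < hi - 1e-12) {
    centers <- c(centers, lo + stride * (n + 1))
  }
  centers
}

#' Expand a scalar covariate over Gaussian radial basis functions
#'
#' Component m is `exp(-gamma * (x - mu_m)^2)`; every component lies in
#' (0, 1] and equals 1 exactly at its center. Missing values (`NA`) expand
#' to a zero row so they contribute nothing downstream.
#'
#' @param x numeric vector.
#' @param centers center grid from [build_rbf_centers()].
#' @param gamma kernel shape parameter (default 10).
#' @return matrix `length(x) x length(centers)`.
#' @export
rbf_expand <- function(x, centers, gamma = 10) {
  stopifnot(gamma > 0, length(centers) >= 1)
  out <- exp(-gamma * outer(x, centers, `-`)^2)
  out[is.na(x), ] <- 0
  out
}

#' Build the feature specification from training data
#'
#' Freezes everything featurization needs: the two embedders, the RBF
#' center grids for pH and temperature (spanning the training range;
#' values outside the span at prediction time simply fall on the Gaussian
#' tails), the organism vocabulary, and the auxiliary dimension.
#'
#' @param train_entries curated entries of the training split.
#' @param enzyme_embedder,substrate_embedder [embedder()] objects.
#' @param aux_dim auxiliary vector width (default 300).
#' @param gamma RBF shape (default 10).
#' @param stride RBF center spacing (default 0.1).
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(train_entries, enzyme_embedder, substrate_embedder,
                         aux_dim = 300, gamma = 10, stride = 0.1) {
  structure(list(
    enzyme_embedder = enzyme_embedder,
    substrate_embedder = substrate_embedder,
    aux_dim = as.integer(aux_dim),
    gamma = gamma,
    stride = stride,
    ph_centers = build_rbf_centers(train_entries$ph, stride),
    temp_centers = build_rbf_centers(train_entries$temperature, stride),
    organism_vocab = sort(unique(train_entries$organism)),
    d_enzyme = enzyme_embedder$dim,
    d_substrate = substrate_embedder$dim
  ), class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf(
    "feature_spec: enzyme %d + substrate %d + aux %d = %d dims\n",
    x$d_enzyme, x$d_substrate, x$aux_dim, input_dim(x)))
  cat(sprintf("  pH centers: %d (%.2f..%.2f), temp centers: %d (%.2f..%.2f)\n",
              length(x$ph_centers), min(x$ph_centers), max(x$ph_centers),
              length(x$temp_centers), min(x$temp_centers),
              max(x$temp_centers)))
  cat(sprintf("  organisms: %d (+1 unknown)\n", length(x$organism_vocab)))
  invisible(x)
}

#' Fused input dimension implied by a feature spec
#' @param spec a `feature_spec`.
#' @export
input_dim <- function(spec) {
  spec$d_enzyme + spec$d_substrate + spec$aux_dim
}

#' Initialize the trainable auxiliary-encoder parameters
#'
#' The linear maps from the two RBF expansions to the auxiliary dimension
#' and the organism embedding table (one row per vocabulary entry plus a
#' reserved unknown row) are model parameters, trained jointly with the
#' rest of the network.
#'
#' @param spec `feature_spec`.
#' @param seed integer seed.
#' @return list with `W_ph`, `W_temp` (centers x aux_dim) and `E_org`
#'   ((vocab+1) x aux_dim).
#' @export
aux_params_init <- function(spec, seed = 1L) {
  with_seed(seed, {
    rmat <- function(nr, nc) {
      lim <- 1 / sqrt(max(nr, 1))
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    list(
      W_ph = rmat(length(spec$ph_centers), spec$aux_dim),
      W_temp = rmat(length(spec$temp_centers), spec$aux_dim),
      E_org = rmat(length(spec$organism_vocab) + 1L, spec$aux_dim)
    )
  })
}

# organism -> row index into E_org; unknown -> reserved last row; NA -> 0
organism_index <- function(organism, spec) {
  idx <- match(organism, spec$organism_vocab)
  unknown <- length(spec$organism_vocab) + 1L
  idx[is.na(idx) & !is.na(organism)] <- unknown
  idx[is.na(organism)] <- 0L
  idx
}

#' Embed an organism name
#'
#' Known organisms index their row of the embedding table; unknown names
#' map to the reserved unknown row; a missing organism contributes zeros.
#'
#' @param name organism string (or `NA`).
#' @param spec `feature_spec`.
#' @param params [aux_params_init()] parameters.
#' @return numeric vector of length `spec$aux_dim`.
#' @export
encode_organism <- function(name, spec, params) {
  i <- organism_index(name, spec)
  if (i == 0L) return(numeric(spec$aux_dim))
  params$E_org[i, ]
}

#' Encode the auxiliary (pH, temperature, organism) information
#'
#' `aux = W_ph' rbf(ph) + W_temp' rbf(temperature) + E_org[organism]`.
#' Any missing component contributes the zero vector, matching the
#' optional-input semantics of the prediction interface.
#'
#' @param ph,temperature scalars or `NA`.
#' @param organism string or `NA`.
#' @param spec `feature_spec`.
#' @param params auxiliary parameters.
#' @return numeric vector of length `spec$aux_dim`.
#' @export
encode_aux <- function(ph, temperature, organism, spec, params) {
  v_ph <- drop(rbf_expand(ph, spec$ph_centers, spec$gamma) %*% params$W_ph)
  v_t <- drop(rbf_expand(temperature, spec$temp_centers, spec$gamma) %*%
                params$W_temp)
  v_ph + v_t + encode_organism(organism, spec, params)
}

#' Column-wise mean pooling
#'
#' Collapses an `n x m` matrix of per-token vectors (e.g. per-residue
#' embeddings) to a single length-m vector of column means.
#'
#' @param m numeric matrix with at least one row.
#' @return numeric vector of column means.
#' @export
mean_pool <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) == 0L) stopf("mean_pool: empty matrix")
  colMeans(m)
}

#' Assemble the fused model input for one curated entry
#'
#' @param entry one-row `curated_entries` data.frame.
#' @param spec `feature_spec`.
#' @param params auxiliary parameters.
#' @return object of class `model_input`: list with `enzyme_vec`,
#'   `substrate_vec`, `aux_vec` and their concatenation `fused`.
#' @export
assemble_input <- function(entry, spec, params) {
  stopifnot(nrow(entry) == 1L)
  ev <- drop(embed_strings(spec$enzyme_embedder, entry$sequence))
  sv <- drop(embed_strings(spec$substrate_embedder, entry$canonical_smiles))
  av <- encode_aux(entry$ph, entry$temperature, entry$organism, spec, params)
  structure(list(enzyme_vec = ev, substrate_vec = sv, aux_vec = av,
                 fused = c(ev, sv, av)), class = "model_input")
}

#' Featurize a table of curated entries for training or prediction
#'
#' Precomputes everything the multitask core consumes: the fixed
#' enzyme+substrate block, the raw RBF expansions (the linear maps onto
#' the auxiliary dimension are trainable and live in the model), organism
#' indices, and the label/mask matrices.
#'
#' @param entries `curated_entries`.
#' @param spec `feature_spec`.
#' @return list of class `feature_set` with elements `XB` (n x
#'   (d_enzyme+d_substrate)), `R_ph`, `R_temp` (RBF expansions), `org_idx`,
#'   `Y` (n x 2 labels, NA-free with `mask` marking observed), `mask`
#'   (n x 2 logical), `spec`, and `entries`.
#' @export
featurize_entries <- function(entries, spec) {
  n <- nrow(entries)
  useq <- unique(entries$sequence)
  Es <- embed_strings(spec$enzyme_embedder, useq)
  usmi <- unique(entries$canonical_smiles)
  Em <- embed_strings(spec$substrate_embedder, usmi)
  XB <- cbind(Es[match(entries$sequence, useq), , drop = FALSE],
              Em[match(entries$canonical_smiles, usmi), , drop = FALSE])
  Y <- cbind(kcat = entries$log10_kcat, km = entries$log10_km)
  mask <- !is.na(Y)
  Y[!mask] <- 0
  structure(list(
    XB = XB,
    R_ph = rbf_expand(entries$ph, spec$ph_centers, spec$gamma),
    R_temp = rbf_expand(entries$temperature, spec$temp_centers, spec$gamma),
    org_idx = organism_index(entries$organism, spec),
    Y = Y, mask = mask, n = n, spec = spec, entries = entries
  ), class = "feature_set")
}

# materialize the fused n x d input matrix for given aux parameters
fused_matrix <- function(fs, aux) {
  A <- fs$R_ph %*% aux$W_ph + fs$R_temp %*% aux$W_temp
  has_org <- fs$org_idx > 0L
  if (any(has_org)) {
    A[has_org, ] <- A[has_org, , drop = FALSE] +
      aux$E_org[fs$org_idx[has_org], , drop = FALSE]
  }
  cbind(fs$XB, A)
}
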