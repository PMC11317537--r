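#' @name evalsplit
#' @title Splitting, metrics, subtest partitions and comparison reporting
#' @description
#' Stratified 8:1:1 splitting by label pattern, the regression metrics
#' (Pearson correlation, coefficient of determination, RMSE) with their
#' significance tests, the subtest partitions used to probe a trained
#' model (wild-type vs mutant, substrate promiscuity, mutation
#' fold-change, strictly unseen enzyme and substrate), the hit ratio for
#' enzyme-engineering case studies, and relative-improvement arithmetic.
NULL

#' Stratified train/validation/test split
#'
#' Entries are first partitioned by label pattern (both labels, kcat
#' only, Km only) and each stratum is split independently at the given
#' ratios with floor + largest-remainder rounding, so the label-pattern
#' proportions of the three splits match the full dataset. Strata with
#' fewer than 3 entries go entirely to training (with a warning).
#'
#' @param entries `curated_entries`.
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return list with `train`, `val`, `test` (disjoint subsets whose union
#'   is the input).
#' @export
stratified_split <- function(entries, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8,
            all(ratios >= 0))
  pattern <- label_pattern(entries)
  assign <- integer(nrow(entries))  # 1 train, 2 val, 3 test
  with_seed(seed, {
    for (st in unique(pattern)) {
      ix <- which(pattern == st)
      n <- length(ix)
      if (n < 3) {
        warning(sprintf("stratum '%s' has %d entries; assigning all to train",
                        st, n))
        assign[ix] <- 1L
        next
      }
      counts <- floor(n * ratios)
      rem <- n * ratios - counts
      short <- n - sum(counts)
      if (short > 0) {
        counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
          counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
      }
      ix <- sample(ix)
      assign[ix] <- rep(1:3, times = counts)
    }
  })
  list(train = entries[assign == 1L, , drop = FALSE],
       val = entries[assign == 2L, , drop = FALSE],
       test = entries[assign == 3L, , drop = FALSE])
}

#' Pearson correlation coefficient
#'
#' @param y_e experimental values.
#' @param y_p predicted values.
#' @return PCC in `[-1, 1]`.
#' @export
pcc <- function(y_e, y_p) {
  stopifnot(length(y_e) == length(y_p), length(y_e) >= 2)
  de <- y_e - mean(y_e)
  dp <- y_p - mean(y_p)
  den <- sqrt(sum(de^2)) * sqrt(sum(dp^2))
  if (den == 0) stopf("pcc: zero variance")
  sum(de * dp) / den
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative when predictions are worse than
#' the mean predictor.
#'
#' @inheritParams pcc
#' @export
r2 <- function(y_e, y_p) {
  stopifnot(length(y_e) == length(y_p), length(y_e) >= 2)
  ss_tot <- sum((y_e - mean(y_e))^2)
  if (ss_tot == 0) stopf("r2: constant experimental values")
  1 - sum((y_e - y_p)^2) / ss_tot
}

#' Root mean squared error
#'
#' @inheritParams pcc
#' @export
rmse <- function(y_e, y_p) {
  stopifnot(length(y_e) == length(y_p), length(y_e) >= 1)
  sqrt(mean((y_p - y_e)^2))
}

#' Two-sided t-test p-value for a Pearson correlation
#'
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on `n-2` degrees of freedom; `|r| = 1`
#' returns 0 by convention.
#'
#' @param pcc correlation coefficient.
#' @param n sample size (>= 3).
#' @return two-sided p-value.
#' @export
pcc_p_value <- function(pcc, n) {
  stopifnot(n >= 3, abs(pcc) <= 1)
  if (abs(pcc) == 1) return(0)
  t <- pcc * sqrt(n - 2) / sqrt(1 - pcc^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples without ties, tie-corrected normal
#' approximation otherwise (the standard behaviour of
#' [stats::wilcox.test()], which this wraps).
#'
#' @param a,b numeric samples.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  res <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  unname(res$p.value)
}

#' One evaluation report row
#'
#' @param y_e,y_p experimental and predicted log10 values.
#' @param task `"kcat"` or `"km"`.
#' @param subset label of the evaluated subset.
#' @return data.frame with `task`, `subset`, `n`, `pcc`, `r2`, `rmse`,
#'   `p_value` (t-test on the PCC).
#' @export
metric_report <- function(y_e, y_p, task, subset = "all") {
  r <- pcc(y_e, y_p)
  data.frame(task = task, subset = subset, n = length(y_e),
             pcc = r, r2 = r2(y_e, y_p), rmse = rmse(y_e, y_p),
             p_value = pcc_p_value(r, length(y_e)),
             stringsAsFactors = FALSE)
}

#' Partition test entries by enzyme type
#'
#' @param entries curated entries with `enzyme_type`.
#' @return list `wild_type`, `mutant` (a disjoint cover).
#' @export
partition_enzyme_type <- function(entries) {
  wt <- entries$enzyme_type == "wild_type"
  list(wild_type = entries[wt, , drop = FALSE],
       mutant = entries[!wt, , drop = FALSE])
}

#' Partition wild-type entries by substrate promiscuity
#'
#' Wild-type enzymes (grouped by sequence) catalyzing two or more
#' substrates are promiscuous. Per enzyme, the substrate with the highest
#' experimental kcat (task `"kcat"`) or the lowest experimental Km (task
#' `"km"`) is the preferred substrate, all others are alternative
#' substrates. Single-substrate enzymes are excluded. Ties for the
#' extremum mark all tied substrates preferred (logged in the `ties`
#' attribute).
#'
#' @param entries wild-type curated entries.
#' @param task which experimental label drives the classification.
#' @return list `preferred`, `alternative`, `non_promiscuous`.
#' @export
partition_promiscuity <- function(entries, task = c("kcat", "km")) {
  task <- match.arg(task)
  col <- paste0("log10_", task)
  sub <- entries[!is.na(entries[[col]]), , drop = FALSE]
  groups <- split(seq_len(nrow(sub)), sub$sequence)
  pref <- alt <- nonp <- integer(0)
  ties <- character(0)
  for (g in groups) {
    vals <- sub[[col]][g]
    if (length(unique(sub$canonical_smiles[g])) < 2) {
      nonp <- c(nonp, g)
      next
    }
    best <- if (task == "kcat") max(vals) else min(vals)
    hit <- vals == best
    if (sum(hit) > 1) ties <- c(ties, sub$sequence[g[1]])
    pref <- c(pref, g[hit])
    alt <- c(alt, g[!hit])
  }
  structure(list(preferred = sub[sort(pref), , drop = FALSE],
                 alternative = sub[sort(alt), , drop = FALSE],
                 non_promiscuous = sub[sort(nonp), , drop = FALSE]),
            ties = ties)
}

#' Classify a mutant by fold change relative to its wild type
#'
#' The linear-scale ratio `r = mutant / wild` classifies the mutation as
#' wild-type-like (`0.5 <= r <= 2`), increased (`r > 2`) or decreased
#' (`r < 0.5`). Scale-invariant: multiplying both values by a positive
#' constant preserves the category.
#'
#' @param mutant_value,wild_value positive linear-scale values
#'   (vectorized).
#' @return character vector in
#'   `{"wild_type_like","increased","decreased"}`; `NA` where the
#'   wild-type reference is missing.
#' @export
classify_fold_change <- function(mutant_value, wild_value) {
  r <- mutant_value / wild_value
  out <- rep(NA_character_, length(r))
  out[!is.na(r) & r >= 0.5 & r <= 2.0] <- "wild_type_like"
  out[!is.na(r) & r > 2.0] <- "increased"
  out[!is.na(r) & r < 0.5] <- "decreased"
  out
}

#' Match mutant entries to wild-type reference values
#'
#' Candidates share (EC number, organism, canonical substrate); among
#' candidates the one with the closest (pH, temperature) pair (Euclidean
#' distance, first on ties) supplies the reference. Mutants without any
#' candidate are left unmatched (`NA`), mirroring the shortfall between
#' classified and total mutants in practice.
#'
#' @param mutants,wild_types curated entries.
#' @param task `"kcat"` or `"km"`.
#' @return numeric vector of wild-type linear-scale reference values per
#'   mutant row (`NA` when unmatched).
#' @export
match_wild_reference <- function(mutants, wild_types,
                                 task = c("kcat", "km")) {
  task <- match.arg(task)
  col <- paste0("log10_", task)
  wt <- wild_types[!is.na(wild_types[[col]]), , drop = FALSE]
  key <- function(df) paste(df$ec_number, df$organism, df$canonical_smiles,
                            sep = "\r")
  wt_key <- key(wt)
  out <- rep(NA_real_, nrow(mutants))
  mkey <- key(mutants)
  for (i in seq_len(nrow(mutants))) {
    cand <- which(wt_key == mkey[i])
    if (!length(cand)) next
    d <- (wt$ph[cand] - mutants$ph[i])^2 +
      (wt$temperature[cand] - mutants$temperature[i])^2
    out[i] <- 10^wt[[col]][cand[which.min(d)]]
  }
  out
}

#' Strictly unseen test subset
#'
#' Keeps test entries whose enzyme sequence does not occur in the
#' training split and whose canonical substrate does not occur either, so
#' performance on the subset probes generalization to novel enzymes and
#' substrates simultaneously.
#'
#' @param test,train curated entries.
#' @return subset of `test`.
#' @export
strict_unseen_subset <- function(test, train) {
  keep <- !(test$sequence %in% train$sequence) &
    !(test$canonical_smiles %in% train$canonical_smiles)
  test[keep, , drop = FALSE]
}

#' Hit ratio of predicted efficiency-change directions
#'
#' For each non-reference variant, a hit is scored when the sign of the
#' predicted efficiency change relative to the reference matches the sign
#' of the experimental change; the hit ratio is the mean over variants.
#' Efficiencies are compared in log space (`log10 kcat - log10 Km`),
#' which is monotone-equivalent to the linear kcat/Km ratio. Variants
#' tied with the reference on either scale are excluded and logged.
#'
#' @param exp_eff,pred_eff experimental and predicted efficiencies,
#'   reference first unless `ref` says otherwise.
#' @param ref index of the reference entry (default 1).
#' @return list with `hr` (in `[0, 1]`), `n` (variants scored), `hits`
#'   (logical per scored variant) and `excluded` (indices of tied
#'   variants).
#' @export
hit_ratio <- function(exp_eff, pred_eff, ref = 1L) {
  stopifnot(length(exp_eff) == length(pred_eff), length(exp_eff) >= 2)
  vi <- setdiff(seq_along(exp_eff), ref)
  de <- exp_eff[vi] - exp_eff[ref]
  dp <- pred_eff[vi] - pred_eff[ref]
  tied <- de == 0 | dp == 0
  hits <- sign(de[!tied]) == sign(dp[!tied])
  list(hr = mean(hits), n = sum(!tied), hits = hits,
       excluded = vi[tied])
}

#' Relative improvement of a metric, in percent
#'
#' `100 (new - old) / old`; the convention used when comparing the PCC of
#' competing models.
#'
#' @param metric_new,metric_old metric values; `metric_old` must be > 0.
#' @export
relative_improvement <- function(metric_new, metric_old) {
  if (any(metric_old <= 0)) stopf("relative_improvement: old metric <= 0")
  100 * (metric_new - metric_old) / metric_old
}

#' Evaluate predictions over the standard subtest partitions
#'
#' Produces one [metric_report()] row per task for the full test set, the
#' wild-type and mutant subsets, the fold-change categories, and the
#' strictly unseen subset (when `train` is supplied).
#'
#' @param fit `cgc_fit`.
#' @param test curated test entries.
#' @param train optional curated training entries (enables the strict
#'   subset and fold-change reference matching).
#' @return data.frame of metric reports.
#' @export
evaluate_subtests <- function(fit, test, train = NULL) {
  preds <- predict_entries(fit, test)
  tns <- task_names(fit$config)
  rows <- list()
  add <- function(sub, pred_sub, label) {
    for (k in tns) {
      col <- paste0("log10_", k)
      ok <- !is.na(sub[[col]])
      if (sum(ok) >= 3 && stats::sd(sub[[col]][ok]) > 0) {
        rows[[length(rows) + 1]] <<- metric_report(
          sub[[col]][ok], pred_sub[[paste0("pred_log10_", k)]][ok],
          task = k, subset = label)
      }
    }
  }
  add(test, preds, "all")
  et <- partition_enzyme_type(test)
  ix_wt <- test$enzyme_type == "wild_type"
  add(et$wild_type, preds[ix_wt, , drop = FALSE], "wild_type")
  add(et$mutant, preds[!ix_wt, , drop = FALSE], "mutant")
  if (!is.null(train)) {
    keep <- !(test$sequence %in% train$sequence) &
      !(test$canonical_smiles %in% train$canonical_smiles)
    add(test[keep, , drop = FALSE], preds[keep, , drop = FALSE],
        "strict_unseen")
    mut <- test[!ix_wt, , drop = FALSE]
    mut_preds <- preds[!ix_wt, , drop = FALSE]
    for (k in tns) {
      col <- paste0("log10_", k)
      refv <- match_wild_reference(mut, train, task = k)
      cat3 <- classify_fold_change(10^mut[[col]], refv)
      for (cl in c("wild_type_like", "increased", "decreased")) {
        sel <- !is.na(cat3) & cat3 == cl & !is.na(mut[[col]])
        if (sum(sel) >= 3 && stats::sd(mut[[col]][sel]) > 0) {
          rows[[length(rows) + 1]] <- metric_report(
            mut[[col]][sel],
            mut_preds[[paste0("pred_log10_", k)]][sel],
            task = k, subset = paste0("fold_", cl))
        }
      }
    }
  }
  do.call(rbind, rows)
}
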