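#' Differential stability of regional expression
#'
#' For every gene, the Pearson correlation of its structure-wise expression
#' profile is computed between each pair of subjects over the structures
#' observed in both, and DS is the unweighted mean over pairs (15 pairs for
#' 6 subjects). Pairs sharing fewer than 3 structures are skipped with a
#' warning; a gene with no usable pair gets an undefined-DS error (or `NA`
#' in the all-genes table).
#'
#' @param expr a `subject_expression_set`.
#' @param genes genes to score; default all genes in `expr`.
#' @return data.frame with columns `gene`, `ds`, `n_pairs`.
#' @export
differential_stability <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "subject_expression_set"))
  genes <- genes %||% expr$genes
  missing <- setdiff(genes, expr$genes)
  if (length(missing))
    stop_brainsig("genes not measured: %s",
                  paste(utils::head(missing, 5), collapse = ", "))
  mats <- expr$matrices
  n_s <- length(mats)
  if (n_s < 2L) stop_brainsig("DS needs at least 2 subjects")
  pairs <- utils::combn(n_s, 2L)
  acc <- matrix(NA_real_, length(genes), ncol(pairs))
  skipped <- 0L
  for (j in seq_len(ncol(pairs))) {
    a <- mats[[pairs[1, j]]][, genes, drop = FALSE]
    b <- mats[[pairs[2, j]]][, genes, drop = FALSE]
    ok <- rowSums(is.na(a)) == 0 & rowSums(is.na(b)) == 0
    if (sum(ok) < 3L) { skipped <- skipped + 1L; next }
    a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
    # columnwise Pearson between paired columns
    a <- scale(a); b <- scale(b)
    acc[, j] <- colSums(a * b) / (nrow(a) - 1)
  }
  if (skipped)
    warn_brainsig("%d subject pairs skipped (fewer than 3 shared structures)",
                  skipped)
  n_pairs <- as.integer(rowSums(!is.na(acc)))
  if (all(n_pairs == 0))
    stop_brainsig("DS undefined: no subject pair shares 3 or more structures")
  ds <- rowMeans(acc, na.rm = TRUE)
  ds[n_pairs == 0] <- NA_real_
  data.frame(gene = genes, ds = ds, n_pairs = n_pairs,
             stringsAsFactors = FALSE)
}

#' Split genes into high- and low-stability halves
#'
#' Thresholds DS at the stated quantile; genes strictly above the threshold
#' form the high set (the source atlas used the corpus median, DS > 0.5284).
#'
#' @param records a [differential_stability()] table.
#' @param quantile DS quantile defining the threshold.
#' @return list with `high`, `low` gene vectors and the `threshold`.
#' @export
ds_partition <- function(records, quantile = 0.5) {
  if (nrow(records) < 2L) stop_brainsig("ds_partition needs >= 2 records")
  # quantile 0 keeps every gene (threshold below the minimum), matching the
  # strict-inequality convention used at all other quantiles
  thr <- if (quantile <= 0) -Inf else
    stats::quantile(records$ds, probs = quantile, na.rm = TRUE, names = FALSE)
  high <- records$gene[!is.na(records$ds) & records$ds > thr]
  low <- setdiff(records$gene, high)
  list(high = high, low = low, threshold = thr)
}

#' Gene-level association with canonical module eigengenes
#'
#' Correlates each gene's structure profile with every module eigengene
#' within each subject, stabilizes with the Fisher r-to-z transform
#' (correlations clipped to |rho| <= 1 - 1e-6 so atanh stays finite),
#' averages z across subjects, and standardizes every module column over
#' all scored genes (mean 0, sd 1).
#'
#' @param expr a `subject_expression_set`.
#' @param eigengenes a `module_eigengenes` whose structures are contained
#'   in `expr`'s.
#' @param genes genes to score; default all.
#' @return a `module_score_matrix`: `scores` (gene-by-module, z units) and
#'   `raw` (pre-standardization Fisher-z means).
#' @export
module_scores <- function(expr, eigengenes, genes = NULL) {
  stopifnot(inherits(expr, "subject_expression_set"),
            inherits(eigengenes, "module_eigengenes"))
  genes <- genes %||% expr$genes
  absent <- setdiff(genes, expr$genes)
  if (length(absent)) {
    warn_brainsig("%d genes absent from expression set skipped",
                  length(absent))
    genes <- intersect(genes, expr$genes)
  }
  if (!length(genes)) stop_brainsig("no scored genes")
  pat <- eigengenes$patterns
  if (!all(colnames(pat) %in% expr$structures))
    stop_brainsig("eigengene structures missing from expression set")
  clip <- 1 - 1e-6
  zs <- lapply(expr$matrices, function(m) {
    ok <- rowSums(is.na(m[, genes, drop = FALSE])) == 0
    st <- intersect(expr$structures[ok], colnames(pat))
    rho <- stats::cor(m[st, genes, drop = FALSE], t(pat[, st, drop = FALSE]))
    atanh(pmin(pmax(rho, -clip), clip))
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  raw <- zbar
  scores <- scale(zbar)
  dimnames(scores) <- list(genes, eigengenes$modules)
  structure(list(scores = scores, raw = raw, modules = eigengenes$modules),
            class = "module_score_matrix")
}

#' Disease-level module association
#'
#' Averages the standardized gene-level module scores over each disease's
#' scored genes; diseases with no scored genes are dropped with a warning.
#'
#' @param gene_scores a [module_scores()] result.
#' @param sets a [filter_associations()] result.
#' @return disease-by-module matrix of mean standardized scores.
#' @export
disease_module_matrix <- function(gene_scores, sets) {
  stopifnot(inherits(gene_scores, "module_score_matrix"),
            inherits(sets, "disease_gene_sets"))
  scored <- rownames(gene_scores$scores)
  rows <- lapply(names(sets$sets), function(d) {
    g <- intersect(sets$sets[[d]], scored)
    if (!length(g)) return(NULL)
    colMeans(gene_scores$scores[g, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warn_brainsig("diseases with no scored genes dropped: %s",
                  paste(names(sets$sets)[!keep], collapse = ", "))
  if (!any(keep)) stop_brainsig("no disease has scored genes")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(sets$sets)[keep]
  out
}
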