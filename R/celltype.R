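#' Counts-per-million normalization of a cell-type expression matrix
#'
#' Scales each cell-type row to sum to one million. Idempotent on
#' already-normalized input.
#'
#' @param counts nonnegative cell-type-by-gene matrix, or a
#'   `celltype_expression_matrix` whose `values` are rescaled.
#' @return same shape as the input, rows summing to 1e6.
#' @export
cpm_normalize <- function(counts) {
  if (inherits(counts, "celltype_expression_matrix")) {
    counts$values <- cpm_normalize(counts$values)
    return(counts)
  }
  m <- as.matrix(counts)
  if (any(m < 0)) stop_brainsig("cpm_normalize: negative counts")
  rs <- rowSums(m)
  if (any(rs == 0))
    stop_brainsig("cpm_normalize: zero total counts for cell type(s): %s",
                  paste(rownames(m)[rs == 0] %||% which(rs == 0),
                        collapse = ", "))
  sweep(m, 1L, rs, "/") * 1e6
}

#' Tau expression-specificity index
#'
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)` over N cell types: 0 for
#' perfectly uniform expression, 1 for expression confined to a single cell
#' type. Invariant to positive rescaling of the profile.
#'
#' @param x nonnegative per-cell-type expression vector for one gene.
#' @return tau in `[0,1]`.
#' @examples
#' tau_specificity(c(1, 0.5, 0))  # 0.75
#' @export
tau_specificity <- function(x) {
  if (length(x) < 2L) stop_brainsig("tau needs at least 2 cell types")
  if (anyNA(x) || any(x < 0)) stop_brainsig("tau: expression must be nonnegative")
  mx <- max(x)
  if (mx == 0) stop_brainsig("tau undefined for an all-zero profile")
  sum(1 - x / mx) / (length(x) - 1L)
}

# tau for every column of a cell-type-by-gene matrix; NA for all-zero genes
#' @noRd
tau_columns <- function(values) {
  mx <- apply(values, 2L, max)
  tau <- (nrow(values) - colSums(sweep(values, 2L, pmax(mx, 1e-300), "/"))) /
    (nrow(values) - 1L)
  tau[mx == 0] <- NA_real_
  tau
}

# aggregate a celltype_expression_matrix to class or subclass level means
#' @noRd
aggregate_level <- function(expr, level = c("type", "subclass", "class")) {
  level <- match.arg(level)
  if (level == "type") return(expr$values)
  grp <- switch(level, subclass = expr$subclasses, class = expr$classes)
  agg <- rowsum(expr$values, grp) / as.vector(table(grp)[sort(unique(grp))])
  agg[sort(unique(grp)), , drop = FALSE]
}

#' Disease-by-cell-type expression matrix with cell-type groups
#'
#' Averages (transformed) CPM of each disease's measured genes over cell
#' types, z-scores disease rows, and clusters them (1 - Pearson, Ward.D2)
#' into `k` cell-type groups. Also reports each disease's mean tau
#' specificity, the pooled tau per GBD class, and a permutation p-value for
#' each class's pooled tau against same-size random gene sets (the
#' correction for class size).
#'
#' @param sets a [filter_associations()] result.
#' @param expr a `celltype_expression_matrix`.
#' @param transform `"log1p"` (default) or `"linear"` CPM before averaging.
#' @param k number of cell-type groups.
#' @param n_perm permutations for the class-tau null.
#' @param seed integer seed.
#' @return a `disease_celltype_result`: `values` (z-scored disease-by-cell-
#'   type), `raw`, `ctg` (a `cluster_result`), `tau_disease`, `tau_class`
#'   (data.frame with observed pooled tau and permutation p).
#' @export
disease_celltype_matrix <- function(sets, expr, transform = c("log1p", "linear"),
                                    k = 4L, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(sets, "disease_gene_sets"),
            inherits(expr, "celltype_expression_matrix"))
  transform <- match.arg(transform)
  vals <- expr$values
  if (transform == "log1p") vals <- log1p(vals)
  measured <- lapply(sets$sets, intersect, expr$genes)
  dropped <- names(measured)[lengths(measured) == 0L]
  if (length(dropped))
    warn_brainsig("diseases with no measured genes dropped: %s",
                  paste(dropped, collapse = ", "))
  keep <- names(measured)[lengths(measured) > 0L]
  if (!length(keep)) stop_brainsig("no disease gene measured")
  raw <- t(vapply(keep, function(d) rowMeans(vals[, measured[[d]], drop = FALSE]),
                  numeric(length(expr$celltypes))))
  colnames(raw) <- expr$celltypes
  values <- zscore_rows(raw, "disease")
  ctg <- if (nrow(values) >= 2L) {
    cluster_profiles(values, k = min(k, nrow(values)))
  } else {
    structure(list(labels = stats::setNames(1L, rownames(values)),
                   hclust = NULL, k = 1L), class = "cluster_result")
  }

  tau_all <- tau_columns(expr$values)
  names(tau_all) <- expr$genes
  tau_disease <- vapply(keep, function(d) mean(tau_all[measured[[d]]],
                                               na.rm = TRUE), numeric(1))

  cls <- sets$classes[keep]
  class_levels <- sort(unique(cls))
  pooled <- function(genes) mean(tau_all[genes], na.rm = TRUE)
  pool_genes <- lapply(class_levels, function(cl)
    unique(unlist(measured[keep[cls == cl]], use.names = FALSE)))
  observed <- vapply(pool_genes, pooled, numeric(1))
  set.seed(seed)
  universe <- expr$genes[!is.na(tau_all)]
  n_ge <- numeric(length(class_levels))
  for (b in seq_len(n_perm)) {
    perm <- vapply(pool_genes, function(g)
      pooled(sample(universe, length(g))), numeric(1))
    n_ge <- n_ge + (perm >= observed)
  }
  tau_class <- data.frame(gbd_class = class_levels, pooled_tau = observed,
                          perm_p = perm_pvalue(n_ge, n_perm),
                          stringsAsFactors = FALSE)
  structure(list(values = values, raw = raw, ctg = ctg,
                 tau_disease = tau_disease, tau_class = tau_class,
                 transform = transform, dropped = dropped),
            class = "disease_celltype_result")
}

#' @export
print.disease_celltype_result <- function(x, ...) {
  cat(sprintf("Disease x cell-type matrix: %d diseases x %d cell types (%s CPM)\n",
              nrow(x$values), ncol(x$values), x$transform))
  cat(sprintf("  %d cell-type groups; mean disease tau %.3f\n",
              x$ctg$k, mean(x$tau_disease)))
  invisible(x)
}

#' Expression-weighted cell-type enrichment by permutation
#'
#' Scores a gene set's summed cell-type specificity (each gene's expression
#' divided by its total across cell types) against `n_perm` random
#' background sets of the same size drawn from all measured genes excluding
#' the target set. Reports per cell type the observed score, the fold over
#' the null mean, a permutation p-value with pseudocount, and BH-FDR across
#' cell types.
#'
#' @param gene_set character vector of target genes.
#' @param expr a `celltype_expression_matrix`.
#' @param n_perm number of permutations (the study used 100,000; scale down
#'   for interactive work).
#' @param seed integer seed.
#' @param level `"type"`, `"subclass"`, or `"class"`: cell types are
#'   aggregated by mean expression before scoring.
#' @param scoring `"specificity"` (default, expression normalized per gene
#'   across cell types) or `"cpm"` (raw expression sums).
#' @return an `enrichment_result` data.frame: celltype, observed, null_mean,
#'   fold, p, q.
#' @export
ewce <- function(gene_set, expr, n_perm = 10000L, seed = 1L,
                 level = c("type", "subclass", "class"),
                 scoring = c("specificity", "cpm")) {
  stopifnot(inherits(expr, "celltype_expression_matrix"))
  level <- match.arg(level)
  scoring <- match.arg(scoring)
  vals <- aggregate_level(expr, level)
  vals <- cpm_normalize(vals)   # library size must not affect specificity
  gene_set <- normalize_symbols(gene_set)
  target <- intersect(gene_set, colnames(vals))
  if (!length(target)) stop_brainsig("ewce: no target gene measured")
  background <- setdiff(colnames(vals), gene_set)
  if (length(target) > length(background))
    stop_brainsig("ewce: target set larger than background")

  S <- if (scoring == "specificity") {
    tot <- colSums(vals)
    keep <- tot > 0
    sweep(vals[, keep, drop = FALSE], 2L, tot[keep], "/")
  } else vals
  target <- intersect(target, colnames(S))
  background <- intersect(background, colnames(S))
  k <- length(target)
  observed <- rowSums(S[, target, drop = FALSE])

  St <- t(S[, background, drop = FALSE])    # background genes x cell types
  set.seed(seed)
  idx <- matrix(0L, n_perm, k)
  for (b in seq_len(n_perm)) idx[b, ] <- sample.int(nrow(St), k)
  perm <- matrix(0, n_perm, ncol(St))
  for (j in seq_len(k)) perm <- perm + St[idx[, j], , drop = FALSE]

  null_mean <- colMeans(perm)
  n_ge <- colSums(sweep(perm, 2L, observed, ">="))
  p <- perm_pvalue(n_ge, n_perm)
  res <- data.frame(celltype = rownames(vals), observed = observed,
                    null_mean = null_mean,
                    fold = observed / null_mean, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "level") <- level
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' EWCE signatures for every disease
#'
#' Convenience wrapper running [ewce()] per disease and assembling the
#' disease-by-cell-type matrix of a chosen statistic.
#'
#' @param sets a [filter_associations()] result.
#' @param expr a `celltype_expression_matrix`.
#' @param statistic matrix entries: `"fold"`, `"observed"`, or `"p"`.
#' @inheritParams ewce
#' @return list with `matrix` (disease by cell type) and `results` (named
#'   list of `enrichment_result`s).
#' @export
ewce_signatures <- function(sets, expr, n_perm = 2000L, seed = 1L,
                            level = "subclass", statistic = "fold") {
  stopifnot(inherits(sets, "disease_gene_sets"))
  results <- lapply(seq_along(sets$sets), function(i) {
    ewce(sets$sets[[i]], expr, n_perm = n_perm,
         seed = derive_seed(seed, i), level = level)
  })
  names(results) <- names(sets$sets)
  mat <- t(vapply(results, function(r) r[[statistic]],
                  numeric(nrow(results[[1]]))))
  colnames(mat) <- results[[1]]$celltype
  list(matrix = mat, results = results)
}

#' Cell-type covariation maps from disease-unique genes
#'
#' For each disease, the absolute cosine similarity between every pair of
#' cell types over that disease's unique genes (per-gene max-normalized by
#' default so high-magnitude genes do not dominate), independently
#' thresholded at mean + `sigma_mult` * sd of its off-diagonal entries. The
#' combined map records which diseases exceed their own threshold at each
#' cell-type pair.
#'
#' @param unique_sets named list: disease to genes unique to it.
#' @param expr a `celltype_expression_matrix`.
#' @param sigma_mult threshold multiplier (the study used 1.5).
#' @param normalize `"max"` per-gene max-normalization or `"raw"`.
#' @return a `covariation_map`: `maps` (named list of cell-type-by-cell-type
#'   matrices), `thresholds`, and `combined` (long data.frame of pairs with
#'   the diseases passing).
#' @export
covariation_map <- function(unique_sets, expr, sigma_mult = 1.5,
                            normalize = c("max", "raw")) {
  stopifnot(inherits(expr, "celltype_expression_matrix"))
  normalize <- match.arg(normalize)
  maps <- list(); thresholds <- numeric(0)
  for (d in names(unique_sets)) {
    genes <- intersect(normalize_symbols(unique_sets[[d]]), expr$genes)
    if (length(genes) < 2L)
      stop_brainsig("covariation_map: disease %s has < 2 measured unique genes", d)
    E <- expr$values[, genes, drop = FALSE]
    if (normalize == "max") {
      mx <- apply(E, 2L, max)
      E <- sweep(E, 2L, pmax(mx, 1e-300), "/")
    }
    nrm <- sqrt(rowSums(E^2))
    zero <- nrm == 0
    if (any(zero))
      warn_brainsig("cell types with all-zero expression over %s genes: %s",
                    d, paste(expr$celltypes[zero], collapse = ", "))
    nrm[zero] <- 1
    cosim <- abs(tcrossprod(E / nrm))
    cosim[zero, ] <- 0; cosim[, zero] <- 0
    diag(cosim) <- ifelse(zero, 0, 1)
    dimnames(cosim) <- list(expr$celltypes, expr$celltypes)
    off <- cosim[upper.tri(cosim)]
    thresholds[d] <- mean(off) + sigma_mult * stats::sd(off)
    maps[[d]] <- cosim
  }
  ut <- which(upper.tri(maps[[1]]), arr.ind = TRUE)
  combined <- data.frame(
    celltype_i = expr$celltypes[ut[, 1]],
    celltype_j = expr$celltypes[ut[, 2]],
    stringsAsFactors = FALSE)
  passing <- vapply(seq_len(nrow(ut)), function(r) {
    who <- names(maps)[vapply(names(maps), function(d)
      maps[[d]][ut[r, 1], ut[r, 2]] > thresholds[[d]], logical(1))]
    paste(who, collapse = ";")
  }, character(1))
  combined$diseases <- passing
  structure(list(maps = maps, thresholds = thresholds, combined = combined,
                 sigma_mult = sigma_mult, normalize = normalize),
            class = "covariation_map")
}

#' @export
print.covariation_map <- function(x, ...) {
  cat(sprintf("Covariation maps for %d diseases (threshold mean + %.1f sd)\n",
              length(x$maps), x$sigma_mult))
  n_pass <- sum(nzchar(x$combined$diseases))
  cat(sprintf("  %d of %d cell-type pairs pass for at least one disease\n",
              n_pass, nrow(x$combined)))
  invisible(x)
}

#' Consensus of structural and cellular disease similarity
#'
#' Element-wise mean of two disease-by-disease correlation matrices sharing
#' the same ordered universe.
#'
#' @param corr_struct,corr_cell disease-by-disease correlation matrices.
#' @return averaged matrix.
#' @export
consensus_matrix <- function(corr_struct, corr_cell) {
  if (!identical(dimnames(corr_struct), dimnames(corr_cell)))
    stop_brainsig("consensus_matrix: matrices must share the disease universe and order")
  (corr_struct + corr_cell) / 2
}

#' Embed a disease similarity matrix in 2-D
#'
#' Converts a correlation matrix to the 1 - r distance and delegates to a
#' pluggable embedder; the deterministic default is classical metric
#' scaling ([stats::cmdscale()]). A nonlinear embedder (e.g. UMAP) can be
#' passed as `embed`.
#'
#' @param corr disease-by-disease correlation matrix.
#' @param embed function mapping a `dist` to an n-by-2 coordinate matrix.
#' @return n-by-2 coordinate matrix with disease rownames.
#' @export
consensus_embedding <- function(corr, embed = NULL) {
  d <- stats::as.dist(1 - corr)
  coords <- if (is.null(embed)) stats::cmdscale(d, k = 2) else embed(d)
  rownames(coords) <- rownames(corr)
  coords
}

#' Within- versus between-class distance ratio in an embedding
#'
#' For each disease, the mean Euclidean distance to diseases of the same
#' GBD class divided by the mean distance to all other diseases: values
#' below 1 mean the disease sits nearer its own phenotypic class. Diseases
#' without a same-class partner are reported as `NA`.
#'
#' @param embedding n-by-2 coordinate matrix with disease rownames.
#' @param gbd named disease-to-class labels.
#' @return named numeric vector of ratios.
#' @export
gbd_ratio <- function(embedding, gbd) {
  diseases <- rownames(embedding)
  lab <- gbd[diseases]
  if (anyNA(lab)) stop_brainsig("gbd_ratio: labels missing for some diseases")
  D <- as.matrix(stats::dist(embedding))
  vapply(seq_along(diseases), function(i) {
    same <- lab == lab[i]; same[i] <- FALSE
    diff <- lab != lab[i]
    if (!any(same)) return(NA_real_)
    mean(D[i, same]) / mean(D[i, diff])
  }, numeric(1)) |> stats::setNames(diseases)
}
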