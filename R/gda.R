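#' Literature-evidence weight of a gene-disease association
#'
#' Combines four evidence counts into a weight in `[0,1]`:
#' a curated-source component C of 0, 0.3, 0.5, or 0.6 for 0, 1, 2, or more
#' than 2 curated sources; an animal-model component M of 0.2 if any
#' mouse/rat report exists; an inferred component I of 0.1 if any inferred
#' source exists; and a literature component L of 0.01 per supporting
#' publication, capped at 0.1 from 10 publications on.
#'
#' @param n_curated,n_animal,n_inferred,n_literature nonnegative integer
#'   evidence counts (vectorized).
#' @return numeric weight(s) in `[0,1]`.
#' @examples
#' gda_score(1, 0, 0, 0)   # 0.3
#' gda_score(3, 1, 1, 20)  # 1.0
#' @export
gda_score <- function(n_curated, n_animal, n_inferred, n_literature) {
  if (any(c(n_curated, n_animal, n_inferred, n_literature) < 0, na.rm = TRUE))
    stop_brainsig("gda_score: evidence counts must be nonnegative")
  C <- ifelse(n_curated == 0, 0,
              ifelse(n_curated == 1, 0.3,
                     ifelse(n_curated == 2, 0.5, 0.6)))
  M <- 0.2 * (n_animal > 0)
  I <- 0.1 * (n_inferred > 0)
  L <- ifelse(n_literature <= 9, 0.01 * n_literature, 0.1)
  C + M + I + L
}

#' @noRd
validate_gda_table <- function(table) {
  need <- c("disease_id", "gbd_class", "gene", "n_curated", "n_animal",
            "n_inferred", "n_literature")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop_brainsig("gene-disease table lacks columns: %s",
                  paste(missing, collapse = ", "))
  if (!nrow(table)) stop_brainsig("gene-disease table is empty")
  invisible(table)
}

#' Read a long-format gene-disease association table
#'
#' One record per disease-gene pair with GBD class label and the four
#' evidence counts feeding [gda_score()].
#'
#' @param path TSV file path.
#' @return data.frame with normalized (uppercase) gene symbols.
#' @export
read_gda_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gda_table(tab)
  tab$gene <- normalize_symbols(tab$gene)
  tab
}

#' Filter a gene-disease table into disease gene sets
#'
#' Applies the study's two filters: records must carry at least
#' `min_curated` curated sources, and diseases must retain at least
#' `min_genes` genes afterwards. Counts dropped at each step are kept in the
#' result's `log`.
#'
#' @param table long-format gene-disease data.frame (see [read_gda_table()]).
#' @param min_curated minimum curated-source count per record.
#' @param min_genes minimum surviving set size per disease.
#' @return a `disease_gene_sets` object: named list `sets` (disease to gene
#'   vector), `classes` (disease to GBD class), `weights` (disease to named
#'   per-gene GDA score vector), `names` (disease id to display name), and
#'   a `log` of filter counts.
#' @export
filter_associations <- function(table, min_curated = 1L, min_genes = 10L) {
  validate_gda_table(table)
  table$gene <- normalize_symbols(table$gene)
  if (anyDuplicated(table[c("disease_id", "gene")]))
    stop_brainsig("duplicated (disease_id, gene) records in table")
  n0 <- nrow(table)
  keep <- table$n_curated >= min_curated
  table <- table[keep, , drop = FALSE]
  n_dropped_evidence <- n0 - nrow(table)

  sizes <- table(table$disease_id)
  small <- names(sizes)[sizes < min_genes]
  n_dropped_small <- length(small)
  table <- table[!(table$disease_id %in% small), , drop = FALSE]
  if (!nrow(table))
    stop_brainsig("no diseases survive filters (min_curated=%d, min_genes=%d)",
                  min_curated, min_genes)

  split_idx <- split(seq_len(nrow(table)), table$disease_id)
  sets <- lapply(split_idx, function(i) table$gene[i])
  weights <- lapply(split_idx, function(i) {
    stats::setNames(gda_score(table$n_curated[i], table$n_animal[i],
                              table$n_inferred[i], table$n_literature[i]),
                    table$gene[i])
  })
  classes <- vapply(split_idx, function(i) table$gbd_class[i[1]],
                    character(1))
  disp <- if ("disease_name" %in% names(table)) {
    vapply(split_idx, function(i) table$disease_name[i[1]], character(1))
  } else stats::setNames(names(split_idx), names(split_idx))
  structure(list(sets = sets, classes = classes, weights = weights,
                 names = disp,
                 log = list(n_records_in = n0,
                            n_dropped_evidence = n_dropped_evidence,
                            n_diseases_dropped_small = n_dropped_small,
                            n_diseases = length(sets),
                            n_genes_union = length(unique(table$gene)))),
            class = "disease_gene_sets")
}

#' @export
print.disease_gene_sets <- function(x, ...) {
  cat(sprintf("Disease gene sets: %d diseases, %d genes in union\n",
              length(x$sets), x$log$n_genes_union))
  cat(sprintf("  filters dropped %d records (evidence), %d diseases (size)\n",
              x$log$n_dropped_evidence, x$log$n_diseases_dropped_small))
  invisible(x)
}

#' Pairwise and class-level overlap structure of disease gene sets
#'
#' Computes the disease-by-disease Jaccard matrix, the fraction of each
#' disease's genes found in no other disease, pooled class union sizes and
#' class-pair intersection counts, and a permutation p-value per class for
#' its mean within-class shared-gene percentage, obtained by shuffling
#' disease-to-class labels while preserving class sizes (the correction for
#' class size).
#'
#' @param sets a [filter_associations()] result.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @param shared_metric how "percent shared genes" is measured for the class
#'   statistic: `"jaccard"` for mean pairwise Jaccard x 100, `"min"` for
#'   mean pairwise intersection over the smaller set x 100.
#' @return an `overlap_result`: `jaccard` matrix, `unique_fraction`,
#'   `class_union_sizes`, `class_intersections`, `class_shared_pct`,
#'   `perm_p`.
#' @export
overlap_stats <- function(sets, n_perm = 1000L, seed = 1L,
                          shared_metric = c("jaccard", "min")) {
  stopifnot(inherits(sets, "disease_gene_sets"))
  shared_metric <- match.arg(shared_metric)
  if (length(sets$sets) < 2L)
    stop_brainsig("overlap_stats needs at least 2 diseases")
  diseases <- names(sets$sets)
  genes <- unique(unlist(sets$sets, use.names = FALSE))
  X <- vapply(sets$sets, function(g) genes %in% g, logical(length(genes)))
  storage.mode(X) <- "double"
  inter <- crossprod(X)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  jac <- inter / uni
  pairwise <- switch(shared_metric,
                     jaccard = jac,
                     min = inter / outer(sizes, sizes, pmin))
  diag(jac) <- 1

  tot <- rowSums(X)
  unique_fraction <- vapply(seq_along(diseases), function(i) {
    mem <- X[, i] > 0
    sum(tot[mem] == 1) / sum(mem)
  }, numeric(1))
  names(unique_fraction) <- diseases

  cls <- sets$classes[diseases]
  class_levels <- sort(unique(cls))
  pools <- lapply(class_levels, function(cl) {
    unique(unlist(sets$sets[cls == cl], use.names = FALSE))
  })
  names(pools) <- class_levels
  class_union_sizes <- vapply(pools, length, integer(1))
  class_intersections <- outer(class_levels, class_levels,
                               Vectorize(function(a, b) {
                                 length(intersect(pools[[a]], pools[[b]]))
                               }))
  dimnames(class_intersections) <- list(class_levels, class_levels)

  class_stat <- function(labels) {
    vapply(class_levels, function(cl) {
      i <- which(labels == cl)
      if (length(i) < 2L) return(NA_real_)
      sub <- pairwise[i, i]
      mean(sub[upper.tri(sub)]) * 100
    }, numeric(1))
  }
  observed <- class_stat(cls)
  set.seed(seed)
  n_ge <- numeric(length(class_levels))
  for (b in seq_len(n_perm)) {
    perm <- class_stat(sample(cls))
    n_ge <- n_ge + as.numeric(!is.na(perm) & !is.na(observed) &
                                perm >= observed)
  }
  perm_p <- perm_pvalue(n_ge, n_perm)
  perm_p[is.na(observed)] <- NA_real_
  names(perm_p) <- class_levels

  structure(list(jaccard = jac, unique_fraction = unique_fraction,
                 class_union_sizes = class_union_sizes,
                 class_intersections = class_intersections,
                 class_shared_pct = observed, perm_p = perm_p,
                 shared_metric = shared_metric, n_perm = n_perm,
                 seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Gene-set overlap over %d diseases (%s metric)\n",
              nrow(x$jaccard), x$shared_metric))
  cat("  class union sizes:\n")
  print(x$class_union_sizes)
  cat("  within-class shared %% (permutation p):\n")
  out <- data.frame(shared_pct = round(x$class_shared_pct, 2),
                    perm_p = signif(x$perm_p, 3))
  print(out)
  invisible(x)
}
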