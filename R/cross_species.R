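#' Align disease cell-type signatures through homologous cell types
#'
#' Averages, within each species, the columns mapping to the same consensus
#' cell type, and drops (with a message) consensus types missing on either
#' side, yielding a pair of disease-by-consensus matrices on identical
#' axes.
#'
#' @param human,mouse disease-by-cell-type matrices sharing a disease
#'   universe.
#' @param map homology data.frame with columns consensus_id, species,
#'   celltype_id.
#' @return list with aligned `human` and `mouse` matrices and the
#'   `consensus` ids kept.
#' @export
align_signatures <- function(human, mouse, map) {
  need <- c("consensus_id", "species", "celltype_id")
  if (!all(need %in% names(map)))
    stop_brainsig("homology map needs columns: %s", paste(need, collapse = ", "))
  if (!setequal(rownames(human), rownames(mouse)))
    stop_brainsig("species matrices must share the disease universe")
  mouse <- mouse[rownames(human), , drop = FALSE]
  if (anyDuplicated(map[c("species", "celltype_id")]))
    stop_brainsig("a cell type maps to more than one consensus type")

  collapse <- function(mat, species) {
    sub <- map[map$species == species & map$celltype_id %in% colnames(mat), ]
    groups <- split(sub$celltype_id, sub$consensus_id)
    cols <- vapply(groups, function(ct)
      rowMeans(mat[, ct, drop = FALSE]), numeric(nrow(mat)))
    colnames(cols) <- names(groups)
    cols
  }
  h <- collapse(human, "human")
  m <- collapse(mouse, "mouse")
  common <- intersect(colnames(h), colnames(m))
  if (!length(common)) stop_brainsig("no consensus type present in both species")
  dropped <- setdiff(union(colnames(h), colnames(m)), common)
  if (length(dropped))
    message(sprintf("consensus types dropped (single species): %s",
                    paste(dropped, collapse = ", ")))
  list(human = h[, common, drop = FALSE], mouse = m[, common, drop = FALSE],
       consensus = common)
}

#' Joint clustering of species-tagged disease signatures
#'
#' Stacks the aligned human and mouse disease-by-consensus matrices (rows
#' tagged by species), clusters them jointly (1 - Pearson, Ward.D2), and
#' reports the fraction of diseases whose nearest cross-species row
#' (Pearson) is the same disease.
#'
#' @param ewce_h,ewce_m aligned disease-by-consensus matrices (e.g. EWCE
#'   signatures) from [align_signatures()].
#' @param k clusters for the joint tree cut.
#' @return a `species_cocluster`: `cluster` (a `cluster_result` on 2D rows),
#'   `nn_same_disease_fraction`, and the per-disease logical `nn_hit`.
#' @export
species_coclustering <- function(ewce_h, ewce_m, k = 2L) {
  if (!identical(dimnames(ewce_h)[[1]], dimnames(ewce_m)[[1]]) ||
      !identical(colnames(ewce_h), colnames(ewce_m)))
    stop_brainsig("matrices must be aligned (same diseases and consensus types)")
  sdh <- apply(ewce_h, 1L, stats::sd); sdm <- apply(ewce_m, 1L, stats::sd)
  if (any(sdh == 0) || any(sdm == 0)) {
    bad <- c(paste0("human:", rownames(ewce_h)[sdh == 0]),
             paste0("mouse:", rownames(ewce_m)[sdm == 0]))
    stop_brainsig("constant signature row: %s", paste(bad, collapse = ", "))
  }
  stacked <- rbind(ewce_h, ewce_m)
  rownames(stacked) <- c(paste0("human:", rownames(ewce_h)),
                         paste0("mouse:", rownames(ewce_m)))
  cl <- cluster_profiles(stacked, k = k)

  xcor <- stats::cor(t(ewce_h), t(ewce_m))   # human rows x mouse rows
  nn_h <- apply(xcor, 1L, which.max)         # nearest mouse row per human
  nn_m <- apply(xcor, 2L, which.max)
  hit <- (nn_h == seq_len(nrow(ewce_h))) & (nn_m == seq_len(nrow(ewce_h)))
  # the headline fraction counts each disease once, human-side nearest
  frac <- mean(nn_h == seq_len(nrow(ewce_h)))
  structure(list(cluster = cl, nn_same_disease_fraction = frac,
                 nn_hit = stats::setNames(nn_h == seq_len(nrow(ewce_h)),
                                          rownames(ewce_h)),
                 mutual_hit = stats::setNames(hit, rownames(ewce_h))),
            class = "species_cocluster")
}

#' @export
print.species_cocluster <- function(x, ...) {
  cat(sprintf("Cross-species co-clustering: %d diseases x 2 species\n",
              length(x$nn_hit)))
  cat(sprintf("  nearest cross-species signature is the same disease: %.1f%%\n",
              100 * x$nn_same_disease_fraction))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample approximation.
#'
#' @param a,b numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(a, b) {
  if (!length(a) || !length(b)) stop_brainsig("ks_compare: empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}
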