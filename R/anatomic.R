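#' Anatomic transcriptomic disease profiles
#'
#' For each disease, averages the (optionally GDA-weighted) expression of
#' its measured genes at every structure within each subject, averages the
#' per-subject means structure-wise across subjects (structures masked in a
#' subject are excluded from that subject's contribution), and z-scores
#' each disease row across structures. Per-subject profiles (z-scored
#' within subject) are retained for holdout and identifiability analyses.
#'
#' @param expr a `subject_expression_set` (see [synth_subject_expression()]).
#' @param sets a [filter_associations()] result.
#' @param weights `NULL` for unweighted means, or `"gda"` to weight each
#'   gene by its GDA score from `sets$weights`.
#' @return a `disease_profile_matrix`: `values` (disease-by-structure
#'   z-scored matrix), `per_subject` (list of same-shape z-scored matrices),
#'   `dropped` (diseases with no measured genes), `weights_used` flag.
#' @export
disease_profile <- function(expr, sets, weights = NULL) {
  stopifnot(inherits(expr, "subject_expression_set"),
            inherits(sets, "disease_gene_sets"))
  use_w <- !is.null(weights)
  if (use_w && !identical(weights, "gda"))
    stop_brainsig("weights must be NULL or \"gda\"")
  diseases <- names(sets$sets)
  genes_measured <- expr$genes
  structures <- expr$structures

  measured <- lapply(sets$sets, intersect, genes_measured)
  dropped <- diseases[lengths(measured) == 0L]
  if (length(dropped))
    warn_brainsig("diseases with no measured genes dropped: %s",
                  paste(dropped, collapse = ", "))
  keep <- setdiff(diseases, dropped)
  if (!length(keep))
    stop_brainsig("no disease has measured genes in the expression set")

  # per subject: structures x diseases matrix of (weighted) means
  subj_means <- lapply(expr$matrices, function(m) {
    vapply(keep, function(d) {
      g <- measured[[d]]
      sub <- m[, g, drop = FALSE]
      if (use_w) {
        w <- sets$weights[[d]][g]
        if (all(w == 0)) w[] <- 1   # degenerate all-zero weights: fall back
        as.numeric(sub %*% (w / sum(w)))
      } else {
        rowMeans(sub)
      }
    }, numeric(length(structures)))
  })

  # average across subjects structure-wise, masked structures excluded
  acc <- matrix(0, length(structures), length(keep))
  cnt <- matrix(0, length(structures), length(keep))
  for (sm in subj_means) {
    ok <- !is.na(sm)
    acc[ok] <- acc[ok] + sm[ok]
    cnt <- cnt + ok
  }
  if (any(cnt == 0))
    stop_brainsig("some structures are masked in every subject")
  mean_mat <- acc / cnt
  values <- zscore_rows(t(mean_mat), "disease")
  dimnames(values) <- list(keep, structures)

  per_subject <- lapply(subj_means, function(sm) {
    prof <- t(sm)
    dimnames(prof) <- list(keep, structures)
    present <- colSums(is.na(prof)) == 0
    prof[, present] <- zscore_rows(prof[, present, drop = FALSE], "disease")
    prof
  })

  structure(list(values = values, per_subject = per_subject,
                 diseases = keep, structures = structures,
                 dropped = dropped, weights_used = use_w),
            class = "disease_profile_matrix")
}

#' @export
print.disease_profile_matrix <- function(x, ...) {
  cat(sprintf("Disease profile matrix: %d diseases x %d structures (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$weights_used) "GDA-weighted" else "unweighted"))
  if (length(x$dropped))
    cat(sprintf("  dropped (no measured genes): %s\n",
                paste(x$dropped, collapse = ", ")))
  invisible(x)
}

#' Cluster disease profiles into anatomic disease groups
#'
#' Agglomerative hierarchical clustering with Ward linkage (the `ward.D2`
#' squared-distance convention) on the distance 1 - Pearson correlation
#' between profile rows, cut into `k` groups.
#'
#' @param profiles a `disease_profile_matrix`, or a plain numeric matrix
#'   whose rows are entities to cluster.
#' @param k number of clusters.
#' @return a `cluster_result`: `labels` (named integer cluster ids in input
#'   order), `hclust` (the merge tree), `k`.
#' @export
cluster_profiles <- function(profiles, k) {
  m <- if (inherits(profiles, "disease_profile_matrix")) profiles$values
       else as.matrix(profiles)
  if (nrow(m) < k) stop_brainsig("fewer rows (%d) than clusters (%d)",
                                 nrow(m), k)
  sdv <- apply(m, 1L, stats::sd)
  if (any(sdv == 0))
    stop_brainsig("constant profile, correlation undefined: %s",
                  paste(rownames(m)[sdv == 0], collapse = ", "))
  hc <- stats::hclust(cor_dist(m), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, k = as.integer(k)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d entities in %d groups (Ward.D2, 1-Pearson)\n",
              length(x$labels), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Structure-wise group tests on disease profiles
#'
#' At each structure, a one-way ANOVA of the disease z-scores across groups,
#' followed by all pairwise two-sided unpaired t-tests. Benjamini-Hochberg
#' correction is applied across structures for the ANOVA family and across
#' structure-by-pair for the t-test family. Groups with fewer than 2
#' members are excluded (with a warning) from pairwise tests.
#'
#' @param profiles a `disease_profile_matrix`.
#' @param labels named disease-to-group vector covering the profile rows.
#' @return a `structure_test_result` with data.frames `anova` (structure,
#'   F, p, q) and `pairwise` (structure, group pair, t, p, q).
#' @export
structure_tests <- function(profiles, labels) {
  stopifnot(inherits(profiles, "disease_profile_matrix"))
  m <- profiles$values
  labels <- labels[rownames(m)]
  if (anyNA(labels))
    stop_brainsig("labels missing for some diseases")
  grp <- factor(labels)
  if (nlevels(grp) < 2L) stop_brainsig("need at least 2 groups")
  counts <- table(grp)
  small <- names(counts)[counts < 2L]
  if (length(small))
    warn_brainsig("groups with a single member excluded from pairwise tests: %s",
                  paste(small, collapse = ", "))
  pair_levels <- setdiff(levels(grp), small)

  anova_rows <- lapply(colnames(m), function(s) {
    y <- m[, s]
    if (all(tapply(y, grp, stats::var, na.rm = TRUE) == 0, na.rm = TRUE) &&
        stats::var(y) == 0) {
      return(data.frame(structure = s, F = 0, p = 1))
    }
    fit <- stats::aov(y ~ grp)
    sm <- summary(fit)[[1]]
    data.frame(structure = s, F = sm$`F value`[1], p = sm$`Pr(>F)`[1])
  })
  anova_df <- do.call(rbind, anova_rows)
  # identical group means give F = 0 whose p is 1 by convention
  anova_df$p[anova_df$F == 0] <- 1
  anova_df$q <- stats::p.adjust(anova_df$p, method = "BH")

  pairs <- if (length(pair_levels) >= 2L) utils::combn(pair_levels, 2L)
           else matrix(character(0), nrow = 2)
  pw <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    for (s in colnames(m)) {
      ya <- m[grp == a, s]; yb <- m[grp == b, s]
      tt <- tryCatch(stats::t.test(ya, yb, var.equal = FALSE),
                     error = function(e) NULL)
      pw[[length(pw) + 1L]] <- data.frame(
        structure = s, group_a = a, group_b = b,
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        p = if (is.null(tt)) NA_real_ else tt$p.value)
    }
  }
  pairwise_df <- if (length(pw)) do.call(rbind, pw) else
    data.frame(structure = character(0), group_a = character(0),
               group_b = character(0), t = numeric(0), p = numeric(0))
  if (nrow(pairwise_df))
    pairwise_df$q <- stats::p.adjust(pairwise_df$p, method = "BH")

  structure(list(anova = anova_df, pairwise = pairwise_df),
            class = "structure_test_result")
}

#' @export
print.structure_test_result <- function(x, ...) {
  cat(sprintf("Structure tests: %d structures, %d pairwise rows\n",
              nrow(x$anova), nrow(x$pairwise)))
  cat(sprintf("  structures with ANOVA q < 0.05: %d\n",
              sum(x$anova$q < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Cross-subject identifiability of disease signatures
#'
#' For every subject and disease, finds the most similar disease profile
#' among all diseases of every other subject (Pearson similarity or
#' Euclidean distance) and tallies how often the nearest profile is the
#' same disease, the same anatomic disease group, and the same GBD class.
#' Nearest-neighbor ties break to the lowest disease index. With
#' `exclude_self = TRUE` the same disease is never a candidate, probing
#' which *other* disease a signature resembles most.
#'
#' @param profiles a `disease_profile_matrix` with per-subject profiles.
#' @param adg named disease-to-ADG labels (optional).
#' @param gbd named disease-to-GBD labels (optional).
#' @param metric `"pearson"` or `"euclidean"`.
#' @param exclude_self drop the same disease from the candidate pool.
#' @return an `identity_result`: `exact_freq`, `adg_freq`, `gbd_freq` (per
#'   disease), and `assignment_counts` (disease-by-disease tally).
#' @export
crosssubject_identity <- function(profiles, adg = NULL, gbd = NULL,
                                  metric = c("pearson", "euclidean"),
                                  exclude_self = FALSE) {
  stopifnot(inherits(profiles, "disease_profile_matrix"))
  metric <- match.arg(metric)
  ps <- profiles$per_subject
  if (length(ps) < 2L)
    stop_brainsig("cross-subject identity needs at least 2 subjects")
  diseases <- profiles$diseases
  n_d <- length(diseases)
  counts <- matrix(0L, n_d, n_d, dimnames = list(diseases, diseases))

  for (s in seq_along(ps)) {
    for (o in seq_along(ps)) {
      if (o == s) next
      # structures observed in both subjects' profiles
      ok <- colSums(is.na(ps[[s]])) == 0 & colSums(is.na(ps[[o]])) == 0
      A <- ps[[s]][, ok, drop = FALSE]
      B <- ps[[o]][, ok, drop = FALSE]
      score <- if (metric == "pearson") {
        stats::cor(t(A), t(B))                     # higher is closer
      } else {
        -as.matrix(proxy_euclid(A, B))             # negate: higher closer
      }
      if (exclude_self) diag(score) <- -Inf
      nn <- apply(score, 1L, which.max)            # ties: lowest index
      counts[cbind(seq_len(n_d), nn)] <- counts[cbind(seq_len(n_d), nn)] + 1L
    }
  }
  n_comp <- length(ps) * (length(ps) - 1L)
  exact_freq <- diag(counts) / n_comp
  group_freq <- function(lab) {
    if (is.null(lab)) return(NULL)
    lab <- lab[diseases]
    same <- outer(lab, lab, "==")
    rowSums(counts * same) / n_comp
  }
  structure(list(exact_freq = exact_freq, adg_freq = group_freq(adg),
                 gbd_freq = group_freq(gbd), assignment_counts = counts,
                 metric = metric, exclude_self = exclude_self,
                 n_comparisons = n_comp),
            class = "identity_result")
}

# Euclidean cross-distance between rows of A and rows of B.
#' @noRd
proxy_euclid <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("Cross-subject identity (%s%s): mean exact match %.3f\n",
              x$metric, if (x$exclude_self) ", self excluded" else "",
              mean(x$exact_freq)))
  if (!is.null(x$adg_freq))
    cat(sprintf("  mean same-ADG frequency: %.3f\n", mean(x$adg_freq)))
  if (!is.null(x$gbd_freq))
    cat(sprintf("  mean same-GBD frequency: %.3f\n", mean(x$gbd_freq)))
  invisible(x)
}

#' Prime-factorization code of a 5-group expression signature
#'
#' Ranks the five group means at a structure from lowest (1) to highest (5)
#' and encodes the rank permutation as
#' `2^r1 * 3^r2 * 5^r3 * 7^r4 * 11^r5`; unique factorization makes the code
#' injective over permutations. Exact ties error by default, or resolve by
#' first-occurrence order with `tie_policy = "stable-order"`.
#'
#' @param group_means numeric vector of 5 group means.
#' @param tie_policy `"error"` or `"stable-order"`.
#' @return numeric signature code (an exact integer value up to
#'   `2 * 3^2 * 5^3 * 7^4 * 11^5`, beyond 32-bit range but exactly
#'   representable in a double).
#' @seealso [signature_decode()]
#' @export
signature_code <- function(group_means, tie_policy = c("error", "stable-order")) {
  tie_policy <- match.arg(tie_policy)
  if (length(group_means) != 5L)
    stop_brainsig("signature_code expects exactly 5 group means")
  if (anyDuplicated(group_means) && tie_policy == "error")
    stop_brainsig("tied group means; set tie_policy=\"stable-order\" to break by order")
  r <- rank(group_means, ties.method = "first")
  primes <- c(2, 3, 5, 7, 11)
  round(prod(primes^r))
}

#' Decode a prime-factorization signature code back to ranks
#'
#' @param code integer produced by [signature_code()].
#' @return integer vector of 5 ranks.
#' @export
signature_decode <- function(code) {
  primes <- c(2, 3, 5, 7, 11)
  r <- integer(5)
  n <- as.numeric(code)
  for (i in seq_along(primes)) {
    while (n %% primes[i] == 0) {
      r[i] <- r[i] + 1L
      n <- n / primes[i]
    }
  }
  if (n != 1 || !setequal(r, 1:5))
    stop_brainsig("not a valid signature code: %s", format(code))
  r
}

#' Co-clustering stability under gene-set downsampling
#'
#' Repeatedly downsamples every oversized disease set to `max_genes` genes,
#' rebuilds the anatomic profiles, reclusters at `k`, and records pairwise
#' co-membership; returns the co-clustering frequency over replicates.
#'
#' @param sets a [filter_associations()] result.
#' @param expr a `subject_expression_set`.
#' @param max_genes downsampling cap.
#' @param reps number of replicates.
#' @param k cluster count per replicate.
#' @param seed integer seed.
#' @return disease-by-disease co-clustering frequency matrix.
#' @export
subsample_stability <- function(sets, expr, max_genes = 200L, reps = 1000L,
                                k = 5L, seed = 1L) {
  stopifnot(inherits(sets, "disease_gene_sets"), reps >= 1L)
  set.seed(seed)
  diseases <- names(sets$sets)
  co <- matrix(0, length(diseases), length(diseases),
               dimnames = list(diseases, diseases))
  used <- matrix(0, length(diseases), length(diseases),
                 dimnames = list(diseases, diseases))
  for (b in seq_len(reps)) {
    sub <- sets
    sub$sets <- lapply(sets$sets, function(g) {
      if (length(g) > max_genes) sample(g, max_genes) else g
    })
    prof <- disease_profile(expr, sub)
    cl <- cluster_profiles(prof, k = k)$labels
    same <- outer(cl, cl, "==")
    idx <- match(names(cl), diseases)
    co[idx, idx] <- co[idx, idx] + same
    used[idx, idx] <- used[idx, idx] + 1
  }
  co / pmax(used, 1)
}

#' Pairwise co-membership agreement between two clusterings
#'
#' Fraction of unordered entity pairs whose same/different-cluster status
#' agrees between two labelings of the same universe.
#'
#' @param labels_a,labels_b named cluster labelings of the same entities.
#' @return agreement fraction in `[0,1]`.
#' @export
clustering_agreement <- function(labels_a, labels_b) {
  if (!setequal(names(labels_a), names(labels_b)))
    stop_brainsig("clusterings label different universes")
  ids <- names(labels_a)
  a <- labels_a[ids]; b <- labels_b[ids]
  sa <- outer(a, a, "==")[upper.tri(diag(length(ids)))]
  sb <- outer(b, b, "==")[upper.tri(diag(length(ids)))]
  mean(sa == sb)
}
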