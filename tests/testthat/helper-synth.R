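# Shared fixtures: a desk-scale synthetic study small enough for fast tests.

tiny_config <- function(...) {
  args <- list(n_subjects = 3L, n_structures = 30L, n_regions = 5L,
               n_modules = 6L, genes_per_module = 60L,
               n_unstable_genes = 20L, subject_noise_sd = 0.1,
               n_celltypes = 10L, n_classes = 3L, n_subclasses = 5L,
               n_diseases = 12L, n_disease_groups = 3L,
               genes_per_disease = c(10L, 12L), overlap_rate = 0,
               seed = 42L)
  override <- list(...)
  do.call(synth_config, utils::modifyList(args, override))
}

# filter tuned to the tiny set sizes (no evidence filtering, small floor)
tiny_sets <- function(gda) {
  filter_associations(gda, min_curated = 0L, min_genes = 2L)
}

# build a subject_expression_set directly from a list of matrices
make_expr <- function(mats) {
  structures <- rownames(mats[[1]])
  structure(list(subjects = names(mats) %||%
                   paste0("B", seq_along(mats)),
                 matrices = mats, structures = structures,
                 ontology = stats::setNames(rep("R1", length(structures)),
                                            structures),
                 genes = colnames(mats[[1]])),
            class = "subject_expression_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a plain disease-by-structure matrix (rows already z-scored) together
# with per-subject copies into a disease_profile_matrix
make_profiles <- function(values, per_subject = NULL) {
  structure(list(values = values,
                 per_subject = per_subject %||% list(values, values),
                 diseases = rownames(values),
                 structures = colnames(values),
                 dropped = character(0), weights_used = FALSE),
            class = "disease_profile_matrix")
}

# literal step-up Benjamini-Hochberg, kept independent of stats::p.adjust
bh_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# adjusted Rand index between two labelings (closed form on the
# contingency table); independent oracle for planted-recovery checks
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}
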