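#' Configuration for the synthetic data generators
#'
#' Defines the dimensions and noise levels of a synthetic study: per-subject
#' structure-by-gene expression with planted co-expression modules, cell-type
#' mean-expression matrices with planted marker structure, and a gene-disease
#' association table whose diseases draw genes from the planted modules.
#' Defaults mirror the study design the package targets: 6 donor brains by
#' 104 structures in 15 parent regions, 32 canonical modules, 40 diseases in
#' 5 planted groups, 75 cortical cell types in 3 classes / 20 subclasses.
#'
#' @param n_subjects number of donor brains.
#' @param n_structures number of brain structures (rows of each expression
#'   matrix).
#' @param n_regions number of parent regions partitioning the structures.
#' @param n_modules number of planted co-expression modules.
#' @param genes_per_module genes loading on each module eigengene.
#' @param n_unstable_genes genes with an independent random pattern per
#'   subject (no reproducible anatomy).
#' @param subject_noise_sd standard deviation of per-subject additive noise
#'   around the eigengene pattern, in units of the (unit-variance) pattern.
#' @param structure_dropout probability that a structure is unmeasured
#'   (masked, not zero) in a given subject.
#' @param n_celltypes number of cell types in the cell-type matrices.
#' @param n_classes number of broad cell-type classes.
#' @param n_subclasses number of cell-type subclasses.
#' @param marker_specificity weight in `[0,1]` a marker gene concentrates on
#'   its home cell type; 0 gives uniform expression, 1 exclusive expression.
#' @param expression_jitter lognormal sd of per-(gene, cell type) variation
#'   around the marker model, shared between species; real cell-type means
#'   vary continuously, so 0 (an exactly uniform background) is only useful
#'   for boundary checks.
#' @param species_effect lognormal perturbation sd applied to the mouse
#'   matrix relative to human; 0 makes homologous types identical.
#' @param n_diseases number of diseases in the synthetic association table.
#' @param n_disease_groups planted disease groups (each aligned to one
#'   module).
#' @param genes_per_disease length-2 integer range of disease set sizes.
#' @param module_purity fraction of a disease's genes drawn from its group's
#'   home module (the remainder comes from other modules).
#' @param overlap_rate fraction of each disease's set replaced by genes from
#'   a random disease in the same group (planted overlap).
#' @param evidence_rates Poisson means of the four evidence counts
#'   (curated, animal-model, inferred, literature).
#' @param seed master integer seed; each generator derives its own stream.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 6L, n_structures = 104L,
                         n_regions = 15L, n_modules = 32L,
                         genes_per_module = 120L, n_unstable_genes = 384L,
                         subject_noise_sd = 0.3, structure_dropout = 0,
                         n_celltypes = 75L, n_classes = 3L,
                         n_subclasses = 20L, marker_specificity = 0.8,
                         expression_jitter = 0.15,
                         species_effect = 0.1, n_diseases = 40L,
                         n_disease_groups = 5L,
                         genes_per_disease = c(10L, 14L),
                         module_purity = 0.9, overlap_rate = 0.1,
                         evidence_rates = c(2, 0.5, 0.5, 3), seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_structures = as.integer(n_structures),
              n_regions = as.integer(n_regions),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              n_unstable_genes = as.integer(n_unstable_genes),
              subject_noise_sd = subject_noise_sd,
              structure_dropout = structure_dropout,
              n_celltypes = as.integer(n_celltypes),
              n_classes = as.integer(n_classes),
              n_subclasses = as.integer(n_subclasses),
              marker_specificity = marker_specificity,
              expression_jitter = expression_jitter,
              species_effect = species_effect,
              n_diseases = as.integer(n_diseases),
              n_disease_groups = as.integer(n_disease_groups),
              genes_per_disease = as.integer(genes_per_disease),
              module_purity = module_purity,
              overlap_rate = overlap_rate,
              evidence_rates = evidence_rates,
              seed = as.integer(seed))
  counts <- c("n_subjects", "n_structures", "n_regions", "n_modules",
              "genes_per_module", "n_celltypes", "n_classes",
              "n_subclasses", "n_diseases", "n_disease_groups")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_brainsig("synth_config: %s must be a count >= 1", f)
  }
  if (cfg$n_unstable_genes < 0L)
    stop_brainsig("synth_config: n_unstable_genes must be >= 0")
  if (cfg$n_celltypes < 2L)
    stop_brainsig("synth_config: n_celltypes must be >= 2")
  if (length(cfg$genes_per_disease) != 2L ||
      any(cfg$genes_per_disease < 1L) ||
      cfg$genes_per_disease[1] > cfg$genes_per_disease[2])
    stop_brainsig("synth_config: genes_per_disease must be a nondecreasing range of counts")
  for (f in c("marker_specificity", "overlap_rate", "module_purity",
              "structure_dropout")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_brainsig("synth_config: %s must lie in [0,1]", f)
  }
  if (cfg$subject_noise_sd < 0 || cfg$species_effect < 0 ||
      cfg$expression_jitter < 0)
    stop_brainsig("synth_config: noise parameters must be nonnegative")
  if (length(cfg$evidence_rates) != 4L || any(cfg$evidence_rates < 0))
    stop_brainsig("synth_config: evidence_rates must be 4 nonnegative reals")
  class(cfg) <- "synth_config"
  cfg
}

#' @noRd
synth_gene_universe <- function(config) {
  n_genes <- config$genes_per_module * config$n_modules +
    config$n_unstable_genes
  sprintf("G%05d", seq_len(n_genes))
}

#' @noRd
synth_truth_map <- function(config) {
  genes <- synth_gene_universe(config)
  module_of <- c(rep(sprintf("M%d", seq_len(config$n_modules)),
                     each = config$genes_per_module),
                 rep(NA_character_, config$n_unstable_genes))
  stats::setNames(module_of, genes)
}

#' Generate per-subject structure-by-gene expression with planted modules
#'
#' Each module gene's profile is its module eigengene plus independent
#' Gaussian noise per subject; unstable genes get a fresh random profile in
#' every subject. Values are on a log-expression scale (eigengenes are
#' z-scored across structures). Structures may be masked per subject with
#' probability `structure_dropout` (rows set to `NA`, never zero).
#'
#' @param config a [synth_config()].
#' @return list with components `expr` (a `subject_expression_set`: subject
#'   ids, per-subject structure-by-gene matrices, structure ontology),
#'   `eigengenes` (a `module_eigengenes`: module-by-structure z-scored
#'   patterns), and `truth` (named gene-to-module map, `NA` for unstable
#'   genes).
#' @export
synth_subject_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 1L))
  genes <- synth_gene_universe(config)
  truth <- synth_truth_map(config)
  structures <- sprintf("S%03d", seq_len(config$n_structures))
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  ontology <- stats::setNames(
    regions[1 + (seq_len(config$n_structures) - 1L) %% config$n_regions],
    structures)

  patterns <- matrix(stats::rnorm(config$n_modules * config$n_structures),
                     nrow = config$n_modules,
                     dimnames = list(sprintf("M%d", seq_len(config$n_modules)),
                                     structures))
  patterns <- zscore_rows(patterns, "eigengene")

  subjects <- sprintf("B%d", seq_len(config$n_subjects))
  module_idx <- match(truth, rownames(patterns))
  matrices <- lapply(subjects, function(s) {
    base <- t(patterns)[, module_idx, drop = FALSE] # structures x genes
    base[is.na(base)] <- 0
    noise <- if (config$subject_noise_sd > 0) {
      matrix(stats::rnorm(length(base), sd = config$subject_noise_sd),
             nrow = nrow(base))
    } else 0
    m <- base + noise
    unstable <- which(is.na(truth))
    if (length(unstable)) {
      m[, unstable] <- matrix(stats::rnorm(config$n_structures *
                                             length(unstable)),
                              nrow = config$n_structures)
    }
    dimnames(m) <- list(structures, genes)
    if (config$structure_dropout > 0) {
      drop <- stats::runif(config$n_structures) < config$structure_dropout
      m[drop, ] <- NA_real_
    }
    m
  })
  names(matrices) <- subjects
  expr <- structure(list(subjects = subjects, matrices = matrices,
                         structures = structures, ontology = ontology,
                         genes = genes),
                    class = "subject_expression_set")
  eig <- structure(list(modules = rownames(patterns), patterns = patterns),
                   class = "module_eigengenes")
  list(expr = expr, eigengenes = eig, truth = truth)
}

#' Generate cell-type mean-expression matrices for two species
#'
#' Every gene gets a home cell type (derived from its module so that disease
#' groups planted on disjoint modules concentrate in disjoint cell-type
#' pools). A gene places weight `marker_specificity` on its home type and
#' spreads the remainder uniformly; rows are scaled to counts per million.
#' The mouse matrix shares the marker identity of homologous types up to a
#' multiplicative lognormal `species_effect` perturbation.
#'
#' @param config a [synth_config()].
#' @return list with `human` and `mouse` (`celltype_expression_matrix`:
#'   cell-type-by-gene CPM with class/subclass taxonomy and species tag) and
#'   `homology` data.frame (consensus_id, species, celltype_id).
#' @export
synth_cell_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_celltypes < 2L)
    stop_brainsig("synth_cell_expression: n_celltypes must be >= 2")
  set.seed(derive_seed(config$seed, 2L))
  genes <- synth_gene_universe(config)
  truth <- synth_truth_map(config)
  n_ct <- config$n_celltypes
  celltypes <- sprintf("CT%02d", seq_len(n_ct))
  classes <- sprintf("class%d", 1 + (seq_len(n_ct) - 1L) %% config$n_classes)
  subclasses <- sprintf("subclass%02d",
                        1 + (seq_len(n_ct) - 1L) %% config$n_subclasses)

  module_num <- as.integer(sub("^M", "", truth))
  home <- ifelse(is.na(module_num),
                 1 + (seq_along(genes) - 1L) %% n_ct,
                 1 + (module_num - 1L) %% n_ct)
  ms <- config$marker_specificity
  base <- matrix((1 - ms) / n_ct, nrow = n_ct, ncol = length(genes),
                 dimnames = list(celltypes, genes))
  base[cbind(home, seq_along(genes))] <- base[cbind(home, seq_along(genes))] + ms
  if (config$expression_jitter > 0) {
    # continuous per-(gene, cell type) variation, shared between species
    base <- base * exp(matrix(stats::rnorm(length(base),
                                           sd = config$expression_jitter),
                              nrow = n_ct))
  }

  make_species <- function(weights, species) {
    if (config$species_effect > 0 && species == "mouse") {
      weights <- weights * exp(matrix(
        stats::rnorm(length(weights), sd = config$species_effect),
        nrow = nrow(weights)))
    }
    cpm <- sweep(weights, 1L, rowSums(weights), "/") * 1e6
    structure(list(celltypes = celltypes, classes = classes,
                   subclasses = subclasses, genes = genes, values = cpm,
                   species = species),
              class = "celltype_expression_matrix")
  }
  human <- make_species(base, "human")
  mouse <- make_species(base, "mouse")
  homology <- data.frame(
    consensus_id = rep(sprintf("CONS%02d", seq_len(n_ct)), 2L),
    species = rep(c("human", "mouse"), each = n_ct),
    celltype_id = rep(celltypes, 2L),
    stringsAsFactors = FALSE)
  list(human = human, mouse = mouse, homology = homology)
}

#' Generate a synthetic gene-disease association table from planted modules
#'
#' Diseases in the same planted group draw `module_purity` of their genes
#' from that group's home module (disjointly within the group), the rest
#' from other modules; a fraction `overlap_rate` of each set is then
#' replaced by genes of a random disease in the same group, planting
#' within-group overlap. Evidence counts N1..N4 are Poisson with means
#' `evidence_rates` (N1 shifted by +1 so every record has curated support).
#'
#' @param config a [synth_config()].
#' @param truth gene-to-module map from [synth_subject_expression()].
#' @return long-format data.frame (disease_id, disease_name, gbd_class,
#'   gene, n_curated, n_animal, n_inferred, n_literature) with attributes
#'   `group` (planted disease-to-group map) and `home_module`.
#' @export
synth_gda <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 3L))
  genes <- names(truth)
  modules <- sprintf("M%d", seq_len(config$n_modules))
  n_grp <- config$n_disease_groups
  # spread home modules across the module range so groups are well separated
  home_module <- modules[unique(round(seq(1, config$n_modules,
                                          length.out = n_grp)))]
  if (length(home_module) < n_grp)
    stop_brainsig("synth_gda: fewer modules than disease groups")
  diseases <- sprintf("D%02d", seq_len(config$n_diseases))
  group <- stats::setNames(
    sprintf("group%d", 1 + (seq_len(config$n_diseases) - 1L) %% n_grp),
    diseases)

  sizes <- sample(seq(config$genes_per_disease[1], config$genes_per_disease[2]),
                  config$n_diseases, replace = TRUE)
  names(sizes) <- diseases

  sets <- vector("list", config$n_diseases)
  names(sets) <- diseases
  for (g in seq_len(n_grp)) {
    members <- diseases[group == sprintf("group%d", g)]
    pool_home <- sample(genes[!is.na(truth) & truth == home_module[g]])
    other_modules <- setdiff(modules, home_module[g])
    for (j in seq_along(members)) {
      d <- members[j]
      n_home <- ceiling(config$module_purity * sizes[[d]])
      n_other <- sizes[[d]] - n_home
      # each member spills into its own secondary module, so signatures of
      # same-group diseases stay distinguishable at low noise
      sec <- other_modules[1 + (j - 1L) %% length(other_modules)]
      pool_sec <- genes[!is.na(truth) & truth == sec]
      if (n_home > length(pool_home) || n_other > length(pool_sec))
        stop_brainsig("synth_gda: genes_per_disease exceeds available gene pool")
      sets[[d]] <- c(pool_home[seq_len(n_home)],
                     if (n_other > 0) sample(pool_sec, n_other))
      pool_home <- pool_home[-seq_len(n_home)]
    }
    # planted overlap: replace a fraction of each set with a peer's genes
    if (config$overlap_rate > 0 && length(members) > 1) {
      for (d in members) {
        n_share <- floor(config$overlap_rate * length(sets[[d]]))
        if (n_share < 1) next
        donor <- sample(setdiff(members, d), 1L)
        incoming <- sample(sets[[donor]], min(n_share, length(sets[[donor]])))
        keep <- sample(setdiff(sets[[d]], incoming))  # drop random genes
        sets[[d]] <- c(keep[seq_len(length(sets[[d]]) - length(incoming))],
                       incoming)
      }
    }
  }

  records <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(disease_id = d,
               disease_name = paste("synthetic disease", d),
               gbd_class = group[[d]], gene = sets[[d]],
               stringsAsFactors = FALSE)
  }))
  n <- nrow(records)
  records$n_curated <- 1L + stats::rpois(n, config$evidence_rates[1])
  records$n_animal <- stats::rpois(n, config$evidence_rates[2])
  records$n_inferred <- stats::rpois(n, config$evidence_rates[3])
  records$n_literature <- stats::rpois(n, config$evidence_rates[4])
  attr(records, "group") <- group
  attr(records, "home_module") <- stats::setNames(
    home_module[1 + (seq_len(config$n_diseases) - 1L) %% n_grp], diseases)
  records
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  subjects: %d, structures: %d (%d regions)\n",
              x$n_subjects, x$n_structures, x$n_regions))
  cat(sprintf("  modules: %d x %d genes + %d unstable (noise sd %.2f)\n",
              x$n_modules, x$genes_per_module, x$n_unstable_genes,
              x$subject_noise_sd))
  cat(sprintf("  cell types: %d (%d classes, %d subclasses), marker specificity %.2f\n",
              x$n_celltypes, x$n_classes, x$n_subclasses,
              x$marker_specificity))
  cat(sprintf("  diseases: %d in %d groups, set sizes %d-%d, overlap %.2f\n",
              x$n_diseases, x$n_disease_groups, x$genes_per_disease[1],
              x$genes_per_disease[2], x$overlap_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.subject_expression_set <- function(x, ...) {
  cat(sprintf("Subject expression set: %d subjects x %d structures x %d genes\n",
              length(x$subjects), length(x$structures), length(x$genes)))
  invisible(x)
}

#' @export
print.celltype_expression_matrix <- function(x, ...) {
  cat(sprintf("Cell-type expression (%s): %d cell types x %d genes (CPM)\n",
              x$species, length(x$celltypes), length(x$genes)))
  invisible(x)
}
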