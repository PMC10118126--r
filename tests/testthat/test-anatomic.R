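test_that("disease rows are z-scored means of their genes", {
  cfg <- tiny_config()
  sim <- synth_subject_expression(cfg)
  sets <- tiny_sets(synth_gda(cfg, sim$truth))
  prof <- disease_profile(sim$expr, sets)
  # z-row invariant at tight tolerance
  expect_lt(max(abs(rowMeans(prof$values))), 1e-9)
  expect_lt(max(abs(apply(prof$values, 1, sd) - 1)), 1e-9)
  # recompute one disease by hand: mean over genes within subject, then
  # across subjects, then z-score
  d <- prof$diseases[1]
  g <- intersect(sets$sets[[d]], sim$expr$genes)
  manual <- rowMeans(sapply(sim$expr$matrices, function(m)
    rowMeans(m[, g, drop = FALSE])))
  manual <- (manual - mean(manual)) / sd(manual)
  expect_equal(unname(prof$values[d, ]), unname(manual), tolerance = 1e-12)
})

test_that("single-gene disease profile equals that gene's mean profile", {
  cfg <- tiny_config()
  sim <- synth_subject_expression(cfg)
  g <- sim$expr$genes[5]
  tab <- data.frame(disease_id = "dX", gbd_class = "movement", gene = g,
                    n_curated = 1L, n_animal = 0L, n_inferred = 0L,
                    n_literature = 0L, stringsAsFactors = FALSE)
  sets <- filter_associations(tab, min_genes = 1L)
  prof <- disease_profile(sim$expr, sets)
  manual <- rowMeans(sapply(sim$expr$matrices, function(m) m[, g]))
  manual <- (manual - mean(manual)) / sd(manual)
  expect_equal(unname(prof$values["dX", ]), unname(manual),
               tolerance = 1e-12)
})

test_that("equal GDA weights reproduce the unweighted profile", {
  cfg <- tiny_config()
  sim <- synth_subject_expression(cfg)
  gda <- synth_gda(cfg, sim$truth)
  gda$n_curated <- 1L; gda$n_animal <- 0L
  gda$n_inferred <- 0L; gda$n_literature <- 0L   # every weight 0.3
  sets <- filter_associations(gda, min_curated = 0L, min_genes = 2L)
  unw <- disease_profile(sim$expr, sets)
  wtd <- disease_profile(sim$expr, sets, weights = "gda")
  expect_true(wtd$weights_used)
  expect_equal(wtd$values, unw$values, tolerance = 1e-12)
})

test_that("GDA weighting shifts the profile toward high-evidence genes", {
  m <- matrix(rnorm(20 * 2), 20, 2,
              dimnames = list(sprintf("S%02d", 1:20), c("GA", "GB")))
  expr <- make_expr(list(B1 = m, B2 = m))
  tab <- data.frame(disease_id = "dW", gbd_class = "other",
                    gene = c("GA", "GB"),
                    n_curated = c(3L, 1L), n_animal = c(1L, 0L),
                    n_inferred = c(1L, 0L), n_literature = c(20L, 0L),
                    stringsAsFactors = FALSE)
  sets <- filter_associations(tab, min_genes = 1L)
  wtd <- disease_profile(expr, sets, weights = "gda")
  manual <- (1.0 * m[, "GA"] + 0.3 * m[, "GB"]) / 1.3
  manual <- (manual - mean(manual)) / sd(manual)
  expect_equal(unname(wtd$values["dW", ]), unname(manual),
               tolerance = 1e-12)
})

test_that("diseases without measured genes are reported, not zeroed", {
  cfg <- tiny_config()
  sim <- synth_subject_expression(cfg)
  tab <- data.frame(disease_id = rep(c("dIn", "dOut"), each = 2),
                    gbd_class = "other",
                    gene = c(sim$expr$genes[1:2], "NOPE1", "NOPE2"),
                    n_curated = 1L, n_animal = 0L, n_inferred = 0L,
                    n_literature = 0L, stringsAsFactors = FALSE)
  sets <- filter_associations(tab, min_genes = 1L)
  expect_warning(prof <- disease_profile(sim$expr, sets), "dOut")
  expect_identical(prof$dropped, "dOut")
  expect_identical(rownames(prof$values), "dIn")
})

test_that("clustering recovers planted groups and degenerate cuts", {
  cfg <- tiny_config(subject_noise_sd = 0.1)
  sim <- synth_subject_expression(cfg)
  gda <- synth_gda(cfg, sim$truth)
  sets <- tiny_sets(gda)
  prof <- disease_profile(sim$expr, sets)
  cl <- cluster_profiles(prof, k = cfg$n_disease_groups)
  expect_equal(ari(cl$labels, attr(gda, "group")[names(cl$labels)]), 1.0)
  # degenerate cut: every disease its own cluster
  cl_n <- cluster_profiles(prof, k = nrow(prof$values))
  expect_identical(length(unique(cl_n$labels)), nrow(prof$values))
  # merge heights are non-decreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("duplicated profiles merge first at height zero", {
  base <- matrix(rnorm(4 * 12), 4, 12,
                 dimnames = list(paste0("d", 1:4), paste0("S", 1:12)))
  base[2, ] <- base[1, ]
  hc <- cluster_profiles(base, k = 2)$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))
})

test_that("correlation distance ignores row scaling of the inputs", {
  m <- matrix(rnorm(6 * 15), 6, 15,
              dimnames = list(paste0("d", 1:6), paste0("S", 1:15)))
  scaled <- m * matrix(runif(6, 0.5, 4), 6, 15)
  expect_identical(cluster_profiles(m, k = 3)$labels,
                   cluster_profiles(scaled, k = 3)$labels)
  m[3, ] <- 7  # constant profile must be named in the error
  expect_error(cluster_profiles(m, k = 2), "d3")
})

test_that("structure tests return the null on identical groups", {
  vals <- matrix(rnorm(12), 1, 12)
  values <- matrix(rep(vals, 6), 6, 12, byrow = TRUE,
                   dimnames = list(paste0("d", 1:6), paste0("S", 1:12)))
  values <- (values - mean(values[1, ])) / sd(values[1, ])
  prof <- make_profiles(values)
  labels <- stats::setNames(rep(c("g1", "g2"), each = 3), rownames(values))
  res <- structure_tests(prof, labels)
  expect_true(all(res$anova$F == 0))
  expect_true(all(res$anova$p == 1))
  expect_true(all(res$anova$q == 1))
})

test_that("BH adjustment matches the literal step-up rule", {
  set.seed(11)
  values <- matrix(rnorm(10 * 20), 10, 20,
                   dimnames = list(paste0("d", 1:10), paste0("S", 1:20)))
  values <- t(apply(values, 1, function(r) (r - mean(r)) / sd(r)))
  prof <- make_profiles(values)
  labels <- stats::setNames(rep(c("g1", "g2"), each = 5), rownames(values))
  res <- structure_tests(prof, labels)
  expect_equal(res$anova$q, bh_literal(res$anova$p), tolerance = 1e-12)
  expect_equal(res$pairwise$q, bh_literal(res$pairwise$p), tolerance = 1e-12)
  expect_true(all(res$anova$q >= res$anova$p))
})

test_that("a planted group shift is detected at the right structure", {
  set.seed(21)
  values <- matrix(rnorm(20 * 30, sd = 0.2), 20, 30,
                   dimnames = list(paste0("d", 1:20), paste0("S", 1:30)))
  labels <- stats::setNames(rep(c("g1", "g2"), each = 10), rownames(values))
  values[labels == "g2", "S7"] <- values[labels == "g2", "S7"] + 3
  values <- t(apply(values, 1, function(r) (r - mean(r)) / sd(r)))
  res <- structure_tests(make_profiles(values), labels)
  expect_lt(res$anova$q[res$anova$structure == "S7"], 0.05)
  others <- res$anova$p[res$anova$structure != "S7"]
  expect_gt(suppressWarnings(stats::ks.test(others, "punif"))$p.value, 0.01)
})

test_that("singleton groups are excluded from pairwise tests", {
  set.seed(3)
  values <- matrix(rnorm(5 * 8), 5, 8,
                   dimnames = list(paste0("d", 1:5), paste0("S", 1:8)))
  values <- t(apply(values, 1, function(r) (r - mean(r)) / sd(r)))
  labels <- stats::setNames(c("g1", "g1", "g2", "g2", "g3"),
                            rownames(values))
  expect_warning(res <- structure_tests(make_profiles(values), labels),
                 "g3")
  expect_setequal(unique(c(res$pairwise$group_a, res$pairwise$group_b)),
                  c("g1", "g2"))
})

test_that("identical subjects are perfectly identifiable", {
  cfg <- tiny_config(subject_noise_sd = 0)
  sim <- synth_subject_expression(cfg)
  sets <- tiny_sets(synth_gda(cfg, sim$truth))
  prof <- disease_profile(sim$expr, sets)
  id <- crosssubject_identity(prof)
  expect_true(all(id$exact_freq == 1))
  expect_identical(sum(id$assignment_counts),
                   as.integer(id$n_comparisons * nrow(prof$values)))
  expect_error(crosssubject_identity(prof, metric = "cosine"))
})

test_that("randomized profiles match at chance level", {
  set.seed(77)
  n_d <- 10L
  hits <- replicate(100, {
    per <- lapply(1:3, function(s) {
      m <- matrix(rnorm(n_d * 20), n_d, 20,
                  dimnames = list(paste0("d", 1:n_d), paste0("S", 1:20)))
      t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
    })
    prof <- make_profiles(per[[1]], per_subject = per)
    mean(crosssubject_identity(prof)$exact_freq)
  })
  # expectation 1/n_d; 100 replicates bound the Monte-Carlo error
  expect_lt(abs(mean(hits) - 1 / n_d), 3 * sd(hits) / sqrt(length(hits)))
})

test_that("pearson identity is invariant to per-subject affine rescaling", {
  cfg <- tiny_config(subject_noise_sd = 0.2)
  sim <- synth_subject_expression(cfg)
  sets <- tiny_sets(synth_gda(cfg, sim$truth))
  prof <- disease_profile(sim$expr, sets)
  rescaled <- prof
  rescaled$per_subject <- lapply(seq_along(prof$per_subject), function(s)
    prof$per_subject[[s]] * (1 + s) + s)
  a <- crosssubject_identity(prof)
  b <- crosssubject_identity(rescaled)
  expect_identical(a$assignment_counts, b$assignment_counts)
})

test_that("excluding self finds the nearest other disease", {
  cfg <- tiny_config(subject_noise_sd = 0)
  sim <- synth_subject_expression(cfg)
  sets <- tiny_sets(synth_gda(cfg, sim$truth))
  prof <- disease_profile(sim$expr, sets)
  id <- crosssubject_identity(prof, exclude_self = TRUE)
  expect_true(all(diag(id$assignment_counts) == 0))
  expect_true(all(id$exact_freq == 0))
})

test_that("signature codes round-trip all 120 rank permutations", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) all(sort(r) == 1:5)), ]
  expect_identical(nrow(perms), 120L)
  codes <- apply(perms, 1, function(r) signature_code(as.numeric(r)))
  expect_identical(length(unique(codes)), 120L)   # injective
  for (i in seq_len(nrow(perms))) {
    expect_identical(signature_decode(codes[i]), as.integer(perms[i, ]))
  }
  expect_error(signature_code(c(1, 1, 2, 3, 4)), "tied")
  expect_identical(signature_code(c(1, 1, 2, 3, 4), "stable-order"),
                   signature_code(c(1, 1.5, 2, 3, 4) - c(0, 0.5, 0, 0, 0),
                                  "stable-order"))
  expect_error(signature_decode(13L), "valid")
})

test_that("clustering agreement counts co-membership pairs", {
  a <- stats::setNames(c(1, 1, 2, 2), paste0("d", 1:4))
  b <- stats::setNames(c(1, 2, 1, 2), paste0("d", 1:4))
  expect_equal(clustering_agreement(a, b), 1 / 3)
  expect_equal(clustering_agreement(a, a), 1)
  singletons <- stats::setNames(1:4, paste0("d", 1:4))
  expect_equal(clustering_agreement(singletons, singletons), 1)
  expect_error(clustering_agreement(a, b[1:3]), "universes")
})

test_that("subsample stability is deterministic and finds stable groups", {
  cfg <- tiny_config(subject_noise_sd = 0.1)
  sim <- synth_subject_expression(cfg)
  gda <- synth_gda(cfg, sim$truth)
  sets <- tiny_sets(gda)
  f1 <- subsample_stability(sets, sim$expr, max_genes = 8L, reps = 15L,
                            k = cfg$n_disease_groups, seed = 5L)
  f2 <- subsample_stability(sets, sim$expr, max_genes = 8L, reps = 15L,
                            k = cfg$n_disease_groups, seed = 5L)
  expect_identical(f1, f2)
  group <- attr(gda, "group")[rownames(f1)]
  within <- f1[outer(group, group, "==") & upper.tri(f1)]
  expect_true(all(within >= 0.95))
  # sets at or below the cap are never downsampled: frequencies are 0/1
  cap_all <- subsample_stability(sets, sim$expr, max_genes = 50L,
                                 reps = 5L, k = 3L, seed = 9L)
  expect_true(all(cap_all %in% c(0, 1)))
})
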