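#' Synthetic stand-in for the study-scale gene-disease catalog
#'
#' Builds a deterministic, fully synthetic gene-disease association table
#' (synthetic gene symbols `SYNG...`) whose class-level composition mirrors
#' the published catalog the package was designed around: 40 diseases in 7
#' GBD classes, 1,646 genes in the union, class unions of 1,107
#' (psychiatric), 257 (neurodegenerative), 212 (substance abuse), 168
#' (tumor), 139 (developmental), 136 (movement), and 123 (other), a
#' 132-gene psychiatric/substance-abuse intersection, a 41-gene
#' movement/neurodegenerative intersection, and disease set sizes from 11
#' (frontotemporal lobar degeneration) to 733 (schizophrenia). It contains
#' no real gene identifiers and exists so the parsing, filtering, and
#' set-arithmetic machinery can be exercised end to end at study scale
#' without external data.
#'
#' Within a class, disease sets are consecutive cyclic blocks over the class
#' gene pool, guaranteeing the class union is covered and producing nested
#' within-class overlap. Evidence counts cycle deterministically with every
#' record carrying at least one curated source.
#'
#' @return long-format data.frame with columns disease_id, disease_name,
#'   gbd_class, gene, n_curated, n_animal, n_inferred, n_literature.
#' @export
synth_study_gda <- function() {
  # class-level membership patterns (multiset of classes per shared gene)
  # realizing the published class-union / unique / intersection counts
  pat <- list(
    list(c("psychiatric", "substance_abuse"), 120L),
    list(c("psychiatric", "substance_abuse", "other"), 12L),
    list(c("neurodegenerative", "movement"), 33L),
    list(c("neurodegenerative", "movement", "substance_abuse"), 2L),
    list(c("psychiatric", "neurodegenerative", "movement"), 6L),
    list(c("substance_abuse", "tumor"), 10L),
    list(c("psychiatric", "neurodegenerative", "other"), 34L),
    list(c("psychiatric", "neurodegenerative"), 12L),
    list(c("psychiatric", "neurodegenerative", "tumor"), 20L),
    list(c("psychiatric", "neurodegenerative", "developmental"), 18L),
    list(c("psychiatric", "movement"), 57L),
    list(c("psychiatric", "movement", "developmental"), 1L),
    list(c("psychiatric", "tumor", "developmental", "other"), 26L))
  unique_counts <- c(psychiatric = 801L, neurodegenerative = 132L,
                     substance_abuse = 68L, tumor = 112L,
                     developmental = 94L, movement = 37L, other = 51L)

  pools <- lapply(names(unique_counts), function(cl) character(0))
  names(pools) <- names(unique_counts)
  next_id <- 1L
  take <- function(n) {
    ids <- sprintf("SYNG%05d", seq.int(next_id, length.out = n))
    next_id <<- next_id + n
    ids
  }
  for (p in pat) {
    ids <- take(p[[2]])
    for (cl in p[[1]]) pools[[cl]] <- c(pools[[cl]], ids)
  }
  for (cl in names(unique_counts)) {
    pools[[cl]] <- c(pools[[cl]], take(unique_counts[[cl]]))
  }

  roster <- list(
    psychiatric = c(schizophrenia = 733L, `bipolar disorder` = 385L,
                    `autistic disorder` = 290L,
                    `major depressive disorder` = 250L,
                    `attention deficit disorder` = 120L,
                    `obsessive-compulsive disorder` = 80L, anxiety = 60L,
                    `anorexia nervosa` = 40L, `panic disorder` = 30L,
                    `tourette syndrome` = 25L),
    neurodegenerative = c(`alzheimer disease` = 180L,
                          `parkinson disease` = 102L,
                          `amyotrophic lateral sclerosis` = 60L,
                          dementia = 50L,
                          `hereditary spastic paraplegia` = 67L,
                          `prion disease` = 25L,
                          `frontotemporal lobar degeneration` = 11L),
    substance_abuse = c(`alcohol use disorder` = 90L,
                        `cocaine-related disorder` = 70L,
                        `opioid-related disorder` = 60L,
                        `tobacco use disorder` = 50L,
                        `marijuana abuse` = 40L,
                        `amphetamine-related disorder` = 30L),
    tumor = c(glioma = 80L, glioblastoma = 60L, astrocytoma = 50L,
              meningioma = 30L, `neurofibromatosis 1` = 25L),
    developmental = c(`intellectual disability` = 70L,
                      `language development disorder` = 50L,
                      `learning disorder` = 40L, `williams syndrome` = 30L),
    movement = c(dystonia = 60L, `huntington disease` = 50L,
                 `essential tremor` = 40L, `parkinsonian disorders` = 40L),
    other = c(epilepsy = 70L, migraine = 50L, narcolepsy = 30L,
              amnesia = 20L))

  rows <- list()
  d_idx <- 0L
  for (cl in names(roster)) {
    pool <- pools[[cl]]
    n_pool <- length(pool)
    offset <- 0L
    for (i in seq_along(roster[[cl]])) {
      d_idx <- d_idx + 1L
      size <- roster[[cl]][[i]]
      idx <- 1L + (offset + seq_len(size) - 1L) %% n_pool
      genes <- pool[idx]
      offset <- (offset + size) %% n_pool
      k <- seq_along(genes)
      rows[[length(rows) + 1L]] <- data.frame(
        disease_id = sprintf("SD%02d", d_idx),
        disease_name = names(roster[[cl]])[i],
        gbd_class = cl,
        gene = genes,
        n_curated = 1L + (k %% 3L),
        n_animal = k %% 2L,
        n_inferred = (k + 1L) %% 2L,
        n_literature = k %% 12L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
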