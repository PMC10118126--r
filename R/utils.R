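# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_brainsig <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_brainsig <- function(...) warning(sprintf(...), call. = FALSE)

# Row-wise z-score; errors on zero-variance rows (constant profiles have no
# correlation structure and would silently poison downstream clustering).
#' @noRd
zscore_rows <- function(m, what = "row") {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad)) {
    stop_brainsig("constant %s profile (zero variance): %s", what,
                  paste(rownames(m)[bad] %||% which(bad), collapse = ", "))
  }
  sweep(sweep(m, 1L, mu, "-"), 1L, sdv, "/")
}

# Pairwise 1 - Pearson distance between rows of a matrix, as a stats::dist.
#' @noRd
cor_dist <- function(m) {
  stats::as.dist(1 - stats::cor(t(m)))
}

# Deterministic sub-seed derivation so each generator draws from its own
# stream: adding a call to one generator never perturbs another.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) + stream * 1000003L) %% 2147483629L
}

#' @noRd
normalize_symbols <- function(genes) {
  toupper(trimws(as.character(genes)))
}

# Permutation p-value with pseudocount so p is never exactly zero.
#' @noRd
perm_pvalue <- function(n_ge, n_perm) {
  (1 + n_ge) / (n_perm + 1)
}
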