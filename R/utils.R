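# Internal numerical and sequence utilities.

# IUPAC nucleotide codes -> partial-likelihood vectors over (A, C, G, T).
# Ambiguity codes and gaps contribute 1 for every compatible state
# (missing-data treatment).
.iupac_states <- local({
  m <- list(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1),
    `.` = c(1, 1, 1, 1), X = c(1, 1, 1, 1)
  )
  do.call(cbind, m)
})

.dna_letters <- c("A", "C", "G", "T")

is_iupac_dna <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% colnames(.iupac_states))
}

# 4 x nsites conditional-likelihood matrix for one sequence string.
seq_conditionals <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), colnames(.iupac_states))
  if (length(bad) > 0)
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  .iupac_states[, chars, drop = FALSE]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic hierarchical seed derivation (survey -> lot -> egg streams).
# Mixes integer components so sibling streams are decoupled. Multipliers are
# small enough that every product stays below 2^53 (exact in doubles).
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 104729
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 12345) %% 2147483647
  }
  for (i in 1:2) h <- (h * 69069 + 12345) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
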