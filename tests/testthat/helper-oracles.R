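# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive (enumeration, quadratic DP, direct CDF inversion) and
# share no code with the implementation paths they check.

.fixtures <- new.env(parent = emptyenv())

# One reference panel (with haplotype pool) shared across test files.
shared_db <- function() {
  if (is.null(.fixtures$db)) {
    .fixtures$db <- generate_references(sim_config(seed = 424242L))
  }
  .fixtures$db
}

# Exhaustive-enumeration log-likelihood: sums over every assignment of
# states to internal nodes, per site, per Gamma category.
enum_loglik <- function(tree, aln, model) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  internal <- sort(unique(tr$edge[, 1]))
  q <- gtr_rate_matrix(model)
  rates <- discrete_gamma_rates(model$alpha, model$k)
  seqs <- lapply(unclass(aln)[tr$tip.label], function(s) strsplit(toupper(s), "")[[1]])
  ns <- length(seqs[[1]])
  code <- function(ch) match(ch, c("A", "C", "G", "T"))  # NA = missing
  P <- lapply(rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(e)
      as.matrix(Matrix::expm(q * tr$edge.length[e] * r))))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (s in seq_len(ns)) {
    site_l <- 0
    for (kk in seq_along(rates)) {
      lsum <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[internal] <- grid[g, ]
        pr <- unname(model$freqs[st[root]])
        ok <- TRUE
        for (e in seq_len(nrow(tr$edge))) {
          p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
          if (ch <= ntip) {
            tipst <- code(seqs[[ch]][s])
            if (is.na(tipst)) next  # missing data: sums to 1 over states
            pr <- pr * P[[kk]][[e]][st[p], tipst]
          } else {
            pr <- pr * P[[kk]][[e]][st[p], st[ch]]
          }
          if (pr == 0) { ok <- FALSE; break }
        }
        if (ok) lsum <- lsum + pr
      }
      site_l <- site_l + lsum / length(rates)
    }
    total <- total + log(site_l)
  }
  total
}

# Quadratic-space Gotoh local alignment (match/mismatch, affine gaps with
# cost open + L * ext). Returns the best local score.
gotoh_local_score <- function(a, b, match = 2, mismatch = -3,
                              open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (a[i - 1] == b[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Clopper-Pearson interval by direct beta-quantile inversion of the
# binomial CDF.
cp_interval_oracle <- function(x, n, conf = 0.95) {
  al <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(al, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - al, x + 1, n - x)
  c(lo, hi)
}

# Two-sided Fisher exact p by full hypergeometric enumeration of 2x2
# tables with the observed margins.
fisher_p_oracle <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  kk <- max(0, k - n2):min(n1, k)
  probs <- dhyper(kk, n1, n2, k)
  obs <- dhyper(x1, n1, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force bipartition sets via ape::prop.part (independent of the
# package's own bipartition code).
support_oracle <- function(best, boots) {
  pp_keys <- function(tree) {
    tr <- ape::unroot(tree)
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    anchor <- sort(labs)[1]
    keys <- vapply(pp, function(idx) {
      side <- labs[idx]
      if (!(anchor %in% side)) side <- setdiff(labs, side)
      paste(sort(side), collapse = "|")
    }, character(1))
    sizes <- vapply(pp, length, integer(1))
    keys[sizes > 1 & sizes < length(labs) - 1]
  }
  bk <- pp_keys(best)
  counts <- setNames(numeric(length(bk)), bk)
  for (bt in boots) {
    hit <- bk %in% pp_keys(bt)
    counts[hit] <- counts[hit] + 1
  }
  100 * counts / length(boots)
}

random_gtr <- function(seed, alpha = NULL, k = 4L) {
  set.seed(seed)
  f <- runif(4, 0.1, 1); f <- f / sum(f)
  r <- runif(6, 0.3, 3)
  if (is.null(alpha)) alpha <- runif(1, 0.2, 2)
  gtr_model(freqs = f, rates = r, alpha = alpha, k = k)
}

random_case <- function(seed, max_tips = 5, max_sites = 30, k = 2L) {
  set.seed(seed)
  ntip <- sample(3:max_tips, 1)
  tr <- ape::rtree(ntip)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.6)
  m <- random_gtr(seed + 1, k = k)
  ns <- sample(5:max_sites, 1)
  aln <- simulate_alignment(tr, m, ns, seed = seed + 2)
  list(tree = tr, model = m, aln = aln)
}
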