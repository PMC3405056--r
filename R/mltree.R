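# ML tree search (NNI hill climbing from multiple starts) and bootstrap
# bipartition support.

# Canonical keys for the non-trivial bipartitions of an unrooted tree.
# Each internal edge splits the tips in two; the key is the sorted tip set
# on the side containing the lexicographically smallest tip label, so keys
# are invariant to rooting and tip order.
tree_bipartitions <- function(tree) {
  tr <- ape::unroot(tree)
  tr <- stats::reorder(tr, "postorder")
  ntip <- length(tr$tip.label)
  all_tips <- sort(tr$tip.label)
  anchor <- all_tips[1]
  # accumulate tip sets below each node
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  nodes <- integer(0)
  root <- tr$edge[nrow(tr$edge), 1]
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (!(anchor %in% side)) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Bootstrap bipartition support
#'
#' Filters a best tree through a swarm of bootstrap trees: the support of an
#' internal node is the percentage of bootstrap trees whose bipartition set
#' contains that node's tip bipartition. Values are invariant to tip order
#' and rooting of either tree set.
#'
#' @param best_tree `ape::phylo`, the tree whose nodes are annotated.
#' @param bootstrap_trees list (or `multiPhylo`) of trees on the same tips.
#' @return data.frame with columns `node` (internal node id in `best_tree`'s
#'   postorder/unrooted numbering), `bipartition` (canonical tip-set key) and
#'   `support` (percent in \[0, 100\]).
#' @export
bootstrap_support <- function(best_tree, bootstrap_trees) {
  tipset <- sort(best_tree$tip.label)
  bp <- tree_bipartitions(best_tree)
  counts <- setNames(numeric(nrow(bp)), bp$key)
  for (bt in bootstrap_trees) {
    if (!setequal(bt$tip.label, tipset))
      stop("bootstrap tree tip set does not match the best tree")
    bkeys <- tree_bipartitions(bt)$key
    hit <- bp$key %in% bkeys
    counts[hit] <- counts[hit] + 1
  }
  n <- length(bootstrap_trees)
  data.frame(node = bp$node, bipartition = bp$key,
             support = if (n > 0) 100 * counts / n else rep(NA_real_, nrow(bp)),
             stringsAsFactors = FALSE)
}

# Distance-based starting tree (neighbor joining on JC-corrected distances).
nj_start_tree <- function(aln) {
  mat <- do.call(rbind, strsplit(toupper(unclass(aln)), ""))
  rownames(mat) <- names(aln)
  dna <- ape::as.DNAbin(mat)
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 0.1) * 2
  d[d <= 0] <- 1e-6
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  tr
}

#' Maximum-likelihood tree search
#'
#' Hill-climbing search under GTR+Gamma: each restart begins from either a
#' neighbor-joining tree (restart 1) or a stepwise-addition maximum
#' parsimony tree with a random addition order, then repeatedly evaluates
#' all nearest-neighbor-interchange rearrangements with branch-length
#' re-optimization and accepts the best improvement. The best tree across
#' restarts is returned; bootstrap support can be attached by resampling
#' alignment columns and repeating a single-start search per replicate.
#'
#' @param aln a [dna_alignment()] of at least 3 sequences.
#' @param model a [gtr_model()]. Base frequencies are typically empirical
#'   (see [empirical_frequencies()]).
#' @param n_starts number of independent restarts (default 10).
#' @param n_bootstrap number of bootstrap pseudoreplicates (default 0).
#' @param seed integer seed controlling addition orders and resampling.
#' @param tol log-likelihood convergence tolerance for the NNI climb.
#' @return list with `tree` (branch lengths optimized), `loglik`,
#'   `restart_logliks`, and `support` (data.frame from
#'   [bootstrap_support()], or NULL when `n_bootstrap = 0`).
#' @export
build_ml_tree <- function(aln, model, n_starts = 10, n_bootstrap = 0,
                          seed = 1L, tol = 1e-4) {
  if (length(aln) < 3) stop("need at least 3 sequences")
  climb <- function(a, start) {
    cur <- optimize_branch_lengths(start, a, model, max_passes = 4)
    cur_ll <- attr(cur, "loglik")
    if (length(a) > 3) {
      repeat {
        # nni wants cladewise edge ordering (traversal code returns
        # postorder) and sometimes drops tip labels; restore them by index
        # (rearrangements keep tip numbering)
        src <- ape::read.tree(text = ape::write.tree(cur))
        nbs <- phangorn::nni(src)
        improved <- FALSE
        for (nb in nbs) {
          if (is.null(nb$tip.label)) nb$tip.label <- src$tip.label
          nb$edge.length <- rep(0.05, nrow(nb$edge))
          cand <- optimize_branch_lengths(nb, a, model, max_passes = 3)
          if (attr(cand, "loglik") > cur_ll + tol) {
            cur <- cand
            cur_ll <- attr(cand, "loglik")
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    cur
  }
  search <- function(a, nst, sd) {
    starts <- list(nj_start_tree(a))
    if (nst > 1) {
      mat <- do.call(rbind, strsplit(toupper(unclass(a)), ""))
      rownames(mat) <- names(a)
      pd <- phangorn::phyDat(mat, type = "DNA")
      for (i in seq_len(nst - 1)) {
        set.seed(derive_seed(sd, i))
        st <- phangorn::random.addition(pd)
        st <- ape::unroot(st)
        st$edge.length <- rep(0.05, nrow(st$edge))
        starts[[i + 1]] <- st
      }
    }
    fits <- lapply(starts, function(s) climb(a, s))
    lls <- vapply(fits, attr, numeric(1), "loglik")
    list(tree = fits[[which.max(lls)]], logliks = lls)
  }
  main <- search(aln, n_starts, seed)
  support <- NULL
  boots <- NULL
  if (n_bootstrap > 0) {
    ns <- n_sites(aln)
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      set.seed(derive_seed(seed, 1000L, b))
      cols <- sample.int(ns, ns, replace = TRUE)
      mat <- do.call(rbind, strsplit(toupper(unclass(aln)), ""))
      res <- dna_alignment(setNames(
        apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""),
        names(aln)))
      boots[[b]] <- search(res, 1, derive_seed(seed, 2000L, b))$tree
    }
    support <- bootstrap_support(main$tree, boots)
  }
  list(tree = main$tree, loglik = max(main$logliks),
       restart_logliks = main$logliks, support = support,
       bootstrap_trees = boots)
}

#' Empirical base frequencies of an alignment
#'
#' Counts A/C/G/T over all sequences (ambiguity codes and gaps ignored),
#' the usual plug-in estimate of the GTR stationary frequencies.
#'
#' @param aln a [dna_alignment()].
#' @return numeric vector of 4 frequencies summing to 1.
#' @export
empirical_frequencies <- function(aln) {
  chars <- unlist(strsplit(toupper(unclass(aln)), ""))
  counts <- table(factor(chars, levels = .dna_letters))
  f <- as.numeric(counts)
  if (sum(f) == 0) stop("alignment contains no unambiguous bases")
  f <- f / sum(f)
  f[f <= 0] <- 1e-6
  setNames(f / sum(f), .dna_letters)
}
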