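# Felsenstein pruning log-likelihood for GTR+Gamma on an ape "phylo" tree.
#
# Partial likelihoods are scaled per internal node (column maxima) to avoid
# underflow; the Gamma mixture is combined per site on the log scale.

# Precompute the per-tree traversal structure once.
tree_traversal <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  list(tree = tr, ntip = ntip, root = root,
       nnode = ntip + tr$Nnode)
}

# Core pruning over compressed site patterns for one set of category rates.
# conds: list keyed by tip label of 4 x P conditional matrices.
# Returns per-category list of (log site likelihood vector over patterns).
prune_loglik_patterns <- function(trav, conds, model, eig = NULL,
                                  edge_lengths = NULL) {
  tr <- trav$tree
  if (is.null(eig)) eig <- gtr_eigen(model)
  if (is.null(edge_lengths)) edge_lengths <- tr$edge.length
  rates <- discrete_gamma_rates(model$alpha, model$k)
  np <- ncol(conds[[1]])
  ntip <- trav$ntip
  ll_cat <- vector("list", model$k)
  tipidx <- match(tr$tip.label, names(conds))
  if (anyNA(tipidx))
    stop("missing tip sequence: ",
         paste(tr$tip.label[is.na(tipidx)], collapse = ", "))
  for (kk in seq_len(model$k)) {
    L <- vector("list", trav$nnode)
    for (i in seq_len(ntip)) L[[i]] <- conds[[tipidx[i]]]
    logsc <- numeric(np)
    parents <- tr$edge[, 1]
    children <- tr$edge[, 2]
    for (e in seq_along(parents)) {
      p <- parents[e]; ch <- children[e]
      pm <- transition_prob(eig, edge_lengths[e] * rates[kk])
      contrib <- pm %*% L[[ch]]
      if (is.null(L[[p]])) L[[p]] <- contrib else L[[p]] <- L[[p]] * contrib
      # scale when the parent is complete (last incoming edge in postorder)
      if (e == length(parents) || parents[e + 1] != p) {
        mx <- pmax(L[[p]][1, ], L[[p]][2, ], L[[p]][3, ], L[[p]][4, ])
        mx[mx <= 0] <- 1
        L[[p]] <- L[[p]] / rep(mx, each = 4)
        logsc <- logsc + log(mx)
      }
    }
    ll_cat[[kk]] <- log(colSums(model$freqs * L[[trav$root]])) + logsc
  }
  ll_cat
}

#' Tree log-likelihood under GTR+Gamma
#'
#' Computes the log-likelihood of an alignment on a phylogeny by Felsenstein
#' pruning, with among-site rate heterogeneity handled as an equal-weight
#' discrete-Gamma mixture. Gaps and IUPAC ambiguity codes are treated as
#' missing data. By time reversibility the value does not depend on root
#' placement.
#'
#' @param tree an `ape::phylo` with branch lengths in expected
#'   substitutions/site; tip labels must name sequences in `aln`.
#' @param aln a [dna_alignment()] containing every tip label.
#' @param model a [gtr_model()].
#' @return the log-likelihood (scalar).
#' @export
tree_loglik <- function(tree, aln, model) {
  trav <- tree_traversal(tree)
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing) > 0)
    stop("missing tip sequence: ", paste(missing, collapse = ", "))
  pat <- site_patterns(aln, trav$tree$tip.label)
  ll_cat <- prune_loglik_patterns(trav, pat$conds, model)
  site_ll <- site_mixture_loglik(ll_cat)
  sum(pat$weights * site_ll)
}

# Combine per-category pattern log-likelihood vectors into the equal-weight
# mixture log-likelihood per pattern.
site_mixture_loglik <- function(ll_cat) {
  k <- length(ll_cat)
  if (k == 1) return(ll_cat[[1]])
  m <- do.call(pmax, ll_cat)
  acc <- 0
  for (kk in seq_len(k)) acc <- acc + exp(ll_cat[[kk]] - m)
  m + log(acc / k)
}
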