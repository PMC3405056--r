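#' Simulate an alignment along a tree
#'
#' Evolves `n_sites` independent sites from the stationary distribution at
#' the root down every branch under GTR+Gamma: each site draws one Gamma
#' rate category, then states mutate along each edge with transition
#' probabilities `expm(Q * t * rate)`. Deterministic given `seed`.
#'
#' @param tree `ape::phylo` with branch lengths in substitutions/site.
#' @param model a [gtr_model()].
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed for the site/category/state draws.
#' @return a [dna_alignment()] with one sequence per tip.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  trav <- tree_traversal(tree)
  tr <- trav$tree
  eig <- gtr_eigen(model)
  rates <- discrete_gamma_rates(model$alpha, model$k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cat_of_site <- sample.int(model$k, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, trav$nnode, n_sites)
  states[trav$root, ] <- sample.int(4, n_sites, replace = TRUE,
                                    prob = model$freqs)
  # preorder: reverse postorder edge order guarantees parents precede children
  for (e in rev(seq_len(nrow(tr$edge)))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    child <- integer(n_sites)
    for (kk in seq_len(model$k)) {
      pm <- transition_prob(eig, len * rates[kk])
      pm <- pm / rowSums(pm)
      for (s in 1:4) {
        idx <- which(cat_of_site == kk & states[p, ] == s)
        if (length(idx) > 0)
          child[idx] <- sample.int(4, length(idx), replace = TRUE,
                                   prob = pm[s, ])
      }
    }
    states[ch, ] <- child
  }
  seqs <- vapply(seq_len(trav$ntip), function(i) {
    paste(.dna_letters[states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- tr$tip.label
  dna_alignment(seqs)
}
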