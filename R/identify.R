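# Query identification: best-hit identity screen, ML placement on the
# reference tree, and group-aware species calling.

#' Default identification thresholds
#'
#' `identity`: minimum percent identity of the top hit for any species-level
#' or group-level call (default 98, the lower end of the identity range that
#' supports confident barcode matches). `tie_margin`: hits within this many
#' percentage points of the top hit are treated as statistically tied and
#' contribute candidate species (default 0.5). `support`: bootstrap
#' percentage above which a node is reported as well-supported (default 90).
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(identity = 98, tie_margin = 0.5, support = 90)
}

default_alignment_scores <- function() {
  list(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Percent identity of the best local alignment
#'
#' Smith-Waterman local alignment under match/mismatch/affine-gap scores
#' (defaults +2/-3, gap open 5, extend 2), reporting percent identity over
#' the aligned region. Symmetric in its arguments.
#'
#' @param query,reference DNA sequence strings (gaps are stripped).
#' @param scores list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @return list with `identity` (percent), `aligned_length`, `score`.
#' @export
percent_identity <- function(query, reference,
                             scores = default_alignment_scores()) {
  if (nchar(degap(query)) == 0 || nchar(degap(reference)) == 0)
    stop("sequences must be non-empty")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = scores$match,
                                                 mismatch = scores$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(degap(query)), Biostrings::DNAString(degap(reference)),
    type = "local", substitutionMatrix = sm,
    gapOpening = scores$gap_open, gapExtension = scores$gap_ext)
  al <- Biostrings::nchar(pa)
  list(identity = 100 * Biostrings::nmatch(pa) / al,
       aligned_length = al, score = Biostrings::score(pa))
}

#' Rank reference sequences by local-alignment score
#'
#' Scores the query against every reference sequence of one marker and
#' returns the ranked hit report (score descending, ties broken by
#' reference id for determinism).
#'
#' @param query DNA sequence string.
#' @param db a `reference_db`.
#' @param marker one of cytb / dloop / cox1.
#' @param scores alignment scores (see [percent_identity()]).
#' @return data.frame (`hit_report`) with columns `id`, `species`,
#'   `identity`, `aligned_length`, `score`, sorted best-first.
#' @export
best_hits <- function(query, db, marker, scores = default_alignment_scores()) {
  aln <- db$alignments[[marker]]
  if (is.null(aln) || length(aln) == 0) stop("empty reference library for ", marker)
  refs <- vapply(unclass(aln), degap, character(1))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = scores$match,
                                                 mismatch = scores$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(refs), Biostrings::DNAString(degap(query)),
    type = "local", substitutionMatrix = sm,
    gapOpening = scores$gap_open, gapExtension = scores$gap_ext)
  al <- Biostrings::nchar(pa)
  rep <- data.frame(id = names(aln),
                    species = species_of_ids(db, names(aln), marker),
                    identity = 100 * Biostrings::nmatch(pa) / al,
                    aligned_length = al,
                    score = Biostrings::score(pa),
                    stringsAsFactors = FALSE)
  rep <- rep[order(-rep$score, rep$id), ]
  rownames(rep) <- NULL
  class(rep) <- c("hit_report", "data.frame")
  rep
}

#' Map a query into reference alignment coordinates
#'
#' Globally aligns the query to one (ungapped) reference sequence, then
#' threads the query characters through that reference's alignment columns.
#' Columns inserted by the query are discarded; reference columns the query
#' does not cover become gaps.
#'
#' @param query DNA sequence string.
#' @param db a `reference_db`.
#' @param marker marker name.
#' @param ref_id reference id to align against (typically the best hit).
#' @param scores alignment scores.
#' @return query string of the reference alignment's length.
#' @export
align_query_to_profile <- function(query, db, marker, ref_id,
                                   scores = default_alignment_scores()) {
  aln <- db$alignments[[marker]]
  ref_aln <- unclass(aln)[[ref_id]]
  if (is.null(ref_aln)) stop("unknown reference id ", ref_id)
  ref <- degap(ref_aln)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = scores$match,
                                                 mismatch = scores$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(degap(query)), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = sm,
    gapOpening = scores$gap_open, gapExtension = scores$gap_ext)
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  by_ref_pos <- rep("-", nchar(ref))
  pos <- 0
  for (i in seq_along(sa)) {
    if (sa[i] != "-") {
      pos <- pos + 1
      by_ref_pos[pos] <- qa[i]
    }
  }
  # thread through the reference's alignment columns
  out <- rep("-", nchar(ref_aln))
  ref_chars <- strsplit(ref_aln, "")[[1]]
  out[ref_chars != "-"] <- by_ref_pos
  paste(out, collapse = "")
}

# Per-(db, marker, model) placement workspace: for every reference-tree edge
# and Gamma category, the elementwise product of the rootward and tipward
# conditional likelihoods at the edge midpoint, plus log scalers. These are
# query-independent, so placement of each query only costs one 4x4 matrix
# product per pendant-length evaluation.
placement_workspace <- function(db, marker, model = NULL) {
  key <- paste0("ws_", marker)
  if (!is.null(db$cache[[key]])) return(db$cache[[key]])
  model <- model %||% db$models[[marker]]
  tree <- db$trees[[marker]]
  aln <- db$alignments[[marker]]
  trav <- tree_traversal(tree)
  tr <- trav$tree
  eig <- gtr_eigen(model)
  rates <- discrete_gamma_rates(model$alpha, model$k)
  ns <- n_sites(aln)
  conds <- lapply(unclass(aln)[tr$tip.label], seq_conditionals)
  nnode <- trav$nnode
  ntip <- trav$ntip
  parents <- tr$edge[, 1]; children <- tr$edge[, 2]
  nedge <- nrow(tr$edge)
  H <- vector("list", model$k)
  SC <- vector("list", model$k)
  ll_ref_cat <- vector("list", model$k)
  for (kk in seq_len(model$k)) {
    P <- lapply(seq_len(nedge), function(e)
      transition_prob(eig, tr$edge.length[e] * rates[kk]))
    Ph <- lapply(seq_len(nedge), function(e)
      transition_prob(eig, tr$edge.length[e] / 2 * rates[kk]))
    # tipward (down) pass
    D <- vector("list", nnode)
    Dsc <- vector("list", nnode)
    for (i in seq_len(ntip)) { D[[i]] <- conds[[i]]; Dsc[[i]] <- numeric(ns) }
    for (e in seq_len(nedge)) {
      p <- parents[e]; ch <- children[e]
      contrib <- P[[e]] %*% D[[ch]]
      if (is.null(D[[p]])) { D[[p]] <- contrib; Dsc[[p]] <- Dsc[[ch]] }
      else { D[[p]] <- D[[p]] * contrib; Dsc[[p]] <- Dsc[[p]] + Dsc[[ch]] }
      if (e == nedge || parents[e + 1] != p) {
        mx <- pmax(D[[p]][1, ], D[[p]][2, ], D[[p]][3, ], D[[p]][4, ])
        mx[mx <= 0] <- 1
        D[[p]] <- D[[p]] / rep(mx, each = 4)
        Dsc[[p]] <- Dsc[[p]] + log(mx)
      }
    }
    # rootward (up) pass, preorder: O[[v]] = likelihood of all data outside
    # subtree(v), as a function of the state at v's parent; includes pi.
    O <- vector("list", nnode)
    Osc <- vector("list", nnode)
    kids <- split(seq_len(nedge), parents)
    for (e in rev(seq_len(nedge))) {
      p <- parents[e]; v <- children[e]
      sibs <- setdiff(kids[[as.character(p)]], e)
      if (p == trav$root) { acc <- matrix(model$freqs, 4, ns); accsc <- numeric(ns) }
      else {
        acc <- crossprod(P[[match(p, children)]], O[[p]])
        accsc <- Osc[[p]]
      }
      for (se in sibs) {
        acc <- acc * (P[[se]] %*% D[[children[se]]])
        accsc <- accsc + Dsc[[children[se]]]
      }
      mx <- pmax(acc[1, ], acc[2, ], acc[3, ], acc[4, ])
      mx[mx <= 0] <- 1
      O[[v]] <- acc / rep(mx, each = 4)
      Osc[[v]] <- accsc + log(mx)
    }
    # per-edge midpoint products
    Hk <- vector("list", nedge)
    SCk <- vector("list", nedge)
    for (e in seq_len(nedge)) {
      v <- children[e]
      top <- crossprod(Ph[[e]], O[[v]])
      bot <- Ph[[e]] %*% D[[v]]
      Hk[[e]] <- top * bot
      SCk[[e]] <- Osc[[v]] + Dsc[[v]]
    }
    H[[kk]] <- Hk
    SC[[kk]] <- SCk
    ll_ref_cat[[kk]] <- log(colSums(model$freqs * D[[trav$root]])) + Dsc[[trav$root]]
  }
  # human-readable edge descriptions: tip set below each edge
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nedge)) below[[parents[e]]] <-
    c(below[[parents[e]]], below[[children[e]]])
  ws <- list(tree = tr, model = model, eig = eig, rates = rates,
             H = H, SC = SC, nedge = nedge,
             clade_tips = lapply(seq_len(nedge), function(e) below[[children[e]]]),
             ref_loglik = sum(site_mixture_loglik(ll_ref_cat)))
  db$cache[[key]] <- ws
  ws
}

#' Place a query sequence on the reference tree
#'
#' Evaluates attachment of the query at the midpoint of every reference-tree
#' edge under the marker's GTR+Gamma model, optimizing the pendant branch
#' length (internal branch lengths stay fixed). Returns the best edge and
#' likelihood-weight ratios across all edges.
#'
#' @param query DNA sequence string (unaligned).
#' @param db a `reference_db`.
#' @param marker marker name.
#' @param model optional [gtr_model()] override.
#' @param aligned optional pre-aligned query (reference alignment length);
#'   when NULL the query is aligned to its best hit via
#'   [align_query_to_profile()].
#' @param hits optional precomputed [best_hits()] report.
#' @return a `placement`: list with `edge` (index), `clade_tips` (tips on
#'   the tipward side of the best edge), `loglik`, `pendant`, and
#'   `weights` (likelihood-weight ratio per edge, summing to 1).
#' @export
place_query <- function(query, db, marker, model = NULL, aligned = NULL,
                        hits = NULL) {
  ws <- placement_workspace(db, marker, model)
  if (is.null(aligned)) {
    if (is.null(hits)) hits <- best_hits(query, db, marker)
    aligned <- align_query_to_profile(query, db, marker, hits$id[1])
  }
  if (nchar(degap(aligned)) == 0)
    return(structure(list(edge = NA_integer_, clade_tips = character(0),
                          loglik = NA_real_, pendant = NA_real_,
                          weights = NULL, failed = TRUE,
                          reason = "profile_alignment_failed"),
                     class = "placement"))
  qcond <- seq_conditionals(aligned)
  k <- ws$model$k
  edge_ll <- function(e, t) {
    lv <- vector("list", k)
    for (kk in seq_len(k)) {
      pq <- transition_prob(ws$eig, t * ws$rates[kk]) %*% qcond
      v <- colSums(ws$H[[kk]][[e]] * pq)
      v[v <= 0] <- .Machine$double.xmin
      lv[[kk]] <- log(v) + ws$SC[[kk]][[e]]
    }
    sum(site_mixture_loglik(lv))
  }
  # coarse scan, then refine the most promising edges
  grid <- c(1e-4, 0.005, 0.03)
  scan <- matrix(NA_real_, ws$nedge, length(grid))
  for (e in seq_len(ws$nedge))
    for (j in seq_along(grid)) scan[e, j] <- edge_ll(e, grid[j])
  best_per_edge <- apply(scan, 1, max)
  pend_per_edge <- grid[apply(scan, 1, which.max)]
  top <- order(-best_per_edge)[seq_len(min(5, ws$nedge))]
  for (e in top) {
    opt <- optimize(function(t) edge_ll(e, t), interval = c(1e-9, 1),
                    maximum = TRUE, tol = 1e-5)
    if (opt$objective > best_per_edge[e]) {
      best_per_edge[e] <- opt$objective
      pend_per_edge[e] <- opt$maximum
    }
  }
  w <- exp(best_per_edge - max(best_per_edge))
  w <- w / sum(w)
  be <- which.max(best_per_edge)
  structure(list(edge = be, clade_tips = ws$clade_tips[[be]],
                 loglik = best_per_edge[be], pendant = pend_per_edge[be],
                 weights = w, failed = FALSE, reason = NA_character_),
            class = "placement")
}

#' Call a species from hits and placement
#'
#' The call is species-level when the evidence points at a single species:
#' candidate species are those on the tipward side of the placement edge
#' plus any hit within `tie_margin` percentage points of the top identity.
#' If all candidates belong to one species group that is unresolvable at
#' this marker, the group is called (members of such groups are never
#' called at species level). Mixed candidates spanning no single group, or
#' a top identity below the `identity` threshold, yield `unresolved` with a
#' reason code.
#'
#' @param hits a [best_hits()] report.
#' @param placement a [place_query()] result.
#' @param db a `reference_db`.
#' @param marker marker name.
#' @param thresholds see [default_thresholds()].
#' @return a `species_call`: list with `marker`, `type`
#'   (species / group / unresolved), `species`, `group`, `display`,
#'   `top_identity`, `best_ref`, `reason`.
#' @export
call_species <- function(hits, placement, db, marker,
                         thresholds = default_thresholds()) {
  mk_call <- function(type, species = NA_character_, group = NA_character_,
                      display = NA_character_, reason = NA_character_) {
    structure(list(marker = marker, type = type, species = species,
                   group = group, display = display,
                   top_identity = if (nrow(hits) > 0) hits$identity[1] else NA_real_,
                   best_ref = if (nrow(hits) > 0) hits$id[1] else NA_character_,
                   reason = reason),
              class = "species_call")
  }
  if (is.null(placement) || isTRUE(placement$failed))
    return(mk_call("unresolved", reason = placement$reason %||% "no_placement"))
  if (hits$identity[1] < thresholds$identity)
    return(mk_call("unresolved", reason = "low_identity"))
  cand <- unique(species_of_ids(db, placement$clade_tips, marker))
  near <- hits$species[hits$identity >= hits$identity[1] - thresholds$tie_margin]
  cand <- unique(c(cand, near))
  if (length(cand) == 1) {
    g <- group_at_marker(db$groups, cand, marker)
    if (is.null(g)) return(mk_call("species", species = cand, display = cand))
    return(mk_call("group", group = g$id, display = g$display))
  }
  for (g in db$groups) {
    if (all(cand %in% g$members) && marker %in% g$unresolvable_markers)
      return(mk_call("group", group = g$id, display = g$display))
  }
  mk_call("unresolved", reason = "ambiguous")
}

#' @export
print.species_call <- function(x, ...) {
  cat("<species_call>", x$marker, ":",
      switch(x$type, species = x$species, group = x$display,
             unresolved = paste0("unresolved (", x$reason, ")")), "\n")
  invisible(x)
}

#' Identify one sequence at one marker
#'
#' Convenience wrapper: best-hit screen, placement, and species call.
#' Results are memoised per (marker, sequence) on the database object, so
#' re-identifying an identical haplotype is free.
#'
#' @inheritParams best_hits
#' @param thresholds see [default_thresholds()].
#' @return a `species_call` with the `hit_report` and `placement` attached
#'   as attributes `hits` and `placement`.
#' @export
identify_sequence <- function(query, db, marker,
                              thresholds = default_thresholds()) {
  key <- paste0("id_", marker, "_", query)
  hit <- db$cache[[key]]
  if (!is.null(hit)) return(hit)
  hits <- best_hits(query, db, marker)
  pl <- place_query(query, db, marker, hits = hits)
  call <- call_species(hits, pl, db, marker, thresholds)
  attr(call, "hits") <- hits
  attr(call, "placement") <- pl
  db$cache[[key]] <- call
  call
}
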