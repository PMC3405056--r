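# Synthetic caviar-market surveys with known ground truth: a simulated
# reference panel (sequences evolved along a sturgeon phylogeny under
# GTR+Gamma), market lots with label-dependent substitution, haplotype
# pooling and per-marker amplification dropout, plus the encoded 2006-2008
# New York City survey.

#' Default species phylogeny for simulation
#'
#' A 12-taxon acipenseriform tree (plus pike as a far outgroup / substitute
#' roe source) with branch lengths in substitutions/site. Members of the
#' gueldenstaedtii complex and of Scaphirhynchus sit on near-zero branches,
#' which is what makes those groups unresolvable from simulated mtDNA.
#'
#' @return an `ape::phylo`.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(((((((Acipenser_gueldenstaedtii:0.0008,Acipenser_naccarii:0.0008):0.0006,",
    "Acipenser_persicus:0.0012):0.006,Acipenser_baerii:0.009):0.02,",
    "(Acipenser_stellatus:0.035,Acipenser_ruthenus:0.032):0.012):0.018,",
    "Huso_huso:0.045):0.025,(Acipenser_transmontanus:0.04,",
    "(Scaphirhynchus_platorynchus:0.0009,Scaphirhynchus_albus:0.0009):0.03):0.02):0.06,",
    "Polyodon_spathula:0.09,Esox_lucius:0.35);")
  ape::read.tree(text = txt)
}

#' Default market-label templates
#'
#' Label text, true-species distribution and draw weight for each product
#' type sold on the market; weights mirror the label composition of the
#' New York City survey.
#'
#' @return list of templates.
#' @export
default_label_templates <- function() {
  tpl <- function(name, raw, species, weight)
    list(name = name, raw = raw, species = species, weight = weight)
  list(
    tpl("beluga", "Beluga (Huso huso)", c("Huso huso" = 1), 7),
    tpl("sevruga", "Sevruga (Acipenser stellatus)", c("Acipenser stellatus" = 1), 21),
    tpl("osetra_baerii", "Osetra (Acipenser baerii), farmed",
        c("Acipenser baerii" = 1), 8),
    tpl("osetra_gueldenstaedtii", "Osetra (Acipenser gueldenstaedtii)",
        c("Acipenser gueldenstaedtii" = 1), 7),
    tpl("osetra_persicus", "Osetra (Acipenser persicus)",
        c("Acipenser persicus" = 1), 4),
    tpl("osetra_unspecified", "Osetra (unspecified)",
        c("Acipenser gueldenstaedtii" = 0.5, "Acipenser baerii" = 0.5), 13),
    tpl("white", "White (Acipenser transmontanus)",
        c("Acipenser transmontanus" = 1), 6),
    tpl("paddlefish", "Paddlefish (Polyodon spathula)",
        c("Polyodon spathula" = 1), 12),
    tpl("hackleback", "Hackleback (Scaphirhynchus platorynchus)",
        c("Scaphirhynchus platorynchus" = 1), 8),
    tpl("american", "American (unspecified)",
        c("Acipenser transmontanus" = 0.4, "Polyodon spathula" = 0.3,
          "Scaphirhynchus platorynchus" = 0.3), 4)
  )
}

#' Default label -> substitute-species table
#'
#' What a mislabeled lot of each product type actually contains, mirroring
#' the substitutions observed on the market: paddlefish / sterlet / Russian
#' sturgeon sold as sevruga, the gueldenstaedtii complex or Siberian
#' sturgeon sold as beluga, A. baerii and A. gueldenstaedtii swapped under
#' osetra labels, and pike roe as a generic substitute.
#'
#' @return named list (by template name) of probability vectors over species.
#' @export
default_substitution_table <- function() {
  list(
    beluga = c("Acipenser gueldenstaedtii" = 0.5, "Acipenser baerii" = 0.5),
    sevruga = c("Polyodon spathula" = 0.4, "Acipenser ruthenus" = 0.3,
                "Acipenser gueldenstaedtii" = 0.3),
    osetra_baerii = c("Acipenser gueldenstaedtii" = 1),
    osetra_gueldenstaedtii = c("Acipenser baerii" = 1),
    osetra_persicus = c("Acipenser baerii" = 1),
    osetra_unspecified = c("Esox lucius" = 0.5, "Polyodon spathula" = 0.5),
    white = c("Polyodon spathula" = 1),
    paddlefish = c("Esox lucius" = 1),
    hackleback = c("Esox lucius" = 1),
    american = c("Esox lucius" = 1)
  )
}

#' Simulation configuration
#'
#' Study conditions for the synthetic market: survey size and true
#' mislabeling rate match the 90-lot / 10% setting; eggs per lot span
#' 10-14; pooling of eggs from several females is occasional (two, rarely
#' three, haplotypes); amplification dropout is a few percent per marker
#' (the D-loop primers fail a little more often than cytb); marker lengths
#' approximate the sequenced fragments; Gamma shapes use the fitted
#' mitochondrial values (cytb 0.224, D-loop 0.345) and the D-loop evolves
#' about twice as fast as cytb.
#'
#' @param seed master seed; all lot/egg/site streams derive from it.
#' @param n_lots lots per survey.
#' @param rate true mislabeling probability per lot.
#' @param labels label templates ([default_label_templates()]).
#' @param substitutions substitution table ([default_substitution_table()]).
#' @param eggs_per_lot integer vector to draw the per-lot egg count from.
#' @param pooling_prob probability a lot pools several females' eggs.
#' @param pooling_haps named probability vector over pooled haplotype counts.
#' @param dropout named per-marker amplification-failure probability.
#' @param marker_length named per-marker sequence length (>= 100).
#' @param marker_scale named per-marker branch-length multiplier.
#' @param marker_alpha named per-marker Gamma shape.
#' @param base_freqs,gtr_rates GTR stationary frequencies / exchangeabilities.
#' @param n_refs_per_species reference sequences simulated per species.
#' @param n_pool_haplotypes market haplotypes simulated per species.
#' @param ref_pendant,pool_pendant pendant branch lengths (subs/site) for
#'   reference and market-haplotype tips.
#' @param species_tree base phylogeny ([default_species_tree()]).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_lots = 90L, rate = 0.10,
                       labels = default_label_templates(),
                       substitutions = default_substitution_table(),
                       eggs_per_lot = 10:14,
                       pooling_prob = 0.15,
                       pooling_haps = c("2" = 0.8, "3" = 0.2),
                       dropout = c(cytb = 0.03, dloop = 0.05, cox1 = 0.03),
                       marker_length = c(cytb = 620, dloop = 500, cox1 = 650),
                       marker_scale = c(cytb = 1, dloop = 2, cox1 = 0.8),
                       marker_alpha = c(cytb = 0.224, dloop = 0.345, cox1 = 0.25),
                       base_freqs = c(0.28, 0.27, 0.16, 0.29),
                       gtr_rates = c(1, 5, 1, 1, 5, 1),
                       n_refs_per_species = 2L,
                       n_pool_haplotypes = 6L,
                       ref_pendant = 5e-4, pool_pendant = 0.004,
                       species_tree = default_species_tree()) {
  stopifnot(rate >= 0, rate <= 1, all(dropout >= 0 & dropout <= 1),
            pooling_prob >= 0, pooling_prob <= 1,
            all(marker_length >= 100), n_lots >= 1)
  pooling_haps <- pooling_haps / sum(pooling_haps)
  structure(list(seed = as.integer(seed), n_lots = as.integer(n_lots),
                 rate = rate, labels = labels, substitutions = substitutions,
                 eggs_per_lot = eggs_per_lot, pooling_prob = pooling_prob,
                 pooling_haps = pooling_haps, dropout = dropout,
                 marker_length = marker_length, marker_scale = marker_scale,
                 marker_alpha = marker_alpha, base_freqs = base_freqs,
                 gtr_rates = gtr_rates,
                 n_refs_per_species = as.integer(n_refs_per_species),
                 n_pool_haplotypes = as.integer(n_pool_haplotypes),
                 ref_pendant = ref_pendant, pool_pendant = pool_pendant,
                 species_tree = species_tree),
            class = "sim_config")
}

#' Generate a synthetic reference database
#'
#' Simulates per-marker reference alignments and market-haplotype pools
#' along the species tree: each species tip is expanded into a clade of
#' `n_refs_per_species` reference tips plus `n_pool_haplotypes` market
#' haplotype tips on short pendant branches, the whole tree is scaled per
#' marker, and sequences are evolved under that marker's GTR+Gamma model.
#' Reference tips become the library and per-marker reference tree;
#' haplotype tips populate `db$haplotype_pool` for survey generation.
#' Unresolvable species groups arise from the near-zero branches separating
#' their members. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a validated `reference_db`.
#' @export
generate_references <- function(config = sim_config()) {
  base <- config$species_tree
  species <- gsub("_", " ", base$tip.label)
  if (length(species) < 2) stop("species tree must have >= 2 tips")
  out_aln <- list(); out_tree <- list(); meta <- list(); models <- list()
  pool <- list()
  for (mi in seq_along(MARKERS)) {
    mk <- MARKERS[mi]
    ref_ids <- list(); pool_ids <- list()
    txt <- ape::write.tree(base)
    for (si in seq_along(base$tip.label)) {
      rid <- sprintf("%s%03d%d", toupper(mk), si, seq_len(config$n_refs_per_species))
      hid <- sprintf("H%s%03dx%d", toupper(mk), si, seq_len(config$n_pool_haplotypes))
      ref_ids[[si]] <- rid; pool_ids[[si]] <- hid
      sub <- paste0("(", paste(c(
        paste0(rid, ":", config$ref_pendant),
        paste0(hid, ":", config$pool_pendant)), collapse = ","), ")")
      txt <- sub(paste0(base$tip.label[si], ":"), paste0(sub, ":"), txt, fixed = TRUE)
    }
    ext <- ape::read.tree(text = txt)
    ext$edge.length <- ext$edge.length * config$marker_scale[[mk]]
    model <- gtr_model(freqs = config$base_freqs, rates = config$gtr_rates,
                       alpha = config$marker_alpha[[mk]], k = 4L)
    sim <- simulate_alignment(ext, model, config$marker_length[[mk]],
                              seed = derive_seed(config$seed, 11L, mi))
    rids <- unlist(ref_ids)
    out_aln[[mk]] <- dna_alignment(unclass(sim)[rids])
    out_tree[[mk]] <- ape::drop.tip(ext, unlist(pool_ids))
    meta[[mk]] <- data.frame(
      id = rids,
      species = rep(species, each = config$n_refs_per_species),
      marker = mk, stringsAsFactors = FALSE)
    models[[mk]] <- model
    pool[[mk]] <- setNames(lapply(seq_along(species), function(si)
      as.character(unclass(sim)[pool_ids[[si]]])), species)
  }
  db <- reference_db(out_aln, do.call(rbind, meta), out_tree, models = models)
  db$haplotype_pool <- pool
  db
}

# Sample one name from a named probability vector.
draw_named <- function(probs) {
  if (length(probs) == 1) return(names(probs))
  sample(names(probs), 1, prob = probs)
}

#' Generate a synthetic market survey
#'
#' Draws `n_lots` lots: a label template by market weight, a mislabeling
#' Bernoulli(`rate`) event, the true species (from the template's species
#' distribution, or the substitution table when mislabeled), 1-3 pooled
#' haplotypes from the species' simulated pool, the per-lot egg count, and
#' independent per-egg per-marker amplification dropout. The ground-truth
#' mislabeling flag is recorded before any dropout, as "true species not in
#' the label's allowed set" (closed over indistinguishable groups at cytb).
#' Deterministic given `config$seed`; each lot consumes its own derived
#' random stream, so lots are independent of one another.
#'
#' @param config a [sim_config()].
#' @param db a `reference_db` from [generate_references()] (must carry a
#'   haplotype pool).
#' @return list with `lots` (list of [lot()]) and `truth` (data.frame:
#'   `lot_id`, `template`, `label`, `true_species`, `mislabeled`,
#'   `n_haplotypes`, `n_eggs`).
#' @export
generate_survey <- function(config, db) {
  if (length(db$haplotype_pool) == 0) stop("db has no haplotype pool")
  weights <- vapply(config$labels, `[[`, numeric(1), "weight")
  lots <- vector("list", config$n_lots)
  rows <- vector("list", config$n_lots)
  for (i in seq_len(config$n_lots)) {
    set.seed(derive_seed(config$seed, 101L, i))
    tpl <- config$labels[[sample(length(config$labels), 1, prob = weights)]]
    mislabel_event <- runif(1) < config$rate
    sp <- if (mislabel_event) {
      subs <- config$substitutions[[tpl$name]]
      if (is.null(subs)) stop("no substitution entry for label '", tpl$name, "'")
      draw_named(subs)
    } else draw_named(tpl$species)
    label <- parse_label(tpl$raw)
    truth_flag <- !(sp %in% allowed_species(label, db$policy, db$groups, "cytb"))
    n_eggs <- if (length(config$eggs_per_lot) == 1) config$eggs_per_lot
      else sample(config$eggs_per_lot, 1)
    n_hap <- if (runif(1) < config$pooling_prob)
      as.integer(draw_named(config$pooling_haps)) else 1L
    n_hap <- min(n_hap, config$n_pool_haplotypes)
    hap_idx <- sample(config$n_pool_haplotypes, n_hap)
    lot_id <- sprintf("L%04d", i)
    eggs <- lapply(seq_len(n_eggs), function(j) {
      hap <- hap_idx[(j - 1) %% n_hap + 1]
      seqs <- lapply(MARKERS, function(mk) {
        if (runif(1) < config$dropout[[mk]]) NA_character_
        else db$haplotype_pool[[mk]][[sp]][hap]
      })
      names(seqs) <- MARKERS
      egg_record(lot_id, j, cytb = seqs$cytb, dloop = seqs$dloop,
                 cox1 = seqs$cox1)
    })
    channel <- sample(c("in-store", "internet"), 1, prob = c(0.45, 0.55))
    year <- sample(c(2006L, 2008L), 1)
    lots[[i]] <- lot(lot_id, label, channel, year, eggs)
    rows[[i]] <- data.frame(lot_id = lot_id, template = tpl$name,
                            label = tpl$raw, true_species = sp,
                            mislabeled = truth_flag, n_haplotypes = n_hap,
                            n_eggs = n_eggs, stringsAsFactors = FALSE)
  }
  list(lots = lots, truth = do.call(rbind, rows))
}
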