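# Reference barcode library: per-marker alignments + trees, species groups,
# and the trade-label -> allowed-species policy.

MARKERS <- c("cytb", "dloop", "cox1")

# Species that occur in commercial caviar labeling plus known substitutes.
KNOWN_SPECIES <- c(
  "Huso huso", "Acipenser stellatus", "Acipenser baerii",
  "Acipenser gueldenstaedtii", "Acipenser naccarii", "Acipenser persicus",
  "Acipenser ruthenus", "Acipenser transmontanus", "Acipenser nudiventris",
  "Acipenser schrenckii", "Polyodon spathula",
  "Scaphirhynchus platorynchus", "Scaphirhynchus albus", "Esox lucius"
)

# Acipenseriform species of the default reference panel (ship and Amur
# sturgeon are recognized by the label parser but carried in no panel).
ACIPENSERIFORM_SPECIES <- setdiff(
  KNOWN_SPECIES,
  c("Esox lucius", "Acipenser nudiventris", "Acipenser schrenckii"))

MARKET_NAMES <- c("beluga", "sevruga", "osetra", "white", "paddlefish",
                  "hackleback", "american", "other")

#' Parse a trade label
#'
#' Parses raw caviar label text into a structured trade label. The grammar
#' is `"MarketName (qualifier)[, farmed]"`: the market name maps to one of
#' beluga / sevruga / osetra / white / paddlefish / hackleback / american
#' (anything else is `other`; the common misspelling "ostera" normalizes to
#' osetra); a parenthesized qualifier is interpreted as a claimed species
#' when it matches a known binomial (full or abbreviated, e.g. "A. baerii"),
#' otherwise it is kept as free-text origin. The parse is total: unknown
#' patterns degrade to `market = "other"`.
#'
#' @param raw non-empty label text.
#' @return a `trade_label`: list with `raw`, `market`, `claimed_species`
#'   (NA if absent), `origin` (NA if absent) and `farmed` flag.
#' @examples
#' parse_label("Osetra (A. baerii), farmed")
#' parse_label("Beluga (Caspian Sea)")
#' @export
parse_label <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || nchar(trimws(raw)) == 0)
    stop("label text must be a non-empty string")
  txt <- trimws(raw)
  farmed <- grepl("\\bfarmed\\b", txt, ignore.case = TRUE)
  txt2 <- trimws(sub(",?\\s*farmed\\s*$", "", txt, ignore.case = TRUE))
  market <- if (grepl("^beluga\\b", txt2, ignore.case = TRUE)) "beluga"
    else if (grepl("^sevruga\\b", txt2, ignore.case = TRUE)) "sevruga"
    else if (grepl("^os[e]?t[e]?ra\\b", txt2, ignore.case = TRUE)) "osetra"
    else if (grepl("^white\\b", txt2, ignore.case = TRUE)) "white"
    else if (grepl("^paddlefish\\b", txt2, ignore.case = TRUE)) "paddlefish"
    else if (grepl("^hackleback\\b", txt2, ignore.case = TRUE)) "hackleback"
    else if (grepl("^american\\b", txt2, ignore.case = TRUE)) "american"
    else "other"
  claimed <- NA_character_
  origin <- NA_character_
  qual <- regmatches(txt2, regexpr("\\(([^)]*)\\)", txt2))
  if (length(qual) == 1) {
    q <- trimws(sub("^\\(", "", sub("\\)$", "", qual)))
    sp <- match_binomial(q)
    if (!is.na(sp)) claimed <- sp
    else if (nchar(q) > 0 && !grepl("^unspecified$", q, ignore.case = TRUE))
      origin <- q
  }
  structure(list(raw = raw, market = market, claimed_species = claimed,
                 origin = origin, farmed = farmed),
            class = "trade_label")
}

# Match a qualifier against the known-species list; handles abbreviated
# genus ("A. baerii", "P. spathula", "S. platorynchus", "H. huso").
match_binomial <- function(q) {
  q <- trimws(gsub("\\s+", " ", q))
  if (grepl("\\bx\\b", q, ignore.case = TRUE)) return(NA_character_)  # hybrids
  hit <- KNOWN_SPECIES[tolower(KNOWN_SPECIES) == tolower(q)]
  if (length(hit) == 1) return(hit)
  m <- regmatches(q, regexec("^([A-Za-z])\\.?\\s+([a-z]+)$", q))[[1]]
  if (length(m) == 3) {
    cand <- KNOWN_SPECIES[tolower(substr(KNOWN_SPECIES, 1, 1)) == tolower(m[2]) &
                            tolower(sub("^\\S+\\s+", "", KNOWN_SPECIES)) == tolower(m[3])]
    if (length(cand) == 1) return(cand)
  }
  NA_character_
}

#' Format a trade label canonically
#'
#' Inverse of [parse_label()] on the canonical grammar:
#' `parse_label(format_label(x))` reproduces `x`'s fields.
#'
#' @param label a `trade_label`.
#' @return canonical label string.
#' @export
format_label <- function(label) {
  stopifnot(inherits(label, "trade_label"))
  mk <- paste0(toupper(substr(label$market, 1, 1)), substring(label$market, 2))
  qual <- if (!is.na(label$claimed_species)) paste0(" (", label$claimed_species, ")")
    else if (!is.na(label$origin)) paste0(" (", label$origin, ")")
    else ""
  paste0(mk, qual, if (label$farmed) ", farmed" else "")
}

#' @export
print.trade_label <- function(x, ...) {
  cat("<trade_label>", format_label(x), "\n")
  invisible(x)
}

#' Default trade-label policy
#'
#' Maps each market name to the species that label may legitimately
#' contain. `other` (unrecognized labels, e.g. generic "black caviar")
#' admits any acipenseriform species, so only non-sturgeon substitutes
#' (such as pike roe) are inconsistent with it.
#'
#' @return named list market name -> character vector of allowed species.
#' @export
default_label_policy <- function() {
  list(
    beluga     = "Huso huso",
    sevruga    = "Acipenser stellatus",
    osetra     = c("Acipenser gueldenstaedtii", "Acipenser persicus",
                   "Acipenser baerii"),
    white      = "Acipenser transmontanus",
    paddlefish = "Polyodon spathula",
    hackleback = "Scaphirhynchus platorynchus",
    american   = c("Acipenser transmontanus", "Polyodon spathula",
                   "Scaphirhynchus platorynchus"),
    other      = ACIPENSERIFORM_SPECIES
  )
}

#' Default species groups
#'
#' Species sets that mtDNA cannot resolve at particular markers. The
#' gueldenstaedtii complex (A. gueldenstaedtii / A. naccarii / A. persicus)
#' is unresolvable at both cytb and the D-loop and is reported as a group;
#' Scaphirhynchus is unresolvable at all three markers and reported at
#' genus level. A. baerii is resolvable at both cytb and D-loop and is not
#' grouped.
#'
#' @return list of groups, each with `id`, `display`, `members`,
#'   `unresolvable_markers`.
#' @export
default_species_groups <- function() {
  list(
    list(id = "gueldenstaedtii_complex",
         display = "Acipenser gueldenstaedtii/A. naccarii",
         members = c("Acipenser gueldenstaedtii", "Acipenser naccarii",
                     "Acipenser persicus"),
         unresolvable_markers = c("cytb", "dloop")),
    list(id = "scaphirhynchus",
         display = "Scaphirhynchus spp.",
         members = c("Scaphirhynchus platorynchus", "Scaphirhynchus albus"),
         unresolvable_markers = c("cytb", "dloop", "cox1"))
  )
}

# Group containing `species` that is unresolvable at `marker`, or NULL.
group_at_marker <- function(groups, species, marker) {
  for (g in groups) {
    if (species %in% g$members && marker %in% g$unresolvable_markers) return(g)
  }
  NULL
}

#' Species allowed by a trade label
#'
#' An explicit claimed species narrows the market-name set to that species;
#' otherwise the full market-name set applies. When `groups` and `marker`
#' are supplied, each allowed species is expanded to the members of its
#' mtDNA-indistinguishable group at that marker, so a group-level
#' identification of a claimed species is not flagged.
#'
#' @param label a `trade_label`.
#' @param policy named list from [default_label_policy()] (or an override).
#' @param groups optional list from [default_species_groups()].
#' @param marker optional marker at which indistinguishability applies.
#' @return character vector of allowed species.
#' @export
allowed_species <- function(label, policy = default_label_policy(),
                            groups = NULL, marker = NULL) {
  stopifnot(inherits(label, "trade_label"))
  if (is.null(policy[[label$market]]))
    stop("label policy has no entry for market name '", label$market, "'")
  base <- if (!is.na(label$claimed_species)) label$claimed_species
          else policy[[label$market]]
  if (!is.null(groups) && !is.null(marker)) {
    extra <- unlist(lapply(base, function(sp) {
      g <- group_at_marker(groups, sp, marker)
      if (is.null(g)) character(0) else g$members
    }))
    base <- union(base, extra)
  }
  sort(unique(base))
}

#' Assemble and validate a reference barcode database
#'
#' @param alignments named list (by marker) of [dna_alignment()] objects
#'   whose sequence names are reference ids.
#' @param meta data.frame with columns `id`, `species`, `marker`.
#' @param trees named list (by marker) of `ape::phylo` reference trees whose
#'   tip labels are reference ids of that marker.
#' @param groups species groups (see [default_species_groups()]).
#' @param policy label policy (see [default_label_policy()]).
#' @param models optional named list (by marker) of [gtr_model()] objects
#'   used for placement; markers without one get an empirical-frequency
#'   default.
#' @return a validated `reference_db`.
#' @export
reference_db <- function(alignments, meta, trees,
                         groups = default_species_groups(),
                         policy = default_label_policy(),
                         models = NULL) {
  db <- structure(list(alignments = alignments, meta = meta, trees = trees,
                       groups = groups, policy = policy,
                       models = models %||% list(),
                       haplotype_pool = list(),
                       cache = new.env(parent = emptyenv())),
                  class = "reference_db")
  validate_reference_db(db)
  for (mk in names(db$alignments)) {
    if (is.null(db$models[[mk]])) {
      db$models[[mk]] <- gtr_model(freqs = empirical_frequencies(db$alignments[[mk]]),
                                   alpha = 0.3, k = 4L)
    }
  }
  db
}

#' Validate reference-database invariants
#'
#' Checks that every tree tip resolves to exactly one reference sequence of
#' its marker, `(id, marker)` pairs are unique, alignments are rectangular
#' and IUPAC (enforced by [dna_alignment()]), every group species and every
#' policy species occurs in the library, and markers are known. Violations
#' are reported with the offending record ids.
#'
#' @param db a `reference_db`.
#' @return `db`, invisibly, on success; otherwise an error.
#' @export
validate_reference_db <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  meta <- db$meta
  need <- c("id", "species", "marker")
  if (!all(need %in% names(meta))) stop("meta must have columns id, species, marker")
  bad_marker <- setdiff(unique(meta$marker), MARKERS)
  if (length(bad_marker) > 0)
    stop("unknown markers in metadata: ", paste(bad_marker, collapse = ", "))
  dup <- duplicated(meta[, c("id", "marker")])
  if (any(dup))
    stop("duplicate (id, marker) records: ",
         paste(paste(meta$id[dup], meta$marker[dup]), collapse = "; "))
  for (mk in names(db$alignments)) {
    aln <- db$alignments[[mk]]
    ids <- meta$id[meta$marker == mk]
    miss <- setdiff(names(aln), ids)
    if (length(miss) > 0)
      stop("sequences without metadata at ", mk, ": ", paste(miss, collapse = ", "))
    miss2 <- setdiff(ids, names(aln))
    if (length(miss2) > 0)
      stop("metadata without sequence at ", mk, ": ", paste(miss2, collapse = ", "))
    tree <- db$trees[[mk]]
    if (is.null(tree)) stop("no reference tree for marker ", mk)
    orphan <- setdiff(tree$tip.label, names(aln))
    if (length(orphan) > 0)
      stop("tree tips without a reference sequence at ", mk, ": ",
           paste(orphan, collapse = ", "))
  }
  lib_species <- unique(meta$species)
  for (g in db$groups) {
    miss <- setdiff(g$members, lib_species)
    if (length(miss) > 0)
      stop("group ", g$id, " species absent from the library: ",
           paste(miss, collapse = ", "))
  }
  miss <- setdiff(unique(unlist(db$policy)), lib_species)
  if (length(miss) > 0)
    stop("policy species absent from the library: ", paste(miss, collapse = ", "))
  invisible(db)
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db>", nrow(x$meta), "sequences,",
      length(unique(x$meta$species)), "species, markers:",
      paste(names(x$alignments), collapse = ", "), "\n")
  invisible(x)
}

species_of_ids <- function(db, ids, marker) {
  m <- db$meta[db$meta$marker == marker, ]
  m$species[match(ids, m$id)]
}

#' Write a reference database to a directory
#'
#' Emits one aligned FASTA per marker (headers `id|species|marker`), one
#' Newick tree per marker, and a YAML config holding the species groups,
#' label policy and per-marker model parameters. [load_reference_db()]
#' reads the same layout back.
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (mk in names(db$alignments)) {
    aln <- db$alignments[[mk]]
    sp <- species_of_ids(db, names(aln), mk)
    out <- setNames(unclass(aln), paste(names(aln), sp, mk, sep = "|"))
    write_fasta_alignment(dna_alignment(out), file.path(dir, paste0(mk, ".fasta")))
    ape::write.tree(db$trees[[mk]], file.path(dir, paste0(mk, ".nwk")))
  }
  cfg <- list(
    groups = lapply(db$groups, function(g) g[c("id", "display", "members",
                                               "unresolvable_markers")]),
    policy = db$policy,
    models = lapply(db$models, function(m)
      list(freqs = as.numeric(m$freqs), rates = m$rates,
           alpha = m$alpha, k = m$k))
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Load a reference database from files
#'
#' @param dir directory written by [write_reference_db()], or individual
#'   paths via the other arguments.
#' @param fasta_paths named character vector (by marker) of aligned FASTA
#'   files with `id|species|marker` headers.
#' @param newick_paths named character vector (by marker) of Newick files.
#' @param config_path YAML config with `groups`, `policy`, `models`.
#' @return a validated `reference_db`.
#' @export
load_reference_db <- function(dir = NULL, fasta_paths = NULL,
                              newick_paths = NULL, config_path = NULL) {
  if (!is.null(dir)) {
    mks <- sub("\\.fasta$", "", basename(Sys.glob(file.path(dir, "*.fasta"))))
    fasta_paths <- setNames(file.path(dir, paste0(mks, ".fasta")), mks)
    newick_paths <- setNames(file.path(dir, paste0(mks, ".nwk")), mks)
    config_path <- file.path(dir, "config.yaml")
  }
  alignments <- list(); meta_rows <- list(); trees <- list()
  for (mk in names(fasta_paths)) {
    raw <- read_fasta_alignment(fasta_paths[[mk]])
    parts <- strsplit(names(raw), "|", fixed = TRUE)
    bad <- names(raw)[vapply(parts, length, integer(1)) != 3]
    if (length(bad) > 0)
      stop("FASTA headers must be id|species|marker; offending: ",
           paste(bad, collapse = ", "))
    ids <- vapply(parts, `[`, character(1), 1)
    sps <- vapply(parts, `[`, character(1), 2)
    mks2 <- vapply(parts, `[`, character(1), 3)
    if (any(mks2 != mk))
      stop("marker mismatch in ", fasta_paths[[mk]], ": ",
           paste(ids[mks2 != mk], collapse = ", "))
    alignments[[mk]] <- dna_alignment(setNames(unclass(raw), ids))
    meta_rows[[mk]] <- data.frame(id = ids, species = sps, marker = mk,
                                  stringsAsFactors = FALSE)
    trees[[mk]] <- ape::read.tree(newick_paths[[mk]])
  }
  cfg <- if (!is.null(config_path) && file.exists(config_path))
    yaml::read_yaml(config_path) else list()
  groups <- if (!is.null(cfg$groups)) cfg$groups else default_species_groups()
  policy <- if (!is.null(cfg$policy)) cfg$policy else default_label_policy()
  models <- NULL
  if (!is.null(cfg$models)) {
    models <- lapply(cfg$models, function(m)
      gtr_model(freqs = m$freqs, rates = m$rates, alpha = m$alpha, k = m$k))
  }
  reference_db(alignments, do.call(rbind, meta_rows), trees,
               groups = groups, policy = policy, models = models)
}
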