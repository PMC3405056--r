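# The 2006-2008 New York City caviar survey, encoded as a runnable fixture:
# 92 tins plus one meat sample, with per-lot labels, purchase channel and
# year, extraction failures, D-loop amplification failures, the cox1-only
# pike lot, and the nine confirmed substitutions. Sequences are synthetic
# (drawn from the simulated haplotype pool of a generated reference panel,
# keyed to each lot's documented identification); purchase metadata and
# expected outcomes follow the published survey tables.

nyc_lot_table <- function() {
  row <- function(ids, label, channel, year, species, n_eggs = 1L,
                  n_hap = 1L, dloop_fail = FALSE, no_dna = FALSE,
                  cox1_only = FALSE, sample_type = "caviar") {
    data.frame(id = ids, label = label, channel = channel, year = year,
               species = species, n_eggs = n_eggs, n_hap = n_hap,
               dloop_fail = dloop_fail, no_dna = no_dna,
               cox1_only = cox1_only, sample_type = sample_type,
               stringsAsFactors = FALSE)
  }
  hh <- "Huso huso"; ast <- "Acipenser stellatus"; ab <- "Acipenser baerii"
  ag <- "Acipenser gueldenstaedtii"; ap <- "Acipenser persicus"
  ar <- "Acipenser ruthenus"; at <- "Acipenser transmontanus"
  ps <- "Polyodon spathula"; sp <- "Scaphirhynchus platorynchus"
  el <- "Esox lucius"
  beluga <- "Beluga (Huso huso)"
  sevruga <- "Sevruga (Acipenser stellatus)"
  ost_ba <- "Ostera (A. baerii), farmed"
  ost_gu <- "Osetra (A. gueldenstaedtii)"
  ost_pe <- "Osetra (A. persicus)"
  ost_un <- "Osetra (unspecified)"
  white <- "White (A. transmontanus)"
  paddle <- "Paddlefish (Polyodon spathula)"
  hackle <- "Hackleback (Scaphirhynchus platorynchus)"
  amer <- "American (unspecified)"
  tab <- rbind(
    # label-consistent lots (one egg each)
    row(c(1, 13), beluga, "in-store", 2006, hh),
    row(c(23, 32), beluga, "internet", 2006, hh),
    row(57, beluga, "internet", 2008, hh),
    row(c(3, 6, 9, 12, 18), sevruga, "in-store", 2006, ast),
    row(c(56, 58, 71, 92), sevruga, "in-store", 2008, ast),
    row(c(25, 28, 31), sevruga, "internet", 2006, ast),
    row(c(60, 69, 76, 77, 84), sevruga, "internet", 2008, ast),
    row(c(2, 8), ost_ba, "in-store", 2006, ab),
    row(c(51, 54, 85), ost_ba, "in-store", 2008, ab),
    row(24, ost_ba, "internet", 2006, ab),
    row(27, ost_gu, "internet", 2006, ag),
    row(c(68, 82, 83, 86, 87), ost_gu, "internet", 2008, ag),
    row(14, "Osetra (A. gueldenstaedii x A. baerii), farmed",
        "in-store", 2006, ag),
    row(55, ost_pe, "in-store", 2006, ap),
    row(29, ost_pe, "internet", 2006, ap),
    row(c(63, 73), ost_pe, "internet", 2008, ap),
    row(c(10, 21), ost_un, "in-store", 2006, ag),
    row(20, ost_un, "in-store", 2006, ag, dloop_fail = TRUE),
    row(c(48, 53, 70), ost_un, "in-store", 2008, ag),
    row(c(44, 47), ost_un, "in-store", 2008, ag, dloop_fail = TRUE),
    row(c(34, 35), ost_un, "internet", 2006, ag),
    row(c(62, 65, 67), ost_un, "internet", 2008, ag),
    row(c(11, 15), white, "in-store", 2006, at),
    row(c(45, 90), white, "in-store", 2008, at),
    row(52, white, "in-store", 2008, at, sample_type = "meat"),
    row(40, white, "internet", 2006, at),
    row(c(4, 16, 19, 22), paddle, "in-store", 2006, ps),
    row(c(43, 50), paddle, "in-store", 2008, ps),
    row(26, paddle, "internet", 2006, ps),
    row(c(61, 66, 72, 80, 89), paddle, "internet", 2008, ps),
    row(c(5, 7, 17), hackle, "in-store", 2006, sp),
    row(49, hackle, "in-store", 2008, sp),
    row(39, hackle, "internet", 2006, sp),
    row(c(74, 79, 91), hackle, "internet", 2008, sp),
    row(46, amer, "in-store", 2008, at),
    row(41, amer, "internet", 2006, ps),
    row(c(59, 88), amer, "internet", 2008, ps),
    # extraction failures
    row(94, ost_ba, "internet", 2008, ab, no_dna = TRUE),
    row(95, "Caviar Substitute", "internet", 2008, el, no_dna = TRUE),
    # the nine mislabeled lots (multi-egg confirmation)
    row(30, "Beluga", "internet", 2006, ag, n_eggs = 14L),
    row(33, "Sevruga (Caspian/Black Sea)", "internet", 2006, ps, n_eggs = 14L),
    row(36, "Sevruga (Caspian Sea)", "internet", 2006, ag, n_eggs = 10L, n_hap = 2L),
    row(38, "Beluga (Caspian Sea)", "internet", 2006, ab, n_eggs = 10L),
    row(64, "Sevruga (Kazakhstan)", "internet", 2008, ar, n_eggs = 10L, n_hap = 2L),
    row(75, "Sevruga", "internet", 2008, ps, n_eggs = 10L, n_hap = 2L),
    row(81, ost_ba, "internet", 2008, ag, n_eggs = 10L),
    row(93, ost_gu, "internet", 2008, ab, n_eggs = 10L),
    row(96, "Caspian Sea Black Caviar", "internet", 2008, el, n_eggs = 11L,
        n_hap = 2L, cox1_only = TRUE)
  )
  tab[order(tab$id), ]
}

# Expected per-lot outcomes for the nine substitutions (survey table of
# mislabeled lots): identification display, eggs sampled, haplotypes.
nyc_expected_mislabeled <- function() {
  data.frame(
    id = c(30, 33, 36, 38, 64, 75, 81, 93, 96),
    display = c("Acipenser gueldenstaedtii/A. naccarii", "Polyodon spathula",
                "Acipenser gueldenstaedtii/A. naccarii", "Acipenser baerii",
                "Acipenser ruthenus", "Polyodon spathula",
                "Acipenser gueldenstaedtii/A. naccarii", "Acipenser baerii",
                "Esox lucius"),
    n = c(14, 14, 10, 10, 10, 10, 10, 10, 11),
    n_hap = c(1, 1, 2, 1, 2, 2, 1, 1, 2),
    dloop = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' The 2006-2008 New York City caviar survey as a runnable fixture
#'
#' Builds the 93-sample market survey (92 caviar tins and one meat sample)
#' with per-lot labels, purchase channel and year, the two samples from
#' which no DNA could be extracted, the three lots whose D-loop failed to
#' amplify, the cox1-only pike lot, and the nine substituted lots with
#' their documented egg and haplotype counts. Sequences are synthetic,
#' drawn from the haplotype pool of a [generate_references()] panel so that
#' each lot reproduces its documented identification; everything else is
#' encoded survey metadata.
#'
#' @param db optional `reference_db`; by default one is generated with
#'   `sim_config(seed = seed)`.
#' @param seed seed for the generated reference panel.
#' @return list with `db`, `lots` (93 [lot()]s), `table` (the per-lot
#'   metadata data.frame) and `expected` (expected outcomes for the nine
#'   mislabeled lots).
#' @export
nyc_survey_fixture <- function(db = NULL, seed = 2006L) {
  if (is.null(db)) db <- generate_references(sim_config(seed = seed))
  tab <- nyc_lot_table()
  lots <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    eggs <- lapply(seq_len(r$n_eggs), function(j) {
      if (r$no_dna) return(egg_record(as.character(r$id), j))
      hap <- (j - 1) %% r$n_hap + 1
      s <- lapply(MARKERS, function(mk) db$haplotype_pool[[mk]][[r$species]][hap])
      names(s) <- MARKERS
      egg_record(as.character(r$id), j,
                 cytb = if (r$cox1_only) NA_character_ else s$cytb,
                 dloop = if (r$cox1_only || r$dloop_fail) NA_character_ else s$dloop,
                 cox1 = s$cox1)
    })
    lots[[i]] <- lot(as.character(r$id), r$label, r$channel, r$year, eggs,
                     sample_type = r$sample_type)
  }
  list(db = db, lots = lots, table = tab, expected = nyc_expected_mislabeled())
}
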