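# Marker escalation, multi-egg confirmation, haplotype counting.

mk_egg <- function(db, sp, lot_id = "T1", egg = 1, hap = 1,
                   markers = c("cytb", "dloop", "cox1")) {
  s <- lapply(c("cytb", "dloop", "cox1"), function(mk)
    if (mk %in% markers) db$haplotype_pool[[mk]][[sp]][hap] else NA_character_)
  names(s) <- c("cytb", "dloop", "cox1")
  egg_record(lot_id, egg, cytb = s$cytb, dloop = s$dloop, cox1 = s$cox1)
}

mk_lot <- function(db, id, label, sp, n_eggs, hap_of_egg = NULL, ...) {
  if (is.null(hap_of_egg)) hap_of_egg <- rep(1, n_eggs)
  eggs <- lapply(seq_len(n_eggs), function(j)
    mk_egg(db, if (length(sp) > 1) sp[j] else sp, id, j, hap_of_egg[j], ...))
  lot(id, label, "internet", 2008, eggs)
}

test_that("D-loop escalation triggers on osetra labels and the complex", {
  cfg <- caviar_config()
  sev <- parse_label("Sevruga")
  os <- parse_label("Osetra (unspecified)")
  bel <- parse_label("Beluga (Caspian Sea)")
  sp_call <- function(sp) structure(
    list(marker = "cytb", type = "species", species = sp, group = NA,
         display = sp), class = "species_call")
  grp_call <- structure(list(marker = "cytb", type = "group",
                             group = "gueldenstaedtii_complex",
                             display = "x"), class = "species_call")
  expect_false(needs_dloop(sp_call("Acipenser stellatus"), sev, cfg))
  expect_true(needs_dloop(sp_call("Acipenser stellatus"), os, cfg))   # any osetra
  expect_true(needs_dloop(sp_call("Acipenser baerii"), bel, cfg))
  expect_true(needs_dloop(grp_call, bel, cfg))
  expect_false(needs_dloop(NULL, sev, cfg))
})

test_that("run_egg escalates, overrides within the complex, falls back to cox1", {
  db <- shared_db()
  cfg <- caviar_config()
  # Siberian sturgeon under a beluga label: cytb call triggers the D-loop,
  # which confirms the species-level call
  e1 <- mk_egg(db, "Acipenser baerii")
  r1 <- run_egg(e1, parse_label("Beluga"), db, cfg)
  expect_equal(r1$markers_used, c("cytb", "dloop"))
  expect_equal(r1$final$marker, "dloop")
  expect_equal(r1$final$species, "Acipenser baerii")
  # pike roe with failed cytb and D-loop: cox1 fallback
  e2 <- mk_egg(db, "Esox lucius", markers = "cox1")
  r2 <- run_egg(e2, parse_label("Caspian Sea Black Caviar"), db, cfg)
  expect_equal(r2$markers_used, "cox1")
  expect_equal(r2$final$species, "Esox lucius")
  # everything failed
  r3 <- run_egg(egg_record("T1", 1), parse_label("Sevruga"), db, cfg)
  expect_null(r3$final)
  # sevruga containing stellate sturgeon: no escalation
  e4 <- mk_egg(db, "Acipenser stellatus")
  r4 <- run_egg(e4, parse_label("Sevruga"), db, cfg)
  expect_equal(r4$markers_used, "cytb")
})

test_that("confirm_lot verdicts follow the confirmation rule", {
  db <- shared_db()
  # consistent lot: one egg, no resampling
  l1 <- mk_lot(db, "C1", "Sevruga", "Acipenser stellatus", 5)
  r1 <- confirm_lot(l1, db)
  expect_equal(r1$verdict, "consistent")
  expect_equal(r1$n_eggs, 1)
  # mislabeled lot with 14 eggs, one haplotype
  l2 <- mk_lot(db, "M1", "Beluga", "Acipenser gueldenstaedtii", 14)
  r2 <- confirm_lot(l2, db)
  expect_equal(r2$verdict, "mislabeled")
  expect_equal(r2$confirmation, "confirmed")
  expect_equal(r2$n_eggs, 14)
  expect_equal(r2$n_haplotypes, 1)
  expect_equal(r2$final$group, "gueldenstaedtii_complex")
  # two pooled haplotypes are counted
  l3 <- mk_lot(db, "M2", "Sevruga (Kazakhstan)", "Acipenser ruthenus", 10,
               hap_of_egg = rep(c(1, 2), 5))
  r3 <- confirm_lot(l3, db)
  expect_equal(r3$verdict, "mislabeled")
  expect_equal(r3$n_haplotypes, 2)
  # mixed lot: some eggs consistent with the label, some not
  l4 <- mk_lot(db, "X1", "Sevruga",
               c("Polyodon spathula", rep(c("Acipenser stellatus",
                                            "Polyodon spathula"), 5)[1:9]), 10)
  r4 <- confirm_lot(l4, db)
  expect_equal(r4$verdict, "mixed")
  # few available eggs: verdict kept, confirmation downgraded
  l5 <- mk_lot(db, "M3", "Sevruga", "Polyodon spathula", 3)
  r5 <- confirm_lot(l5, db)
  expect_equal(r5$verdict, "mislabeled")
  expect_equal(r5$confirmation, "partial")
})

test_that("verdicts do not depend on egg order", {
  db <- shared_db()
  l <- mk_lot(db, "M4", "Beluga", "Acipenser baerii", 10,
              hap_of_egg = rep(c(1, 2), 5))
  r <- confirm_lot(l, db)
  l2 <- l
  set.seed(7)
  l2$eggs <- l$eggs[sample(10)]
  r2 <- confirm_lot(l2, db)
  expect_equal(r2$verdict, r$verdict)
  expect_equal(r2$n_haplotypes, r$n_haplotypes)
  expect_equal(r2$n_eggs, r$n_eggs)
})

test_that("haplotype counting trims and masks before comparing", {
  expect_equal(count_haplotypes(rep("ACGTACGT", 10)), 1)
  expect_equal(count_haplotypes(c(rep("ACGTACGT", 8), rep("ACGTACGA", 2))), 2)
  # difference only at an N position does not split haplotypes
  expect_equal(count_haplotypes(c("ACNTACGT", "ACGTACGT", "ACATACGT")), 1)
  # gap columns are outside the common covered region
  expect_equal(count_haplotypes(c("AC-TACGT", "ACGTACGT")), 1)
  expect_error(count_haplotypes(character(0)), "no resolvable")
})

test_that("run_survey isolates failures and handles empty input", {
  db <- shared_db()
  expect_length(run_survey(list(), db), 0)
  good <- mk_lot(db, "G1", "Sevruga", "Acipenser stellatus", 2)
  bad <- good
  bad$eggs <- list(structure(list(lot_id = "B1", egg = 1,
                                  seqs = list(cytb = "!!!", dloop = NA,
                                              cox1 = NA)),
                             class = "egg_record"))
  bad$id <- "B1"
  res <- run_survey(list(good, bad), db)
  df <- as.data.frame(res)
  expect_equal(df$verdict, c("consistent", "error"))
})
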