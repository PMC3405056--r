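# Label parsing, the allowed-species policy, and reference-db validation.

test_that("labels parse into market, claimed species, origin and farmed flag", {
  l1 <- parse_label("Osetra (A. baerii)")
  expect_equal(l1$market, "osetra")
  expect_equal(l1$claimed_species, "Acipenser baerii")
  expect_true(is.na(l1$origin))

  l2 <- parse_label("Beluga (Caspian Sea)")
  expect_equal(l2$market, "beluga")
  expect_true(is.na(l2$claimed_species))
  expect_equal(l2$origin, "Caspian Sea")

  expect_equal(parse_label("Ostera (A. baerii), farmed")$market, "osetra")
  expect_true(parse_label("Ostera (A. baerii), farmed")$farmed)
  expect_equal(parse_label("XYZ roe")$market, "other")
  # hybrids do not parse as a single claimed species
  l3 <- parse_label("Osetra (A. gueldenstaedii x A. baerii)")
  expect_true(is.na(l3$claimed_species))
  expect_equal(l3$market, "osetra")
  expect_error(parse_label(""), "non-empty")
})

test_that("parse_label . format_label is the identity on canonical labels", {
  raws <- c("Beluga (Huso huso)", "Sevruga", "Osetra (Acipenser baerii), farmed",
            "White (Caspian Sea)", "Paddlefish (Polyodon spathula)",
            "Hackleback", "American")
  for (r in raws) {
    l <- parse_label(r)
    l2 <- parse_label(format_label(l))
    expect_equal(l2[c("market", "claimed_species", "origin", "farmed")],
                 l[c("market", "claimed_species", "origin", "farmed")])
  }
})

test_that("allowed_species honors claims, market sets and group closure", {
  pol <- default_label_policy()
  grp <- default_species_groups()
  expect_equal(allowed_species(parse_label("Sevruga"), pol), "Acipenser stellatus")
  expect_setequal(allowed_species(parse_label("Osetra (unspecified)"), pol),
                  c("Acipenser gueldenstaedtii", "Acipenser persicus",
                    "Acipenser baerii"))
  # explicit claim narrows the osetra set
  expect_equal(allowed_species(parse_label("Osetra (A. baerii)"), pol),
               "Acipenser baerii")
  # claim expands to its indistinguishable group at the marker
  expect_setequal(
    allowed_species(parse_label("Osetra (A. gueldenstaedtii)"), pol, grp, "cytb"),
    c("Acipenser gueldenstaedtii", "Acipenser naccarii", "Acipenser persicus"))
  # baerii is resolvable at cytb: no expansion
  expect_equal(allowed_species(parse_label("Osetra (A. baerii)"), pol, grp, "cytb"),
               "Acipenser baerii")
  expect_error(allowed_species(parse_label("Beluga"), list(sevruga = "x")),
               "no entry")
})

test_that("allowed_species is monotone in the policy", {
  pol <- default_label_policy()
  lab <- parse_label("American")
  base <- allowed_species(lab, pol)
  pol2 <- pol
  pol2$american <- c(pol2$american, "Acipenser ruthenus")
  expect_true(all(base %in% allowed_species(lab, pol2)))
})

test_that("reference db validation names offending records", {
  db <- shared_db()
  expect_silent(validate_reference_db(db))
  # tree tip with no sequence
  db2 <- db
  db2$trees$cytb$tip.label[1] <- "GHOST1"
  expect_error(validate_reference_db(db2), "GHOST1")
  # duplicate (id, marker)
  db3 <- db
  db3$meta <- rbind(db3$meta, db3$meta[1, ])
  expect_error(validate_reference_db(db3), "duplicate")
  # ragged alignment is rejected at construction
  expect_error(dna_alignment(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("a written reference db reloads identically", {
  db <- shared_db()
  dir <- tempfile("refdb")
  write_reference_db(db, dir)
  db2 <- load_reference_db(dir)
  for (mk in names(db$alignments)) {
    expect_identical(unclass(db$alignments[[mk]]), unclass(db2$alignments[[mk]]))
    expect_equal(ape::dist.topo(ape::unroot(db$trees[[mk]]),
                                ape::unroot(db2$trees[[mk]])), 0,
                 ignore_attr = TRUE)
  }
  expect_equal(db2$policy, db$policy)
  expect_equal(lapply(db2$groups, `[[`, "members"),
               lapply(db$groups, `[[`, "members"))
  unlink(dir, recursive = TRUE)
})
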