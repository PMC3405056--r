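# Synthetic reference panels, market surveys, and the encoded NYC survey.

test_that("generated reference panels are valid and deterministic", {
  db <- shared_db()
  expect_silent(validate_reference_db(db))
  expect_setequal(names(db$alignments), c("cytb", "dloop", "cox1"))
  # same seed reproduces the panel byte for byte
  db2 <- generate_references(sim_config(seed = 424242L))
  for (mk in names(db$alignments))
    expect_identical(unclass(db$alignments[[mk]]), unclass(db2$alignments[[mk]]))
  expect_identical(db$haplotype_pool, db2$haplotype_pool)
  # a different seed gives different sequences
  db3 <- generate_references(sim_config(seed = 7L))
  expect_false(identical(unclass(db$alignments$cytb), unclass(db3$alignments$cytb)))
})

test_that("group members sit on near-zero branches and are near-identical", {
  db <- shared_db()
  g1 <- db$groups[[1]]$members
  ids <- db$meta$id[db$meta$marker == "cytb" & db$meta$species %in% g1]
  seqs <- unclass(db$alignments$cytb)[ids]
  d <- utils::combn(seq_along(seqs), 2, function(ij)
    mean(strsplit(seqs[[ij[1]]], "")[[1]] != strsplit(seqs[[ij[2]]], "")[[1]]))
  expect_lt(max(d), 0.02)
  # whereas e.g. stellatus vs huso differ substantially
  other <- unclass(db$alignments$cytb)[
    db$meta$id[db$meta$marker == "cytb" &
                 db$meta$species %in% c("Acipenser stellatus", "Huso huso")]]
  dd <- mean(strsplit(other[[1]], "")[[1]] != strsplit(other[[3]], "")[[1]])
  expect_gt(dd, 0.05)
})

test_that("survey generation respects rate, pooling and dropout settings", {
  db <- shared_db()
  s0 <- generate_survey(sim_config(seed = 5, n_lots = 40, rate = 0,
                                   pooling_prob = 0), db)
  expect_equal(sum(s0$truth$mislabeled), 0)
  expect_true(all(s0$truth$n_haplotypes == 1))
  nod <- sim_config(seed = 6, n_lots = 20, rate = 0,
                    dropout = c(cytb = 0, dloop = 0, cox1 = 0))
  sv <- generate_survey(nod, db)
  all_seqs <- unlist(lapply(sv$lots, function(l)
    lapply(l$eggs, function(e) unlist(e$seqs))))
  expect_false(anyNA(all_seqs))
  # determinism
  sv2 <- generate_survey(nod, db)
  expect_identical(sv$truth, sv2$truth)
})

test_that("simulated mislabeling counts have the right binomial mean", {
  db <- shared_db()
  counts <- vapply(1:40, function(s)
    sum(generate_survey(sim_config(seed = s, n_lots = 90, rate = 0.10),
                        db)$truth$mislabeled), numeric(1))
  expect_lt(abs(mean(counts) - 9), 1.5)  # ~3 SE at 40 surveys
})

test_that("ground-truth flags follow the label policy", {
  db <- shared_db()
  sv <- generate_survey(sim_config(seed = 11, n_lots = 120, rate = 0.3), db)
  for (i in seq_len(nrow(sv$truth))) {
    lab <- parse_label(sv$truth$label[i])
    ok <- sv$truth$true_species[i] %in%
      allowed_species(lab, db$policy, db$groups, "cytb")
    expect_equal(sv$truth$mislabeled[i], !ok)
  }
})

test_that("the encoded NYC survey table matches the published design", {
  fx <- nyc_survey_fixture(db = shared_db())
  tab <- fx$table
  expect_equal(nrow(tab), 93)
  expect_equal(anyDuplicated(tab$id), 0)
  expect_equal(sum(tab$channel == "internet"), 51)
  expect_equal(sum(tab$channel == "in-store"), 42)
  expect_equal(sum(tab$sample_type == "meat"), 1)
  expect_equal(sum(tab$no_dna), 2)
  expect_equal(sum(tab$cox1_only), 1)
  expect_equal(nrow(fx$expected), 9)
  # purchases by year match the survey totals (41 in 2006, 52 in 2008)
  expect_equal(sum(tab$year == 2006), 41)
  expect_equal(sum(tab$year == 2008), 52)
  # every mislabeled lot is an internet purchase with >= 10 eggs
  mis <- tab[tab$id %in% fx$expected$id, ]
  expect_true(all(mis$channel == "internet"))
  expect_true(all(mis$n_eggs >= 10))
})
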