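# Best-hit identity, phylogenetic placement, and group-aware calling.

test_that("percent identity matches arithmetic and is symmetric", {
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  expect_equal(percent_identity(s, s)$identity, 100)
  expect_equal(percent_identity(s, s)$aligned_length, 500)
  ch <- strsplit(s, "")[[1]]
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  ch[50 + 0:9 * 45] <- flip[ch[50 + 0:9 * 45]]  # 10 scattered mismatches
  s2 <- paste(ch, collapse = "")
  expect_equal(percent_identity(s, s2)$identity, 98, tolerance = 1e-9)
  expect_equal(percent_identity(s, s2)$score, percent_identity(s2, s)$score)
})

test_that("local alignment scores match a quadratic DP oracle", {
  set.seed(91)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1), replace = TRUE),
               collapse = "")
    expect_equal(percent_identity(a, b)$score, gotoh_local_score(a, b))
  }
})

test_that("best_hits ranks an exact reference first at 100%", {
  db <- shared_db()
  q <- unclass(db$alignments$cytb)[[5]]
  hits <- best_hits(q, db, "cytb")
  expect_equal(hits$id[1], names(db$alignments$cytb)[5])
  expect_equal(hits$identity[1], 100)
  expect_equal(nrow(hits), length(db$alignments$cytb))
  expect_true(all(diff(hits$score) <= 0))
})

test_that("placement of a tip's own sequence lands on that tip's clade", {
  db <- shared_db()
  id <- names(db$alignments$cytb)[7]
  q <- unclass(db$alignments$cytb)[[id]]
  pl <- place_query(q, db, "cytb")
  expect_true(id %in% pl$clade_tips)
  expect_lt(pl$pendant, 1e-3)
  expect_equal(sum(pl$weights), 1, tolerance = 1e-12)
})

test_that("placement agrees with de novo tree building on toy data", {
  # 4 well-separated species, one query from species "c"
  tr <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.1,(c:0.05,d:0.05):0.1);")
  m <- gtr_model(alpha = Inf, k = 1)
  ext <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.1,((c:0.04,q:0.01):0.01,d:0.05):0.1);")
  sim <- simulate_alignment(ext, m, 400, seed = 101)
  refs <- unclass(sim)[c("a", "b", "c", "d")]
  meta <- data.frame(id = names(refs), species = paste("Sp", names(refs)),
                     marker = "cytb", stringsAsFactors = FALSE)
  db <- reference_db(list(cytb = dna_alignment(refs)), meta,
                     list(cytb = tr), groups = list(),
                     policy = list(other = paste("Sp", names(refs))))
  pl <- place_query(unclass(sim)[["q"]], db, "cytb")
  expect_true("c" %in% pl$clade_tips && !("b" %in% pl$clade_tips))
  # oracle: full ML tree with the query included puts q sister to c
  denovo <- build_ml_tree(dna_alignment(unclass(sim)), m, n_starts = 3, seed = 5)
  bp <- caviarid:::tree_bipartitions(denovo$tree)
  expect_true(any(vapply(strsplit(bp$key, "|", fixed = TRUE), function(k)
    setequal(k, c("c", "q")) || setequal(k, c("a", "b", "d")), logical(1))))
})

test_that("species calls respect unresolvable groups", {
  db <- shared_db()
  th <- default_thresholds()
  # a Russian sturgeon haplotype: group call, never species-level
  q <- db$haplotype_pool$cytb[["Acipenser gueldenstaedtii"]][1]
  call <- identify_sequence(q, db, "cytb", th)
  expect_equal(call$type, "group")
  expect_equal(call$group, "gueldenstaedtii_complex")
  # same for Persian sturgeon, at cytb and at the D-loop
  for (mk in c("cytb", "dloop")) {
    qp <- db$haplotype_pool[[mk]][["Acipenser persicus"]][1]
    cp <- identify_sequence(qp, db, mk, th)
    expect_equal(cp$type, "group")
  }
  # stellate sturgeon is cleanly resolvable
  qs <- db$haplotype_pool$cytb[["Acipenser stellatus"]][1]
  cs <- identify_sequence(qs, db, "cytb", th)
  expect_equal(cs$type, "species")
  expect_equal(cs$species, "Acipenser stellatus")
  expect_gte(cs$top_identity, 98)
})

test_that("synthetic queries identify to the right species or group", {
  db <- shared_db()
  th <- default_thresholds()
  grouped <- unlist(lapply(db$groups, `[[`, "members"))
  n_ok <- 0; n_tot <- 0
  for (sp in names(db$haplotype_pool$cytb)) {
    for (h in 1:3) {
      q <- db$haplotype_pool$cytb[[sp]][h]
      call <- identify_sequence(q, db, "cytb", th)
      n_tot <- n_tot + 1
      if (sp %in% grouped) {
        # members of unresolvable groups must never get species-level calls
        expect_false(call$type == "species" && call$species %in% grouped)
        if (call$type == "group") n_ok <- n_ok + 1
      } else if (call$type == "species" && call$species == sp) {
        n_ok <- n_ok + 1
      }
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("calls are deterministic for fixed inputs", {
  db <- shared_db()
  q <- db$haplotype_pool$cytb[["Huso huso"]][2]
  hits <- best_hits(q, db, "cytb")
  pl <- place_query(q, db, "cytb", hits = hits)
  c1 <- call_species(hits, pl, db, "cytb")
  c2 <- call_species(hits, pl, db, "cytb")
  expect_identical(c1, c2)
  expect_equal(c1$species, "Huso huso")
})
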