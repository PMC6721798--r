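test_that("element lengths use 1-based inclusive arithmetic", {
  m <- element_map()
  expect_identical(element_length(m, "PAR"), 24L)
  expect_identical(element_length(m, "3RE"), 33L)
  m2 <- element_map(par = c(5, 5))
  expect_identical(element_length(m2, "PAR"), 1L)
  expect_error(element_length(m, "XYZ"), "available")
  expect_error(element_length(m, "IRE"), "unset")  # IRE start unconfigured
  expect_identical(element_length(element_map(ire = c(10, 57)), "IRE"), 48L)
})

test_that("variant annotation places the hyperferritinemia SNPs", {
  m <- element_map()
  g52 <- annotate_variant("G52C", m)
  expect_length(g52$overlaps, 0)
  expect_identical(g52$nearest, "PAR")
  expect_identical(g52$distance_nt, 1L)
  expect_identical(g52$direction, "upstream")

  g51 <- annotate_variant("G51C", m)
  expect_identical(g51$distance_nt, 2L)

  a15 <- annotate_variant("A15G", m)
  expect_true("IRP-contact loop" %in% a15$overlaps)

  pos60 <- annotate_variant("G60C", m)
  expect_setequal(pos60$overlaps, c("PAR", "3RE"))

  expect_error(annotate_variant("51C", m), "expected")
  expect_error(annotate_variant("G51X", m), "expected")
})

test_that("annotation containment agrees with element intervals", {
  m <- element_map()
  for (pos in c(53, 60, 76, 90)) {
    a <- annotate_variant(sprintf("A%dG", pos), m)
    for (el in intersect(a$overlaps, c("PAR", "3RE"))) {
      b <- m$intervals[[el]]
      expect_true(pos >= b[1] && pos <= b[2])
    }
  }
})

test_that("cap distances and the 60-nt steric rule match the constructs", {
  m <- element_map()
  expect_identical(cap_distance(m, "native"), 32L)
  expect_identical(cap_distance(m, "extended"), 70L)
  expect_identical(cap_distance(m, "extended") - cap_distance(m, "native"),
                   38L)
  expect_identical(steric_class(cap_distance(m, "native"), m), "full-block")
  expect_identical(steric_class(cap_distance(m, "extended"), m),
                   "partial-block")
  # strict inequality: the flip happens just past the threshold
  expect_identical(steric_class(60, m), "full-block")
  expect_identical(steric_class(61, m), "partial-block")
  expect_error(cap_distance(m, "circular"), "unknown construct")
})

test_that("construct edits apply 5'->3' with a correct lift-over", {
  utr <- synthetic_ftl_utr()
  specs <- ftl_construct_specs()

  dpar <- apply_construct(utr, specs$DPAR)
  expect_identical(nchar(dpar$sequence), nchar(utr) - 24L)
  d3re <- apply_construct(utr, specs$D3RE)
  expect_identical(nchar(d3re$sequence), nchar(utr) - 33L)

  loop <- apply_construct(utr, specs$LOOP)
  expect_identical(nchar(loop$sequence), nchar(utr))
  expect_identical(substr(loop$sequence, 15, 16), "GC")

  ext <- apply_construct(utr, specs$EXT)
  expect_identical(nchar(ext$sequence), nchar(utr) + 38L)

  # round trip: every kept position maps back to its original base
  lift <- d3re$liftover
  kept <- lift[!is.na(lift$new), ]
  orig <- strsplit(utr, "")[[1]]
  new <- strsplit(d3re$sequence, "")[[1]]
  expect_identical(new[kept$new], orig[kept$old])
  expect_true(all(is.na(lift$new[58:90])))
})

test_that("identity, mismatch and overlap handling are exact", {
  utr <- synthetic_ftl_utr()
  ident <- apply_construct(utr, construct_spec("WT", list()))
  expect_identical(ident$sequence, utr)
  expect_identical(ident$liftover$new, ident$liftover$old)

  wrong_ref <- construct_spec("bad", list(edit_substitution(15, "C", "G")))
  expect_error(apply_construct(utr, wrong_ref),
               "position 15.*expected C.*found A")
  expect_error(construct_spec("ov", list(edit_deletion(10, 20),
                                         edit_substitution(15, "A", "G"))),
               "overlapping")
})

test_that("edits compose: deletion then lifted substitution equals one pass", {
  utr <- synthetic_ftl_utr()
  composed <- apply_construct(utr, construct_spec("c", list(
    edit_deletion(53, 76), edit_substitution(100, substr(utr, 100, 100),
                                             "A"))))
  step1 <- apply_construct(utr, construct_spec("d", list(
    edit_deletion(53, 76))))
  lifted_pos <- step1$liftover$new[100]
  step2 <- apply_construct(step1$sequence, construct_spec("s", list(
    edit_substitution(lifted_pos, substr(step1$sequence, lifted_pos,
                                         lifted_pos), "A"))))
  expect_identical(step2$sequence, composed$sequence)
})

test_that("DNA input keeps the DNA alphabet and U/T are equivalent", {
  dna <- chartr("U", "T", synthetic_ftl_utr())
  out <- apply_construct(dna, construct_spec("loop", list(
    edit_substitution(17, "U", "C"))))  # ref given as RNA base
  expect_false(grepl("U", out$sequence))
  expect_identical(substr(out$sequence, 17, 17), "C")
})

test_that("the synthetic stand-in UTR carries the annotated anchor bases", {
  utr <- synthetic_ftl_utr()
  expect_identical(substr(utr, 15, 18), "AGUC")
  expect_identical(substr(utr, 51, 52), "GG")
  expect_identical(synthetic_ftl_utr(), synthetic_ftl_utr())  # seeded
})
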