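test_that("BW numbering follows the anchor offset rule within spans", {
  seqv <- paste(rep("A", 150), collapse = "")
  spans <- data.frame(helix = 3, start = 120, end = 140)
  bw <- assign_bw_numbers(seqv, spans, c("3" = 130))
  expect_equal(bw$bw[bw$resno == 130], "3.50")
  expect_equal(bw$bw[bw$resno == 132], "3.52")
  expect_equal(bw$bw[bw$resno == 120], "3.40")
  expect_equal(bw$bw, sprintf("3.%d", 40:60))   # 21 residues -> 3.40..3.60
})

test_that("missing or out-of-span anchors are rejected by helix name", {
  seqv <- paste(rep("A", 60), collapse = "")
  spans <- data.frame(helix = c(1, 2), start = c(1, 31), end = c(20, 50))
  expect_error(assign_bw_numbers(seqv, spans, c("1" = 10)),
               "helix 2")
  expect_error(assign_bw_numbers(seqv, spans, c("1" = 10, "2" = 25)),
               "helix 2.*span|outside")
})

test_that("helix blocks have one column per label-union entry with gaps only for absences", {
  mk_rec <- function(positions, letters) {
    bw <- data.frame(resno = seq_along(positions), helix = 3,
                     pos = positions,
                     bw = sprintf("3.%02d", positions), aa = letters)
    list(sequence = paste(letters, collapse = ""), bw_map = bw)
  }
  full <- mk_rec(48:52, c("L", "D", "R", "Y", "S"))
  blk <- align_helix_blocks(list(r1 = full, r2 = full), 3)
  expect_equal(unname(nchar(blk$rows)), c(5L, 5L))
  expect_false(any(grepl("-", blk$rows)))
  partial <- mk_rec(48:51, c("L", "D", "R", "Y"))
  blk2 <- align_helix_blocks(list(r1 = full, r2 = partial), 3)
  expect_equal(blk2$rows[["r2"]], "LDRY-")
  expect_equal(blk2$rows[["r1"]], "LDRYS")
  # random label sets: column count equals the size of the union
  gpcrnet:::with_seed(101, {
    recs <- lapply(1:4, function(i) {
      pos <- sort(sample(40:60, sample(5:10, 1)))
      mk_rec(pos, sample(gpcrnet:::AA_STATES, length(pos), TRUE))
    })
  })
  names(recs) <- paste0("r", 1:4)
  blk3 <- align_helix_blocks(recs, 3)
  u <- length(unique(unlist(lapply(recs, function(r) r$bw_map$pos))))
  expect_equal(nchar(blk3$rows[[1]]), u)
  expect_error(align_helix_blocks(list(r1 = full, r2 = full), 5), "helix 5")
})

test_that("pairwise alignment scores equal the exhaustive DP oracle", {
  pa <- pairwise_global("ACD", "AD")
  expect_equal(pa$score, oracle_align_score("ACD", "AD"))
  expect_equal(unname(pa$rows), c("ACD", "A-D"))
  gpcrnet:::with_seed(103, {
    for (i in 1:4) {
      a <- paste(sample(gpcrnet:::AA_STATES, sample(4:8, 1), TRUE),
                 collapse = "")
      b <- paste(sample(gpcrnet:::AA_STATES, sample(4:8, 1), TRUE),
                 collapse = "")
      expect_equal(pairwise_global(a, b)$score, oracle_align_score(a, b))
    }
  })
})

test_that("loop alignment handles identical, empty and divergent loops", {
  same <- c(r1 = "GESTK", r2 = "GESTK", r3 = "GESTK")
  blk <- align_loop(same, "el1")
  expect_false(any(grepl("-", blk$rows)))
  with_empty <- c(r1 = "GESTK", r2 = "", r3 = "GESK")
  blk2 <- align_loop(with_empty, "il2")
  W <- nchar(blk2$rows[[1]])
  expect_equal(blk2$rows[["r2"]], paste(rep("-", W), collapse = ""))
  expect_equal(gsub("-", "", blk2$rows[["r1"]]), "GESTK")
  expect_equal(gsub("-", "", blk2$rows[["r3"]]), "GESK")
})

test_that("composite width is the sum of block widths and round-trips FASTA", {
  recs <- list(r1 = toy_receptor("r1"), r2 = toy_receptor("r2", loop4 = 6),
               r3 = toy_receptor("r3", n_res = c(24L, 22L, rep(24L, 5))))
  ca <- composite_alignment(recs)
  widths <- vapply(ca$blocks, function(b) nchar(b$rows[[1]]), integer(1))
  expect_equal(nchar(ca$rows[[1]]), sum(widths))
  expect_equal(names(ca$blocks),
               c("TM1", "il1", "TM2", "el1", "TM3", "il2", "TM4",
                 "el2", "TM5", "il3", "TM6", "el3", "TM7"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_composite_fasta(ca, f)
  expect_identical(read_fasta(f)[names(ca$rows)], ca$rows)
})

test_that("stripping gaps from composite rows recovers the 7TM input sequences", {
  recs <- list(r1 = toy_receptor("r1"), r2 = toy_receptor("r2", loop4 = 5),
               r3 = toy_receptor("r3", n_res = c(24L, 22L, rep(24L, 5))))
  ca <- composite_alignment(recs)
  for (nm in names(recs)) {
    sp <- recs[[nm]]$helix_spans
    expected <- substr(recs[[nm]]$sequence, sp$start[1], sp$end[7])
    expect_identical(gsub("-", "", ca$rows[[nm]]), expected)
  }
})

test_that("the composite is invariant to input receptor order", {
  recs <- list(r1 = toy_receptor("r1"), r2 = toy_receptor("r2", loop4 = 6),
               r3 = toy_receptor("r3", n_res = c(24L, 22L, rep(24L, 5))))
  ca1 <- composite_alignment(recs)
  ca2 <- composite_alignment(recs[c(3, 1, 2)])
  expect_identical(ca1$rows, ca2$rows[names(ca1$rows)])
})

test_that("taxon mismatches across blocks are reported with offenders", {
  recs <- list(r1 = toy_receptor("r1"), r2 = toy_receptor("r2"))
  ann <- lapply(recs, function(r) {
    r$bw_map <- assign_bw_numbers(r$sequence, r$helix_spans, r$anchors)
    r
  })
  hb <- lapply(1:7, function(h) align_helix_blocks(ann, h))
  lb <- lapply(gpcrnet:::LOOP_IDS, function(id)
    align_loop(c(r1 = "GES", r2 = "GES"), id))
  lb_bad <- lb
  lb_bad[[2]]$rows <- c(r1 = "GES", rX = "GES")
  expect_s3_class(build_composite(hb, lb), "composite_alignment")
  expect_error(build_composite(hb, lb_bad), "rX|mismatch")
})
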