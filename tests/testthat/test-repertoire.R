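test_that("length filter removes strictly-longer sequences and logs them", {
  seqs <- c(ok = paste(rep("A", 1500), collapse = ""),
            long = paste(rep("A", 1501), collapse = ""))
  lf <- length_filter(seqs, 1500)
  expect_named(lf$kept, "ok")
  expect_equal(lf$removed$name, "long")
  expect_equal(lf$removed$length, 1501L)
  empty <- length_filter(stats::setNames(character(0), character(0)), 100)
  expect_length(empty$kept, 0)
  gpcrnet:::with_seed(131, {
    seqs2 <- stats::setNames(
      vapply(c(200, 300, 1600, 1700, 1800, 100),
             function(n) paste(sample(gpcrnet:::AA_STATES, n, TRUE),
                               collapse = ""), character(1)),
      sprintf("s%d", 1:6))
  })
  expect_equal(nrow(length_filter(seqs2, 1500)$removed), 3)
})

test_that("the farthest crystal-free family is extracted as one group", {
  tree <- paste0("((c1:0.1,m1:0.1):0.2,(c2:0.1,m2:0.1):0.2,",
                 "(x1:0.05,x2:0.05):1.5);")
  aln <- simulate_alignment(tree, 400, seed = 61)
  ex <- extract_farthest_group(aln, c("c1", "c2"), realign = FALSE)
  expect_setequal(names(ex$group), c("x1", "x2"))
  expect_setequal(names(ex$remainder), c("c1", "c2", "m1", "m2"))
  # completion: crystal-only input signals done
  expect_null(extract_farthest_group(aln[c("c1", "c2")], c("c1", "c2"),
                                     realign = FALSE))
  expect_error(extract_farthest_group(aln[c("m1", "m2")], c("c1", "c2")),
               "no crystal")
})

test_that("equally distant singletons are extracted lexicographically first", {
  seqs <- c(c1 = "WWWWKKKKRRRR",
            a  = "WWWWKKKKDDDD",
            b  = "WWWWKKKKDDDD")
  # a and b identical, hence equidistant from c1; 'a' must come out first
  ex <- extract_farthest_group(seqs, "c1", realign = FALSE)
  expect_true("a" %in% names(ex$group))
})

test_that("template assignment picks the closest-to-majority crystal", {
  fs <- make_family_set(3, 4, divergence = 0.1, inter_divergence = 1.0,
                        length = 250, seed = 62)
  templates <- fs$info$name[fs$info$is_template]
  for (fam in unique(fs$info$family)) {
    members <- fs$sequences[fs$info$name[fs$info$family == fam &
                                           !fs$info$is_template]]
    chosen <- assign_template(members, fs$sequences[templates])
    expect_equal(fs$info$family[match(chosen, fs$info$name)], fam)
  }
  # symmetric tie: two identical crystals -> lexicographic winner
  crystals <- c(tB = fs$sequences[[templates[1]]],
                tA = fs$sequences[[templates[1]]])
  expect_equal(assign_template(fs$sequences[1], crystals), "tA")
})

test_that("7TM trimming maps template span ends onto the query", {
  gpcrnet:::with_seed(63, {
    core <- paste(sample(gpcrnet:::AA_STATES, 160, TRUE), collapse = "")
  })
  template <- list(sequence = core, span = c(21, 140))
  expect_equal(trim_to_7tm(core, template), substr(core, 21, 140))
  # N-terminal extension is removed exactly
  ext <- paste0(paste(rep("M", 50), collapse = ""), core)
  expect_equal(trim_to_7tm(ext, template), substr(core, 21, 140))
  # internal insertion inside the span is retained
  ins <- paste0(substr(core, 1, 80), "GGGGG", substr(core, 81, 160))
  trimmed <- trim_to_7tm(ins, template)
  expect_equal(nchar(trimmed), 120 + 5)
  expect_true(grepl("GGGGG", trimmed))
  expect_error(trim_to_7tm(core, list(sequence = core, span = c(150, 10))),
               "span")
})

test_that("merged sets contain own-class members plus cross-class crystals", {
  groups <- list(
    list(group_id = "g1", members = c(r1 = "AAA", r2 = "CCC")),
    list(group_id = "g2", members = c(r3 = "DDD")),
    list(group_id = "g3", members = c(n1 = "EEE")))
  class_labels <- c(g1 = "rhodopsin", g2 = "rhodopsin", g3 = "non_rhodopsin")
  crystal_7tm <- c(cr1 = "WWW", cr2 = "KKK", cn1 = "YYY", cn2 = "HHH")
  crystal_classes <- c(cr1 = "rhodopsin", cr2 = "rhodopsin",
                       cn1 = "non_rhodopsin", cn2 = "non_rhodopsin")
  sets <- build_merged_sets(groups, class_labels, crystal_7tm,
                            crystal_classes)
  expect_setequal(names(sets$rhodopsin), c("r1", "r2", "r3", "cn1", "cn2"))
  expect_setequal(names(sets$non_rhodopsin), c("n1", "cr1", "cr2"))
  dup <- groups
  dup[[2]]$members <- c(r1 = "DDD")
  expect_error(build_merged_sets(dup, class_labels, crystal_7tm,
                                 crystal_classes), "duplicate")
  expect_error(build_merged_sets(groups, class_labels[-3], crystal_7tm,
                                 crystal_classes), "class label")
})

test_that("the full grouping run partitions every input sequence", {
  fs <- make_family_set(3, 4, divergence = 0.1, inter_divergence = 1.0,
                        length = 200, seed = 64)
  crystal <- fs$info$name[fs$info$is_template]
  long_decoy <- stats::setNames(
    paste(rep("A", 3000), collapse = ""), "decoy")
  res <- run_repertoire(c(fs$sequences, long_decoy), crystal,
                        max_len = 1500, max_groups = 3, realign = FALSE)
  grouped <- unlist(lapply(res$groups, function(g) names(g$members)))
  expect_false(anyDuplicated(grouped) > 0)
  expect_setequal(c(grouped, res$removed$name, crystal),
                  c(names(fs$sequences), "decoy"))
  # template assignment is perfect at 10x divergence contrast
  fam <- fs$info$family[match(res$table$name, fs$info$name)]
  tfam <- fs$info$family[match(res$table$template, fs$info$name)]
  expect_true(all(fam == tfam))
})
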