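test_that("contact extraction respects the distance cutoff exactly", {
  spec <- toy_receptor_spec()
  b_in <- make_toy_bundle(spec, pocket_resnos = 68, pocket_distance = 3.9)
  expect_true(68 %in% extract_ligand_contacts(b_in, cutoff = 4.0)$resno)
  b_out <- make_toy_bundle(spec, pocket_resnos = 68, pocket_distance = 4.1,
                           margin = 0.2)
  expect_false(68 %in% extract_ligand_contacts(b_out, cutoff = 4.0)$resno)
  expect_error(extract_ligand_contacts(b_in, ligand_resid = "XYZ"),
               "empty ligand selection")
  expect_error(extract_ligand_contacts(b_in, cutoff = -1), "cutoff")
})

test_that("planted pocket and sodium/water sites are recovered exactly", {
  b <- make_toy_bundle(toy_receptor_spec(), pocket_resnos = c(40, 68, 96),
                       ion_resnos = c(128, 156))
  pk <- extract_ligand_contacts(b, cutoff = 4.0, bw_map = b$bw_map,
                                helix_spans = b$helix_spans)
  expect_setequal(pk$resno, b$planted$pocket)
  expect_setequal(pk$bw, c("2.50", "3.50", "4.50"))
  na <- extract_sodium_site(b, cutoff = 4.0, bw_map = b$bw_map)
  expect_setequal(na$resno, b$planted$ion_site)
  # residue 156 only contacts a water probe, not the ion, yet is included
  ion_only <- gpcrnet:::contacts_to_probes(
    b, b$atoms[b$atoms$resid == "NA", ], 4.0)
  expect_false(156 %in% ion_only$resno)
  expect_true(156 %in% na$resno)
  # tiny cutoff: no residue contacts the ion site
  expect_equal(nrow(extract_sodium_site(b, cutoff = 0.5)), 0)
})

test_that("contact extraction is invariant under rigid motion of the structure", {
  b <- make_toy_bundle(toy_receptor_spec(), pocket_resnos = c(40, 68))
  at <- b$atoms
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at[, c("x", "y", "z")] <- sweep(xyz, 2, c(-12, 4, 30), "+")
  expect_setequal(extract_ligand_contacts(at, cutoff = 4.0)$resno,
                  extract_ligand_contacts(b, cutoff = 4.0)$resno)
})

test_that("pocket profiles share one position index with gaps for absences", {
  sets <- list(
    rA = data.frame(resno = 1:3, aa = c("D", "R", "W"),
                    bw = c("2.50", "3.50", "4.50")),
    rB = data.frame(resno = 1:3, aa = c("E", "K", "W"),
                    bw = c("2.50", "3.50", "4.50")))
  prof <- build_pocket_profiles(sets)
  expect_equal(prof$positions, c("2.50", "3.50", "4.50"))
  expect_false(any(grepl("-", prof$profiles)))
  sets$rB <- sets$rB[-2, ]       # rB lacks 3.50
  prof2 <- build_pocket_profiles(sets)
  expect_equal(substr(prof2$profiles[["rB"]], 2, 2), "-")
  # loop tags sort after helix positions
  sets$rA <- rbind(sets$rA, data.frame(resno = 9, aa = "G", bw = "el2"))
  prof3 <- build_pocket_profiles(sets)
  expect_equal(utils::tail(prof3$positions, 1), "el2")
  # duplicate positions within a receptor are rejected
  bad <- list(rA = data.frame(resno = 1:2, aa = c("D", "E"),
                              bw = c("2.50", "2.50")))
  expect_error(build_pocket_profiles(bad), "duplicate")
  # random sets: column count equals the position union
  gpcrnet:::with_seed(113, {
    rnd <- lapply(1:4, function(i) {
      n <- sample(3:6, 1)
      pos <- unique(sprintf("%d.%02d", sample(1:7, n, TRUE),
                            sample(40:60, n)))
      data.frame(resno = seq_along(pos),
                 aa = sample(gpcrnet:::AA_STATES, length(pos), TRUE),
                 bw = pos)
    })
  })
  names(rnd) <- paste0("r", 1:4)
  prof4 <- build_pocket_profiles(rnd)
  expect_equal(length(prof4$positions),
               length(unique(unlist(lapply(rnd, `[[`, "bw")))))
})

test_that("position removal drops exactly the named columns", {
  sets <- list(
    rA = data.frame(resno = 1:10, aa = strsplit("DRWYSTEKQN", "")[[1]],
                    bw = sprintf("3.%02d", 41:50)),
    rB = data.frame(resno = 1:10, aa = strsplit("ERWYSTEKQD", "")[[1]],
                    bw = sprintf("3.%02d", 41:50)))
  prof <- build_pocket_profiles(sets)
  v1 <- variant_without_positions(prof, "3.45")
  expect_length(v1$positions, 9)
  expect_false("3.45" %in% v1$positions)
  v2 <- variant_without_positions(prof, c("3.41", "3.42"))
  expect_setequal(setdiff(prof$positions, v2$positions), c("3.41", "3.42"))
  expect_equal(nchar(v2$profiles[["rA"]]), 8)
  expect_error(variant_without_positions(prof, "9.99"), "unknown")
  # dropped positions never reappear through shared_positions
  expect_false("3.45" %in% shared_positions(v1, prof))
})

test_that("shared positions are the intersection of the two site indexes", {
  a <- build_pocket_profiles(list(r = data.frame(
    resno = 1:4, aa = c("D", "N", "S", "W"),
    bw = c("2.50", "3.32", "3.36", "6.48"))))
  b_same <- a
  expect_setequal(shared_positions(a, b_same), a$positions)
  b_disj <- build_pocket_profiles(list(r = data.frame(
    resno = 1:2, aa = c("Y", "F"), bw = c("5.58", "7.43"))))
  expect_length(shared_positions(a, b_disj), 0)
  b_part <- build_pocket_profiles(list(r = data.frame(
    resno = 1:3, aa = c("D", "N", "F"), bw = c("2.50", "3.32", "7.43"))))
  expect_setequal(shared_positions(a, b_part), c("2.50", "3.32"))
})

test_that("planted two-class pockets separate into a positive-weight split", {
  prof <- two_class_profiles()
  ss <- neighbor_net(pocket_dist(prof, method = "p"))
  keys <- ss$splits$split[!vapply(ss$splits$split,
                                  gpcrnet:::is_trivial_split,
                                  logical(1), taxa = ss$taxa)]
  class_split <- gpcrnet:::split_key(c("a1", "a2", "a3"), ss$taxa)
  expect_true(class_split %in% keys)
  w <- ss$splits$weight[ss$splits$split == class_split]
  expect_gt(w, 0)
})

test_that("removing the conserved shared positions leaves the split set unchanged", {
  prof <- two_class_profiles()
  shared <- c("2.50", "7.49")
  reduced <- variant_without_positions(prof, shared)
  ss_full <- neighbor_net(pocket_dist(prof))
  ss_red <- neighbor_net(pocket_dist(reduced))
  expect_equal(compare_split_systems(ss_full, ss_red)$jaccard, 1.0)
})
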