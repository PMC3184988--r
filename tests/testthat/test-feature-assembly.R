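test_that("PSSM fixture round-trips through the ASCII parser", {
  fx <- make_pssm_fixture("ACD", seed = 3)
  p <- parse_pssm_ascii(fx)
  expect_equal(p$sequence, "ACD")
  expect_equal(dim(p$scores), c(3, 20))
  expect_equal(unname(p$scores), unname(attr(fx, "scores")))
  # diagonal conservation is each position's own-residue column
  expect_equal(p$diagonal,
               p$scores[cbind(1:3, match(c("A", "C", "D"),
                                         colnames(p$scores)))])
})

test_that("PSSM parser reports truncated rows with their line number", {
  fx <- make_pssm_fixture("ACD", seed = 3)
  bad <- fx
  bad[5] <- "    2 C   1 2 3"
  expect_error(parse_pssm_ascii(bad), "line 5")
  expect_error(parse_pssm_ascii(c("header only", "")), "no PSSM data rows")
})

test_that("parser reads files from disk too", {
  tmp <- withr::local_tempfile(fileext = ".pssm")
  make_pssm_fixture("GHKL", seed = 9, path = tmp)
  expect_equal(parse_pssm_ascii(tmp)$sequence, "GHKL")
})

test_that("labeling: ASA exclusion wins, distance rule splits the rest", {
  # three single-atom residues; heme iron 4.4 A from residue 1
  s <- make_chain(3, "line", spacing = 8)
  cx <- make_complex(s, list(data.frame(x = 0, y = 4.4, z = 0)))
  res <- protein_residues(cx, "A")
  hemes <- extract_heme_groups(cx)
  asa <- c(10, 10, 10)
  lab <- label_residues(res, asa, hemes, cutoff = 4.5)
  expect_equal(as.character(lab), c("binding", "nonbinding", "nonbinding"))
  # buried residue right next to the heme is still excluded
  lab2 <- label_residues(res, c(0, 10, 10), hemes, cutoff = 4.5)
  expect_equal(as.character(lab2)[1], "excluded")
  # any-heme rule: residue near only the second heme binds
  cx2 <- make_complex(s, list(data.frame(x = 0, y = 50, z = 0),
                              data.frame(x = 16, y = 4.0, z = 0)))
  res2 <- protein_residues(cx2, "A")
  lab3 <- label_residues(res2, asa, extract_heme_groups(cx2), cutoff = 4.5)
  expect_equal(as.character(lab3), c("nonbinding", "nonbinding", "binding"))
  # apo: no hemes, all surface residues non-binding
  lab4 <- label_residues(res, asa, list(), cutoff = 4.5)
  expect_true(all(lab4 == "nonbinding"))
})

test_that("label partition is exact over many random complexes", {
  for (seed in 1:5) {
    s <- cloud_structure(n = 12, seed = seed)
    cx <- make_complex(s, list(data.frame(x = 0, y = 0, z = 0)))
    res <- protein_residues(cx, "A")
    set.seed(seed)
    asa <- round(runif(12, 0, 5), 1)
    lab <- label_residues(res, asa, extract_heme_groups(cx))
    expect_equal(sum(lab == "binding") + sum(lab == "nonbinding") +
                   sum(lab == "excluded"), length(res))
    expect_true(all(lab[asa == 0] == "excluded"))
  }
})

test_that("label import overrides matched keys and reports unmatched", {
  s <- make_chain(10, "line")
  res <- protein_residues(s, "A")
  lab <- label_residues(res, rep(10, 10), list())
  tab <- data.frame(chain_id = "A", seq_num = c(5L, 9L), icode = "",
                    label = "binding")
  out <- import_labels(lab, res, tab)
  expect_equal(as.character(out[c(5, 9)]), c("binding", "binding"))
  expect_equal(sum(out == "binding"), 2)
  # empty table leaves labels unchanged
  expect_equal(as.character(import_labels(lab, res, tab[0, ])),
               as.character(lab))
  # one absent key among many is reported, not fatal
  tab2 <- data.frame(chain_id = "A", seq_num = c(1:9, 99L), icode = "",
                     label = "binding")
  out2 <- import_labels(lab, res, tab2)
  expect_equal(attr(out2, "unmatched")$seq_num, 99L)
  # mostly-unmatched tables are an error
  tab3 <- data.frame(chain_id = "A", seq_num = 90:99, icode = "",
                     label = "binding")
  expect_error(import_labels(lab, res, tab3), "match no residue")
})

test_that("spatial windows: order, padding, ties, permutation invariance", {
  s <- make_chain(16, "helix")
  res <- protein_residues(s, "A")
  w <- spatial_window(res, 8, k = 14)
  expect_length(w$indices, 15)
  expect_equal(w$indices[1], 8)
  expect_equal(w$padding, 0)
  expect_true(w$indices[2] %in% c(7, 9))  # nearest is a sequence neighbor

  # short chain: window shrinks and records padding
  s10 <- make_chain(10, "helix")
  w10 <- spatial_window(protein_residues(s10, "A"), 1, k = 14)
  expect_length(w10$indices, 10)
  expect_equal(w10$padding, 5)

  # equidistant neighbors: lower sequence position first
  s3 <- make_chain(3, "line", spacing = 4)
  w3 <- spatial_window(protein_residues(s3, "A"), 2, k = 1)
  expect_equal(w3$indices, c(2, 1))

  # neighbor set depends on coordinates, not input order
  sc <- cloud_structure(n = 12, seed = 3)
  rc <- protein_residues(sc, "A")
  ids <- vapply(rc, function(r) paste0(r$chain_id, r$seq_num), "")
  wa <- spatial_window(rc, 5, k = 6)
  rev_rc <- rev(rc)
  target_rev <- which(vapply(rev_rc, function(r) r$seq_num, 0L) ==
                        rc[[5]]$seq_num)
  wb <- spatial_window(rev_rc, target_rev, k = 6)
  ids_a <- sort(ids[wa$indices[-1]])
  ids_b <- sort(vapply(rev_rc[wb$indices[-1]],
                       function(r) paste0(r$chain_id, r$seq_num), ""))
  expect_equal(ids_a, ids_b)
})

test_that("logistic scaling is the standard squashing function", {
  expect_equal(logistic_scale(0), 0.5)
  expect_lt(logistic_scale(-50), 1e-20)
  expect_gte(logistic_scale(50), 1 - 1e-12)
  x <- sort(rnorm(100))
  expect_true(all(diff(logistic_scale(x)) > 0))
  expect_equal(inv_logistic(logistic_scale(1.7)), 1.7, tolerance = 1e-12)
})

test_that("assembled matrix has the documented width, range and padding", {
  fx <- helix_heme_complex()
  pssm <- parse_pssm_ascii(make_pssm_fixture(strrep("G", 16), seed = 4))
  cf <- chain_features(fx$holo, "A", pssm = pssm)
  expect_equal(ncol(cf$matrix), (4 + 1 + 6 + 6 + 20) * 15)
  expect_true(all(cf$matrix >= 0 & cf$matrix <= 1))

  cfN <- chain_features(fx$holo, "A",
                        config = hemenet_config(mask = "N"))
  expect_equal(ncol(cfN$matrix), 4 * 15)

  # short chain: padded slots are exact zeros across the whole block
  s5 <- make_chain(5, "helix", full_backbone = TRUE)
  cf5 <- chain_features(s5, "A", pssm = parse_pssm_ascii(
    make_pssm_fixture("GGGGG", seed = 1)))
  last_block <- cf5$matrix[, (14 * 37 + 1):(15 * 37)]
  expect_true(all(last_block == 0))
  # non-padded entries are strictly positive (logistic floor / RASA >= 0)
  first_block <- cf5$matrix[, 1:37]
  expect_true(all(first_block[, -5] > 0))
})

test_that("RASA enters unscaled; topology block inverts to raw z-scores", {
  fx <- helix_heme_complex()
  cf <- chain_features(fx$holo, "A", config = hemenet_config(mask = c("N", "G")))
  surf_rows <- cf$surface_index
  # RASA column of the target slot equals the raw RASA
  expect_equal(unname(cf$matrix[, "w01_rasa"]),
               cf$surface$rasa[surf_rows])
  # inverse logistic of the target topology block recovers the z-scores
  expect_equal(unname(inv_logistic(cf$matrix[, "w01_z_degree"])),
               cf$topology$z_degree[surf_rows], tolerance = 1e-9)
  expect_equal(unname(inv_logistic(cf$matrix[, "w01_z_clustering"])),
               cf$topology$z_clustering[surf_rows], tolerance = 1e-9)
})

test_that("PSSM/structure length mismatches are reported with both lengths", {
  fx <- helix_heme_complex()
  short <- parse_pssm_ascii(make_pssm_fixture("GGG", seed = 1))
  expect_error(chain_features(fx$holo, "A", pssm = short), "3.*16|16.*3")
  expect_error(chain_features(fx$holo, "A",
                              config = hemenet_config(mask = c("N", "C"))),
               "no PSSM")
})
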