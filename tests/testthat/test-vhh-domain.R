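test_that("AHo regions partition positions 1-149", {
  reg <- aho_regions()
  expect_equal(sum(reg$end - reg$start + 1L), 149L)
  labels <- aho_region(1:149)
  expect_false(anyNA(labels))
  # every position belongs to exactly one region and boundaries match
  expect_equal(aho_region(c(26, 27, 42, 43, 44, 56, 57, 69, 70, 107, 108, 138, 139)),
               c("FR1", "HCDR1", "HCDR1", "FR2", "FR2", "FR2", "HCDR2",
                 "HCDR2", "FR3", "FR3", "HCDR3", "HCDR3", "FR4"))
  expect_error(aho_region(150), "out of range")
  expect_error(aho_region(0), "out of range")
})

test_that("aho_sequences validates length and alphabet", {
  good <- paste(rep("A", 149), collapse = "")
  expect_equal(nrow(aho_sequences(good)), 1L)
  expect_error(aho_sequences(substr(good, 1, 120)), "149")
  bad <- paste0("B", substr(good, 2, 149))
  expect_error(aho_sequences(bad), "illegal")
  perm <- aho_sequences(bad, strict = FALSE)
  expect_equal(substr(perm$seq, 1, 1), "X")
})

test_that("read_aho_fasta parses records in order and rejects bad lengths", {
  s1 <- paste(rep("A", 149), collapse = "")
  s2 <- paste0(strrep("-", 10), strrep("G", 139))
  fa <- c(">one desc", s1, ">two", substr(s2, 1, 80), substr(s2, 81, 149))
  out <- read_aho_fasta(paste(fa, collapse = "\n"))
  expect_equal(out$id, c("one", "two"))
  expect_equal(out$seq, c(s1, s2))
  expect_error(read_aho_fasta(">x\nACDE"), "149")
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(fa, tmp)
  expect_equal(read_aho_fasta(tmp), out)
})

make_seq_with_cys <- function(cys_pos) {
  ch <- rep("A", 149)
  ch[cys_pos] <- "C"
  aho_sequences(paste(ch, collapse = ""))
}

test_that("cysteine_profile captures canonical pair, anchors and HCDR3 cys", {
  p <- cysteine_profile(make_seq_with_cys(c(23, 106)))
  expect_equal(p$n_cys, 2L)
  expect_true(p$has_canonical_pair)
  expect_length(p$hcdr3_cys[[1]], 0L)

  p2 <- cysteine_profile(make_seq_with_cys(c(23, 57, 115, 106)))
  expect_equal(p2$n_cys, 4L)
  expect_equal(p2$anchor_cys[[1]], 57L)
  expect_equal(p2$hcdr3_cys[[1]], 115L)

  p3 <- cysteine_profile(make_seq_with_cys(integer()))
  expect_equal(p3$n_cys, 0L)
  expect_false(p3$has_canonical_pair)
})

test_that("ncdb_candidates applies all three criteria and is monotone", {
  expect_true(ncdb_candidates(make_seq_with_cys(c(23, 57, 115, 106)))$ncdb_candidate)
  expect_false(ncdb_candidates(make_seq_with_cys(c(23, 106)))$ncdb_candidate)
  expect_false(ncdb_candidates(make_seq_with_cys(c(23, 50, 115, 106)))$ncdb_candidate)
  # six cysteines: too many
  expect_false(ncdb_candidates(make_seq_with_cys(c(23, 40, 57, 110, 115, 106)))$ncdb_candidate)
  # removing a required cysteine never flips FALSE -> TRUE
  base <- c(23, 57, 115, 106)
  for (drop in base) {
    reduced <- ncdb_candidates(make_seq_with_cys(setdiff(base, drop)))$ncdb_candidate
    expect_false(reduced && !ncdb_candidates(make_seq_with_cys(base))$ncdb_candidate)
  }
})

test_that("dedup_by_cdrs collapses identical CDR triplets", {
  ch <- rep("A", 149)
  mk <- function(fr1, cdr3) {
    x <- ch
    x[1] <- fr1
    x[110:115] <- strsplit(cdr3, "")[[1]]
    paste(x, collapse = "")
  }
  seqs <- aho_sequences(c(mk("A", "GGGGGG"), mk("V", "GGGGGG"), mk("A", "WWWWWW")),
                        id = c("a", "b", "c"))
  out <- dedup_by_cdrs(seqs)
  expect_equal(out$id, c("a", "c"))
  # quality key picks the better representative
  out2 <- dedup_by_cdrs(seqs, quality = c(1, 5, 0))
  expect_equal(sort(out2$id), c("b", "c"))
  # all distinct: identity; empty: empty
  expect_equal(dedup_by_cdrs(seqs[c(1, 3), ]), seqs[c(1, 3), ])
  expect_equal(nrow(dedup_by_cdrs(seqs[0, ])), 0L)
})

test_that("PDB round trip preserves coordinates to 1e-3 and numbering maps apply", {
  toy <- make_toy_vhh("kinked", seed = 3)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_vhh_pdb(toy$atoms, tmp)
  back <- read_vhh_structure(tmp, id = "toy_kinked")
  expect_equal(nrow(back), nrow(toy$atoms))
  ord0 <- order(toy$atoms$aho, toy$atoms$atom)
  ord1 <- order(back$aho, back$atom)
  expect_equal(back$x[ord1], toy$atoms$x[ord0], tolerance = 1e-3)
  expect_equal(back$z[ord1], toy$atoms$z[ord0], tolerance = 1e-3)
  expect_equal(back$aa[ord1], toy$atoms$aa[ord0])

  # numbering map shifts residues
  map <- data.frame(author = as.character(sort(unique(toy$atoms$aho))),
                    aho = sort(unique(toy$atoms$aho)) )
  map$aho[map$author == "1"] <- 149L
  shifted <- read_vhh_structure(tmp, numbering = map)
  expect_true(149L %in% shifted$aho)
  expect_false(1L %in% shifted$aho)
})

test_that("minimal hand-written PDB parses with identity numbering", {
  lines <- c(
    "ATOM      1  CA  ALA A 105      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A 106      13.800  10.000  10.000  1.00  0.00           C",
    "ATOM      3  CA  SER A 107      17.600  10.000  10.000  1.00  0.00           C",
    "END"
  )
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  st <- read_vhh_structure(tmp)
  expect_equal(st$aho, c(105L, 106L, 107L))
  expect_equal(st$aa, c("A", "G", "S"))

  # two chains without a selector -> error; with selector -> works
  lines2 <- c(lines[1:3],
    "ATOM      4  CA  ALA B  10       1.000   2.000   3.000  1.00  0.00           C",
    "END")
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines2, tmp2)
  expect_error(read_vhh_structure(tmp2), "chains")
  stB <- read_vhh_structure(tmp2, chain = "B")
  expect_equal(stB$aho, 10L)
})

test_that("altloc is resolved to highest occupancy and hydrogens are dropped", {
  lines <- c(
    "ATOM      1  CA AALA A 105      10.000  10.000  10.000  0.40  0.00           C",
    "ATOM      2  CA BALA A 105      11.000  10.000  10.000  0.60  0.00           C",
    "ATOM      3  H   ALA A 105      12.000  10.000  10.000  1.00  0.00           H",
    "END"
  )
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  st <- read_vhh_structure(tmp)
  expect_equal(nrow(st), 1L)
  expect_equal(st$x, 11.0)
})

test_that("mmCIF atom records parse through the same surface", {
  cif <- c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 105 ? 1.000 2.000 3.000 1.00 0.00 ? 105 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 105 ? 2.000 2.500 3.000 1.00 0.00 ? 105 ALA A CA 1",
    "ATOM 3 C CA . GLY A 1 106 ? 5.500 2.500 3.000 1.00 0.00 ? 106 GLY A CA 1"
  )
  tmp <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, tmp)
  st <- read_vhh_structure(tmp)
  expect_equal(st$aho, c(105L, 105L, 106L))
  expect_equal(st$atom, c("N", "CA", "CA"))
  expect_equal(st$y, c(2.0, 2.5, 2.5))
})

test_that("structure_sequence is consistent with residue amino acids", {
  toy <- make_toy_vhh("kinked", ncdb = c(57, 115), seed = 2)
  seq <- structure_sequence(toy$atoms)$seq
  expect_equal(nchar(seq), 149L)
  expect_equal(substr(seq, 23, 23), "C")
  expect_equal(substr(seq, 44, 44), "F")
  expect_equal(substr(seq, 109, 109), "-")  # unoccupied slot
})
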