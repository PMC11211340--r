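test_that("base-position map loads with 19 validated positions", {
  map <- load_base_position_map()
  expect_s3_class(map, "fc_base_map")
  expect_equal(nrow(map), 19)
  expect_true(all(diff(map$kabat) > 0))
  expect_true(all(diff(map$pdb) > 0))
  expect_equal(map$index[map$conserved], c(4, 12, 16, 18))
  expect_equal(map$pdb[map$conserved], c(354, 418, 440, 443))
  ## spot-check rows of the catalogue
  expect_equal(map$kabat[map$index == 4], 374)
  expect_equal(map$variants[map$index == 4], "P")
  expect_equal(sort(strsplit(map$variants[map$index == 6], "/")[[1]]),
               sort(c("E", "A", "K", "R", "Q")))
  expect_false(map$conserved[map$index == 6])
})

test_that("corrupt base-map fixtures are rejected naming the offending row", {
  map <- as.data.frame(load_base_position_map())
  bad <- map
  bad$variants[7] <- "E/Z"
  f <- tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(load_base_position_map(f), "row 7")
  bad <- map
  bad$conserved[4] <- FALSE
  write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(load_base_position_map(f), "row 4")
  bad <- map
  bad$pdb[10] <- 300
  write.csv(bad, f, row.names = FALSE, quote = FALSE)
  expect_error(load_base_position_map(f), "strictly increasing")
})

test_that("residue classification partitions the 20 standard residues 8/7/3/2", {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  cls <- classify_residue(aa20)
  expect_false(any(cls == "unknown"))
  counts <- table(cls)
  expect_equal(unname(counts["hydrophobic"]), 8L)
  expect_equal(unname(counts["hydrophilic"]), 7L)
  expect_equal(unname(counts["positive"]), 3L)
  expect_equal(unname(counts["negative"]), 2L)
  expect_equal(classify_residue("W"), "hydrophobic")
  expect_equal(classify_residue("E"), "negative")
  expect_equal(classify_residue("T"), "hydrophilic")
  expect_equal(classify_residue("Y"), "hydrophilic")
  expect_equal(classify_residue("H"), "positive")
  expect_equal(classify_residue("Z"), "unknown")
})

test_that("base motif summary classifies the dimer and is chain-symmetric", {
  dimer <- make_ch3_dimer()
  s <- base_motif_summary(dimer)
  expect_equal(nrow(s), 38)
  expect_equal(sum(s$chain == "B"), 19)
  b <- s[s$chain == "B", ]
  ## hydrophobic core positions plus flanking charged residues
  expect_true(all(b$class[b$pdb %in% c(351, 352, 353, 354, 355, 359)] ==
                    "hydrophobic"))
  expect_equal(b$class[b$pdb == 356], "negative")
  expect_equal(b$class[b$pdb == 444], "positive")
  expect_equal(b$class[b$pdb == 360], "hydrophilic")
  expect_true(all(s$in_variants))
  ## chain swap leaves the per-position summary unchanged
  d <- s[s$chain == "D", ]
  expect_equal(b[, setdiff(names(b), "chain")], d[, setdiff(names(d), "chain")],
               ignore_attr = TRUE)
})

test_that("base motif summary fails listing missing residues", {
  dimer <- make_ch3_dimer()
  broken <- dimer[!(dimer$chain == "B" & dimer$resno == 444), ]
  class(broken) <- c("fc_structure", "data.frame")
  expect_error(base_motif_summary(broken), "444")
})

test_that("net-charge bisection reproduces the two-group midpoint and zero crossing", {
  ## glycine: only termini ionise -> pI at the midpoint of their pKas
  expect_equal(isoelectric_point("G"), (9.0 + 2.0) / 2, tolerance = 1e-3)
  expect_lt(abs(net_charge("G", isoelectric_point("G"))), 1e-2)
})

test_that("pI bisection agrees with direct root finding on random sequences", {
  set.seed(42)
  aa20 <- names(fcbase:::RESIDUE_MASS)
  for (i in 1:100) {
    s <- paste(sample(aa20, sample(5:40, 1), replace = TRUE), collapse = "")
    root <- uniroot(function(p) net_charge(s, p), c(0, 14), tol = 1e-9)$root
    expect_equal(isoelectric_point(s), root, tolerance = 2e-3)
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-2)
  }
})

test_that("appending an acidic residue never raises the pI", {
  set.seed(11)
  aa20 <- names(fcbase:::RESIDUE_MASS)
  for (i in 1:20) {
    s <- paste(sample(aa20, sample(3:20, 1), replace = TRUE), collapse = "")
    expect_lte(isoelectric_point(paste0(s, "D")), isoelectric_point(s) + 1e-3)
  }
})

test_that("molecular weight sums average residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 0.05)
  ## additivity: Mwt(AB) = Mwt(A) + Mwt(B) - water
  a <- "ACDEFG"; b <- "WYKR"
  expect_equal(molecular_weight(paste0(a, b)),
               molecular_weight(a) + molecular_weight(b) - 18.0153,
               tolerance = 1e-6)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("ABZ"), "unknown residue")
})

test_that("FASTA round trip preserves ids, labels and sequences", {
  rec <- data.frame(id = c("1IGT", "4C55"),
                    label = c("mouse IgG2a", "human IgG4"),
                    seq = c("ACDEFGHIK", "LMNPQRSTVWY"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_equal(back$id, rec$id)
  expect_equal(back$label, rec$label)
  expect_equal(back$seq, rec$seq)
})
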