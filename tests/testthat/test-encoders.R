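test_that("tokenize truncates to k N-terminal residues and post-pads", {
  t1 <- tokenize("FLPKA", k = 15)
  expect_length(t1, 15L)
  expect_equal(t1[1:5], c("F", "L", "P", "K", "A"))
  expect_equal(t1[6:15], rep("-", 10))

  long <- strrep("F", 20)
  expect_equal(tokenize(long, k = 15), rep("F", 15))
  expect_equal(tokenize("AC", k = 2), c("A", "C"))
  expect_error(tokenize("", k = 5), "empty")
  expect_error(tokenize("ACD", k = 0), "positive")
})

test_that("BPF rows are one-hot in canonical order and PAD rows are zero", {
  m <- encodeBPF(tokenize("AV", k = 4))
  expect_equal(dim(m), c(4L, 20L))
  expect_equal(unname(m[1, ]), c(1, rep(0, 19)))          # A hot at index 1
  expect_equal(unname(m[2, ]), c(rep(0, 19), 1))          # V hot at index 20
  expect_equal(unname(m[3, ]), rep(0, 20))                # PAD
  expect_equal(rowSums(m), c(A = 1, V = 1, `-` = 0, `-` = 0),
               ignore_attr = TRUE)
  ## every residue is hot exactly at its canonical position
  all20 <- encodeBPF(tokenize(paste(aminoAcidOrder(), collapse = ""), k = 20))
  expect_equal(unname(all20), diag(20))
})

test_that("the 31-bit physicochemical rows obey the partition structure", {
  tab <- loadPropertyTable()
  expect_length(tab@overlapGroups, 10L)
  expect_length(tab@attributes, 7L)
  m <- encodePhyschem(tokenize(paste(aminoAcidOrder(), collapse = ""), k = 20),
                      tab)
  expect_equal(dim(m), c(20L, 31L))
  expect_true(all(m %in% c(0, 1)))
  ## 21-bit segment: exactly one group per attribute -> 7 ones per residue
  expect_equal(unname(rowSums(m[, 11:31])), rep(7, 20))
  ## charge attribute: D and E share the acidic group, and K has exactly one
  ## charge bit
  bits <- propertyBits(tab)
  chargeCols <- grep("^charge\\.", colnames(bits))
  expect_equal(bits["D", chargeCols], bits["E", chargeCols])
  expect_equal(sum(bits["K", chargeCols]), 1)
  ## PAD rows all-zero
  expect_equal(unname(encodePhyschem(tokenize("A", k = 3), tab)[2:3, ]),
               matrix(0, 2, 31))
})

test_that("structurally invalid property tables are rejected by name", {
  lines <- readLines(system.file("extdata", "property_groups.tsv",
                                 package = "ACPcnn"))
  ## duplicate a residue inside one attribute's partition
  broken <- sub("^charge_positive\tattribute:charge:1\tKR$",
                "charge_positive\tattribute:charge:1\tKRD", lines)
  f <- tempfile(); writeLines(broken, f)
  expect_error(loadPropertyTable(f), "charge.*partition|partition.*charge")
  ## drop W from one attribute
  broken2 <- sub("^polz_high\tattribute:polarizability:3\tKMHFRYW$",
                 "polz_high\tattribute:polarizability:3\tKMHFRY", lines)
  f2 <- tempfile(); writeLines(broken2, f2)
  expect_error(loadPropertyTable(f2), "polarizability.*W")
})

test_that("the shipped BLOSUM62 matches the published scores", {
  sm <- loadSubstitutionMatrix()
  expect_equal(dim(sm@scores), c(20L, 20L))
  expect_true(isSymmetric(sm@scores))
  ## independent oracle: the published matrix as distributed by Biostrings
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  ref <- env$BLOSUM62[aminoAcidOrder(), aminoAcidOrder()]
  expect_equal(unname(sm@scores), unname(ref))

  m <- encodeBlosum(tokenize("A", k = 2), sm)
  expect_equal(m["A", "A"], 4)
  expect_equal(unname(m[2, ]), rep(0, 20))
  ## row i column j equals row j column i for all residues
  expect_true(all(sm@scores == t(sm@scores)))
})

test_that("asymmetric or incomplete matrix files are rejected", {
  f <- writeIdentityMatrixFile()
  lines <- readLines(f)
  ## corrupt entry (A,R) only
  row <- strsplit(lines[3], "\\s+")[[1]]
  row[3] <- "9"
  broken <- lines; broken[3] <- paste(row, collapse = " ")
  fb <- tempfile(); writeLines(broken, fb)
  expect_error(loadSubstitutionMatrix(fb), "asymmetric")
  ## missing canonical residue
  fm <- tempfile(); writeLines(lines[-3], fm)
  expect_error(loadSubstitutionMatrix(fm), "missing canonical")
})

test_that("an identity substitution matrix reduces BLO62 to BPF", {
  ident <- loadSubstitutionMatrix(writeIdentityMatrixFile(), name = "identity")
  toks <- tokenize("KWKLFKACDV", k = 15)
  expect_equal(unname(encodeBlosum(toks, ident)), unname(encodeBPF(toks)))
})

test_that("encodeDataset stacks share ordering, shapes and labels", {
  ps <- generateSynthetic(syntheticSpec(nPos = 6, nNeg = 4, seed = 8))
  es <- encodeDataset(ps, "C7")
  expect_named(es@stacks, c("BPF", "PHYSCHEM", "BLO62"))
  expect_equal(vapply(es@stacks, function(a) dim(a)[3], 1L),
               c(BPF = 20L, PHYSCHEM = 31L, BLO62 = 20L))
  expect_true(all(vapply(es@stacks, function(a) dim(a)[1], 1L) == 10L))
  expect_equal(es@labels, labels(ps))
  expect_equal(es@ids, names(ps))
  ## single representation, and code resolution
  expect_named(encodeDataset(ps, "C3")@stacks, "BLO62")
  expect_named(encodeDataset(ps, c("BLO62", "BPF"))@stacks,
               c("BPF", "BLO62"))
  expect_error(encodeDataset(ps, character(0)), "combination")

  ## per-record stack rows agree with the single-sequence encoders
  sm <- loadSubstitutionMatrix(); tab <- loadPropertyTable()
  i <- 3L
  toks <- tokenize(sequences(ps)[[i]], k = 15)
  expect_equal(unname(es@stacks$BPF[i, , ]), unname(encodeBPF(toks)))
  expect_equal(unname(es@stacks$PHYSCHEM[i, , ]),
               unname(encodePhyschem(toks, tab)))
  expect_equal(unname(es@stacks$BLO62[i, , ]), unname(encodeBlosum(toks, sm)))
})

test_that("full-sequence mode uses the longest sequence as k", {
  ps <- PeptideSet(c(a = "ACDEFGHIKL", b = strrep("KV", 19)),
                   labels = c(1, 0))
  es <- encodeDataset(ps, "C1", k = "max")
  expect_equal(es@k, 38L)
  expect_equal(dim(es@stacks$BPF)[2], 38L)
})

test_that("encoding is position-local", {
  s1 <- "KWKLFKACDVKWKLF"
  s2 <- paste0(substr(s1, 1, 4), "W", substr(s1, 6, nchar(s1)))  # change position 5
  ps <- PeptideSet(c(a = s1, b = s2), labels = c(1, 1))
  es <- encodeDataset(ps, "C7")
  for (r in names(es@stacks)) {
    diffRows <- which(apply(es@stacks[[r]][1, , ] != es@stacks[[r]][2, , ], 1,
                            any))
    expect_equal(diffRows, 5L, info = r)
  }
})
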