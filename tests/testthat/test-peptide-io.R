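test_that("FASTA headers with |label tokens and forced labels both parse", {
  f <- writeTempFasta(c(">p1|1", "FLPK", ">p2|0", "GGGG"))
  ps <- readFasta(f)
  expect_s4_class(ps, "PeptideSet")
  expect_equal(names(ps), c("p1", "p2"))
  expect_equal(unname(sequences(ps)), c("FLPK", "GGGG"))
  expect_equal(labels(ps), c(1L, 0L))

  f2 <- writeTempFasta(c(">a", "ACDE", ">b", "FGHI", ">c", "KLMN"))
  expect_equal(labels(readFasta(f2, label = 1)), rep(1L, 3))
  expect_true(all(is.na(labels(readFasta(f2)))))

  ## multi-line sequences are concatenated
  f3 <- writeTempFasta(c(">m|1", "ACDEF", "GHIKL"))
  expect_equal(unname(sequences(readFasta(f3))), "ACDEFGHIKL")
})

test_that("malformed FASTA and invalid residues are rejected with context", {
  f <- writeTempFasta(c("FLPK", ">p1", "ACDE"))
  expect_error(readFasta(f), "line 1")

  fb <- writeTempFasta(c(">bad|1", "ACBDE"))
  expect_error(readFasta(fb), "B")
  expect_warning(skipped <- readFasta(fb, onInvalid = "skip"), "bad")
  expect_equal(length(skipped), 0L)
  expect_warning(masked <- readFasta(fb, onInvalid = "zero"), "mask")
  expect_equal(unname(sequences(masked)), "ACXDE")
})

test_that("sequence normalization uppercases, trims and strips stops", {
  expect_warning(ps <- PeptideSet(" flpka* ", ids = "s1"), "stop")
  expect_equal(unname(sequences(ps)), "FLPKA")
  expect_error(PeptideSet(character(0)), NA)  # empty set constructs
  expect_error(PeptideSet("", ids = "e"), "length")
  expect_error(PeptideSet(c(a = "ACD", a = "GHK")), "duplicated")
})

test_that("FASTA round trip is lossless for ids, sequences and labels", {
  ps <- generateSynthetic(syntheticSpec(nPos = 7, nNeg = 5, seed = 3))
  f <- tempfile(fileext = ".fasta")
  writeFasta(ps, f)
  back <- readFasta(f)
  expect_equal(names(back), names(ps))
  expect_equal(sequences(back), sequences(ps))
  expect_equal(labels(back), labels(ps))
  ## header dialect: labelled record ends in |<label>
  expect_match(readLines(f)[1], "\\|1$")
  expect_error(writeFasta(ps[integer(0)], tempfile()), "empty")
})

test_that("label manifests override labels by id", {
  ps <- PeptideSet(c(x = "ACDE", y = "FGHK"))
  mf <- tempfile()
  writeLines(c("# id label", "x 1", "y 0"), mf)
  ps2 <- applyLabelManifest(ps, mf)
  expect_equal(labels(ps2), c(1L, 0L))
})

test_that("the synthetic generator honours counts, motif planting and seed", {
  spec <- syntheticSpec(nPos = 25, nNeg = 15, motif = "KWKLFK",
                        motifWindow = 5, signalProb = 1, seed = 9)
  ps <- generateSynthetic(spec)
  labs <- labels(ps)
  expect_equal(sum(labs == 1), 25L)
  expect_equal(sum(labs == 0), 15L)
  ## signalProb = 1: every positive carries the motif within the window
  starts <- regexpr("KWKLFK", sequences(ps)[labs == 1], fixed = TRUE)
  expect_true(all(starts >= 1 & starts <= spec@motifWindow + 1))
  ## byte-identical regeneration from the same spec
  expect_identical(sequences(generateSynthetic(spec)), sequences(ps))
  expect_identical(labels(generateSynthetic(spec)), labs)

  ## signalProb = 0: classes are distributionally identical; motif occurs
  ## only by chance in either class
  ps0 <- generateSynthetic(syntheticSpec(nPos = 200, nNeg = 200,
                                         signalProb = 0, seed = 2))
  hits <- grepl("KWKLFK", sequences(ps0), fixed = TRUE)
  expect_lte(abs(sum(hits[labels(ps0) == 1]) - sum(hits[labels(ps0) == 0])), 2)
})

test_that("infeasible synthetic specs are rejected", {
  expect_error(syntheticSpec(motif = "KWKLFKKWKLFK", lengthRange = c(10, 50)),
               "infeasible")
  expect_error(syntheticSpec(signalProb = 1.5), "signalProb")
  expect_error(syntheticSpec(motif = "KWB"), "motif")
})
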