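test_that("reaction-table parsing produces the expected stoichiometry", {
  cases <- list(
    list(text = "R1: A -> B",
         S = matrix(c(-1, 1), 2, dimnames = list(c("A", "B"), "R1"))),
    list(text = "R1: A -> B\nR2: B -> C",
         S = matrix(c(-1, 1, 0, 0, -1, 1), 3,
                    dimnames = list(c("A", "B", "C"), c("R1", "R2")))),
    list(text = "R1: 2 A -> B",
         S = matrix(c(-2, 1), 2, dimnames = list(c("A", "B"), "R1")))
  )
  for (cs in cases) {
    m <- parseReactionTable(cs$text)
    expect_identical(stoichiometry(m), cs$S)
  }
  # coefficients on both sides, reversibility, comments, external species
  m <- parseReactionTable(c(
    "# a comment",
    "external: X",
    "R1: A + 2 B <-> 3 C + X",
    "R2: C -> A"))
  expect_identical(stoichiometry(m)[, "R1"], c(A = -1, B = -2, C = 3))
  expect_identical(unname(reversible(m)), c(TRUE, FALSE))
  expect_false("X" %in% speciesNames(m))
})

test_that("parser reports malformed input with context", {
  expect_error(parseReactionTable("R1: A -> B\nR1: B -> C"), "duplicate")
  expect_error(parseReactionTable("R1: A -> B\ngarbage line"), "line 2")
  expect_error(parseReactionTable("R1: ->"), "no species")
  expect_error(parseReactionTable("external: A\nR1: A -> A"),
               "no balanced species")
})

test_that("species removal and re-addition round-trip the matrix", {
  m <- parseReactionTable("R1: A -> B\nR2: B -> C")
  m2 <- removeSpecies(m, "C")
  expect_identical(stoichiometry(m2)[, "R2"], c(A = 0, B = -1))
  expect_identical(stoichiometry(removeSpecies(m, character())),
                   stoichiometry(m))
  # remove then re-add with the original row restores S (row appended last)
  rowC <- stoichiometry(m)["C", ]
  m3 <- addSpecies(m2, "C", rowC)
  expect_equal(stoichiometry(m3)[c("A", "B", "C"), ], stoichiometry(m))
  expect_error(removeSpecies(m, "Z"), "not in model")
  expect_error(addSpecies(m, "D", 1), "one entry per reaction")
  # removal that strands a reaction is reported, not silent
  expect_warning(removeSpecies(parseReactionTable("R1: A -> B\nR2: C -> D"),
                               c("C", "D")),
                 "dropped: R2")
})

test_that("partition preserves order, flags boundary cases, and recombines", {
  m <- parseReactionTable("R1: A -> B\nR2: B -> C")
  p <- partitionModel(m, "R1")
  expect_identical(calcNames(p), "R2")
  expect_identical(obsNames(p), "R1")
  expect_identical(p@So, stoichiometry(m)[, "R1", drop = FALSE],
                   ignore_attr = TRUE)
  expect_warning(partitionModel(m, c("R1", "R2")), "nothing to calculate")
  expect_error(partitionModel(m, "R9"), "unknown observed")
  # a single balance cannot determine two fluxes
  m1 <- parseReactionTable("external: X\nR1: A -> X\nR2: A -> X\nR3: X -> A")
  expect_error(partitionModel(m1, "R3"), "underdetermined")
  # recombining the blocks in recorded order reproduces S exactly
  sc <- makeToyNetwork(8, 12, seed = 2)
  p2 <- partitionModel(sc@model, sc@observed)
  S <- stoichiometry(sc@model)
  recombined <- matrix(0, nrow(S), ncol(S))
  recombined[, p2@calcIdx] <- p2@Sc
  recombined[, p2@obsIdx] <- p2@So
  expect_identical(recombined, unname(S))
})

test_that("condition number matches an independent SVD-based oracle", {
  expect_equal(conditionNumber(diag(3)), 1)
  expect_equal(conditionNumber(diag(c(10, 1))), 10)
  set.seed(42)
  M <- matrix(rnorm(15), 5, 3)
  expect_equal(conditionNumber(M), kappa(M, exact = TRUE), tolerance = 1e-10)
  expect_warning(cn <- conditionNumber(matrix(c(1, 1, 2, 2), 2)),
                 "rank-deficient")
  expect_identical(cn, Inf)
})

test_that("nullspace basis is orthonormal, annihilating, and right-sized", {
  K <- nullspaceBasis(matrix(c(1, -1), 1))
  expect_equal(abs(drop(crossprod(K, c(1, 1) / sqrt(2)))), 1,
               tolerance = 1e-12)
  expect_warning(K0 <- nullspaceBasis(diag(3)), "trivial nullspace")
  expect_identical(ncol(K0), 0L)
  # rank-nullity across random models
  for (seed in 1:5) {
    sc <- makeToyNetwork(8, 12, seed = seed)
    S <- stoichiometry(sc@model)
    K <- nullspaceBasis(S)
    expect_identical(qr(S)$rank + ncol(K), ncol(S))
    expect_lt(max(abs(S %*% K)), 1e-10)
    expect_equal(crossprod(K), diag(ncol(K)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("serialization round-trips and summary/SBML readers work", {
  sc <- makeToyNetwork(8, 12, seed = 4)
  m2 <- parseReactionTable(serializeReactionTable(sc@model))
  expect_equal(stoichiometry(m2)[speciesNames(sc@model), ],
               stoichiometry(sc@model))
  tf <- tempfile(fileext = ".tsv")
  writeModelSummary(sc@model, tf)
  df <- read.delim(tf)
  expect_identical(df$species, speciesNames(sc@model))

  sbml <- paste0(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3">',
    '<model><listOfSpecies>',
    '<species id="A"/><species id="B"/>',
    '<species id="Ax" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="up" reversible="false">',
    '<listOfReactants><speciesReference species="Ax"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '</reaction>',
    '<reaction id="conv" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="2"/>',
    '</listOfReactants>',
    '<listOfProducts><speciesReference species="B"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  tf2 <- tempfile(fileext = ".xml")
  writeLines(sbml, tf2)
  m3 <- readSBMLModel(tf2)
  expect_identical(stoichiometry(m3),
                   matrix(c(1, 0, -2, 1), 2,
                          dimnames = list(c("A", "B"), c("up", "conv"))))
  expect_identical(unname(reversible(m3)), c(FALSE, TRUE))
})
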