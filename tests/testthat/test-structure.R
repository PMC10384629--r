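test_that("PDB ATOM parsing keeps heavy atoms of standard residues", {
  txt <- pdbText(data.frame(chain = "A", resno = c(56, 143),
                            resid = c("PHE", "MET"),
                            elety = c("CB", "SD"),
                            x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  m <- readStructure(txt)
  expect_equal(nrow(m@atoms), 2)
  expect_equal(m@atoms$x, c(0, 3))
  expect_error(readStructure("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00"),
               "no ATOM records")
  # a column-drifted coordinate field is rejected with the line number
  good <- strsplit(txt, "\n")[[1]][1]
  bad <- paste0(substr(good, 1, 30), "    ", substr(good, 31, nchar(good)))
  expect_error(readStructure(bad), "coordinate field.*line 1")
})

test_that("non-standard residues are skipped with a warning", {
  txt <- paste(
    pdbText(data.frame(chain = "A", resno = 1, resid = "PHE",
                       elety = "CB", x = 0, y = 0, z = 0)),
    pdbText(data.frame(chain = "A", resno = 2, resid = "MSE",
                       elety = "SE", x = 1, y = 1, z = 1)),
    sep = "\n")
  expect_warning(m <- readStructure(txt), "MSE")
  expect_equal(nrow(m@atoms), 1)
})

test_that("side-chain distances use the closest heavy-atom pair", {
  txt <- pdbText(data.frame(chain = "A", resno = c(56, 143),
                            resid = c("PHE", "MET"),
                            elety = c("CB", "SD"),
                            x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  m <- readStructure(txt)
  expect_equal(sidechainMinDistance(m, c("A", 56), c("A", 143)), 5)
  # symmetric in its arguments; zero against itself
  expect_equal(sidechainMinDistance(m, c("A", 143), c("A", 56)), 5)
  expect_equal(sidechainMinDistance(m, c("A", 56), c("A", 56)), 0)
  expect_error(sidechainMinDistance(m, c("A", 56), c("A", 999)),
               "not found")
})

test_that("multi-atom residues match the exhaustive all-pairs oracle", {
  set.seed(50)
  at <- data.frame(
    chain = "A",
    resno = rep(c(10, 20), c(4, 5)),
    resid = rep(c("LYS", "TRP"), c(4, 5)),
    elety = c("CB", "CG", "CD", "CE", "CB", "CG", "CD1", "CD2", "CE2"),
    x = runif(9, -10, 10), y = runif(9, -10, 10), z = runif(9, -10, 10))
  m <- readStructure(pdbText(at))
  A <- as.matrix(at[at$resno == 10, c("x", "y", "z")])
  B <- as.matrix(at[at$resno == 20, c("x", "y", "z")])
  brute <- min(apply(A, 1, function(p)
    apply(B, 1, function(q) sqrt(sum((p - q)^2)))))
  expect_equal(sidechainMinDistance(m, c("A", 10), c("A", 20)), brute,
               tolerance = 1e-4)
})

test_that("distances are invariant under rigid rotation and translation", {
  set.seed(51)
  at <- data.frame(
    chain = "A", resno = rep(c(1, 2), each = 3),
    resid = "LEU", elety = rep(c("CB", "CG", "CD1"), 2),
    x = runif(6, -5, 5), y = runif(6, -5, 5), z = runif(6, -5, 5))
  d0 <- sidechainMinDistance(readStructure(pdbText(at)),
                             c("A", 1), c("A", 2))
  for (i in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    shift <- rnorm(3, sd = 20)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(Q)
    at2 <- at
    at2$x <- xyz[, 1] + shift[1]
    at2$y <- xyz[, 2] + shift[2]
    at2$z <- xyz[, 3] + shift[3]
    d1 <- sidechainMinDistance(readStructure(pdbText(at2)),
                               c("A", 1), c("A", 2))
    # PDB text carries 3 decimals, so agreement is limited to ~2e-3 A
    expect_equal(d1, d0, tolerance = 5e-3)
  }
})

test_that("glycine falls back to its alpha carbon", {
  at <- data.frame(chain = "A", resno = c(1, 1, 2),
                   resid = c("GLY", "GLY", "MET"),
                   elety = c("N", "CA", "SD"),
                   x = c(5, 0, 6), y = c(0, 0, 8), z = 0)
  m <- readStructure(pdbText(at))
  expect_message(d <- sidechainMinDistance(m, c("A", 1), c("A", 2)),
                 "falling back to CA")
  expect_equal(d, 10)
})

test_that("proximity classes partition the distance axis", {
  expect_equal(as.character(classifyLoopProximity(c(3.4, 5.7, 5.8))),
               rep("close", 3))
  expect_equal(as.character(classifyLoopProximity(c(6.8, 8.0))),
               rep("middle", 2))
  expect_equal(as.character(classifyLoopProximity(8.7)), "far")
  # every non-negative distance lands in exactly one class
  d <- seq(0, 15, by = 0.1)
  cls <- classifyLoopProximity(d)
  expect_false(anyNA(cls))
  expect_error(classifyLoopProximity(-1), "non-negative")
  # configurable thresholds
  expect_equal(as.character(classifyLoopProximity(7, close_max = 7.5,
                                                  middle_max = 9)),
               "close")
})

test_that("proximity reports combine distances and classes", {
  txt <- pdbText(data.frame(chain = "A", resno = c(56, 143),
                            resid = c("PHE", "MET"),
                            elety = c("CB", "SD"),
                            x = c(0, 3), y = c(0, 4), z = c(0, 0)))
  m <- readStructure(txt)
  rep <- proximityReport(m, data.frame(chain_a = "A", resno_a = 56,
                                       chain_b = "A", resno_b = 143))
  expect_equal(rep$distance_A, 5)
  expect_equal(rep$class, "close")
})
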