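# helper: matrix with hand-set blocks on a generic-number axis
toy_matrix <- function(id, gns, cells = list(), name = "LEU") {
  blocks <- lapply(seq_along(gns), function(i) sift2d:::empty_block())
  for (cl in cells) {  # cl = list(block, row, col, value)
    blocks[[cl[[1]]]][cl[[2]], cl[[3]]] <- as.integer(cl[[4]])
  }
  interaction_matrix(
    blocks,
    tibble::tibble(chain = "A", seqnum = seq_along(gns), insertion_code = "",
                   name = name, generic_number = gns, present = TRUE),
    complex_id = id)
}

bin_fp <- function(values) {
  structure(list(values = values, binary = TRUE, index_map = NULL,
                 params_fingerprint = "test"), class = "sift2d_fingerprint")
}

test_that("linearization walks incrementable cells in canonical order", {
  mask_size <- sum(increment_mask())
  z <- toy_matrix("z", c("3x32", "3x33"))
  fp <- to_linear(z)
  expect_equal(fp$values, rep(0, 2 * mask_size))
  m <- toy_matrix("m", c("3x32", "3x33"),
                  list(list(2L, "R", "R", 2L)))
  fp_c <- to_linear(m, binary = FALSE)
  hit <- which(fp_c$values != 0)
  expect_length(hit, 1L)
  expect_equal(fp_c$values[hit], 2)
  expect_equal(fp_c$index_map$residue[hit], "3x33")
  expect_equal(fp_c$index_map$feature[hit], "R")
  expect_equal(fp_c$index_map$interaction[hit], "R")
  fp_b <- to_linear(m, binary = TRUE)
  expect_equal(fp_b$values[hit], 1)
  # nonzero positions of the binary form == nonzero incrementable cells
  cx <- make_random_complex(3, probe = "carboxylate", seed = 21)
  mm <- build_matrix(cx)
  nz_cells <- sum(vapply(mm$blocks, function(b) sum(b[mm$mask] > 0), 0L))
  expect_equal(sum(to_linear(mm, binary = TRUE)$values), nz_cells)
})

test_that("tanimoto obeys its set-overlap definition and conventions", {
  a <- bin_fp(c(1, 1, 0, 0))
  b <- bin_fp(c(1, 0, 1, 0))
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(b, a), 1 / 3)  # symmetry
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(a, bin_fp(c(0, 0, 1, 1))), 0.0)
  expect_equal(tanimoto(bin_fp(rep(0, 4)), bin_fp(rep(0, 4))), 1.0)
  expect_error(tanimoto(a, bin_fp(rep(1, 5))), "length mismatch")
  cnt <- structure(list(values = c(2, 0), binary = FALSE),
                   class = "sift2d_fingerprint")
  expect_error(tanimoto(cnt, cnt), "binary")
  # bounds + identity on random binary vectors
  set.seed(1)
  for (i in 1:20) {
    x <- bin_fp(rbinom(30, 1, 0.3))
    y <- bin_fp(rbinom(30, 1, 0.3))
    s <- tanimoto(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
    if (any(x$values > 0) && s == 1) expect_equal(x$values, y$values)
  }
})

test_that("euclidean distance satisfies the metric axioms", {
  fp <- function(v) structure(list(values = v, binary = FALSE,
                                   params_fingerprint = "test"),
                              class = "sift2d_fingerprint")
  expect_equal(euclidean(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 0)
  expect_equal(euclidean(fp(c(0, 0)), fp(c(3, 4))), 5)
  # a count vector vs its binarization where one cell is 2
  expect_equal(euclidean(fp(c(2, 1, 0)), fp(c(1, 1, 0))), 1)
  expect_error(euclidean(fp(1:3), fp(1:4)), "length mismatch")
  set.seed(2)
  for (i in 1:20) {
    x <- fp(rpois(15, 1)); y <- fp(rpois(15, 1)); z <- fp(rpois(15, 1))
    expect_lte(euclidean(x, z), euclidean(x, y) + euclidean(y, z) + 1e-12)
    expect_equal(euclidean(x, y), euclidean(y, x))
  }
})

test_that("generic-number alignment builds the sorted union axis", {
  a <- toy_matrix("a", c("3x32", "3x33"), list(list(1L, "H", "H", 1L)))
  b <- toy_matrix("b", c("3x33", "7x38"), list(list(2L, "H", "H", 1L)))
  al <- align_by_generic(list(a, b))
  expect_equal(al[[1]]$residues$generic_number, c("3x32", "3x33", "7x38"))
  expect_equal(al[[1]]$residues$present, c(TRUE, TRUE, FALSE))
  expect_equal(al[[2]]$residues$present, c(FALSE, TRUE, TRUE))
  # shared position lands in the same band; absent-filled blocks are zero
  expect_equal(sum(al[[2]]$blocks[[1]]), 0L)
  expect_equal(al[[2]]$blocks[[3]]["H", "H"], 1L)
  # single matrix: unchanged content on its own sorted axis
  solo <- align_by_generic(list(b))[[1]]
  expect_identical(solo$blocks, b$blocks)
  # idempotence
  expect_identical(lapply(align_by_generic(al), `[[`, "blocks"),
                   lapply(al, `[[`, "blocks"))
  # permutation invariance of the axis and content
  al_rev <- align_by_generic(list(b, a))
  expect_identical(al_rev[[2]]$blocks, al[[1]]$blocks)
  # bulge positions sort between their neighbours (5x461 inside 5x46..5x47)
  bulge <- toy_matrix("c", c("5x47", "5x461", "5x46"))
  expect_equal(align_by_generic(list(bulge))[[1]]$residues$generic_number,
               c("5x46", "5x461", "5x47"))
  # duplicate generic numbers within one matrix are a data error
  dup <- toy_matrix("d", c("3x32", "3x32"))
  expect_error(align_by_generic(list(dup)), "duplicate")
  # residues without a generic number are dropped with a warning
  nog <- toy_matrix("e", c("3x32", NA))
  expect_warning(align_by_generic(list(nog)), "without generic number")
})

test_that("matrix JSON serialization round-trips losslessly", {
  set.seed(7)
  gns <- c("1x50", "3x32", "5x461")
  cells <- list(list(1L, "A", "D", 1L), list(2L, "R", "R", 2L),
                list(3L, "vdW", "Any", 1L))
  m <- toy_matrix("roundtrip", gns, cells)
  path <- withr::local_tempfile(fileext = ".json")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(m2$blocks, m$blocks)
  expect_equal(as.data.frame(m2$residues), as.data.frame(m$residues))
  expect_identical(m2$params_fingerprint, m$params_fingerprint)
  expect_identical(m2$mask, m$mask)
  # empty matrix round-trips
  e <- interaction_matrix(list(), tibble::tibble(
    chain = character(), seqnum = integer(), insertion_code = character(),
    name = character(), generic_number = character(), present = logical()))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_matrix(e, p2)
  expect_length(read_matrix(p2)$blocks, 0L)
  # corrupted shape is a named error
  payload <- jsonlite::read_json(path)
  payload$blocks[[2]] <- payload$blocks[[2]][1:3]
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload, p3, auto_unbox = TRUE)
  expect_error(read_matrix(p3), "block 2")
  # version guard
  payload2 <- jsonlite::read_json(path)
  payload2$version <- 99L
  p4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(payload2, p4, auto_unbox = TRUE)
  expect_error(read_matrix(p4), "version")
})

test_that("profiles serialize through the same schema family", {
  m <- toy_matrix("p", c("3x32", "3x33"), list(list(1L, "H", "H", 1L)))
  prof <- average_profile(list(m, m, m), threshold = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_matrix(prof, path)
  p2 <- read_matrix(path)
  expect_s3_class(p2, "sift2d_profile")
  expect_equal(p2$blocks, prof$blocks)
  expect_equal(p2$threshold, 0.3)
  expect_equal(p2$support, prof$support)
})
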