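# toy matrices on a shared generic-number axis
pmat <- function(id, gns, cells = list()) {
  blocks <- lapply(seq_along(gns), function(i) sift2d:::empty_block())
  for (cl in cells) blocks[[cl[[1]]]][cl[[2]], cl[[3]]] <- as.integer(cl[[4]])
  interaction_matrix(
    blocks,
    tibble::tibble(chain = "A", seqnum = seq_along(gns), insertion_code = "",
                   name = "LEU", generic_number = gns, present = TRUE),
    complex_id = id)
}
hb_cells <- list(list(1L, "D", "A", 1L), list(1L, "D", "Any", 1L))
hp_cells <- list(list(1L, "H", "H", 1L), list(1L, "H", "Any", 1L))

test_that("averaging silences values strictly below the threshold", {
  axis <- c("3x32", "5x42")
  on <- pmat("on", axis, hb_cells)
  off <- pmat("off", axis)
  # identical matrices: profile equals the matrix (integer cells >= 1 survive)
  p <- average_profile(rep(list(on), 10))
  expect_equal(p$blocks[[1]]["D", "A"], 1)
  # 2 of 10 -> 0.2, silenced; 3 of 10 -> 0.3, retained (strict "lower than")
  p2 <- average_profile(c(rep(list(on), 2), rep(list(off), 8)))
  expect_equal(p2$blocks[[1]]["D", "A"], 0)
  p3 <- average_profile(c(rep(list(on), 3), rep(list(off), 7)))
  expect_equal(p3$blocks[[1]]["D", "A"], 0.3)
  # single matrix at threshold 0 equals the matrix cast to reals
  p4 <- average_profile(list(on), threshold = 0)
  expect_equal(p4$blocks, lapply(on$blocks, function(b) b * 1.0))
  # silencing is idempotent
  p5 <- average_profile(c(rep(list(on), 3), rep(list(off), 7)))
  expect_equal(p5$blocks, p3$blocks)
  # incompatible parameter sets refuse to average
  alt <- build_matrix(make_random_complex(1, "methyl", seed = 2),
                      params = geometry_params(contact_dist = 4.0))
  expect_error(average_profile(list(on, alt)), "different parameters")
})

test_that("denominator modes differ exactly on absent positions", {
  a <- pmat("a", c("3x32", "3x33"), hb_cells)
  b <- pmat("b", "3x32", hb_cells)
  al <- suppressWarnings(align_by_generic(list(a, b)))
  p_all <- average_profile(al, threshold = 0, denominator_mode = "all_matrices")
  p_pres <- average_profile(al, threshold = 0, denominator_mode = "present_only")
  expect_equal(p_all$blocks[[1]]["D", "A"], 1)    # both present, both set
  expect_equal(p_all$blocks[[2]]["D", "A"], 0)    # only a covers 3x33
  expect_equal(p_pres$blocks[[2]]["D", "A"], 0)
  expect_equal(p_all$support, c(2L, 1L))
})

test_that("contact frequency counts interacting structures per position", {
  axis <- "3x32"
  on <- pmat("on", axis, hp_cells)
  off <- pmat("off", axis)
  mats <- c(rep(list(on), 25), rep(list(off), 10))
  fr <- contact_frequency(mats)
  expect_equal(fr$positions$frequency, 25 / 35, tolerance = 1e-12)
  # order invariance
  fr2 <- contact_frequency(rev(mats))
  expect_equal(fr2$positions, fr$positions)
  # single matrix: fractions in {0, 1}
  fr3 <- contact_frequency(list(on))
  expect_true(all(fr3$positions$frequency %in% c(0, 1)))
  # cell table carries category labels
  expect_true(all(c("hydrophobic", "any") %in% fr$cells$category))
})

test_that("hotspot selection is strictly greater than the cutoff", {
  mk <- function(frac, gn) {
    n_on <- round(frac * 100)
    c(rep(list(pmat("x", gn, hp_cells)), n_on),
      rep(list(pmat("x", gn)), 100 - n_on))
  }
  # fractions 0.31 / 0.30 / 0.29 on three positions
  mats <- lapply(seq_len(100), function(i) {
    cells <- list()
    if (i <= 31) cells <- c(cells, list(list(1L, "H", "H", 1L)))
    if (i <= 30) cells <- c(cells, list(list(2L, "H", "H", 1L)))
    if (i <= 29) cells <- c(cells, list(list(3L, "H", "H", 1L)))
    pmat(paste0("m", i), c("2x60", "3x32", "6x48"), cells)
  })
  hs <- hotspots(contact_frequency(mats), 0.30)
  expect_equal(hs$position, "2x60")
  # empty table
  expect_equal(nrow(hotspots(contact_frequency(list(pmat("z", "3x32"))))), 0L)
  # all positions at 1.0: everything, in axis order
  full <- pmat("f", c("7x38", "3x32"),
               list(list(1L, "H", "H", 1L), list(2L, "H", "H", 1L)))
  al <- align_by_generic(list(full))
  hs2 <- hotspots(contact_frequency(al), 0.30)
  expect_equal(hs2$position, c("3x32", "7x38"))
  # min_fraction 0 returns every contacting position
  hs3 <- hotspots(contact_frequency(mats), 0)
  expect_setequal(hs3$position, c("2x60", "3x32", "6x48"))
})

test_that("differential profiles contrast interaction chemistry per position", {
  axis <- c("3x32", "5x42", "7x38")
  # a: hydrogen-bonding at 3x32 and 5x42; b: hydrophobic at 3x32, unique 7x38
  a1 <- pmat("a1", axis, c(hb_cells, list(list(2L, "D", "A", 1L),
                                          list(2L, "D", "Any", 1L))))
  b1 <- pmat("b1", axis, list(list(1L, "H", "H", 1L), list(1L, "H", "Any", 1L),
                              list(3L, "H", "H", 1L), list(3L, "H", "Any", 1L)))
  pa <- average_profile(list(a1), threshold = 0)
  pb <- average_profile(list(b1), threshold = 0)
  d <- differential_profile(pa, pb)
  expect_equal(d$positions$status, c("common", "unique_to_a", "unique_to_b"))
  expect_equal(d$blocks[[1]]["D", "A"], 1)
  expect_equal(d$blocks[[1]]["H", "H"], -1)
  # identical profiles: all common, zero differences
  d0 <- differential_profile(pa, pa)
  expect_true(all(vapply(d0$blocks, function(b) all(b == 0), TRUE)))
  expect_true(all(d0$positions$status %in% c("common", "absent")))
  # mismatched axes refuse to compare
  pc <- average_profile(list(pmat("c", "3x32", hb_cells)), threshold = 0)
  expect_error(differential_profile(pa, pc), "axis")
})

test_that("outlier ranking orders matrices by distance from the consensus", {
  axis <- c("3x32", "5x42")
  base <- pmat("base", axis, hb_cells)
  odd <- pmat("aaa_odd", axis, c(hb_cells, list(list(2L, "H", "H", 1L),
                                                list(2L, "H", "Any", 1L))))
  mats <- c(rep(list(base), 9), list(odd))
  for (i in 1:9) mats[[i]]$complex_id <- paste0("base", i)
  prof <- average_profile(mats, threshold = 0)
  rk <- outlier_scan(mats, prof)
  expect_equal(rk$complex_id[1], "aaa_odd")
  expect_equal(rk$rank, 1:10)
  # a matrix equal to the profile of identical matrices is at distance 0
  prof_id <- average_profile(rep(list(base), 5), threshold = 0)
  rk2 <- outlier_scan(list(base), prof_id)
  expect_equal(rk2$distance, 0)
  # ties break deterministically by complex id
  t1 <- base; t1$complex_id <- "zeta"
  t2 <- base; t2$complex_id <- "alpha"
  rk3 <- outlier_scan(list(t1, t2), prof_id)
  expect_equal(rk3$complex_id, c("alpha", "zeta"))
})
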