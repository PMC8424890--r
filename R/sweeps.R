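# Boundary sweeps: probe each geometric criterion across a fine grid and
# report the extreme value at which it still fires. Used to verify the
# printed cutoffs and by the acceptance script.

SWEEP_TARGETS <- list(
  contact_distance = list(from = 3.00, to = 4.00, by = 0.01,
                          extreme = "max", units = "Angstrom"),
  hbond_distance = list(from = 2.50, to = 3.20, by = 0.01,
                        extreme = "max", units = "Angstrom"),
  hbond_donor_angle = list(from = 100, to = 140, by = 0.1,
                           extreme = "max", units = "degrees"),
  hbond_acceptor_angle = list(from = 70, to = 110, by = 0.1,
                              extreme = "max", units = "degrees"),
  pi_ff_distance = list(from = 4.00, to = 5.00, by = 0.01,
                        extreme = "max", units = "Angstrom"),
  pi_ef_distance = list(from = 5.00, to = 6.00, by = 0.01,
                        extreme = "max", units = "Angstrom"),
  pi_cation_distance = list(from = 6.00, to = 7.00, by = 0.01,
                            extreme = "max", units = "Angstrom"),
  pi_ff_angle = list(from = 20, to = 40, by = 0.1,
                     extreme = "max", units = "degrees"),
  pi_ef_angle = list(from = 50, to = 70, by = 0.1,
                     extreme = "min", units = "degrees"))

# exact planar ring (hexagon by default) for stacking sweeps
ring_coords <- function(centroid, normal, radius = 1.39, n = 6L) {
  normal <- unit(normal)
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(pracma_cross(normal, ref))
  e2 <- pracma_cross(normal, e1)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  t(vapply(ang, function(a) {
    centroid + radius * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

sweep_detect <- function(target, value, params) {
  switch(target,
    contact_distance = {
      res <- sweep_residue("LEU")
      anchor <- anchor_info("methyl", res)
      probe <- matrix(anchor$point + value * anchor$dir, 1L)
      detect_contact(probe, res, params)$any
    },
    hbond_distance = {
      Y <- c(0, 0, 0); H <- c(0, 0, 1.0); X <- c(0, 0, 1.0 + value)
      detect_hbond(Y, rbind(H), X, rbind(X + c(0, 0, 1.2)), params)
    },
    hbond_donor_angle = {
      H <- c(0, 0, 1); X <- c(0, 0, 3)  # H...X fixed at 2.0 Angstrom
      th <- (180 - value) * pi / 180
      Y <- H + c(sin(th), 0, cos(th))
      detect_hbond(Y, rbind(H), X, rbind(X + c(0, 0, 1.2)), params)
    },
    hbond_acceptor_angle = {
      Y <- c(0, 0, 0); H <- c(0, 0, 1); X <- c(0, 0, 3)
      th <- (180 - value) * pi / 180  # angle(H, X, ante) = 180 - deviation
      ante <- X + 1.2 * c(sin(th), 0, -cos(th))
      detect_hbond(Y, rbind(H), X, rbind(ante), params)
    },
    pi_ff_distance = {
      a <- list(coords = ring_coords(c(0, 0, 0), c(0, 0, 1)))
      b <- list(coords = ring_coords(c(0, 0, value), c(0, 0, 1)))
      detect_aromatic(a, b, params) == "face_to_face"
    },
    pi_ef_distance = {
      a <- list(coords = ring_coords(c(0, 0, 0), c(0, 0, 1)))
      b <- list(coords = ring_coords(c(0, 0, value), c(1, 0, 0)))
      detect_aromatic(a, b, params) == "edge_to_face"
    },
    pi_cation_distance = {
      res <- sweep_residue("LYS")
      nz <- residue_coords(res, names = "NZ")[1L, ]
      ring <- list(coords = ring_coords(nz + c(0, 0, value), c(0, 0, 1)))
      detect_pi_cation(best_fit_plane(ring$coords)$centroid, nz, params)
    },
    pi_ff_angle = {
      a <- list(coords = ring_coords(c(0, 0, 0), c(0, 0, 1)))
      nb <- c(sin(value * pi / 180), 0, cos(value * pi / 180))
      b <- list(coords = ring_coords(c(0, 0, 4.0), nb))
      detect_aromatic(a, b, params) == "face_to_face"
    },
    pi_ef_angle = {
      a <- list(coords = ring_coords(c(0, 0, 0), c(0, 0, 1)))
      nb <- c(sin(value * pi / 180), 0, cos(value * pi / 180))
      b <- list(coords = ring_coords(c(0, 0, 5.0), nb))
      detect_aromatic(a, b, params) == "edge_to_face"
    },
    stop("unknown sweep target: ", target, call. = FALSE))
}

sweep_residue <- function(name) {
  key <- paste0("sweep_res_", name)
  if (is.null(.sift2d_cache[[key]])) {
    .sift2d_cache[[key]] <- residue_template(name)
  }
  .sift2d_cache[[key]]
}

#' Sweep a geometric criterion across a grid of values
#'
#' Constructs, per grid point, an exact probe geometry for the chosen
#' criterion (a methyl carbon approaching a leucine side chain; a collinear
#' donor-H...acceptor triplet; parallel or perpendicular rings; a benzene
#' centroid above a lysine ammonium) and runs the package's detector on it.
#' The `boundary` of the result is the largest (or, for the edge-to-face
#' angle, smallest) value at which the interaction is still detected.
#'
#' @param target one of contact_distance, hbond_distance, hbond_donor_angle,
#'   hbond_acceptor_angle, pi_ff_distance, pi_ef_distance, pi_cation_distance,
#'   pi_ff_angle, pi_ef_angle.
#' @param from,to,by sweep grid; defaults per target (0.01 Angstrom or 0.1
#'   degree resolution around the published cutoff).
#' @param params [geometry_params()].
#' @return list with `table` (tibble value/detected), `boundary`, `n`
#'   (grid size), `units`.
#' @export
boundary_sweep <- function(target, from = NULL, to = NULL, by = NULL,
                           params = geometry_params()) {
  target <- match.arg(target, names(SWEEP_TARGETS))
  cfg <- SWEEP_TARGETS[[target]]
  if (is.null(from)) from <- cfg$from
  if (is.null(to)) to <- cfg$to
  if (is.null(by)) by <- cfg$by
  values <- round(seq(from, to, by = by), 10)
  detected <- vapply(values, function(v) sweep_detect(target, v, params),
                     logical(1))
  hit <- values[detected]
  boundary <- if (length(hit) == 0L) NA_real_
              else if (cfg$extreme == "max") max(hit) else min(hit)
  list(table = tibble::tibble(value = values, detected = detected),
       boundary = boundary, n = length(values), units = cfg$units,
       target = target)
}
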